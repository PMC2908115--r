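# Trial filtering, pooling and the response transforms applied before
# modeling: reaction times are analyzed as -1/RT (seconds) and threshold
# presentation times on the natural-log scale.

#' Filtering rules for raw trial logs
#'
#' Defaults mirror the reaction-time analysis of the training data: drop
#' the very first feedback-training block (task familiarization), keep
#' correct answers only, and keep reaction times inside fixed cutpoints
#' (values exactly at a cutpoint are kept; only times strictly below the
#' lower or strictly above the upper bound are dismissed). Rules are
#' applied in a fixed order -- malformed rows, first training block,
#' correctness, RT bounds -- and each dropped row is attributed to the
#' first rule it fails.
#'
#' @param rt_lower,rt_upper reaction-time cutpoints in ms (`NULL` disables
#'   the bound check). Presets: 500-2000 for the pooled training data of
#'   experiments 1-4, 500-8000 for experiment 5, 500-4000 for experiment 6.
#' @param correct_only keep only trials answered correctly.
#' @param drop_first_training_block drop `phase == "training", block == 1`.
#' @param experiments_pooled experiment ids to keep (and pool); `NULL`
#'   keeps all.
#' @return an object of class `filter_spec`.
#' @export
filter_spec <- function(rt_lower = 500, rt_upper = 2000, correct_only = TRUE,
                        drop_first_training_block = TRUE,
                        experiments_pooled = NULL) {
  if (!is.null(rt_lower) && !is.null(rt_upper) && !(rt_lower < rt_upper))
    stop("need 0 < rt_lower < rt_upper")
  structure(list(rt_lower = rt_lower, rt_upper = rt_upper,
                 correct_only = correct_only,
                 drop_first_training_block = drop_first_training_block,
                 experiments_pooled = experiments_pooled),
            class = "filter_spec")
}

#' Per-experiment filter presets
#'
#' @param experiment integer 1..6; 1/2 return the pooled-training preset
#'   (experiments 1+3 for faces, 2+4 for shoes).
#' @return a [filter_spec()].
#' @export
default_filter_spec <- function(experiment) {
  switch(as.character(experiment),
    "1" = filter_spec(500, 2000, experiments_pooled = c(1, 3)),
    "2" = filter_spec(500, 2000, experiments_pooled = c(2, 4)),
    "3" = filter_spec(500, 2000, experiments_pooled = 3),
    "4" = filter_spec(500, 2000, experiments_pooled = 4),
    "5" = filter_spec(500, 8000, drop_first_training_block = FALSE,
                      experiments_pooled = 5),
    "6" = filter_spec(500, 4000, experiments_pooled = 6),
    stop("configuration error: unknown experiment id"))
}

#' Filter trials and account for every dropped row
#'
#' Order-preserving and idempotent; the audit reconciles exactly:
#' `input = kept + sum(dropped per rule)`.
#'
#' @param trials trial-record data.frame.
#' @param spec a [filter_spec()].
#' @return list with `trials` (kept rows) and `audit` (named counts).
#' @export
filter_trials <- function(trials, spec) {
  stopifnot(inherits(spec, "filter_spec"))
  need <- c("participant_id", "experiment", "phase", "block",
            "response_correct", "reaction_ms")
  miss <- setdiff(need, names(trials))
  if (length(miss)) stop("trial log is missing columns: ",
                         paste(miss, collapse = ", "))
  n <- nrow(trials)
  reason <- rep(NA_character_, n)

  malformed <- is.na(trials$response_correct) |
    !trials$response_correct %in% c(0, 1) |
    is.na(trials$experiment) | is.na(trials$block)
  reason[malformed] <- "malformed"
  if (mean(malformed) > 0.10)
    stop("more than 10% of rows are malformed; refusing to continue")

  if (!is.null(spec$experiments_pooled)) {
    bad <- is.na(reason) & !trials$experiment %in% spec$experiments_pooled
    reason[bad] <- "experiment_not_pooled"
  }
  if (isTRUE(spec$drop_first_training_block)) {
    bad <- is.na(reason) & trials$phase == "training" & trials$block == 1
    reason[bad] <- "first_training_block"
  }
  if (isTRUE(spec$correct_only)) {
    bad <- is.na(reason) & trials$response_correct == 0
    reason[bad] <- "incorrect_answer"
  }
  if (!is.null(spec$rt_lower)) {
    bad <- is.na(reason) & (is.na(trials$reaction_ms) |
      trials$reaction_ms < spec$rt_lower |
      trials$reaction_ms > spec$rt_upper)
    reason[bad] <- "rt_outside_bounds"
  }
  kept <- trials[is.na(reason), , drop = FALSE]
  dropped <- table(factor(reason, levels = c("malformed",
    "experiment_not_pooled", "first_training_block", "incorrect_answer",
    "rt_outside_bounds")))
  audit <- c(list(input = n), lapply(as.list(dropped), as.integer),
             list(kept = nrow(kept)))
  list(trials = kept, audit = audit)
}

#' Inverse reaction-time transform
#'
#' Maps a reaction time in ms to `-1/RT` in 1/seconds: 500 ms becomes -2,
#' 2000 ms becomes -0.5. Strictly increasing (slower responses map to
#' larger values) and invertible via [inverse_rt_to_ms()].
#'
#' @param rt_ms reaction time(s) in ms (> 0).
#' @return transformed value(s), 1/seconds.
#' @export
transform_inverse_rt <- function(rt_ms) {
  if (any(rt_ms <= 0)) stop("reaction time must be positive")
  -1000 / rt_ms
}

#' @rdname transform_inverse_rt
#' @param y transformed value(s) on the -1/RT scale (< 0).
#' @export
inverse_rt_to_ms <- function(y) {
  if (any(y >= 0)) stop("transformed reaction times are negative")
  -1000 / y
}

#' Log-transform of threshold presentation times
#'
#' @param pt80 threshold(s) in ms (> 0).
#' @return natural log of the threshold.
#' @export
transform_pt <- function(pt80) {
  if (any(pt80 <= 0)) stop("presentation time must be positive")
  log(pt80)
}

#' Mean-center a vector of log presentation times
#'
#' @param values numeric vector.
#' @return centered values, summing to zero.
#' @export
center_log_pt <- function(values) values - mean(values)
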