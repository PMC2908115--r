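# Cross-validated normative residual scores: the nullmodel is fitted to
# control observations only and its fixed effects predict the expected
# performance of a hypothetical average control with each participant's
# covariates; averaged residuals from that prediction are per-participant
# abnormality scores. Controls are scored leave-one-out so no participant
# is judged by a reference that saw their own data. Scores are compared
# between groups with rank tests.

#' Fit the reference (nullmodel) on control participants only
#'
#' @param spec a [mixed_model_spec()] (typically the ladder's nullmodel).
#' @param data model frame containing a `group_label` column; CP rows are
#'   ignored, so adding or removing CP observations cannot change the fit.
#' @param exclude participant ids additionally excluded (used for the
#'   leave-one-out control scores).
#' @param ... passed to [fit_mixed_model()].
#' @return a `mixed_model_fit` on the control subset.
#' @export
control_reference_fit <- function(spec, data, exclude = character(), ...) {
  stopifnot("group_label" %in% names(data))
  ctrl <- data[data$group_label == "control" &
                 !data$participant_id %in% exclude, , drop = FALSE]
  if (length(unique(ctrl$participant_id)) < 2)
    stop("need >= 2 control participants for a reference fit")
  fit_mixed_model(spec, ctrl, ...)
}

# fixed-effects-only prediction (random effects zeroed): the expected
# response of an average control with these covariates, on the link scale
.predict_population <- function(fit, newdata) {
  obj <- fit$fit
  if (inherits(obj, "merMod"))
    stats::predict(obj, newdata = newdata, re.form = NA, type = "link",
                   allow.new.levels = TRUE)
  else if (inherits(obj, "glm"))
    stats::predict(obj, newdata = newdata, type = "link")
  else
    stats::predict(obj, newdata = newdata)
}

#' Cross-validated per-participant abnormality scores
#'
#' CP participants are scored against a reference nullmodel fitted to all
#' controls; each control is scored against a reference refitted without
#' that control (leave-one-out). Per-observation residuals are averaged
#' into one score per participant. For Gaussian responses the residual is
#' `observed - predicted` on the modeled (transformed) scale. For binomial
#' responses the default is the link (log-odds) scale -- the participant's
#' empirical logit (with a 0.5/1 continuity adjustment) minus the mean
#' predicted logit -- with `scale = "response"` giving mean `z - p` instead.
#' By default predictions use fixed effects only (random effects zeroed);
#' `conditional = TRUE` instead includes the reference fit's random-effect
#' predictions where available, for sensitivity analysis.
#'
#' @param spec a [mixed_model_spec()] nullmodel.
#' @param data model frame with `group_label`.
#' @param scale residual scale for binomial responses: `"link"` (default)
#'   or `"response"`.
#' @param conditional include random-effect predictions (Gaussian models
#'   fitted with random terms only).
#' @param warm_start reuse the all-controls fit as starting values for the
#'   leave-one-out refits.
#' @param ... passed to the underlying fits.
#' @return data.frame: `participant_id`, `group`, `mean_residual`,
#'   `n_observations`, `reference`.
#' @export
score_participants <- function(spec, data, scale = c("link", "response"),
                               conditional = FALSE, warm_start = TRUE, ...) {
  scale <- match.arg(scale)
  stopifnot(all(c("group_label", "participant_id") %in% names(data)))
  ycol <- .response_col[[spec$response]]
  data <- data[!is.na(data[[ycol]]), , drop = FALSE]
  ref <- control_reference_fit(spec, data, ...)
  if (!ref$converged)
    stop("reference fit did not converge; refusing to score")
  start <- if (warm_start && inherits(ref$fit, "merMod")) {
    th <- lme4::getME(ref$fit, "theta")
    if (spec$family == "binomial-logit")
      list(theta = th, fixef = lme4::fixef(ref$fit)) else th
  }

  score_one <- function(pid, fit, reference) {
    rows <- data[data$participant_id == pid, , drop = FALSE]
    if (nrow(rows) == 0) {
      warning("participant ", pid, " has no eligible observations; omitted")
      return(NULL)
    }
    eta <- .predict_population(fit, rows)
    if (conditional && inherits(fit$fit, "merMod") &&
        pid %in% rownames(lme4::ranef(fit$fit)$participant_id))
      eta <- stats::predict(fit$fit, newdata = rows, type = "link")
    y <- rows[[ycol]]
    res <- if (spec$family == "binomial-logit" && scale == "link") {
      phat <- (sum(y) + 0.5) / (length(y) + 1)
      stats::qlogis(phat) - mean(eta)
    } else if (spec$family == "binomial-logit") {
      mean(y - stats::plogis(eta))
    } else {
      mean(y - eta)
    }
    data.frame(participant_id = pid,
               group = rows$group_label[1],
               mean_residual = res,
               n_observations = nrow(rows),
               reference = reference,
               stringsAsFactors = FALSE)
  }

  cp_ids <- unique(data$participant_id[data$group_label == "cp"])
  ctrl_ids <- unique(data$participant_id[data$group_label == "control"])
  out <- lapply(cp_ids, score_one, fit = ref, reference = "controls-only")
  for (pid in ctrl_ids) {
    loo <- control_reference_fit(spec, data, exclude = pid,
                                 start = start, ...)
    if (!loo$converged)
      loo <- control_reference_fit(spec, data, exclude = pid, ...)
    out[[length(out) + 1L]] <- score_one(pid, loo, "leave-one-out")
  }
  do.call(rbind, Filter(Negate(is.null), out))
}

# midranks and tie counts
.midranks <- function(x) rank(x, ties.method = "average")

#' Wilcoxon rank-sum (Mann-Whitney) test
#'
#' Statistic is the Mann-Whitney U for the first sample (number of pairs
#' `(a, b)` with `a > b`, ties counted half). The exact null distribution
#' is used when the combined sample size is at most 30 and there are no
#' ties; otherwise a normal approximation with continuity and tie
#' correction.
#'
#' @param a,b numeric score vectors (non-empty).
#' @param alternative `"two.sided"`, `"greater"` (a tends larger) or
#'   `"less"`.
#' @return list with `statistic` (U), `p_value`, `exact` flag.
#' @export
wilcoxon_rank_sum <- function(a, b,
                              alternative = c("two.sided", "greater",
                                              "less")) {
  alternative <- match.arg(alternative)
  if (!length(a) || !length(b)) stop("both groups must be non-empty")
  m <- length(a); n <- length(b); N <- m + n
  r <- .midranks(c(a, b))
  u <- sum(r[seq_len(m)]) - m * (m + 1) / 2
  ties <- table(c(a, b))
  has_ties <- any(ties > 1)
  exact <- N <= 30 && !has_ties
  if (exact) {
    p_less <- stats::pwilcox(u, m, n)              # P(U <= u)
    p_greater <- stats::pwilcox(u - 1, m, n, lower.tail = FALSE)
    p <- switch(alternative,
                greater = p_greater, less = p_less,
                two.sided = min(1, 2 * min(p_less, p_greater)))
  } else {
    mu <- m * n / 2
    tie_term <- sum(ties^3 - ties) / (N * (N - 1))
    sigma <- sqrt(m * n / 12 * (N + 1 - tie_term))
    d <- u - mu
    # continuity correction toward the alternative (none exactly at center)
    cc <- switch(alternative, greater = 0.5, less = -0.5,
                 two.sided = sign(d) * 0.5)
    zz <- (d - cc) / sigma
    p <- switch(alternative,
                greater = stats::pnorm(zz, lower.tail = FALSE),
                less = stats::pnorm(zz),
                two.sided = min(1, 2 * min(stats::pnorm(zz),
                                           stats::pnorm(zz,
                                                        lower.tail = FALSE))))
  }
  list(statistic = u, p_value = p, exact = exact)
}

#' Wilcoxon signed-rank test for paired scores
#'
#' Differences of zero are dropped; the statistic is the sum of ranks of
#' positive differences. Exact when n <= 25 with no ties among the absolute
#' differences, normal approximation with continuity and tie correction
#' otherwise.
#'
#' @param paired_a,paired_b equal-length numeric vectors (>= 2 pairs).
#' @param alternative as in [wilcoxon_rank_sum()]; `"greater"` means
#'   `paired_a` tends larger.
#' @return list with `statistic` (V), `p_value`, `exact` flag, `n_used`.
#' @export
wilcoxon_signed_rank <- function(paired_a, paired_b,
                                 alternative = c("two.sided", "greater",
                                                 "less")) {
  alternative <- match.arg(alternative)
  if (length(paired_a) != length(paired_b) || length(paired_a) < 2)
    stop("need equal-length paired vectors with >= 2 pairs")
  d <- paired_a - paired_b
  d <- d[d != 0]
  n <- length(d)
  if (n == 0) {
    warning("all paired differences are zero")
    return(list(statistic = 0, p_value = 1, exact = TRUE, n_used = 0L))
  }
  r <- .midranks(abs(d))
  v <- sum(r[d > 0])
  ties <- table(abs(d))
  has_ties <- any(ties > 1)
  exact <- n <= 25 && !has_ties
  if (exact) {
    p_less <- stats::psignrank(v, n)
    p_greater <- stats::psignrank(v - 1, n, lower.tail = FALSE)
    p <- switch(alternative,
                greater = p_greater, less = p_less,
                two.sided = min(1, 2 * min(p_less, p_greater)))
  } else {
    mu <- n * (n + 1) / 4
    sigma <- sqrt(n * (n + 1) * (2 * n + 1) / 24 -
                    sum(ties^3 - ties) / 48)
    d <- v - mu
    cc <- switch(alternative, greater = 0.5, less = -0.5,
                 two.sided = sign(d) * 0.5)
    zz <- (d - cc) / sigma
    p <- switch(alternative,
                greater = stats::pnorm(zz, lower.tail = FALSE),
                less = stats::pnorm(zz),
                two.sided = min(1, 2 * min(stats::pnorm(zz),
                                           stats::pnorm(zz,
                                                        lower.tail = FALSE))))
  }
  list(statistic = v, p_value = p, exact = exact, n_used = n)
}
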