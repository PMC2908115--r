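# Trial-log generation for the six experiment templates, plus delimited
# trial-log input/output and schema validation.
#
# Experiments 1/2: 2AFC frontal-view recognition of faces/shoes, feedback
#   training to criterion, then staircase-driven test blocks of 8.
# Experiments 3/4: 2AFC recognition under rotation at a fixed presentation
#   time (the CP participant's 90%-criterion time, shared by the triplet).
# Experiment 5: 4AFC delayed matching, 48 stimuli x 4 presentation times.
# Experiment 6: 12 cycles of feedback training plus 32-trial test rounds
#   with durations 50/150/450/750 ms.

TRIAL_LOG_COLUMNS <- c("participant_id", "experiment", "phase", "block",
                       "trial", "stimulus_class", "role", "rotation",
                       "presentation_ms", "response_correct", "reaction_ms")

# triplet key: matched controls share their CP's stimulus orderings
.match_key <- function(id) {
  m <- regmatches(id, regexec("^(?:cp|ct)([0-9]+)", id))[[1]]
  if (length(m) == 2) m[2] else id
}

.trial_rows <- function(profile, experiment, phase, block, trial, role,
                        rotation, presentation_ms, response_correct,
                        reaction_ms, stimulus_class) {
  data.frame(
    participant_id = profile$participant_id, experiment = experiment,
    phase = phase, block = block, trial = trial,
    stimulus_class = stimulus_class, role = role, rotation = rotation,
    presentation_ms = presentation_ms, response_correct = response_correct,
    reaction_ms = reaction_ms, stringsAsFactors = FALSE
  )
}

# one feedback-training round: 16 trials (8 target, 8 distractor),
# unlimited presentation; repeated until at most one error
.training_rounds <- function(profile, experiment, stimulus_class, seed,
                             first_block = 1L, n_trials = 16L,
                             max_rounds = 10L, one_round = FALSE) {
  rows <- list()
  block <- first_block
  p_correct <- 1 - profile$lapse   # unlimited viewing: only lapses err
  repeat {
    s <- derive_seed(seed, "train", block)
    role <- with_seed(derive_seed(seed, "order", block),
                      sample(rep(c("target", "distractor"), n_trials / 2)))
    z <- with_seed(s, as.integer(stats::runif(n_trials) < p_correct))
    rt <- simulate_reaction_time(profile, block,
                                 seed = derive_seed(s, "rt"), n = n_trials)
    rows[[length(rows) + 1L]] <- .trial_rows(
      profile, experiment, "training", block, seq_len(n_trials), role,
      0, Inf, z, rt, stimulus_class)
    done <- one_round || sum(z == 0) <= 1 || (block - first_block + 1L) >= max_rounds
    block <- block + 1L
    if (done) break
  }
  list(trials = do.call(rbind, rows), next_block = block)
}

#' Generate trial logs for one experiment
#'
#' Simulates every observer in `cohort` through the named experiment
#' template. Stimulus orderings (role sequences, rotation orders,
#' counterbalancing) are drawn from a substream keyed on the CP triplet, so
#' matched controls see exactly the same orderings as their CP; answers and
#' reaction times come from per-participant substreams.
#'
#' @param cohort list of [observer_profile()] objects.
#' @param experiment integer 1..6.
#' @param seed root seed for this experiment.
#' @param fixed_pt named vector (by participant_id) of fixed presentation
#'   times in ms for experiments 3/4; when `NULL`, each triplet uses its
#'   CP's true 90 percent-correct time (simulation-only shortcut).
#' @param n_staircase_trials staircase length for experiments 1/2
#'   (multiple of 8).
#' @param staircase list of staircase parameters `x_init`, `c`, `phi`.
#' @return data.frame of trial records (one row per trial, columns
#'   `participant_id, experiment, phase, block, trial, stimulus_class, role,
#'   rotation, presentation_ms, response_correct, reaction_ms`), with the
#'   per-participant threshold estimates of experiments 1/2 attached as
#'   attribute `estimates` and the experiment-5 counterbalancing table as
#'   attribute `stimulus_assignment`.
#' @export
generate_experiment <- function(cohort, experiment, seed = 1,
                                fixed_pt = NULL, n_staircase_trials = 64,
                                staircase = list(x_init = 200, c = 100,
                                                 phi = 0.8)) {
  if (!experiment %in% 1:6) stop("configuration error: unknown experiment id")
  stimulus_class <- if (experiment %in% c(2, 4)) "shoe" else "face"
  gen <- switch(as.character(experiment),
    "1" = , "2" = .gen_staircase_exp,
    "3" = , "4" = .gen_rotation_exp,
    "5" = .gen_matching_exp,
    "6" = .gen_duration_exp)
  gen(cohort, experiment, stimulus_class, seed, fixed_pt,
      n_staircase_trials, staircase)
}

.gen_staircase_exp <- function(cohort, experiment, stimulus_class, seed,
                               fixed_pt, n_staircase_trials, sc) {
  stopifnot(n_staircase_trials %% 8 == 0, n_staircase_trials >= 24)
  out <- list(); est <- list()
  n_blocks <- n_staircase_trials / 8
  for (profile in cohort) {
    pseed <- derive_seed(seed, "exp", experiment, profile$participant_id)
    oseed <- derive_seed(seed, "exp", experiment, "order",
                         .match_key(profile$participant_id))
    tr <- .training_rounds(profile, experiment, stimulus_class,
                           derive_seed(pseed, "pre"))
    run <- run_staircase(profile, n_trials = n_staircase_trials,
                         x_init = sc$x_init, c = sc$c, phi = sc$phi,
                         seed = derive_seed(pseed, "staircase"))
    # blocks of 8 with every target exactly once (4 target + 4 distractor)
    role <- unlist(lapply(seq_len(n_blocks), function(b)
      with_seed(derive_seed(oseed, "roles", b),
                sample(rep(c("target", "distractor"), 4)))))
    block <- rep(seq_len(n_blocks), each = 8)
    rt <- unlist(lapply(seq_len(n_blocks), function(b)
      simulate_reaction_time(profile, b, seed = derive_seed(pseed, "rt", b),
                             n = 8)))
    test <- .trial_rows(profile, experiment, "test", block,
                        rep(1:8, n_blocks), role, 0,
                        run$trials$presentation_ms,
                        run$trials$response_correct, rt, stimulus_class)
    # mid-test refresher training round
    mid <- .training_rounds(profile, experiment, stimulus_class,
                            derive_seed(pseed, "mid"),
                            first_block = tr$next_block, one_round = TRUE)
    out[[length(out) + 1L]] <- rbind(tr$trials, test, mid$trials)
    est[[profile$participant_id]] <- run$estimate$pt80
  }
  res <- do.call(rbind, out)
  attr(res, "estimates") <- unlist(est)
  res
}

.gen_rotation_exp <- function(cohort, experiment, stimulus_class, seed,
                              fixed_pt, ...) {
  # faces: 7 signed rotation conditions, 2 blocks of 56;
  # shoes: 3 view conditions (coded 0/60/90), 4 blocks of 24
  if (stimulus_class == "face") {
    conditions <- c(0, -30, 30, -60, 60, -90, 90); n_blocks <- 2L
  } else {
    conditions <- c(0, 60, 90); n_blocks <- 4L
  }
  if (is.null(fixed_pt)) {
    cps <- Filter(function(p) p$group == "cp", cohort)
    fixed_pt <- vapply(cps, function(p) {
      f <- (0.8 - p$guess) / (1 - p$guess - p$lapse)
      alpha <- p$true_pt80 - stats::qlogis(f) / p$slope_scale
      m <- psychometric_model(p$guess, p$lapse, max(alpha, 1e-3),
                              p$slope_scale)
      invert_psychometric(m, 0.9)
    }, numeric(1))
    names(fixed_pt) <- vapply(cps, `[[`, character(1), "participant_id")
  }
  out <- list()
  for (profile in cohort) {
    key <- .match_key(profile$participant_id)
    pt_key <- names(fixed_pt)[vapply(names(fixed_pt), .match_key,
                                     character(1)) == key]
    if (length(pt_key) == 0)
      pt_key <- if (profile$participant_id %in% names(fixed_pt))
        profile$participant_id else stop("no fixed presentation time for ",
                                         profile$participant_id)
    pt <- quantize_presentation(fixed_pt[[pt_key[1]]], profile$frame_rate)
    pseed <- derive_seed(seed, "exp", experiment, profile$participant_id)
    oseed <- derive_seed(seed, "exp", experiment, "order", key)
    tr <- .training_rounds(profile, experiment, stimulus_class,
                           derive_seed(pseed, "pre"))
    rows <- list()
    for (b in seq_len(n_blocks)) {
      design <- expand.grid(rotation = conditions,
                            role = c("target", "distractor"),
                            rep = 1:4, stringsAsFactors = FALSE)[, 1:2]
      design <- with_seed(derive_seed(oseed, "shuffle", b),
                          design[sample(nrow(design)), ])
      n <- nrow(design)
      p <- vapply(design$rotation, function(r)
        true_accuracy(profile, pt, r), numeric(1))
      z <- with_seed(derive_seed(pseed, "ans", b),
                     as.integer(stats::runif(n) < p))
      rt <- simulate_reaction_time(profile, b,
                                   seed = derive_seed(pseed, "rt", b), n = n)
      rows[[b]] <- .trial_rows(profile, experiment, "test", b, seq_len(n),
                               design$role, design$rotation, pt, z, rt,
                               stimulus_class)
    }
    out[[length(out) + 1L]] <- rbind(tr$trials, do.call(rbind, rows))
  }
  res <- do.call(rbind, out)
  attr(res, "fixed_pt") <- fixed_pt
  res
}

.gen_matching_exp <- function(cohort, experiment, stimulus_class, seed, ...) {
  # 48 stimuli x 4 presentation times, 4AFC; a cyclic Latin square assigns
  # each stimulus to each presentation time exactly once across 4 blocks
  pts <- c(50, 150, 450, 750)
  out <- list(); assignment <- NULL
  for (profile in cohort) {
    pseed <- derive_seed(seed, "exp", experiment, profile$participant_id)
    oseed <- derive_seed(seed, "exp", experiment, "order",
                         .match_key(profile$participant_id))
    rows <- list()
    for (b in 1:4) {
      stim <- 1:48
      pt_idx <- (stim + b) %% 4 + 1
      ord <- with_seed(derive_seed(oseed, "shuffle", b), sample(48))
      stim <- stim[ord]; pt <- pts[pt_idx[ord]]
      pt <- quantize_presentation(pt, profile$frame_rate)
      p <- vapply(pt, function(d) true_accuracy(profile, d, 0, guess = 0.25),
                  numeric(1))
      z <- with_seed(derive_seed(pseed, "ans", b),
                     as.integer(stats::runif(48) < p))
      rt <- simulate_reaction_time(profile, b,
                                   seed = derive_seed(pseed, "rt", b), n = 48)
      rows[[b]] <- .trial_rows(profile, experiment, "test", b, 1:48,
                               "target", 0, pt, z, rt, stimulus_class)
      if (is.null(assignment) || nrow(assignment) < 192)
        assignment <- rbind(assignment,
                            data.frame(stimulus = stim, block = b,
                                       presentation_ms = pt))
    }
    out[[length(out) + 1L]] <- do.call(rbind, rows)
  }
  res <- do.call(rbind, out)
  attr(res, "stimulus_assignment") <- assignment
  res
}

.gen_duration_exp <- function(cohort, experiment, stimulus_class, seed, ...) {
  # 12 cycles: 8 feedback-training trials then 32 test trials; each cycle's
  # test round shows each of 4 targets once per duration and 8 distractors
  # twice each, durations balanced 4-4-4-4 with no distractor repeated at
  # the same duration
  pts <- c(50, 150, 450, 750)
  out <- list()
  for (profile in cohort) {
    pseed <- derive_seed(seed, "exp", experiment, profile$participant_id)
    oseed <- derive_seed(seed, "exp", experiment, "order",
                         .match_key(profile$participant_id))
    rows <- list()
    for (cyc in 1:12) {
      tr <- .training_rounds(profile, experiment, stimulus_class,
                             derive_seed(pseed, "train", cyc),
                             first_block = cyc, n_trials = 8L,
                             one_round = TRUE)
      tgt_pt <- rep(pts, times = 4)                    # 4 targets x 4 durations
      dis_pt <- pts[c((0:7) %% 4, (1:8) %% 4) + 1]     # 8 distractors x 2, circular
      role <- c(rep("target", 16), rep("distractor", 16))
      pt <- c(tgt_pt, dis_pt)
      ord <- with_seed(derive_seed(oseed, "shuffle", cyc), sample(32))
      role <- role[ord]; pt <- pt[ord]
      pt <- quantize_presentation(pt, profile$frame_rate)
      p <- vapply(pt, function(d) true_accuracy(profile, d, 0), numeric(1))
      z <- with_seed(derive_seed(pseed, "ans", cyc),
                     as.integer(stats::runif(32) < p))
      rt <- simulate_reaction_time(profile, cyc,
                                   seed = derive_seed(pseed, "rt", cyc),
                                   n = 32)
      rows[[length(rows) + 1L]] <- rbind(
        tr$trials,
        .trial_rows(profile, experiment, "test", cyc, 1:32, role, 0, pt, z,
                    rt, stimulus_class))
    }
    out[[length(out) + 1L]] <- do.call(rbind, rows)
  }
  do.call(rbind, out)
}

#' Write a trial log as delimited text
#'
#' Comma-separated with a header row; missing values empty; unlimited
#' presentation written as `Inf`.
#'
#' @param trials trial-record data.frame.
#' @param path output file.
#' @export
write_trial_log <- function(trials, path) {
  stopifnot(all(TRIAL_LOG_COLUMNS %in% names(trials)))
  utils::write.csv(trials[, TRIAL_LOG_COLUMNS], path, row.names = FALSE,
                   na = "", quote = FALSE)
}

#' Read a trial log written by [write_trial_log()]
#'
#' @param path input file.
#' @return trial-record data.frame.
#' @export
read_trial_log <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  missing <- setdiff(TRIAL_LOG_COLUMNS, names(df))
  if (length(missing))
    stop("trial log is missing columns: ", paste(missing, collapse = ", "))
  df
}

#' Validate a trial log against the schema and frame-timing invariant
#'
#' Checks column presence, basic types, and that every finite presentation
#' time is an integer multiple of its participant's frame duration
#' (1000/frame_rate ms, within 1e-6 ms to absorb decimal round-tripping).
#'
#' @param trials a trial-record data.frame or a path to a trial-log file.
#' @param roster data.frame with `participant_id` and `frame_rate` (e.g.
#'   from [cohort_roster()]); when `NULL` the frame check is skipped.
#' @return list with `valid`, `missing_columns`, and a `violations`
#'   data.frame of row-level diagnostics.
#' @export
validate_trial_log <- function(trials, roster = NULL) {
  if (is.character(trials)) {
    if (!file.exists(trials)) stop("cannot read trial log: ", trials)
    trials <- utils::read.csv(trials, stringsAsFactors = FALSE)
  }
  missing <- setdiff(TRIAL_LOG_COLUMNS, names(trials))
  viol <- data.frame(row = integer(0), column = character(0),
                     problem = character(0), stringsAsFactors = FALSE)
  add <- function(rows, column, problem) {
    if (length(rows))
      viol <<- rbind(viol, data.frame(row = rows, column = column,
                                      problem = problem))
  }
  if (!length(missing)) {
    add(which(!trials$response_correct %in% c(0, 1)), "response_correct",
        "not in {0,1}")
    add(which(!(trials$presentation_ms > 0)), "presentation_ms",
        "not positive")
    add(which(!is.na(trials$reaction_ms) & trials$reaction_ms <= 0),
        "reaction_ms", "not positive")
    if (!is.null(roster)) {
      fr <- roster$frame_rate[match(trials$participant_id,
                                    roster$participant_id)]
      x <- trials$presentation_ms
      ok <- is.na(fr) | !is.finite(x) |
        abs(x - round(x * fr / 1000) * 1000 / fr) <= 1e-6
      add(which(!ok), "presentation_ms", "not a frame multiple")
    }
  }
  list(valid = length(missing) == 0 && nrow(viol) == 0,
       missing_columns = missing, violations = viol)
}
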