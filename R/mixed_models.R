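# Nested mixed-model ladders (null -> group main effect -> group
# interactions) on transformed reaction times, log thresholds and
# trial-level correctness, compared by likelihood-ratio tests. Model
# fitting is delegated to lme4 (maximum likelihood, adaptive Gauss-Hermite
# for binomial random-intercept models); ladder construction, nesting
# checks, the data fingerprint guard and the LR test live here.

# term vocabulary -> model-frame columns
.TERM_MAP <- c(age = "age", block = "block", group = "group",
               rotation = "rotation_abs", log_pt = "log_pt",
               log_pt_centered = "log_pt_centered",
               "group:block" = "group:block",
               "group:log_pt" = "group:log_pt",
               "group:log_pt_centered" = "group:log_pt_centered",
               "group:rotation" = "group:rotation_abs")

#' Specify one mixed model of a ladder
#'
#' @param response `"inv_rt"` (Gaussian on the -1/RT scale), `"log_pt80"`
#'   (Gaussian, one observation per participant, fixed effects only) or
#'   `"correct"` (binomial with logit link).
#' @param fixed_terms character vector over `age, block, group, rotation,
#'   log_pt, log_pt_centered` and the `group:` interactions; an interaction
#'   requires both main effects (hierarchy).
#' @param random_terms per-participant random terms: subset of
#'   `c("intercept", "block")`; must be empty for `log_pt80`.
#' @param label short model label.
#' @return an object of class `mixed_model_spec`. Fitting is by maximum
#'   likelihood (not REML) so that likelihood-ratio tests on fixed effects
#'   are valid.
#' @export
mixed_model_spec <- function(response = c("inv_rt", "log_pt80", "correct"),
                             fixed_terms, random_terms = character(),
                             label = "model") {
  response <- match.arg(response)
  bad <- setdiff(fixed_terms, names(.TERM_MAP))
  if (length(bad)) stop("unknown fixed terms: ", paste(bad, collapse = ", "))
  for (tm in grep(":", fixed_terms, value = TRUE)) {
    mains <- strsplit(tm, ":")[[1]]
    if (!all(mains %in% fixed_terms))
      stop("interaction ", tm, " requires its main effects (hierarchy)")
  }
  if (response == "log_pt80" && length(random_terms))
    stop("log_pt80 has one observation per participant: no random terms")
  if (length(random_terms) && !"intercept" %in% random_terms)
    stop("random slopes require a random intercept")
  family <- if (response == "correct") "binomial-logit" else "gaussian"
  structure(list(response = response, family = family,
                 fixed_terms = fixed_terms, random_terms = random_terms,
                 label = label),
            class = "mixed_model_spec")
}

#' Build the nested model ladder for an experiment
#'
#' Returns the ladder fitted for each experiment: a nullmodel holding age
#' and the experimental variables (with participant random effects), then a
#' group main effect, then group-by-variable interactions.
#'
#' * Experiments 1/2, reaction times: `-1/RT ~ age + block` with random
#'   intercept and block slope; `+ group`; `+ group:block`.
#' * Experiments 1/2, thresholds: `log PT80 ~ age` (fixed effects only);
#'   `+ group`.
#' * Experiments 3/4, correctness: `~ age + rotation (nominal, absolute
#'   value) + centered log PT` with random intercept; `+ group`;
#'   `+ group:log PT` (PT interaction model); `+ group:rotation` as well
#'   (full interaction model).
#' * Experiments 5/6, correctness: `~ age + log PT` with random intercept;
#'   `+ group`; `+ group:log PT`; reaction times use the same fixed and
#'   random structure on the -1/RT scale.
#'
#' @param experiment integer 1..6.
#' @param response one of `"inv_rt"`, `"log_pt80"`, `"correct"`; the
#'   default picks the experiment's primary response (RT for 1/2,
#'   correctness for 3-6).
#' @return list of [mixed_model_spec()] objects with strictly increasing
#'   parameter counts; consecutive pairs are nested.
#' @export
build_ladder <- function(experiment, response = NULL) {
  if (!experiment %in% 1:6) stop("configuration error: unknown experiment id")
  response <- response %||% if (experiment %in% 1:2) "inv_rt" else "correct"
  if (experiment %in% 1:2 && response == "inv_rt") {
    base <- c("age", "block")
    return(list(
      mixed_model_spec("inv_rt", base, c("intercept", "block"), "null"),
      mixed_model_spec("inv_rt", c(base, "group"), c("intercept", "block"),
                       "group_main"),
      mixed_model_spec("inv_rt", c(base, "group", "group:block"),
                       c("intercept", "block"), "group_block_interaction")))
  }
  if (experiment %in% 1:2 && response == "log_pt80") {
    return(list(
      mixed_model_spec("log_pt80", "age", label = "null"),
      mixed_model_spec("log_pt80", c("age", "group"), label = "group_main")))
  }
  if (experiment %in% 3:4) {
    if (response != "correct")
      stop("experiments 3/4 are modeled on correctness")
    base <- c("age", "rotation", "log_pt_centered")
    return(list(
      mixed_model_spec("correct", base, "intercept", "null"),
      mixed_model_spec("correct", c(base, "group"), "intercept",
                       "group_main"),
      mixed_model_spec("correct", c(base, "group", "group:log_pt_centered"),
                       "intercept", "pt_interaction"),
      mixed_model_spec("correct", c(base, "group", "group:log_pt_centered",
                                    "group:rotation"),
                       "intercept", "full_interaction")))
  }
  # experiments 5/6
  base <- c("age", "log_pt")
  resp <- if (response == "inv_rt") "inv_rt" else "correct"
  list(
    mixed_model_spec(resp, base, "intercept", "null"),
    mixed_model_spec(resp, c(base, "group"), "intercept", "group_main"),
    mixed_model_spec(resp, c(base, "group", "group:log_pt"), "intercept",
                     "pt_interaction"))
}

#' Prepare a model frame from a trial log and roster
#'
#' Joins group and age onto the trials, codes group numerically
#' (control = 0, CP = 1; a positive group coefficient on the -1/RT scale
#' means slower CP responses), folds rotation to its absolute value on a
#' nominal scale, and computes the transformed responses (`inv_rt`,
#' `log_pt`, dataset-mean-centered `log_pt_centered`).
#'
#' @param trials trial-record data.frame (typically already filtered).
#' @param roster data.frame with `participant_id`, `group`, `age`.
#' @return model-frame data.frame.
#' @export
prepare_model_data <- function(trials, roster) {
  stopifnot(all(c("participant_id", "group", "age") %in% names(roster)))
  idx <- match(trials$participant_id, roster$participant_id)
  if (anyNA(idx)) stop("trials contain participants missing from the roster")
  df <- trials
  df$group_label <- roster$group[idx]
  df$group <- as.integer(df$group_label == "cp")
  df$age <- roster$age[idx]
  df$rotation_abs <- factor(abs(df$rotation))
  df$inv_rt <- ifelse(is.na(df$reaction_ms), NA_real_,
                      -1000 / df$reaction_ms)
  df$log_pt <- ifelse(is.finite(df$presentation_ms) &
                        df$presentation_ms > 0,
                      log(df$presentation_ms), NA_real_)
  df$log_pt_centered <- df$log_pt - mean(df$log_pt, na.rm = TRUE)
  df
}

#' Per-participant threshold table for the log-PT80 ladder
#'
#' @param estimates named vector of PT80 estimates in ms (names are
#'   participant ids), e.g. the `estimates` attribute of
#'   [generate_experiment()] for experiments 1/2.
#' @param roster roster data.frame.
#' @return model frame with one row per participant (`log_pt80`, `group`,
#'   `age`; `experiment`/`trial` keys for fingerprinting).
#' @export
pt80_table <- function(estimates, roster) {
  idx <- match(names(estimates), roster$participant_id)
  if (anyNA(idx)) stop("estimates contain participants missing from the roster")
  data.frame(
    participant_id = names(estimates),
    experiment = 0L, trial = seq_along(estimates),
    log_pt80 = transform_pt(unname(estimates)),
    group_label = roster$group[idx],
    group = as.integer(roster$group[idx] == "cp"),
    age = roster$age[idx], stringsAsFactors = FALSE)
}

.response_col <- c(inv_rt = "inv_rt", log_pt80 = "log_pt80",
                   correct = "response_correct")

.build_formula <- function(spec) {
  lhs <- .response_col[[spec$response]]
  rhs <- unname(.TERM_MAP[spec$fixed_terms])
  rhs <- if (length(rhs)) paste(rhs, collapse = " + ") else "1"
  if (length(spec$random_terms)) {
    rterms <- if ("block" %in% spec$random_terms) "1 + block" else "1"
    rhs <- paste0(rhs, " + (", rterms, " | participant_id)")
  }
  stats::as.formula(paste(lhs, "~", rhs))
}

#' Fit one model of a ladder by maximum likelihood
#'
#' Gaussian models with random effects are fitted with `lme4::lmer`
#' (`REML = FALSE`); binomial models with `lme4::glmer` using adaptive
#' Gauss-Hermite quadrature (9 nodes) for random-intercept-only structures;
#' models without random terms fall back to `lm`/`glm`. Non-convergence and
#' singular (boundary) variance components are flagged, never silently
#' accepted; [lr_test()] refuses flagged fits.
#'
#' @param spec a [mixed_model_spec()].
#' @param data model frame from [prepare_model_data()] / [pt80_table()].
#' @param nAGQ quadrature nodes for binomial random-intercept models.
#' @param start optional warm-start values passed to lme4.
#' @return an object of class `mixed_model_fit`: `spec`, `fixed_estimates`,
#'   `varcomp`, `log_likelihood`, `n_params`, `n_obs`, `converged`,
#'   `boundary`, `fingerprint`, and the underlying `fit` object.
#' @export
fit_mixed_model <- function(spec, data, nAGQ = 9, start = NULL) {
  stopifnot(inherits(spec, "mixed_model_spec"))
  ycol <- .response_col[[spec$response]]
  need <- unique(c("participant_id", ycol,
                   unname(.TERM_MAP[setdiff(spec$fixed_terms,
                                            grep(":", spec$fixed_terms,
                                                 value = TRUE))])))
  miss <- setdiff(need, names(data))
  if (length(miss)) stop("model frame is missing columns: ",
                         paste(miss, collapse = ", "))
  data <- data[!is.na(data[[ycol]]), , drop = FALSE]
  if ("group" %in% spec$fixed_terms) {
    per_group <- tapply(data$participant_id, data$group,
                        function(x) length(unique(x)))
    if (length(per_group) < 2 || any(per_group < 2))
      stop("need >= 2 participants per group to estimate group terms")
  }
  form <- .build_formula(spec)
  binom <- spec$family == "binomial-logit"
  has_re <- length(spec$random_terms) > 0
  boundary <- FALSE
  if (!has_re) {
    fit <- if (binom) stats::glm(form, data = data, family = stats::binomial())
           else stats::lm(form, data = data)
    converged <- if (binom) fit$converged else TRUE
    fe <- stats::coef(fit)
    vc <- NULL
    sigma2 <- if (!binom) sum(stats::residuals(fit)^2) / nrow(data) else NULL
  } else if (binom) {
    n_nodes <- if (identical(spec$random_terms, "intercept")) nAGQ else 1
    fit <- suppressMessages(lme4::glmer(
      form, data = data, family = stats::binomial(), nAGQ = n_nodes,
      start = start,
      control = lme4::glmerControl(optimizer = "bobyqa",
                                   optCtrl = list(maxfun = 1e5),
                                   check.conv.singular = "ignore")))
    converged <- length(fit@optinfo$conv$lme4$messages) == 0 &&
      fit@optinfo$conv$opt == 0
    boundary <- lme4::isSingular(fit)
    fe <- lme4::fixef(fit)
    vc <- lme4::VarCorr(fit)
    sigma2 <- NULL
  } else {
    fit <- suppressMessages(lme4::lmer(
      form, data = data, REML = FALSE, start = start,
      control = lme4::lmerControl(optimizer = "bobyqa",
                                  optCtrl = list(maxfun = 1e5),
                                  check.conv.singular = "ignore")))
    converged <- length(fit@optinfo$conv$lme4$messages) == 0 &&
      fit@optinfo$conv$opt == 0
    boundary <- lme4::isSingular(fit)
    fe <- lme4::fixef(fit)
    vc <- lme4::VarCorr(fit)
    sigma2 <- stats::sigma(fit)^2
  }
  ll <- stats::logLik(fit)
  structure(list(
    spec = spec, fixed_estimates = fe, varcomp = vc,
    residual_variance = sigma2,
    log_likelihood = as.numeric(ll), n_params = attr(ll, "df"),
    n_obs = nrow(data), converged = converged, boundary = boundary,
    fingerprint = if (all(c("experiment", "trial") %in% names(data)))
      data_fingerprint(data) else NA_character_,
    fit = fit
  ), class = "mixed_model_fit")
}

# is `a` nested in `b`?
.is_nested <- function(a, b) {
  a$response == b$response && a$family == b$family &&
    identical(sort(a$random_terms), sort(b$random_terms)) &&
    all(a$fixed_terms %in% b$fixed_terms) &&
    length(b$fixed_terms) > length(a$fixed_terms)
}

#' Likelihood-ratio test of two nested fits
#'
#' `chi2 = 2 (loglik_alt - loglik_null)` (clipped at zero), referred to a
#' chi-square distribution with degrees of freedom equal to the difference
#' in parameter counts. With random effects present this reference
#' distribution is known to be mildly anti-conservative for fixed-effect
#' tests (p-values slightly too small), which is why interaction estimates
#' are also reported with Wald intervals.
#'
#' @param fit_null,fit_alt converged [fit_mixed_model()] results on the same
#'   data (verified through the stored fingerprint), with `fit_null` nested
#'   in `fit_alt`.
#' @return list with `chi2`, `df`, `p_value`.
#' @export
lr_test <- function(fit_null, fit_alt) {
  stopifnot(inherits(fit_null, "mixed_model_fit"),
            inherits(fit_alt, "mixed_model_fit"))
  if (!.is_nested(fit_null$spec, fit_alt$spec))
    stop("models are not nested")
  if (!is.na(fit_null$fingerprint) && !is.na(fit_alt$fingerprint) &&
      fit_null$fingerprint != fit_alt$fingerprint)
    stop("fits were computed on different data (fingerprint mismatch)")
  if (!fit_null$converged || !fit_alt$converged)
    stop("refusing a likelihood-ratio test on non-converged fits")
  df <- fit_alt$n_params - fit_null$n_params
  if (df <= 0) stop("alternative model must have more parameters")
  chi2 <- max(0, 2 * (fit_alt$log_likelihood - fit_null$log_likelihood))
  list(chi2 = chi2, df = df,
       p_value = stats::pchisq(chi2, df, lower.tail = FALSE))
}

#' Wald confidence intervals for fixed effects
#'
#' Normal-approximation intervals from the ML fit, used to report
#' interaction effect sizes (an approximation, flagged as such, in place of
#' a Bayesian refit).
#'
#' @param fit a [fit_mixed_model()] result.
#' @param level confidence level.
#' @return data.frame with term, estimate, se, lower, upper.
#' @export
wald_intervals <- function(fit, level = 0.95) {
  se <- sqrt(diag(as.matrix(stats::vcov(fit$fit))))
  z <- stats::qnorm(1 - (1 - level) / 2)
  est <- fit$fixed_estimates
  data.frame(term = names(est), estimate = unname(est), se = unname(se),
             lower = unname(est - z * se), upper = unname(est + z * se),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Fit a full ladder and run consecutive likelihood-ratio tests
#'
#' @param ladder list of specs from [build_ladder()].
#' @param data model frame.
#' @param ... passed to [fit_mixed_model()].
#' @return list with `fits` (named by label) and `tests` (data.frame of
#'   consecutive comparisons: label, chi2, df, p_value).
#' @export
fit_ladder <- function(ladder, data, ...) {
  fits <- lapply(ladder, fit_mixed_model, data = data, ...)
  names(fits) <- vapply(ladder, `[[`, character(1), "label")
  tests <- do.call(rbind, lapply(seq_len(length(fits) - 1), function(i) {
    lt <- lr_test(fits[[i]], fits[[i + 1]])
    data.frame(comparison = paste(names(fits)[i], "vs", names(fits)[i + 1]),
               chi2 = lt$chi2, df = lt$df, p_value = lt$p_value,
               stringsAsFactors = FALSE)
  }))
  list(fits = fits, tests = tests)
}
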