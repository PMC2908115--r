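# Synthetic observers: cohort generation and the forward behavioral model
# (psychometric accuracy and inverse-scale reaction times).

#' Cohort configuration
#'
#' Describes a case-control cohort: `n_cp` prosopagnosic (CP) observers,
#' each with `n_controls_per_cp` age-matched controls drawn from the same
#' age cluster. Ages come from a mixture of Gaussian clusters (the default
#' emulates a younger cluster around 23 years and an older one around 54).
#' CP thresholds are scaled by `cp_threshold_multiplier` (> 1 means CPs need
#' longer presentation times at matched age), and `group_rt_shift` moves the
#' CP reaction-time distribution on the -1/RT (per-second) scale, positive
#' values meaning slower CP responses.
#'
#' @param n_cp number of CP observers (>= 1).
#' @param n_controls_per_cp matched controls per CP.
#' @param age_clusters list of `c(mean, sd, weight)` triples; weights sum to 1.
#' @param cp_threshold_multiplier multiplicative CP threshold excess (>= 1).
#' @param group_rt_shift CP shift on the -1/RT scale, 1/seconds.
#' @param rotation_effect log-odds accuracy penalty per 30 degrees of
#'   rotation away from the learned view.
#' @param interaction_flags named logical list enabling group-by-variable
#'   generative interactions (`rotation`, `block`); all disabled by default,
#'   matching a population where rotation and practice act equally on both
#'   groups.
#' @param base_pt80_mean,base_pt80_sd lognormal location/scale (ms) of
#'   control thresholds at the reference age of 40 years.
#' @param pt80_age_slope multiplicative threshold increase per year of age.
#' @param seed integer seed; a fixed seed reproduces the cohort exactly.
#' @return an object of class `cohort_config`.
#' @export
cohort_config <- function(n_cp = 16, n_controls_per_cp = 2,
                          age_clusters = list(c(23, 2, 0.5), c(54, 9, 0.5)),
                          cp_threshold_multiplier = 1.6,
                          group_rt_shift = 0.2,
                          rotation_effect = 0.8,
                          interaction_flags = list(rotation = FALSE, block = FALSE),
                          base_pt80_mean = 21, base_pt80_sd = 0.25,
                          pt80_age_slope = 0.004,
                          seed = 1) {
  if (n_cp < 1 || n_controls_per_cp < 0)
    stop("configuration error: counts must be non-negative and n_cp >= 1")
  w <- vapply(age_clusters, `[`, numeric(1), 3)
  if (abs(sum(w) - 1) > 1e-8)
    stop("configuration error: age cluster weights must sum to 1")
  if (cp_threshold_multiplier < 1)
    stop("configuration error: cp_threshold_multiplier must be >= 1")
  structure(list(
    n_cp = as.integer(n_cp),
    n_controls_per_cp = as.integer(n_controls_per_cp),
    age_clusters = age_clusters,
    cp_threshold_multiplier = cp_threshold_multiplier,
    group_rt_shift = group_rt_shift,
    rotation_effect = rotation_effect,
    interaction_flags = interaction_flags,
    base_pt80_mean = base_pt80_mean, base_pt80_sd = base_pt80_sd,
    pt80_age_slope = pt80_age_slope,
    seed = as.integer(seed)
  ), class = "cohort_config")
}

#' A synthetic observer
#'
#' Carries the observer's true psychometric parameters (threshold, guess,
#' lapse, slope), reaction-time coefficients on the -1/RT scale with
#' participant random effects, per-rotation log-odds accuracy penalties, and
#' the monitor frame rate.
#'
#' @param participant_id character token.
#' @param group `"control"` or `"cp"`.
#' @param age years (> 0).
#' @param true_pt80 presentation time (ms) at which frontal-view accuracy is
#'   80 percent.
#' @param guess,lapse chance and lapse probabilities, `0 <= guess < 1 - lapse`.
#' @param slope_scale logistic slope of the inner psychometric curve, 1/ms.
#' @param rt_intercept,rt_age_coef,rt_block_coef,rt_group_coef fixed RT
#'   coefficients on the -1/RT scale (1/s and per-unit variants); the group
#'   coefficient applies only to CP observers.
#' @param random_intercept,random_block_slope participant random effects on
#'   the -1/RT scale.
#' @param rt_noise_sd residual SD on the -1/RT scale.
#' @param rotation_decrements named numeric vector mapping absolute rotation
#'   degrees to log-odds penalties (0 at the learned view).
#' @param frame_rate monitor refresh rate, 170 or 200 Hz.
#' @return an object of class `observer_profile`.
#' @export
observer_profile <- function(participant_id, group = c("control", "cp"),
                             age, true_pt80, guess = 0.5, lapse = 0.02,
                             slope_scale = 0.1,
                             rt_intercept = -1.8, rt_age_coef = 0.004,
                             rt_block_coef = -0.02, rt_group_coef = 0,
                             random_intercept = 0, random_block_slope = 0,
                             rt_noise_sd = 0.25,
                             rotation_decrements = c(`0` = 0, `30` = 0.8,
                                                     `60` = 1.6, `90` = 2.4),
                             frame_rate = 200) {
  group <- match.arg(group)
  stopifnot(age > 0, true_pt80 > 0, slope_scale > 0,
            guess >= 0, lapse >= 0, guess < 1 - lapse,
            frame_rate %in% c(170, 200))
  structure(list(
    participant_id = participant_id, group = group, age = age,
    true_pt80 = true_pt80, guess = guess, lapse = lapse,
    slope_scale = slope_scale,
    rt_intercept = rt_intercept, rt_age_coef = rt_age_coef,
    rt_block_coef = rt_block_coef, rt_group_coef = rt_group_coef,
    random_intercept = random_intercept,
    random_block_slope = random_block_slope,
    rt_noise_sd = rt_noise_sd,
    rotation_decrements = rotation_decrements,
    frame_rate = frame_rate
  ), class = "observer_profile")
}

#' Generate a matched case-control cohort
#'
#' Draws `n_cp` CP observers and, for each, `n_controls_per_cp` controls
#' from the same age cluster (age-matching), assigning the triple a common
#' monitor. CP thresholds at matched age stochastically dominate control
#' thresholds by the configured multiplier. Regeneration under a fixed seed
#' is byte-identical; every observer draws from its own seed substream, so
#' enlarging the cohort leaves existing observers unchanged.
#'
#' @param config a [cohort_config()].
#' @return list of [observer_profile()] objects, CPs first.
#' @export
#' @examples
#' cohort <- generate_cohort(cohort_config(n_cp = 2, seed = 7))
#' vapply(cohort, function(p) p$group, character(1))
generate_cohort <- function(config) {
  stopifnot(inherits(config, "cohort_config"))
  w <- vapply(config$age_clusters, `[`, numeric(1), 3)
  draw_one <- function(cp_index, control_index, cluster, frame_rate) {
    is_cp <- control_index == 0L
    id <- if (is_cp) sprintf("cp%02d", cp_index)
          else sprintf("ct%02d_%d", cp_index, control_index)
    seed_i <- derive_seed(config$seed, "profile", id)
    with_seed(seed_i, {
      cl <- config$age_clusters[[cluster]]
      age <- max(18, stats::rnorm(1, cl[1], cl[2]))
      mult <- if (is_cp) config$cp_threshold_multiplier else 1
      pt80 <- config$base_pt80_mean * mult *
        exp(config$pt80_age_slope * (age - 40)) *
        exp(stats::rnorm(1, 0, config$base_pt80_sd))
      rot_base <- config$rotation_effect
      rot_mult <- if (is_cp && isTRUE(config$interaction_flags$rotation)) 1.5 else 1
      blk_coef <- -0.02 *
        (if (is_cp && isTRUE(config$interaction_flags$block)) 0.5 else 1)
      observer_profile(
        participant_id = id, group = if (is_cp) "cp" else "control",
        age = age, true_pt80 = pt80, guess = 0.5, lapse = 0.02,
        slope_scale = 0.1,
        rt_group_coef = if (is_cp) config$group_rt_shift else 0,
        rt_block_coef = blk_coef,
        random_intercept = stats::rnorm(1, 0, 0.15),
        random_block_slope = stats::rnorm(1, 0, 0.015),
        rotation_decrements = c(`0` = 0, `30` = rot_base * rot_mult,
                                `60` = 2 * rot_base * rot_mult,
                                `90` = 3 * rot_base * rot_mult),
        frame_rate = frame_rate
      )
    })
  }
  cps <- vector("list", config$n_cp)
  controls <- list()
  for (i in seq_len(config$n_cp)) {
    s <- derive_seed(config$seed, "match", i)
    assign_vals <- with_seed(s, list(
      cluster = sample.int(length(w), 1, prob = w),
      frame_rate = sample(c(170, 200), 1)
    ))
    cps[[i]] <- draw_one(i, 0L, assign_vals$cluster, assign_vals$frame_rate)
    for (j in seq_len(config$n_controls_per_cp))
      controls[[length(controls) + 1L]] <-
        draw_one(i, j, assign_vals$cluster, assign_vals$frame_rate)
  }
  c(cps, controls)
}

#' Cohort roster as a data frame
#'
#' @param cohort list of [observer_profile()] objects.
#' @return data.frame with participant_id, group, age, frame_rate and the
#'   observer's true threshold (for simulation audits; unavailable for real
#'   data).
#' @export
cohort_roster <- function(cohort) {
  do.call(rbind, lapply(cohort, function(p) data.frame(
    participant_id = p$participant_id, group = p$group, age = p$age,
    frame_rate = p$frame_rate, true_pt80 = p$true_pt80,
    stringsAsFactors = FALSE
  )))
}

#' True probability of a correct answer
#'
#' Forward psychometric model: `p = guess + (1 - guess - lapse) *
#' plogis(slope * (x - alpha) - penalty(rotation))`, with `alpha` anchored so
#' that frontal-view accuracy is exactly 0.80 at `true_pt80` under the
#' observer's own 2AFC guess rate. Rotation enters as an additive log-odds
#' penalty on the inner curve.
#'
#' @param profile an [observer_profile()].
#' @param presentation_ms presentation time in ms (> 0; `Inf` allowed for
#'   unlimited viewing).
#' @param rotation absolute rotation in degrees; must be a name of the
#'   profile's `rotation_decrements`.
#' @param guess chance rate of the design (0.25 for 4AFC); `NULL` uses the
#'   profile's own rate.
#' @return probability in `[guess, 1 - lapse]`, strictly increasing in
#'   `presentation_ms`.
#' @export
true_accuracy <- function(profile, presentation_ms, rotation = 0, guess = NULL) {
  if (any(presentation_ms <= 0)) stop("presentation_ms must be positive")
  g <- guess %||% profile$guess
  lam <- profile$lapse
  beta <- profile$slope_scale
  # anchor: with the profile's own guess rate, p(true_pt80, frontal) = 0.80
  f80 <- (0.8 - profile$guess) / (1 - profile$guess - lam)
  alpha <- profile$true_pt80 - stats::qlogis(f80) / beta
  key <- as.character(abs(rotation))
  if (!key %in% names(profile$rotation_decrements))
    stop("unknown rotation condition: ", rotation)
  pen <- profile$rotation_decrements[[key]]
  g + (1 - g - lam) * stats::plogis(beta * (presentation_ms - alpha) - pen)
}

#' Simulate one reaction time
#'
#' Draws a reaction time whose inverse transform `-1/RT` (seconds) equals a
#' linear predictor (intercept + age, block and group terms + the
#' participant's random intercept and block slope) plus Gaussian noise.
#' Larger values on the `-1/RT` scale mean slower responses, so a positive
#' group coefficient shifts the CP distribution slower. Draws are rejected
#' and redrawn until RT lands in (0, 20 s); the rejection loop is capped.
#'
#' @param profile an [observer_profile()].
#' @param block training block index (>= 1).
#' @param seed integer seed.
#' @param n number of draws.
#' @return reaction time(s) in ms.
#' @export
simulate_reaction_time <- function(profile, block, seed = 1, n = 1) {
  stopifnot(block >= 1)
  eta <- profile$rt_intercept +
    profile$rt_age_coef * profile$age +
    (profile$rt_block_coef + profile$random_block_slope) * block +
    (if (profile$group == "cp") profile$rt_group_coef else 0) +
    profile$random_intercept
  with_seed(seed, {
    out <- numeric(n)
    for (i in seq_len(n)) {
      for (iter in seq_len(1000)) {
        y <- eta + stats::rnorm(1, 0, profile$rt_noise_sd)
        if (y < 0) {
          rt_s <- -1 / y
          if (rt_s > 0 && rt_s < 20) { out[i] <- rt_s * 1000; break }
        }
        if (iter == 1000)
          stop("simulation error: reaction-time rejection cap exceeded")
      }
    }
    out
  })
}

# Linear predictor on the -1/RT scale, exposed for Monte-Carlo checks.
rt_linear_predictor <- function(profile, block) {
  profile$rt_intercept +
    profile$rt_age_coef * profile$age +
    (profile$rt_block_coef + profile$random_block_slope) * block +
    (if (profile$group == "cp") profile$rt_group_coef else 0) +
    profile$random_intercept
}
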