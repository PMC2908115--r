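# Constrained psychometric function: prediction, maximum-likelihood fitting
# with a fixed guess rate and bounded lapse rate, and inversion to criterion
# presentation times.

#' Construct a psychometric model
#'
#' `p(x) = guess + (1 - guess - lapse) * F(x; location, slope)`, with F the
#' logistic CDF, `F(location) = 0.5`. On the default linear-ms predictor
#' scale `F(x) = plogis(slope * (x - location))`; on the log-ms scale
#' `F(x) = plogis(slope * (log(x) - log(location)))` (location stays a time
#' in ms, which is what makes the positivity constraint meaningful).
#'
#' @param guess chance rate (gamma), fixed by the design (0.5 for 2AFC,
#'   0.25 for 4AFC).
#' @param lapse lapse rate (lambda), `0 <= lapse`, `guess < 1 - lapse`.
#' @param location midpoint alpha in ms (> 0).
#' @param slope slope beta (> 0); 1/ms on the linear scale, 1/log-ms on the
#'   log scale.
#' @param predictor_scale `"linear-ms"` or `"log-ms"`.
#' @return an object of class `psychometric_model`.
#' @export
psychometric_model <- function(guess, lapse, location, slope,
                               predictor_scale = c("linear-ms", "log-ms")) {
  predictor_scale <- match.arg(predictor_scale)
  stopifnot(guess >= 0, lapse >= 0, guess < 1 - lapse,
            location > 0, slope > 0)
  structure(list(guess = guess, lapse = lapse, location = location,
                 slope = slope, predictor_scale = predictor_scale),
            class = "psychometric_model")
}

#' Predicted probability of a correct answer
#'
#' @param model a [psychometric_model()].
#' @param x presentation time(s) in ms (> 0).
#' @return probabilities in `[guess, 1 - lapse]`, strictly increasing in `x`.
#' @export
#' @examples
#' m <- psychometric_model(0.5, 0, location = 40, slope = 0.1)
#' predict_probability(m, 40)  # 0.75, the midpoint
predict_probability <- function(model, x) {
  if (any(x <= 0)) stop("presentation time must be positive")
  u <- if (model$predictor_scale == "log-ms")
    model$slope * (log(x) - log(model$location))
  else model$slope * (x - model$location)
  model$guess + (1 - model$guess - model$lapse) * stats::plogis(u)
}

# Bernoulli negative log-likelihood; par = c(location, slope, lapse)
.psy_nll <- function(par, x, z, guess, predictor_scale) {
  m <- list(guess = guess, lapse = par[3], location = par[1], slope = par[2],
            predictor_scale = predictor_scale)
  p <- pmin(pmax(predict_probability(m, x), 1e-12), 1 - 1e-12)
  -sum(z * log(p) + (1 - z) * log(1 - p))
}

# analytic gradient of .psy_nll
.psy_nll_grad <- function(par, x, z, guess, predictor_scale) {
  alpha <- par[1]; beta <- par[2]; lam <- par[3]
  span <- 1 - guess - lam
  u <- if (predictor_scale == "log-ms") beta * (log(x) - log(alpha))
       else beta * (x - alpha)
  Fu <- stats::plogis(u)
  fu <- Fu * (1 - Fu)
  p <- pmin(pmax(guess + span * Fu, 1e-12), 1 - 1e-12)
  dldp <- -(z / p - (1 - z) / (1 - p))
  if (predictor_scale == "log-ms") {
    du_da <- -beta / alpha; du_db <- log(x) - log(alpha)
  } else {
    du_da <- -beta; du_db <- x - alpha
  }
  c(sum(dldp * span * fu * du_da),
    sum(dldp * span * fu * du_db),
    sum(dldp * (-Fu)))
}

#' Fit the constrained psychometric model by maximum likelihood
#'
#' Maximizes the Bernoulli log-likelihood over (location, slope, lapse)
#' subject to location > 0, slope > 0 and `0 <= lapse <= lapse_max`, with
#' the guess rate fixed by the design. Optimization is multi-start L-BFGS-B
#' from 8 deterministic starting points plus the best point of a coarse
#' parameter grid; it is seedless and reproducible. Degenerate data (all
#' answers identical) yield a flagged, non-converged boundary fit rather
#' than an error.
#'
#' @param trials data.frame with columns `presentation_ms` (or `x`) and
#'   `response_correct` (or `z`).
#' @param guess fixed chance rate.
#' @param lapse_max upper bound on the lapse rate.
#' @param predictor_scale see [psychometric_model()].
#' @param ci compute a 95 percent profile-likelihood interval for the
#'   location parameter.
#' @return an object of class `psychometric_fit`: `model`,
#'   `log_likelihood`, `n_trials`, `converged`, `gradient_norm`,
#'   `ci_location`.
#' @export
fit_psychometric <- function(trials, guess = 0.5, lapse_max = 0.05,
                             predictor_scale = c("linear-ms", "log-ms"),
                             ci = TRUE) {
  predictor_scale <- match.arg(predictor_scale)
  x <- trials$presentation_ms %||% trials$x
  z <- trials$response_correct %||% trials$z
  stopifnot(!is.null(x), !is.null(z), length(x) == length(z))
  if (length(x) < 20 || length(unique(x)) < 3)
    stop("need >= 20 trials spanning >= 3 distinct presentation times")

  degenerate <- length(unique(z)) < 2
  lo <- c(1e-3, 1e-4, 0)
  hi <- c(10 * max(x), 10, lapse_max)
  if (degenerate) {
    # boundary fit: no information about the curve's location/slope
    par <- if (all(z == 1)) c(min(x) / 2, hi[2], 0) else c(hi[1], lo[2], lapse_max)
    model <- psychometric_model(guess, par[3], par[1], par[2], predictor_scale)
    warning("degenerate data (all answers identical): boundary fit, not converged")
    return(structure(list(model = model,
                          log_likelihood = -.psy_nll(par, x, z, guess, predictor_scale),
                          n_trials = length(x), converged = FALSE,
                          gradient_norm = NA_real_,
                          ci_location = c(NA_real_, NA_real_)),
                     class = "psychometric_fit"))
  }

  # coarse grid: locations over the sampled range, slopes log-spaced
  locs <- stats::quantile(x, probs = seq(0.02, 0.98, length.out = 50),
                          names = FALSE)
  slopes <- exp(seq(log(0.5 / diff(range(x)) + 1e-6), log(2), length.out = 50))
  lapses <- seq(0, lapse_max, length.out = 5)
  grid <- as.matrix(expand.grid(locs, slopes, lapses))
  gv <- apply(grid, 1, .psy_nll, x = x, z = z, guess = guess,
              predictor_scale = predictor_scale)
  starts <- rbind(
    grid[which.min(gv), ],
    as.matrix(expand.grid(stats::quantile(x, c(0.25, 0.75), names = FALSE),
                          c(0.05, 0.5), c(0, lapse_max / 2)))
  )

  best <- NULL
  for (i in seq_len(nrow(starts))) {
    fit <- tryCatch(
      stats::optim(pmin(pmax(starts[i, ], lo), hi), .psy_nll,
                   gr = .psy_nll_grad, x = x, z = z, guess = guess,
                   predictor_scale = predictor_scale,
                   method = "L-BFGS-B", lower = lo, upper = hi,
                   control = list(maxit = 1000, factr = 1e6)),
      error = function(e) NULL)
    if (!is.null(fit) && (is.null(best) || fit$value < best$value)) best <- fit
  }
  # polish: restart from the incumbent until the objective stops moving
  for (k in 1:3) {
    pol <- tryCatch(
      stats::optim(best$par, .psy_nll, gr = .psy_nll_grad,
                   x = x, z = z, guess = guess,
                   predictor_scale = predictor_scale,
                   method = "L-BFGS-B", lower = lo, upper = hi,
                   control = list(maxit = 1000, factr = 1e6)),
      error = function(e) NULL)
    if (is.null(pol) || best$value - pol$value < 1e-9) break
    best <- pol
  }
  par <- best$par
  gr <- .psy_nll_grad(par, x, z, guess, predictor_scale)
  # KKT projection: at an active bound only feasible descent directions count
  at_hi <- hi - par < 1e-8 * pmax(1, abs(hi))
  at_lo <- par - lo < 1e-8 * pmax(1, abs(lo))
  gr[(at_hi & gr < 0) | (at_lo & gr > 0)] <- 0
  gnorm <- sqrt(sum(gr^2))
  converged <- best$convergence == 0 && gnorm < 1e-3 * (1 + abs(best$value))
  model <- psychometric_model(guess, par[3], par[1], par[2], predictor_scale)
  ll <- -best$value
  ci_loc <- if (ci) .profile_ci_location(par, lo, hi, x, z, guess,
                                         predictor_scale, ll)
            else c(NA_real_, NA_real_)
  structure(list(model = model, log_likelihood = ll, n_trials = length(x),
                 converged = converged, gradient_norm = gnorm,
                 ci_location = ci_loc),
            class = "psychometric_fit")
}

# 95% profile-likelihood CI for the location parameter
.profile_ci_location <- function(par, lo, hi, x, z, guess, scale, ll_max) {
  cut <- stats::qchisq(0.95, 1) / 2
  prof <- function(alpha) {
    f2 <- function(p) .psy_nll(c(alpha, p), x, z, guess, scale)
    g2 <- function(p) .psy_nll_grad(c(alpha, p), x, z, guess, scale)[2:3]
    -stats::optim(par[2:3], f2, gr = g2, method = "L-BFGS-B",
                  lower = lo[2:3], upper = hi[2:3])$value
  }
  dev <- function(alpha) ll_max - prof(alpha) - cut
  side <- function(from, to) {
    if (dev(to) < 0) return(to)  # bound not crossed inside the box
    tryCatch(stats::uniroot(dev, c(from, to), tol = 1e-3)$root,
             error = function(e) NA_real_)
  }
  lower <- if (par[1] - lo[1] < 1e-9) lo[1] else side(par[1], lo[1])
  upper <- side(par[1], hi[1])
  sort(c(lower, upper))
}

#' Invert a psychometric model at a criterion probability
#'
#' Returns the presentation time at which the model predicts `p_target`,
#' e.g. the 90 percent-correct time used to set fixed presentation times in
#' rotation experiments. Closed form; the round trip through
#' [predict_probability()] reproduces `p_target` to within 1e-9.
#'
#' @param model a [psychometric_model()].
#' @param p_target criterion probability, strictly inside
#'   `(guess, 1 - lapse)`.
#' @return presentation time in ms, strictly increasing in `p_target`.
#' @export
#' @examples
#' m <- psychometric_model(0.5, 0, location = 40, slope = 0.1)
#' invert_psychometric(m, 0.75)  # 40 ms, the midpoint
invert_psychometric <- function(model, p_target) {
  lo <- model$guess; hi <- 1 - model$lapse
  if (any(p_target <= lo | p_target >= hi))
    stop(sprintf(
      "unattainable criterion %.4g: feasible probabilities are (%.4g, %.4g)",
      p_target[which(p_target <= lo | p_target >= hi)[1]], lo, hi))
  f <- (p_target - model$guess) / (1 - model$guess - model$lapse)
  u <- stats::qlogis(f) / model$slope
  if (model$predictor_scale == "log-ms") model$location * exp(u)
  else model$location + u
}
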