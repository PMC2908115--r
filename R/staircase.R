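# Accelerated stochastic approximation staircase with monitor-frame
# quantization, and the mean-of-last-16-trials threshold estimator.

#' Quantize a presentation time to whole monitor frames
#'
#' CRT presentation happens in whole frames: a requested duration is rounded
#' to the nearest frame count (minimum one frame) and converted back to ms.
#' At 200 Hz one frame is 5 ms; at 170 Hz it is 1000/170 ~ 5.88 ms.
#'
#' @param x presentation time in ms (finite).
#' @param frame_rate monitor refresh rate in Hz (> 0).
#' @return quantized duration in ms; idempotent.
#' @export
#' @examples
#' quantize_presentation(12.4, 200)  # 10 ms (2 frames)
quantize_presentation <- function(x, frame_rate) {
  if (!is.numeric(frame_rate) || frame_rate <= 0)
    stop("frame_rate must be a positive number")
  if (any(!is.finite(x))) stop("x must be finite")
  frames <- pmax(1, round(x * frame_rate / 1000))
  frames * 1000 / frame_rate
}

#' Create a staircase state
#'
#' State for the accelerated stochastic approximation procedure
#' `x_{n+1} = x_n - c / (2 + m) * (z_n - phi)`, where `m` counts answer
#' shifts (correct <-> incorrect) over the whole history. Step size shrinks
#' each time the answer sequence reverses, accelerating convergence to the
#' presentation time with probability `phi` of a correct answer.
#'
#' @param x_init initial presentation time in ms (> 0); quantized on entry.
#' @param c initial step constant in ms (> 0).
#' @param phi target fraction correct, in (0, 1]; 0.8 in the default design.
#' @param frame_rate monitor refresh rate in Hz.
#' @param x_max upper clamp in ms, preventing divergence for near-chance
#'   observers; clamp events are counted in the state.
#' @return an object of class `staircase_state`.
#' @export
new_staircase_state <- function(x_init, c, phi = 0.8, frame_rate = 200,
                                x_max = 2000) {
  stopifnot(is.numeric(x_init), x_init > 0, is.numeric(c), c > 0,
            phi > 0, phi <= 1, frame_rate > 0)
  structure(list(
    x_current = quantize_presentation(x_init, frame_rate),
    x_track = x_init,
    n = 0L, m_shifts = 0L, phi = phi, c = c, z_prev = NA_integer_,
    frame_rate = frame_rate, x_max = x_max, n_clamped = 0L,
    history = data.frame(x = numeric(0), z = integer(0))
  ), class = "staircase_state")
}

#' Advance the staircase by one answer
#'
#' Records that the current presentation `x_current` was answered with `z`
#' (1 correct, 0 incorrect), updates the shift counter from `z` versus the
#' previous answer, then applies the update rule. Correct answers decrease
#' the presentation time, errors increase it; the step magnitude
#' `c / (2 + m)` is non-increasing in the shift count. The recursion
#' operates on a continuous internal state (`x_track`); the presented value
#' `x_current` is that state quantized to whole frames, floored at one
#' frame and clamped at `x_max`. Keeping the recursion continuous matters:
#' once steps shrink below half a frame, a recursion on the quantized value
#' can only ratchet away from the threshold, because sub-frame decrements
#' round back to the same frame count while the larger error increments
#' still move.
#'
#' @param state a `staircase_state`.
#' @param z answer, 0 or 1.
#' @return the updated `staircase_state`.
#' @export
#' @examples
#' st <- new_staircase_state(x_init = 100, c = 50, phi = 0.8)
#' staircase_update(st, 0)$x_current  # 120 ms: errors lengthen presentation
staircase_update <- function(state, z) {
  stopifnot(inherits(state, "staircase_state"))
  if (length(z) != 1 || !z %in% c(0L, 1L)) stop("z must be 0 or 1")
  z <- as.integer(z)
  state$history <- rbind(state$history,
                         data.frame(x = state$x_current, z = z))
  state$n <- state$n + 1L
  # shift counting starts with the second answer
  if (!is.na(state$z_prev) && z != state$z_prev)
    state$m_shifts <- state$m_shifts + 1L
  state$z_prev <- z
  x_new <- state$x_track - state$c / (2 + state$m_shifts) * (z - state$phi)
  if (x_new > state$x_max) {
    x_new <- state$x_max
    state$n_clamped <- state$n_clamped + 1L
  }
  state$x_track <- max(x_new, 1e-9)
  state$x_current <- quantize_presentation(state$x_track, state$frame_rate)
  state
}

#' Run a staircase on a simulated observer and estimate its threshold
#'
#' Presents frame-quantized durations chosen by the accelerated stochastic
#' approximation rule, draws each answer as Bernoulli with probability
#' [true_accuracy()] at the presented duration (frontal view), and estimates
#' the threshold presentation time as the arithmetic mean of the last 16
#' presented durations.
#'
#' @param profile an [observer_profile()].
#' @param n_trials number of trials (>= 17: at least two answers are needed
#'   before updating and 16 for the estimate).
#' @param x_init,c,phi staircase parameters, see [new_staircase_state()].
#' @param seed integer seed for the answer draws.
#' @param guess chance rate of the design; defaults to the profile's.
#' @return a list with `trials` (data.frame: trial, presentation_ms,
#'   response_correct), `estimate` (list: pt80, n_trials_used,
#'   converged_sequence) and `n_clamped`.
#' @export
run_staircase <- function(profile, n_trials = 64, x_init = 200, c = 100,
                          phi = 0.8, seed = 1, guess = NULL) {
  if (n_trials < 17)
    stop("n_trials must be >= 17 (two answers to start updating, 16 for the estimate)")
  st <- new_staircase_state(x_init, c, phi, frame_rate = profile$frame_rate)
  z <- integer(n_trials)
  x <- numeric(n_trials)
  with_seed(seed, {
    for (i in seq_len(n_trials)) {
      x[i] <- st$x_current
      p <- true_accuracy(profile, x[i], rotation = 0, guess = guess)
      z[i] <- as.integer(stats::runif(1) < p)
      st <- staircase_update(st, z[i])
    }
  })
  last16 <- x[(n_trials - 15):n_trials]
  list(
    trials = data.frame(trial = seq_len(n_trials), presentation_ms = x,
                        response_correct = z),
    estimate = list(pt80 = mean(last16), n_trials_used = 16L,
                    converged_sequence = last16),
    n_clamped = st$n_clamped
  )
}

#' Replay a staircase over a fixed answer sequence
#'
#' Deterministic driver used for validation and for reconstructing
#' presentation-time sequences from logged answers.
#'
#' @param z integer vector of answers (0/1).
#' @inheritParams new_staircase_state
#' @return data.frame with columns `trial`, `presentation_ms`, `response_correct`.
#' @export
replay_staircase <- function(z, x_init = 200, c = 100, phi = 0.8,
                             frame_rate = 200, x_max = 2000) {
  st <- new_staircase_state(x_init, c, phi, frame_rate, x_max)
  x <- numeric(length(z))
  for (i in seq_along(z)) {
    x[i] <- st$x_current
    st <- staircase_update(st, z[i])
  }
  data.frame(trial = seq_along(z), presentation_ms = x,
             response_correct = as.integer(z))
}
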