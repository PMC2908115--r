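# Shared fixtures and independent oracles used across the test files.

# a 2AFC observer with a smooth psychometric function and 40 ms threshold
ideal_profile <- function(true_pt80 = 40, lapse = 0.02, slope = 0.1,
                          frame_rate = 200, ...) {
  observer_profile("ideal", "control", age = 30, true_pt80 = true_pt80,
                   guess = 0.5, lapse = lapse, slope_scale = slope,
                   frame_rate = frame_rate, ...)
}

# the true location parameter implied by a profile (for recovery checks)
profile_alpha <- function(p) {
  f80 <- (0.8 - p$guess) / (1 - p$guess - p$lapse)
  p$true_pt80 - qlogis(f80) / p$slope_scale
}

# Gauss-Hermite nodes/weights (physicists') by Golub-Welsch; E[f(U)] for
# U ~ N(0,1) is sum(w * f(sqrt(2) * t)) / sqrt(pi)
gauss_hermite <- function(n) {
  i <- seq_len(n - 1)
  J <- matrix(0, n, n)
  J[cbind(i, i + 1)] <- sqrt(i / 2)
  J[cbind(i + 1, i)] <- sqrt(i / 2)
  e <- eigen(J, symmetric = TRUE)
  idx <- order(e$values)
  list(nodes = e$values[idx],
       weights = sqrt(pi) * e$vectors[1, idx]^2)
}

# marginal log-likelihood of a binomial logit random-intercept model by
# direct numerical integration (independent of lme4's Laplace/AGQ path)
binom_ri_loglik_oracle <- function(eta, z, id, sigma, n_nodes = 51) {
  gh <- gauss_hermite(n_nodes)
  u <- sqrt(2) * gh$nodes * sigma
  w <- gh$weights / sqrt(pi)
  sum(vapply(split(seq_along(z), id), function(ix) {
    li <- vapply(u, function(uk) {
      p <- plogis(eta[ix] + uk)
      prod(ifelse(z[ix] == 1, p, 1 - p))
    }, numeric(1))
    log(sum(w * li))
  }, numeric(1)))
}

# full-enumeration Mann-Whitney oracle: exact p over all group assignments
enum_rank_sum <- function(a, b, alternative = "two.sided") {
  m <- length(a); N <- m + length(b)
  vals <- c(a, b)
  u_of <- function(ix) sum(rank(vals)[ix]) - m * (m + 1) / 2
  u_obs <- u_of(seq_len(m))
  us <- apply(utils::combn(N, m), 2, u_of)
  p_le <- mean(us <= u_obs); p_ge <- mean(us >= u_obs)
  switch(alternative,
         greater = p_ge, less = p_le,
         two.sided = min(1, 2 * min(p_le, p_ge)))
}

# full-enumeration signed-rank oracle over all 2^n sign patterns
enum_signed_rank <- function(d, alternative = "two.sided") {
  d <- d[d != 0]
  n <- length(d)
  r <- rank(abs(d))
  v_obs <- sum(r[d > 0])
  signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
  vs <- signs %*% r
  p_le <- mean(vs <= v_obs); p_ge <- mean(vs >= v_obs)
  switch(alternative,
         greater = p_ge, less = p_le,
         two.sided = min(1, 2 * min(p_le, p_ge)))
}

# brute-force staircase replay (independent reimplementation of the update
# rule, no quantization shortcuts shared with the package)
brute_staircase <- function(z_seq, x_init = 200, c = 100, phi = 0.8,
                            fr = 200) {
  track <- x_init; m <- 0; zprev <- NA; out <- numeric(length(z_seq))
  for (i in seq_along(z_seq)) {
    out[i] <- max(1, round(track * fr / 1000)) * 1000 / fr
    z <- z_seq[i]
    if (!is.na(zprev) && z != zprev) m <- m + 1
    zprev <- z
    track <- max(track - c / (2 + m) * (z - phi), 1e-9)
  }
  out
}

# small Gaussian mixed-data simulator for recovery tests:
# y = b0 + b_age*age + b_group*group + u_i + e
simulate_lmm_data <- function(n_per_group = 25, n_trials = 32,
                              b = c(intercept = -1.5, age = 0.02,
                                    group = -0.3),
                              sd_u = 0.2, sd_e = 0.3, seed = 1) {
  set.seed(seed)
  rows <- list()
  for (g in 0:1) for (i in seq_len(n_per_group)) {
    id <- sprintf("g%d_%02d", g, i)
    age <- runif(1, 20, 65)
    u <- rnorm(1, 0, sd_u)
    mu <- b["intercept"] + b["age"] * age + b["group"] * g + u
    rows[[length(rows) + 1L]] <- data.frame(
      participant_id = id, experiment = 1L, trial = seq_len(n_trials),
      block = rep(1:4, length.out = n_trials),
      group_label = ifelse(g == 1, "cp", "control"), group = g, age = age,
      inv_rt = mu + rnorm(n_trials, 0, sd_e))
  }
  do.call(rbind, rows)
}
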