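test_that("ladders are nested with strictly increasing parameter counts", {
  lad <- build_ladder(3)
  expect_length(lad, 4)
  expect_identical(vapply(lad, `[[`, character(1), "label"),
                   c("null", "group_main", "pt_interaction",
                     "full_interaction"))
  for (i in seq_len(length(lad) - 1))
    expect_true(psynorm:::.is_nested(lad[[i]], lad[[i + 1]]))
  # RT ladder for experiments 1/2 carries intercept + block-slope random terms
  rt <- build_ladder(1, "inv_rt")
  expect_identical(rt[[1]]$random_terms, c("intercept", "block"))
  # threshold ladder is fixed-effects only
  pt <- build_ladder(1, "log_pt80")
  expect_length(pt[[1]]$random_terms, 0)
  expect_error(build_ladder(9), "configuration")
  expect_error(mixed_model_spec("correct", c("age", "group:rotation")),
               "hierarchy")
  expect_error(mixed_model_spec("log_pt80", "age", "intercept"),
               "one observation")
})

test_that("rotation enters on a nominal absolute-value scale", {
  trials <- data.frame(participant_id = "p1", experiment = 3L, trial = 1:6,
                       rotation = c(0, -30, 30, -60, 60, 90),
                       presentation_ms = 40, reaction_ms = 700,
                       response_correct = 1)
  roster <- data.frame(participant_id = "p1", group = "cp", age = 30)
  md <- prepare_model_data(trials, roster)
  expect_identical(levels(md$rotation_abs), c("0", "30", "60", "90"))
  expect_identical(md$rotation_abs[2], md$rotation_abs[3])
})

test_that("zero-variance data reduce the mixed fit to the least-squares oracle", {
  # deterministic within-participant pattern, zero between-participant
  # deviation: the ML variance component must land exactly on the boundary
  dat <- simulate_lmm_data(n_per_group = 10, n_trials = 12, sd_u = 0,
                           sd_e = 0, seed = 71)
  dat$inv_rt <- dat$inv_rt + rep(scale(sin(1:12))[, 1] * 0.3,
                                 length.out = nrow(dat))
  spec <- mixed_model_spec("inv_rt", c("age", "group"), "intercept", "m")
  fit <- fit_mixed_model(spec, dat)
  expect_true(fit$boundary)  # variance component collapses to ~0
  ols <- lm(inv_rt ~ age + group, dat)
  expect_equal(unname(fit$fixed_estimates), unname(coef(ols)),
               tolerance = 1e-6)
  re_var <- as.data.frame(fit$varcomp)$vcov[1]
  expect_lt(re_var, 1e-6)
})

test_that("binomial random-intercept likelihood matches a 51-node quadrature oracle", {
  dat <- with_seed(83, {
    do.call(rbind, lapply(1:10, function(i) {
      u <- rnorm(1, 0, 0.8)
      age <- runif(1, 20, 60)
      eta <- 0.5 + 0.01 * age + u
      data.frame(participant_id = sprintf("p%02d", i), experiment = 1L,
                 trial = 1:20, age = age,
                 response_correct = rbinom(20, 1, plogis(eta)))
    }))
  })
  spec <- mixed_model_spec("correct", "age", "intercept", "m")
  fit <- fit_mixed_model(spec, dat, nAGQ = 9)
  beta <- fit$fixed_estimates
  sigma <- attr(fit$varcomp$participant_id, "stddev")
  eta_hat <- beta[1] + beta[2] * dat$age
  oracle <- binom_ri_loglik_oracle(eta_hat, dat$response_correct,
                                   dat$participant_id, sigma, n_nodes = 51)
  expect_equal(fit$log_likelihood, oracle, tolerance = 1e-4)
})

test_that("Gaussian mixed-model recovery lands within 3 SE of the truth", {
  b <- c(intercept = -1.5, age = 0.02, group = -0.3)
  dat <- simulate_lmm_data(n_per_group = 25, n_trials = 32, b = b,
                           sd_u = 0.2, sd_e = 0.3, seed = 97)
  spec <- mixed_model_spec("inv_rt", c("age", "group"), "intercept", "m")
  fit <- fit_mixed_model(spec, dat)
  expect_true(fit$converged)
  wi <- wald_intervals(fit)
  for (term in c("age", "group")) {
    row <- wi[wi$term == term, ]
    expect_lt(abs(row$estimate - b[term]), 3 * row$se)
  }
})

test_that("fixed-effect bias shrinks as the cohort grows", {
  bias_at <- function(n) {
    mean(vapply(1:8, function(r) {
      dat <- simulate_lmm_data(n_per_group = n, n_trials = 8,
                               seed = derive_seed(5, "consist", n, r))
      spec <- mixed_model_spec("inv_rt", c("age", "group"), "intercept", "m")
      abs(fit_mixed_model(spec, dat)$fixed_estimates[["group"]] - (-0.3))
    }, numeric(1)))
  }
  expect_lt(bias_at(24), bias_at(6))
})

test_that("likelihood-ratio test arithmetic and guards", {
  dat <- simulate_lmm_data(n_per_group = 6, n_trials = 8, seed = 13)
  null <- fit_mixed_model(mixed_model_spec("inv_rt", "age", "intercept", "null"), dat)
  alt <- fit_mixed_model(mixed_model_spec("inv_rt", c("age", "group"),
                                          "intercept", "alt"), dat)
  lt <- lr_test(null, alt)
  expect_equal(lt$chi2, 2 * (alt$log_likelihood - null$log_likelihood))
  expect_identical(lt$df, 1L)
  expect_equal(lt$p_value, pchisq(lt$chi2, 1, lower.tail = FALSE))
  # frozen tail example: chi2 = 6 on 2 df
  expect_equal(pchisq(6, 2, lower.tail = FALSE), 0.04978707, tolerance = 1e-6)
  # identical fits give chi2 = 0, p = 1
  self <- lr_test(null, structure(modifyList(alt,
    list(log_likelihood = null$log_likelihood)), class = "mixed_model_fit"))
  expect_equal(self$chi2, 0)
  expect_equal(self$p_value, 1)
  # guards: non-nested specs and mismatched data are refused
  expect_error(lr_test(alt, null), "more parameters|not nested")
  other <- fit_mixed_model(mixed_model_spec("inv_rt", c("age", "group"),
                                            "intercept", "alt"),
                           simulate_lmm_data(n_per_group = 7, n_trials = 8,
                                             seed = 14))
  expect_error(lr_test(null, other), "fingerprint")
  broken <- null; broken$converged <- FALSE
  expect_error(lr_test(broken, alt), "non-converged")
})

test_that("log-likelihood never decreases along a fitted ladder", {
  dat <- simulate_lmm_data(n_per_group = 8, n_trials = 12, seed = 29)
  res <- fit_ladder(build_ladder(1, "inv_rt"), dat)
  lls <- vapply(res$fits, `[[`, numeric(1), "log_likelihood")
  expect_true(all(diff(lls) >= -1e-8))
  nps <- vapply(res$fits, `[[`, numeric(1), "n_params")
  expect_true(all(diff(nps) > 0))
})

test_that("data fingerprints are order-independent but content-sensitive", {
  dat <- simulate_lmm_data(n_per_group = 3, n_trials = 4, seed = 31)
  fp1 <- psynorm:::data_fingerprint(dat)
  fp2 <- psynorm:::data_fingerprint(dat[sample(nrow(dat)), ])
  expect_identical(fp1, fp2)
  expect_false(identical(fp1, psynorm:::data_fingerprint(dat[-1, ])))
})
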