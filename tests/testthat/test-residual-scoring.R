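test_that("the reference fit uses control observations only", {
  dat <- simulate_lmm_data(n_per_group = 8, n_trials = 8, seed = 41)
  spec <- mixed_model_spec("inv_rt", "age", "intercept", "null")
  ref <- control_reference_fit(spec, dat)
  direct <- fit_mixed_model(spec, dat[dat$group_label == "control", ])
  expect_equal(ref$fixed_estimates, direct$fixed_estimates)
  expect_equal(ref$log_likelihood, direct$log_likelihood)
  # adding more CP rows changes nothing
  extra <- dat[dat$group_label == "cp", ][1:20, ]
  extra$inv_rt <- extra$inv_rt + 5
  ref2 <- control_reference_fit(spec, rbind(dat, extra))
  expect_equal(ref$fixed_estimates, ref2$fixed_estimates)
  expect_error(control_reference_fit(spec, dat[dat$group_label == "cp", ]),
               "control")
})

test_that("controls are scored by a reference that never saw them", {
  dat <- simulate_lmm_data(n_per_group = 6, n_trials = 8, seed = 43)
  spec <- mixed_model_spec("inv_rt", "age", "intercept", "null")
  scores <- score_participants(spec, dat)
  expect_identical(scores$reference[scores$group == "cp"],
                   rep("controls-only", 6))
  expect_identical(scores$reference[scores$group == "control"],
                   rep("leave-one-out", 6))
  # manual leave-one-out replication for one control
  pid <- "g0_03"
  manual_fit <- fit_mixed_model(spec,
    dat[dat$group_label == "control" & dat$participant_id != pid, ])
  rows <- dat[dat$participant_id == pid, ]
  eta <- predict(manual_fit$fit, newdata = rows, re.form = NA,
                 allow.new.levels = TRUE)
  expect_equal(scores$mean_residual[scores$participant_id == pid],
               mean(rows$inv_rt - eta), tolerance = 1e-6)
})

test_that("a generative group shift surfaces as larger CP residuals", {
  dat <- simulate_lmm_data(n_per_group = 12, n_trials = 16,
                           b = c(intercept = -1.5, age = 0.02, group = 0.4),
                           seed = 47)
  spec <- mixed_model_spec("inv_rt", "age", "intercept", "null")
  scores <- score_participants(spec, dat)
  cp <- scores$mean_residual[scores$group == "cp"]
  ctrl <- scores$mean_residual[scores$group == "control"]
  expect_gt(median(cp), median(ctrl))
  expect_lt(wilcoxon_rank_sum(cp, ctrl, "greater")$p_value, 0.05)
})

test_that("residual scores shift one-for-one with an added constant", {
  dat <- simulate_lmm_data(n_per_group = 5, n_trials = 6, seed = 53)
  spec <- mixed_model_spec("inv_rt", "age", "intercept", "null")
  s1 <- score_participants(spec, dat)
  dat2 <- dat; dat2$inv_rt <- dat2$inv_rt + 7
  s2 <- score_participants(spec, dat2)
  # with an intercept in the model the reference absorbs the constant for
  # controls; CP scores (excluded from the reference) shift by it
  expect_equal(s1$mean_residual[s1$group == "control"],
               s2$mean_residual[s2$group == "control"], tolerance = 1e-5)
})

test_that("binomial scores default to the link scale", {
  dat <- with_seed(59, {
    do.call(rbind, lapply(1:8, function(i) {
      g <- if (i <= 4) "cp" else "control"
      age <- runif(1, 20, 60)
      p <- plogis(1 + 0.01 * age + if (g == "cp") -1 else 0)
      data.frame(participant_id = sprintf("p%d", i), experiment = 1L,
                 trial = 1:30, age = age, group_label = g,
                 group = as.integer(g == "cp"),
                 response_correct = rbinom(30, 1, p))
    }))
  })
  spec <- mixed_model_spec("correct", "age", "intercept", "null")
  scores <- score_participants(spec, dat)
  expect_lt(mean(scores$mean_residual[scores$group == "cp"]),
            mean(scores$mean_residual[scores$group == "control"]))
  resp <- score_participants(spec, dat, scale = "response")
  expect_false(identical(scores$mean_residual, resp$mean_residual))
})

test_that("rank-sum test matches full enumeration and its documented examples", {
  expect_equal(wilcoxon_rank_sum(c(1, 2, 3), c(4, 5, 6))$p_value, 0.1)
  expect_equal(wilcoxon_rank_sum(c(1, 2, 3), c(1, 2, 3))$p_value, 1)
  for (s in 1:6) {
    ab <- with_seed(s, list(a = rnorm(sample(2:4, 1)),
                            b = rnorm(sample(2:4, 1))))
    for (alt in c("two.sided", "greater", "less")) {
      ours <- wilcoxon_rank_sum(ab$a, ab$b, alt)
      expect_true(ours$exact)
      expect_equal(ours$p_value, enum_rank_sum(ab$a, ab$b, alt),
                   tolerance = 1e-12, label = paste("seed", s, alt))
    }
  }
  expect_error(wilcoxon_rank_sum(numeric(0), 1:3), "non-empty")
})

test_that("exact and normal-approximation rank-sum branches agree", {
  ab <- with_seed(67, list(a = rnorm(14), b = rnorm(15, 0.4)))
  exact <- wilcoxon_rank_sum(ab$a, ab$b)          # n = 29: exact branch
  approx_input <- c(ab$a, ab$b + 1e-9 * 0)        # force approx via size
  big <- with_seed(68, list(a = rnorm(16), b = rnorm(32, 0.4)))
  b_exact <- stats::wilcox.test(big$a, big$b, exact = TRUE,
                                correct = TRUE)$p.value
  b_ours <- wilcoxon_rank_sum(big$a, big$b)$p_value
  expect_false(wilcoxon_rank_sum(big$a, big$b)$exact)
  expect_equal(b_ours, b_exact, tolerance = 0.02)
  expect_equal(exact$p_value,
               stats::wilcox.test(ab$a, ab$b, exact = TRUE)$p.value,
               tolerance = 1e-12)
})

test_that("signed-rank test matches enumeration and handles degeneracies", {
  # all-positive differences {1,2,3}: one-sided exact p = 1/8
  expect_equal(wilcoxon_signed_rank(c(2, 3, 4), c(1, 1, 1),
                                    "greater")$p_value, 0.125)
  for (s in 1:6) {
    n <- with_seed(s, sample(4:8, 1))
    d <- with_seed(100 + s, rnorm(n))
    for (alt in c("two.sided", "greater", "less")) {
      ours <- wilcoxon_signed_rank(d, rep(0, n), alt)
      expect_true(ours$exact)
      expect_equal(ours$p_value, enum_signed_rank(d, alt),
                   tolerance = 1e-12, label = paste("seed", s, alt))
    }
  }
  expect_warning(res <- wilcoxon_signed_rank(c(1, 2), c(1, 2)), "zero")
  expect_equal(res$p_value, 1)
  # antisymmetric differences sit at the center of the null distribution
  d <- c(-2, -1, 1, 2)
  res2 <- wilcoxon_signed_rank(d, rep(0, 4))
  expect_equal(res2$statistic, sum(rank(abs(d))[d > 0]))
  expect_gt(res2$p_value, 0.6)
})

test_that("ties fall back to midranks and the approximate branch", {
  a <- c(1, 2, 2, 3); b <- c(2, 3, 3, 4)
  res <- wilcoxon_rank_sum(a, b)
  expect_false(res$exact)
  ref <- suppressWarnings(stats::wilcox.test(a, b, correct = TRUE))
  expect_equal(res$p_value, ref$p.value, tolerance = 1e-9)
})
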