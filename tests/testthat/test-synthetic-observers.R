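test_that("cohort generation matches the configured design and is deterministic", {
  cfg <- cohort_config(n_cp = 16, n_controls_per_cp = 2, seed = 7)
  co <- generate_cohort(cfg)
  groups <- vapply(co, `[[`, character(1), "group")
  expect_identical(sum(groups == "cp"), 16L)
  expect_identical(sum(groups == "control"), 32L)
  co2 <- generate_cohort(cohort_config(n_cp = 16, n_controls_per_cp = 2,
                                       seed = 7))
  expect_identical(co, co2)
  # matched controls share their CP's monitor (same age cluster assignment)
  ros <- cohort_roster(co)
  for (i in 1:16) {
    trip <- ros[grepl(sprintf("^(cp|ct)%02d", i), ros$participant_id), ]
    expect_identical(length(unique(trip$frame_rate)), 1L)
  }
  expect_error(generate_cohort(cohort_config(n_cp = 0)), "configuration")
  expect_error(cohort_config(age_clusters = list(c(23, 2, 0.4), c(54, 9, 0.4))),
               "sum to 1")
})

test_that("enlarging the cohort leaves existing observers untouched", {
  small <- generate_cohort(cohort_config(n_cp = 4, seed = 3))
  big <- generate_cohort(cohort_config(n_cp = 8, seed = 3))
  expect_identical(small[1:4], big[1:4])
})

test_that("with all group effects disabled CP and control thresholds are exchangeable", {
  cfg <- cohort_config(n_cp = 60, n_controls_per_cp = 1,
                       cp_threshold_multiplier = 1, group_rt_shift = 0,
                       seed = 5)
  ros <- cohort_roster(generate_cohort(cfg))
  ks <- suppressWarnings(ks.test(ros$true_pt80[ros$group == "cp"],
                                 ros$true_pt80[ros$group == "control"]))
  expect_gt(ks$p.value, 0.01)
})

test_that("true accuracy honors its anchor, bounds and monotonicities", {
  p <- ideal_profile()
  expect_equal(true_accuracy(p, p$true_pt80, 0), 0.8)
  p0 <- ideal_profile(lapse = 0)
  expect_equal(true_accuracy(p0, 1e7, 0), 1.0, tolerance = 1e-9)
  xs <- seq(5, 200, by = 5)
  expect_true(all(diff(true_accuracy(p, xs, 0)) > 0))
  acc <- true_accuracy(p, xs, 0)
  expect_true(all(acc >= p$guess & acc <= 1 - p$lapse))
  # rotation penalties lower accuracy at fixed time
  expect_lt(true_accuracy(p, 40, 30), true_accuracy(p, 40, 0))
  expect_lt(true_accuracy(p, 40, 60), true_accuracy(p, 40, 30))
  expect_equal(true_accuracy(p, 40, -30), true_accuracy(p, 40, 30))
  expect_error(true_accuracy(p, -5, 0), "positive")
})

test_that("simulated trial accuracy matches the generating curve within 3 binomial SE", {
  p <- ideal_profile()
  for (case in list(c(x = 40, rot = 0), c(x = 60, rot = 30))) {
    truth <- true_accuracy(p, case["x"], case["rot"])
    z <- with_seed(17 + case["rot"], rbinom(1e4, 1, truth))
    se <- sqrt(truth * (1 - truth) / 1e4)
    expect_lt(abs(mean(z) - truth), 3 * se)
  }
})

test_that("reaction times follow the inverse-scale linear predictor", {
  # deterministic limit: -1/RT = -2 per second means RT = 500 ms
  p <- observer_profile("d", "control", age = 40, true_pt80 = 30,
                        rt_intercept = -2, rt_age_coef = 0,
                        rt_block_coef = 0, rt_noise_sd = 0)
  expect_equal(simulate_reaction_time(p, 1, seed = 1), 500)
  # a positive coefficient on the -1/RT scale means slower responses
  p2 <- observer_profile("d2", "control", age = 40, true_pt80 = 30,
                         rt_intercept = -2, rt_age_coef = 0,
                         rt_block_coef = 0.1, rt_noise_sd = 0)
  expect_gt(simulate_reaction_time(p2, 5, seed = 1),
            simulate_reaction_time(p2, 1, seed = 1))
  # Monte-Carlo mean of -1/RT agrees with the analytic linear predictor
  p3 <- ideal_profile()
  draws <- simulate_reaction_time(p3, 2, seed = 23, n = 1e4)
  y <- -1 / (draws / 1000)
  eta <- psynorm:::rt_linear_predictor(p3, 2)
  expect_lt(abs(mean(y) - eta), 3 * p3$rt_noise_sd / sqrt(1e4))
  # group shift slows CP observers
  pc <- observer_profile("c", "cp", age = 40, true_pt80 = 30,
                         rt_group_coef = 0.3, rt_noise_sd = 0)
  pn <- observer_profile("n", "control", age = 40, true_pt80 = 30,
                         rt_group_coef = 0.3, rt_noise_sd = 0)
  expect_gt(simulate_reaction_time(pc, 1, seed = 2),
            simulate_reaction_time(pn, 1, seed = 2))
})

test_that("experiment templates emit the designed trial counts", {
  co <- generate_cohort(cohort_config(n_cp = 1, seed = 11))
  # experiment 5: 192 4AFC trials, 48 per presentation time
  e5 <- generate_experiment(co, 5, seed = 2)
  one <- e5[e5$participant_id == "cp01", ]
  expect_identical(nrow(one), 192L)
  expect_true(all(table(one$presentation_ms) == 48))
  # counterbalancing: each stimulus is target exactly once per time
  asg <- attr(e5, "stimulus_assignment")
  expect_true(all(table(asg$stimulus, asg$presentation_ms) == 1))
  # experiment 3: two test blocks of 56 (7 rotations x 4 targets + 4 distractors)
  e3 <- generate_experiment(co, 3, seed = 2)
  t3 <- e3[e3$participant_id == "cp01" & e3$phase == "test", ]
  expect_identical(nrow(t3), 112L)
  expect_true(all(table(t3$block) == 56))
  expect_true(all(table(t3$rotation, t3$role) == 8))
  # experiment 6: 12 cycles x 32 test trials, durations balanced 8 target +
  # 8 distractor per duration within each cycle
  e6 <- generate_experiment(co, 6, seed = 2)
  t6 <- e6[e6$participant_id == "cp01" & e6$phase == "test", ]
  expect_identical(nrow(t6), 384L)
  pt_lv <- sort(unique(t6$presentation_ms))
  expect_identical(length(pt_lv), 4L)
  for (cyc in unique(t6$block)) {
    cyc_t <- t6[t6$block == cyc, ]
    expect_true(all(table(cyc_t$presentation_ms, cyc_t$role) == 4))
  }
  expect_error(generate_experiment(co, 7, seed = 2), "configuration")
})

test_that("staircase test blocks of 8 contain every target exactly once", {
  co <- generate_cohort(cohort_config(n_cp = 1, seed = 13))
  e1 <- generate_experiment(co, 1, seed = 5, n_staircase_trials = 32)
  tst <- e1[e1$phase == "test" & e1$participant_id == "cp01", ]
  expect_true(all(table(tst$block) == 8))
  expect_true(all(tapply(tst$role, tst$block,
                         function(r) sum(r == "target")) == 4))
  # training rounds have unlimited presentation
  trn <- e1[e1$phase == "training", ]
  expect_true(all(!is.finite(trn$presentation_ms)))
})

test_that("matched controls receive their CP's stimulus orderings", {
  co <- generate_cohort(cohort_config(n_cp = 1, n_controls_per_cp = 2,
                                      seed = 19))
  e3 <- generate_experiment(co, 3, seed = 4)
  tst <- e3[e3$phase == "test", ]
  cp <- tst[tst$participant_id == "cp01", c("block", "trial", "role", "rotation")]
  for (id in c("ct01_1", "ct01_2")) {
    ct <- tst[tst$participant_id == id, c("block", "trial", "role", "rotation")]
    expect_identical(cp, ct, ignore_attr = TRUE)
  }
})

test_that("trial-log round trip preserves the schema and frame invariant", {
  co <- generate_cohort(cohort_config(n_cp = 2, seed = 23))
  e1 <- generate_experiment(co, 1, seed = 6, n_staircase_trials = 24)
  path <- withr::local_tempfile(fileext = ".csv")
  write_trial_log(e1, path)
  back <- read_trial_log(path)
  expect_identical(nrow(back), nrow(e1))
  rep <- validate_trial_log(back, cohort_roster(co))
  expect_true(rep$valid)
  # corruption is flagged with the offending rows
  bad <- back
  bad$presentation_ms[which(is.finite(bad$presentation_ms))[1]] <- 7
  rep2 <- validate_trial_log(bad, cohort_roster(co))
  expect_false(rep2$valid)
  expect_true(any(rep2$violations$problem == "not a frame multiple"))
  rep3 <- validate_trial_log(bad[, -3])
  expect_identical(rep3$missing_columns, "phase")
})
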