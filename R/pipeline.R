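# End-to-end orchestration: simulate a cohort, run the staircase
# experiments, fit and invert psychometric functions, propagate
# 90%-criterion presentation times into the rotation experiments, fit the
# model ladders and compute residual scores and group tests, emitting a
# machine-readable report.

#' Full study configuration
#'
#' @param cohort a [cohort_config()].
#' @param staircase list: `x_init`, `c`, `phi`, `n_trials`.
#' @param psychometric list: `guess`, `lapse_max`, `criterion`.
#' @param experiments experiment ids to run (subset of 1..6).
#' @param score_experiments experiments for which residual scores are
#'   computed (leave-one-out refits are the expensive stage).
#' @param out_dir optional output directory for trial logs, roster, the
#'   echoed configuration and the report.
#' @param seed root seed; all stage seeds are derived from it.
#' @return an object of class `run_config`.
#' @export
run_config <- function(cohort = cohort_config(),
                       staircase = list(x_init = 200, c = 100, phi = 0.8,
                                        n_trials = 64),
                       psychometric = list(guess = 0.5, lapse_max = 0.05,
                                           criterion = 0.9),
                       experiments = 1:6,
                       score_experiments = 1:2,
                       out_dir = NULL, seed = 1) {
  stopifnot(all(experiments %in% 1:6))
  structure(list(cohort = cohort, staircase = staircase,
                 psychometric = psychometric,
                 experiments = experiments,
                 score_experiments = score_experiments,
                 out_dir = out_dir, seed = as.integer(seed)),
            class = "run_config")
}

#' Run the full simulated study
#'
#' Stages: (1) generate the cohort; (2) experiments 1/2 with feedback
#' training and staircase-driven testing, yielding per-participant PT80
#' estimates; (3) constrained psychometric fits to the staircase data and
#' inversion at the 90 percent criterion; (4) experiments 3/4 at each CP's
#' fitted PT90 (shared with the matched controls); (5) experiments 5/6;
#' (6) per-experiment filtering, model ladders with likelihood-ratio
#' tests; (7) residual scores and Wilcoxon comparisons. The whole run is
#' deterministic under the configured seed.
#'
#' @param config a [run_config()].
#' @return a report list: `roster`, per-experiment sections (`ladder`
#'   tests, `residual_tests`, threshold `estimates`, psychometric `pt90`),
#'   and `provenance` (seed, configuration echo, package version).
#' @export
run_full_study <- function(config = run_config()) {
  stopifnot(inherits(config, "run_config"))
  stage <- "cohort"
  report <- list(experiments = list())
  result <- tryCatch({
    cohort <- generate_cohort(config$cohort)
    roster <- cohort_roster(cohort)
    trials <- list()
    estimates <- list()
    pt90 <- list()
    sc <- config$staircase
    psy <- config$psychometric

    for (e in intersect(1:2, config$experiments)) {
      stage <- paste0("experiment_", e)
      trials[[e]] <- generate_experiment(
        cohort, e, seed = derive_seed(config$seed, "exp", e),
        n_staircase_trials = sc$n_trials,
        staircase = sc[c("x_init", "c", "phi")])
      estimates[[e]] <- attr(trials[[e]], "estimates")

      stage <- paste0("psychometric_", e)
      test <- trials[[e]][trials[[e]]$phase == "test", ]
      fits <- lapply(split(test, test$participant_id), function(d)
        fit_psychometric(d, guess = psy$guess, lapse_max = psy$lapse_max,
                         ci = FALSE))
      pt90[[e]] <- vapply(fits, function(f)
        tryCatch(invert_psychometric(f$model, psy$criterion),
                 error = function(err) NA_real_), numeric(1))
    }

    for (e in intersect(3:4, config$experiments)) {
      stage <- paste0("experiment_", e)
      src <- pt90[[e - 2]]
      fixed <- if (!is.null(src)) {
        cp_ids <- roster$participant_id[roster$group == "cp"]
        src[names(src) %in% cp_ids & !is.na(src)]
      }
      trials[[e]] <- generate_experiment(
        cohort, e, seed = derive_seed(config$seed, "exp", e),
        fixed_pt = if (length(fixed)) fixed else NULL)
    }
    for (e in intersect(5:6, config$experiments)) {
      stage <- paste0("experiment_", e)
      trials[[e]] <- generate_experiment(
        cohort, e, seed = derive_seed(config$seed, "exp", e))
    }

    for (e in config$experiments) {
      stage <- paste0("analysis_", e)
      section <- list()
      if (e %in% 1:2) {
        filt <- filter_trials(do.call(rbind, trials[intersect(c(e, e + 2),
                                                              config$experiments)]),
                              default_filter_spec(e))
        md <- prepare_model_data(filt$trials, roster)
        section$rt_ladder <- fit_ladder(build_ladder(e, "inv_rt"), md)$tests
        section$audit <- filt$audit
        pt_tab <- pt80_table(estimates[[e]], roster)
        section$pt80_ladder <- fit_ladder(build_ladder(e, "log_pt80"),
                                          pt_tab)$tests
        section$estimates <- estimates[[e]]
        section$pt90 <- pt90[[e]]
        if (e %in% config$score_experiments) {
          stage <- paste0("scoring_", e)
          sc_rt <- score_participants(build_ladder(e, "inv_rt")[[1]], md)
          sc_pt <- score_participants(build_ladder(e, "log_pt80")[[1]],
                                      pt_tab)
          section$residual_tests <- list(
            inv_rt = wilcoxon_rank_sum(
              sc_rt$mean_residual[sc_rt$group == "cp"],
              sc_rt$mean_residual[sc_rt$group == "control"], "greater"),
            log_pt80 = wilcoxon_rank_sum(
              sc_pt$mean_residual[sc_pt$group == "cp"],
              sc_pt$mean_residual[sc_pt$group == "control"], "greater"))
          section$scores <- list(inv_rt = sc_rt, log_pt80 = sc_pt)
        }
      } else {
        keep <- trials[[e]][trials[[e]]$phase == "test", ]
        md <- prepare_model_data(keep, roster)
        section$accuracy_ladder <- fit_ladder(build_ladder(e, "correct"),
                                              md)$tests
        if (e %in% config$score_experiments) {
          stage <- paste0("scoring_", e)
          sc_acc <- score_participants(build_ladder(e, "correct")[[1]], md)
          section$residual_tests <- list(correct = wilcoxon_rank_sum(
            sc_acc$mean_residual[sc_acc$group == "cp"],
            sc_acc$mean_residual[sc_acc$group == "control"], "less"))
          section$scores <- list(correct = sc_acc)
        }
      }
      report$experiments[[as.character(e)]] <- section
    }

    report$roster <- roster
    report$provenance <- list(
      seed = config$seed,
      package_version = as.character(utils::packageVersion("psynorm")),
      config = config[c("staircase", "psychometric", "experiments")],
      cohort_config = unclass(config$cohort))

    if (!is.null(config$out_dir)) {
      stage <- "write_outputs"
      dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
      utils::write.csv(roster, file.path(config$out_dir, "roster.csv"),
                       row.names = FALSE)
      for (e in config$experiments)
        write_trial_log(trials[[e]],
                        file.path(config$out_dir,
                                  sprintf("trials_exp%d.csv", e)))
      jsonlite::write_json(report$provenance,
                           file.path(config$out_dir, "config_echo.json"),
                           auto_unbox = TRUE, digits = NA)
      .write_report(report, file.path(config$out_dir, "report.json"))
    }
    report
  }, error = function(err) {
    stop(sprintf("pipeline failed at stage '%s': %s", stage,
                 conditionMessage(err)), call. = FALSE)
  })
  result
}

.write_report <- function(report, path) {
  simplify <- function(x) {
    if (is.data.frame(x)) x
    else if (is.list(x)) lapply(x, simplify)
    else x
  }
  jsonlite::write_json(simplify(report[c("experiments", "provenance")]),
                       path, auto_unbox = TRUE, digits = NA, force = TRUE)
}
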