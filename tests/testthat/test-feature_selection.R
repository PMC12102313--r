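# helper: first-time single-wave records with configurable truth
selection_sim <- function(n, effects = numeric(), repeat_effects = NULL,
                          with_repeats = FALSE, seed = 31) {
  base <- covimod_like_scenario()
  cfg <- simulation_config(
    n_initial = n, n_waves = 1L, wave_dates = as.Date("2020-06-11"),
    prior_participation_probs = if (with_repeats)
      c("0" = 0.5, "1" = 0.2, "2" = 0.2, "3" = 0.1) else c("0" = 1),
    covariate_freqs = base$covariate_freqs, beta0 = log(4),
    effects = effects, phi = 2, fatigue = list(form = "none"),
    repeat_effects = repeat_effects, seed = seed
  )
  preprocess_records(simulate_panel(cfg)$records, seed = seed + 1)
}

test_that("the +/- 5 percent thresholds match their closed form to four decimals", {
  thr <- selection_thresholds()
  expect_equal(unname(thr), c(log(0.95), log(1.05)))
  expect_equal(round(unname(thr), 4), c(-0.0513, 0.0488))
})

test_that("the selection rule classifies medians against the computed thresholds", {
  # fabricated draws with known medians: 0.06 (out), 0.03 (in), -0.052 (out
  # in fatigue mode), -0.02 (in)
  meds <- c(a = 0.06, b = 0.03, c = -0.052, d = -0.02)
  draws <- matrix(rep(meds, each = 20), 20, dimnames = list(NULL, names(meds)))
  fit <- fatiguecast:::new_posterior_draws(
    draws, rep(1:2, 10), "intensity_selection",
    meta = list(test_cols = names(meds)))
  sel_i <- select_features(fit, "intensity")
  expect_setequal(sel_i$selected, c("a", "c"))
  sel_f <- select_features(fit, "fatigue")
  expect_setequal(sel_f$selected, "c")
  fit0 <- fit
  fit0$draws <- fit$draws[0, , drop = FALSE]
  expect_error(select_features(fit0, "intensity"), "empty")
})

test_that("a real employment effect is recovered and selected; spurious selections stay rare", {
  rec <- selection_sim(2000L,
                       effects = c("employment:Full-time employed" = 0.20))
  fit <- fit_intensity_selection(rec, mcmc = quick_mcmc(seed = 32,
                                                        warmup = 800,
                                                        iter = 800))
  sel <- select_features(fit, "intensity")
  ft_med <- sel$table$median[sel$table$column == "employment:Full-time employed"]
  # sum-to-zero recentring absorbs the mean effect 0.2/9 into the baseline
  expect_gt(ft_med, 0.1)
  expect_lt(ft_med, 0.3)
  expect_true("employment:Full-time employed" %in% sel$selected)

  null_rec <- selection_sim(2000L, seed = 33)
  null_fit <- fit_intensity_selection(null_rec,
                                      mcmc = quick_mcmc(seed = 34,
                                                        warmup = 800,
                                                        iter = 800))
  null_sel <- select_features(null_fit, "intensity")
  expect_lte(length(null_sel$selected), ceiling(0.2 * nrow(null_sel$table)))
  expect_error(fit_intensity_selection(selection_sim(200L, with_repeats = TRUE)),
               "repeat rows")
})

test_that("fatigue selection recovers a subgroup fatigue effect under the negative-domain prior", {
  # student-heavy design so the subgroup contrast is well powered
  base <- covimod_like_scenario()
  freqs <- base$covariate_freqs
  freqs$employment <- setNames(c(0.20, 0.05, 0.05, 0.35, 0.15, 0.02, 0.06,
                                 0.02, 0.10), survey_levels$employment)
  cfg <- simulation_config(
    n_initial = 5000L, n_waves = 1L, wave_dates = as.Date("2020-06-11"),
    prior_participation_probs = c("0" = 0.3, "1" = 0.3, "2" = 0.3, "3" = 0.1),
    covariate_freqs = freqs, beta0 = log(4), phi = 2,
    fatigue = list(form = "none"),
    repeat_effects = c("employment:Student (15+)" = -0.15), seed = 35
  )
  rec <- preprocess_records(simulate_panel(cfg)$records, seed = 30)
  plugin <- select_features(
    fit_intensity_selection(rec[rec$repeat_count == 0, ],
                            mcmc = quick_mcmc(seed = 36, warmup = 600,
                                              iter = 600)),
    "intensity")
  fit <- fit_fatigue_selection(rec, plugin,
                               mcmc = quick_mcmc(seed = 37, warmup = 800,
                                                 iter = 800))
  # negative-domain prior: every fatigue coefficient draw is <= 0
  expect_true(all(fit$draws[, fit$meta$test_cols] <= 0))
  sel <- select_features(fit, "fatigue")
  stu <- sel$table$median[sel$table$column == "employment:Student (15+)"]
  expect_gt(stu, -0.30)
  expect_lt(stu, -0.05)
  expect_true("employment:Student (15+)" %in% sel$selected)
})

test_that("with plug-in offsets and no fatigue in truth the fatigue coefficients shrink to zero", {
  rec <- selection_sim(2500L, with_repeats = TRUE, seed = 38)
  plugin <- select_features(
    fit_intensity_selection(rec[rec$repeat_count == 0, ],
                            mcmc = quick_mcmc(seed = 39, warmup = 600,
                                              iter = 600)),
    "intensity")
  fit <- fit_fatigue_selection(rec, plugin,
                               mcmc = quick_mcmc(seed = 40, warmup = 800,
                                                 iter = 800))
  sel <- select_features(fit, "fatigue")
  # spurious fatigue selections are rare and medians hug zero
  expect_lte(length(sel$selected), ceiling(0.2 * nrow(sel$table)))
  expect_gt(median(sel$table$median), -0.05)
})

test_that("the across-wave union combines selections symmetrically", {
  mk <- function(selected) {
    tab <- data.frame(column = c("s", "r", "q"), median = 0, q2.5 = 0,
                      q97.5 = 0, selected = c("s", "r", "q") %in% selected)
    structure(list(table = tab, selected = tab$column[tab$selected]),
              class = "selection_result")
  }
  expect_setequal(union_selected(mk("s"), mk(c("s", "r"))), c("s", "r"))
  expect_length(union_selected(mk(character()), mk(character())), 0)
  expect_identical(union_selected(mk("s"), mk("r")),
                   union_selected(mk("r"), mk("s")))
  bad <- mk("s")
  bad$table$column <- c("x", "y", "z")
  expect_error(union_selected(mk("s"), bad), "different column sets")
})
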