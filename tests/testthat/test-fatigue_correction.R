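test_that("MAPE and coverage satisfy their identities on trivial curves", {
  ref <- c(10, 10, 10, 10)
  expect_equal(mape_curve(ref, ref), 0)
  expect_equal(mape_curve(1.1 * ref, ref), 10, tolerance = 1e-12)
  expect_equal(coverage95_curve(ref, ref - 1, ref + 1), 1)
  expect_equal(coverage95_curve(ref, ref + 1, ref + 2), 0)
  expect_equal(coverage95_curve(c(1, 5), c(0, 6), c(2, 7)), 0.5)
})

test_that("the post-stratification sum matches hand expansion on degenerate weights", {
  # all mass on one stratum: male, household 1, rural, full-time employed
  v_ag <- matrix(0, 85, 2, dimnames = list(0:84, survey_levels$sex))
  v_ag["30", "male"] <- 1
  w1 <- make_weights(v_ag = v_ag, v_h = c(1, 0, 0, 0, 0), v_u = c(1, 0, 0),
                     v_j = c(1, rep(0, 8)))
  coefs <- c("sex:female" = 0.3, "household_size:2" = 0.2,
             "urban_type:urban" = -0.1, "employment:Retired" = -0.4)
  fit <- fake_correction_fit(coefs, beta0 = log(5))
  # reference levels everywhere: lambda = exp(beta0) at every age
  cv <- poststrat_age_curve(fit, w1)
  expect_equal(cv$median, rep(5, 85), tolerance = 1e-6)
  expect_true(all(cv$lo <= cv$median & cv$median <= cv$hi))

  # uniform two-level sex margin with effect +delta on female:
  # lambda = exp(beta0) * (1 + e^delta) / 2
  v_ag2 <- matrix(0, 85, 2, dimnames = list(0:84, survey_levels$sex))
  v_ag2["30", ] <- 0.5
  w2 <- make_weights(v_ag = v_ag2, v_h = c(1, 0, 0, 0, 0), v_u = c(1, 0, 0),
                     v_j = c(1, rep(0, 8)))
  cv2 <- poststrat_age_curve(fit, w2)
  expect_equal(cv2$median, rep(5 * (1 + exp(0.3)) / 2, 85), tolerance = 1e-6)

  # malformed margins are rejected
  w_bad <- w1
  w_bad$v_h <- c(0.5, 0, 0, 0, 0)
  expect_error(poststrat_age_curve(fit, w_bad), "does not sum to 1")
})

test_that("fatigue terms are inert on first-time-only data", {
  # full-scale single wave so the age curve is well pinned and the
  # Monte-Carlo error of the two median curves sits well under the bound
  sim <- simulate_panel(wave21_like_scenario())
  rec <- preprocess_records(sim$records, seed = 70)
  first <- rec[rec$repeat_count == 0, ]
  w <- build_poststrat_weights(synthetic_pop_margins(), rec)
  mc <- quick_mcmc(seed = 70, warmup = 1500, iter = 2500)
  hill <- list(gamma = 1.2, zeta = -1.9, eta = 1.2)
  fa <- fit_correction(first, "global", hill, adjust = TRUE, hsgp_m = 15,
                       mcmc = mc)
  fu <- fit_correction(first, adjust = FALSE, hsgp_m = 15, mcmc = mc)
  ca <- poststrat_age_curve(fa, w)
  cu <- poststrat_age_curve(fu, w)
  expect_lt(mape_curve(ca$median, cu$median), 2)
  expect_error(fit_correction(first, "global", hill_init = NULL,
                              adjust = TRUE), "hill_init")
})

test_that("the adjusted model recovers the truth curve; the unadjusted model is biased downward", {
  wv <- fx_wave21()
  rec <- wv$rec
  w <- wv$weights
  cfg <- wv$sim$truth$config
  mc <- quick_mcmc(seed = 72, warmup = 1200, iter = 1500)
  hill <- list(gamma = 1.2, zeta = -1.9, eta = 1.2)
  fa <- fit_correction(rec, "global", hill, adjust = TRUE, hsgp_m = 20,
                       mcmc = mc)
  fu <- fit_correction(rec, adjust = FALSE, hsgp_m = 20, mcmc = mc)
  ca <- poststrat_age_curve(fa, w)
  cu <- poststrat_age_curve(fu, w)

  # the generating truth, post-stratified with the same margins
  eff <- function(key) if (key %in% names(cfg$effects)) cfg$effects[[key]] else 0
  marg <- function(f, v) {
    sum(v * exp(vapply(survey_levels[[f]],
                       function(l) eff(paste0(f, ":", l)), 0)))
  }
  truth <- exp(cfg$beta0 + cfg$age_curve(0:84)) *
    marg("sex", w$v_g) * marg("household_size", w$v_h) *
    marg("urban_type", w$v_u) * marg("employment", w$v_j)

  expect_lt(mape_curve(ca$median, truth), 10)
  expect_gt(mean(cu$median < truth), 0.9) # systematic under-estimation
  expect_gt(mape_curve(cu$median, truth), mape_curve(ca$median, truth))
})

test_that("the inclusion experiment reproduces the trivial metric anchors", {
  rec <- fx_small_panel()$rec
  wv <- rec[rec$wave == 2, ]
  w <- fx_weights()
  hill <- list(gamma = 1.2, zeta = -1.9, eta = 1.2)
  ie <- inclusion_experiment(wv, "global", hill, w, steps = c(1, 3),
                             hsgp_m = 12,
                             mcmc = quick_mcmc(seed = 73, warmup = 350,
                                               iter = 350))
  expect_identical(ie$metrics$r, c(1, 3))
  expect_true(all(ie$metrics$mape_adj >= 0))
  expect_true(all(ie$metrics$cov_adj >= 0 & ie$metrics$cov_adj <= 1))
  expect_s3_class(ie$baseline, "age_intensity_curve")
  expect_error(inclusion_experiment(wv[wv$repeat_count > 0, ], "global",
                                    hill, w), "no first-time rows")
})
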