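test_that("overall intensity reduces to closed forms on fabricated draws", {
  # all effects zero, f == 0, weights proper: lambda = exp(beta0) exactly
  fit <- fake_correction_fit(beta0 = log(5))
  w <- make_weights()
  oi <- overall_intensity(fit, w)
  expect_equal(oi$median, 5, tolerance = 1e-6)
  expect_equal(oi$lo, oi$hi, tolerance = 1e-9)

  # degenerate weights pick out a single stratum's intensity
  v_ag <- matrix(0, 85, 2, dimnames = list(0:84, survey_levels$sex))
  v_ag["40", "female"] <- 1
  w1 <- make_weights(v_ag = v_ag, v_h = c(0, 1, 0, 0, 0), v_u = c(0, 0, 1),
                     v_j = c(0, 0, 0, 0, 1, 0, 0, 0, 0))
  coefs <- c("sex:female" = 0.3, "household_size:2" = 0.2,
             "urban_type:urban" = -0.1, "employment:Retired" = -0.4)
  fit2 <- fake_correction_fit(coefs, beta0 = log(5))
  oi2 <- overall_intensity(fit2, w1)
  expect_equal(oi2$median, 5 * exp(0.3 + 0.2 - 0.1 - 0.4), tolerance = 1e-6)
})

test_that("subgroup intensities renormalise weights and apply fixed effects", {
  coefs <- c("sex:female" = 0.25, "household_size:3" = 0.1,
             "employment:Stay-at-home parent" = -0.3)
  fit <- fake_correction_fit(coefs, beta0 = log(4))
  w <- make_weights()
  # the full population without fixed covariates equals the overall estimate
  full <- subgroup_intensity(fit, w, 0:84, label = "all")
  oi <- overall_intensity(fit, w)
  expect_equal(full$median, oi$median, tolerance = 1e-9)

  # stay-at-home 19-64 with otherwise-uniform weights: the employment
  # margin collapses to exp(-0.3), the rest is unchanged (f == 0)
  sub <- subgroup_intensity(fit, w, 19:64,
                            fixed = c(employment = "Stay-at-home parent"),
                            label = "stay-at-home")
  # uniform employment margin: 8 reference-effect levels + stay-at-home
  emp_margin <- (8 + exp(-0.3)) / 9
  expect_equal(sub$median, oi$median / emp_margin * exp(-0.3),
               tolerance = 1e-6)
  expect_error(subgroup_intensity(fit, w, integer()), "non-empty")
  expect_error(subgroup_intensity(fit, w, 10:90), "subset of 0..84")
})

test_that("the weighted participant bootstrap behaves on degenerate and iid inputs", {
  rec <- fx_small_panel()$rec
  wv <- rec[rec$wave == 1, ][1:200, ]
  w <- fx_weights()
  const <- wv
  const$contact_count <- 7L
  b0 <- bootstrap_intensity(const, w, B = 300, seed = 1)
  expect_equal(c(b0$median, b0$lo, b0$hi), c(7, 7, 7))

  iid <- wv
  set.seed(2)
  iid$contact_count <- rnbinom(nrow(iid), size = 2, mu = 5)
  b1 <- bootstrap_intensity(iid, w, B = 2000, seed = 3)
  expect_equal(b1$median, mean(iid$contact_count), tolerance = 0.15)
  b2 <- bootstrap_intensity(iid, w, B = 2000, seed = 3)
  expect_identical(b1, b2) # bit-identical under a fixed seed
  expect_error(bootstrap_intensity(iid[0, ], w), "empty wave")
  expect_error(bootstrap_intensity(iid, w, B = 50), "at least 200")
})

test_that("carry-over priors are centred on posterior means with the stated spreads", {
  coefs <- c("sex:female" = 0.5, "employment:Retired" = -0.2)
  fit <- fake_correction_fit(coefs, beta0 = log(4))
  fit$draws <- cbind(fit$draws, "gamma:global" = 1.4, "zeta:global" = -1.7,
                     "eta:global" = 1.25)
  fit$meta$q_names <- "global"
  pr <- fatiguecast:::carry_priors(fit, c(beta = 0.3, gamma = 0.3,
                                          zeta = 0.1, eta = 0.1),
                                   eta_carry = "reciprocal")
  expect_equal(pr$beta[["sex:female"]]$par1, 0.5)
  expect_equal(pr$beta[["sex:female"]]$par2, 0.3)
  expect_equal(pr$gamma[["global"]]$family, "halfnormal")
  expect_equal(pr$gamma[["global"]]$par1, 1.4)
  expect_equal(pr$zeta[["global"]]$par2, 0.1)
  # the literal carry rule centres eta on the reciprocal of the mean
  expect_equal(pr$eta[["global"]]$par1, 1 / 1.25, tolerance = 1e-12)
  pr2 <- fatiguecast:::carry_priors(fit, c(beta = 0.3, gamma = 0.3,
                                           zeta = 0.1, eta = 0.1),
                                    eta_carry = "direct")
  expect_equal(pr2$eta[["global"]]$par1, 1.25)
})

test_that("sequential fitting is stable across statistically identical waves", {
  base <- covimod_like_scenario(n_initial = 700L, n_waves = 2L,
                                recruit_per_wave = 500L, retention = 0.55,
                                prior_participation_probs = c("0" = 1),
                                seed = 80L)
  rec <- preprocess_records(simulate_panel(base)$records, seed = 81)
  w <- build_poststrat_weights(synthetic_pop_margins(), rec)
  hill <- list(gamma = 1.2, zeta = -1.9, eta = 1.2)
  rw <- run_waves(rec, w, "adjusted", "global", hill, hsgp_m = 15,
                  mcmc = quick_mcmc(seed = 82, warmup = 500, iter = 500))
  est <- rw$estimates
  expect_equal(nrow(est), 2)
  expect_true(all(est$lo <= est$median & est$median <= est$hi))
  expect_lt(abs(est$median[2] / est$median[1] - 1), 0.1)
  # carry centres for the Hill parameters stay in their domains
  expect_true(all(rw$carries[["2"]][c("gamma:global", "eta:global")] > 0))
})
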