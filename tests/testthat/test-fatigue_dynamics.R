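test_that("the Hill curve has its closed-form anchors, bounds and monotonicity", {
  expect_equal(hill_rho(0, 1.18, -1.9, 1.16), 0)
  expect_equal(hill_rho(1, gamma = 2, zeta = 0, eta = 1), -1)
  expect_equal(hill_rho(1e9, 1.18, -1.9, 1.16), -1.18, tolerance = 1e-4)
  expect_equal(100 * (exp(hill_rho(1e12, 1.18, -1.9, 1.16)) - 1), -69.27,
               tolerance = 0.01)
  set.seed(50)
  for (i in 1:200) {
    g <- runif(1, 0.1, 3)
    z <- runif(1, -3, 2)
    e <- runif(1, 0.2, 3)
    r <- sort(runif(6, 0, 30))
    v <- hill_rho(r, g, z, e)
    expect_true(all(diff(v) <= 0))            # non-increasing in r
    expect_true(all(v > -g & v <= 0))         # bounded in (-gamma, 0]
  }
  expect_error(hill_rho(1, gamma = -1, zeta = 0, eta = 1), "positive")
  expect_error(hill_rho(-1, gamma = 1, zeta = 0, eta = 1), "non-negative")
})

test_that("the percent-reduction transform matches its closed form", {
  rho_draws <- matrix(rep(c(0, -0.5, -1.18), each = 30), 30,
                      dimnames = list(NULL, c("rho[0]", "rho[1]", "rho[2]")))
  fit <- fatiguecast:::new_posterior_draws(rho_draws, rep(1:2, 15), "x",
                                           meta = list())
  curve <- percent_reduction_curve(fit)
  expect_equal(curve$pct_median, 100 * (exp(c(0, -0.5, -1.18)) - 1),
               tolerance = 1e-10)
  expect_equal(curve$pct_median[3], -69.27, tolerance = 0.01)
  expect_equal(curve$median, c(0, -0.5, -1.18))
})

test_that("a null-fatigue panel yields a near-zero Hill effect at r = 1", {
  base <- covimod_like_scenario(n_initial = 1200L, n_waves = 4L,
                                recruit_per_wave = 150L,
                                fatigue = list(form = "none"), seed = 51L)
  rec <- preprocess_records(simulate_panel(base)$records, seed = 52)
  fit <- fit_longitudinal(rec, form = "hill",
                          mcmc = quick_mcmc(seed = 53, warmup = 900,
                                            iter = 900))
  expect_lt(abs(median(fit$draws[, "rho[1]"])), 0.05)
  expect_identical(unique(fit$draws[, "rho[0]"]), 0)
})

test_that("fixed-effect fatigue forms respect their identifiability anchors", {
  pan <- fx_small_panel()
  rec <- pan$rec
  mc <- quick_mcmc(seed = 54, warmup = 400, iter = 400)
  fid <- fit_longitudinal(rec, form = "identical", mcmc = mc)
  cid <- percent_reduction_curve(fid)
  expect_equal(cid$median[1], 0)
  expect_lt(diff(range(cid$median[-1])), 1e-10) # constant for r >= 1
  find <- fit_longitudinal(rec, form = "independent", mcmc = mc)
  expect_identical(unique(find$draws[, "rho[0]"]), 0)
  # repeat-level effects are free: the estimated curve deepens with r
  cind <- percent_reduction_curve(find)
  expect_lt(cind$median[length(cind$median)], cind$median[2])
})

test_that("intercept shifts in the truth move beta0, not the fatigue curve", {
  mk <- function(b0, seed) {
    cfg <- covimod_like_scenario(n_initial = 900L, n_waves = 4L,
                                 recruit_per_wave = 100L, beta0 = b0,
                                 seed = seed)
    preprocess_records(simulate_panel(cfg)$records, seed = 60)
  }
  mc <- quick_mcmc(seed = 61, warmup = 900, iter = 900)
  f1 <- fit_longitudinal(mk(log(3), 62L), form = "hill", mcmc = mc)
  f2 <- fit_longitudinal(mk(log(3) + 0.5, 62L), form = "hill", mcmc = mc)
  # the two panels are independent NB realisations, so the comparison
  # carries both sampling and Monte-Carlo noise; the bounds below are wide
  # enough for that yet still detect leakage of the baseline into fatigue
  shift <- median(f2$draws[, "beta0"]) - median(f1$draws[, "beta0"])
  expect_gt(shift, 0.25)
  expect_lt(shift, 0.75)
  rho1 <- apply(f1$draws[, c("rho[1]", "rho[5]")], 2, median)
  rho2 <- apply(f2$draws[, c("rho[1]", "rho[5]")], 2, median)
  expect_lt(max(abs(rho1 - rho2)), 0.15)
})

test_that("form comparison ranks the Hill model above the identical-effect model on Hill-truth data", {
  # deep repeat ladder: the identical-effect model's misfit is structural
  rec <- fx_wave21()$rec
  cmp <- compare_forms(rec, forms = c("hill", "identical", "gp"),
                       mcmc = quick_mcmc(seed = 63, warmup = 800, iter = 1000))
  tab <- cmp$table
  expect_gt(tab$elpd_waic[tab$form == "hill"],
            tab$elpd_waic[tab$form == "identical"])
  # Hill and GP median curves agree within their joint posterior spread
  expect_lt(max(abs(cmp$curves$hill$median - cmp$curves$gp$median)), 0.2)
  expect_equal(tab$sup_dist[1], 0)
})
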