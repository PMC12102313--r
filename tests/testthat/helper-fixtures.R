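# Shared fixtures, computed lazily and cached for the whole test run so
# expensive model fits are reused across test files.

.fixtures <- new.env(parent = emptyenv())

fixture <- function(name, expr) {
  if (!exists(name, envir = .fixtures)) assign(name, expr, envir = .fixtures)
  get(name, envir = .fixtures)
}

quick_mcmc <- function(seed = 11, chains = 1, warmup = 500, iter = 500) {
  mcmc_control(chains = chains, warmup = warmup, iter = iter, thin = 1,
               seed = seed)
}

# small multi-wave panel with Hill-fatigue truth (default scenario scaled down)
fx_small_panel <- function() fixture("small_panel", {
  sim <- simulate_panel(covimod_like_scenario(n_initial = 500L, n_waves = 4L,
                                              recruit_per_wave = 60L))
  list(sim = sim, rec = preprocess_records(sim$records, seed = 7))
})

# full-scale default scenario panel + hill longitudinal fit (used by the
# acceptance tests; one chain at reduced length)
fx_covimod_fit <- function() fixture("covimod_fit", {
  sim <- simulate_panel(covimod_like_scenario())
  rec <- preprocess_records(sim$records, seed = 7)
  fit <- fit_longitudinal(rec, form = "hill",
                          mcmc = mcmc_control(chains = 1, warmup = 1000,
                                              iter = 1200, thin = 1,
                                              seed = 41))
  list(rec = rec, fit = fit)
})

fx_weights <- function() fixture("weights", {
  build_poststrat_weights(synthetic_pop_margins(), fx_small_panel()$rec)
})

# single deep-ladder wave (wave-21-like) at moderate scale, with weights
fx_wave21 <- function() fixture("wave21", {
  sim <- simulate_panel(wave21_like_scenario(n_participants = 1600L,
                                             max_repeat = 10L))
  rec <- preprocess_records(sim$records, seed = 71)
  list(sim = sim, rec = rec,
       weights = build_poststrat_weights(synthetic_pop_margins(), rec))
})

# fabricated correction-model draws with known constant coefficients, for
# closed-form checks of the post-stratification sums
fake_correction_fit <- function(coefs = numeric(), beta0 = log(5), S = 40,
                                m = 15) {
  cols <- c("beta0", names(coefs), paste0("zf[", seq_len(m), "]"),
            "sigma_f", "ell_f", "phi")
  vals <- c(beta0, unname(coefs), rep(0, m), 1e-9, 0.3, 2)
  draws <- matrix(rep(vals, each = S), nrow = S,
                  dimnames = list(NULL, cols))
  fatiguecast:::new_posterior_draws(
    draws, chain = rep(1:2, length.out = S), model = "correction_adjusted",
    meta = list(adjust = TRUE, x_cols = names(coefs), q_names = character(0),
                hsgp = list(m = m, c = 1.5, m_phi = numeric(m)), R = 0L)
  )
}

# hand-built post-stratification table from explicit margins
make_weights <- function(v_ag = NULL, v_h = NULL, v_u = NULL, v_j = NULL) {
  if (is.null(v_ag)) {
    v_ag <- matrix(1 / 170, 85, 2,
                   dimnames = list(0:84, survey_levels$sex))
  }
  if (is.null(v_h)) v_h <- rep(1 / 5, 5)
  if (is.null(v_u)) v_u <- rep(1 / 3, 3)
  if (is.null(v_j)) v_j <- rep(1 / 9, 9)
  structure(list(v_ag = v_ag, v_g = colSums(v_ag), v_h = v_h, v_u = v_u,
                 v_j = v_j,
                 provenance = c(age_sex = "synthetic",
                                household_size = "synthetic",
                                urban_type = "synthetic",
                                employment = "synthetic")),
            class = "poststrat_table")
}
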