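## Synthetic longitudinal contact-survey panels with known ground truth.
## The generator is the package's test bed: it emulates the structure of a
## COVID-era German contact panel (quota-like covariate margins, repeat-
## participation ladders, NB counts with log-linear means, saturating
## Hill-shaped fatigue) so that every model stage can be validated against
## a recorded truth.

.age_group_range <- list(
  "Preschool (0-5)" = c(0, 5), "Raised at home (0-5)" = c(0, 5),
  "6-9" = c(6, 9), "10-14" = c(10, 14), "15-19" = c(15, 19),
  "20-24" = c(20, 24), "25-34" = c(25, 34), "35-44" = c(35, 44),
  "45-54" = c(45, 54), "55-64" = c(55, 64), "65-69" = c(65, 69),
  "70-74" = c(70, 74), "75-79" = c(75, 79), "80-84" = c(80, 84)
)

sample_level <- function(n, freqs) {
  sample(names(freqs), n, replace = TRUE, prob = freqs)
}

#' Simulation configuration for a synthetic contact-survey panel
#'
#' @param n_initial initial cohort size at the first wave.
#' @param n_waves number of waves.
#' @param wave_dates vector of wave dates (length >= `n_waves`).
#' @param retention per-wave probability that a current participant
#'   returns at the next wave (dropout is absorbing).
#' @param recruit_per_wave newly recruited first-time participants per
#'   wave (waves 2..T).
#' @param prior_participation_probs named probabilities over the number of
#'   participations a member of the initial cohort completed before the
#'   panel window (names `"0"`, `"1"`, ...); this is how a 10-wave window
#'   can contain repeat counts above 9.
#' @param covariate_freqs named list of level-probability vectors for
#'   `age_group`, `sex`, `household_size`, `employment`, `symptoms`,
#'   `day_type`, `urban_type` (levels as in [survey_levels]).
#' @param beta0 log baseline contact intensity.
#' @param effects named log-scale effect sizes keyed by one-hot column
#'   name (`"factor:level"`); unlisted columns have effect zero.
#' @param age_curve optional function of integer age added to the linear
#'   predictor (smooth age profile of contact intensity).
#' @param phi negative-binomial overdispersion (> 0);
#'   `Var = lambda + lambda^2 / phi`.
#' @param fatigue list describing the fatigue truth: `list(form="none")`,
#'   `list(form="identical", rho=)`, `list(form="independent", rhos=)`
#'   (values for r = 1..R), `list(form="hill", gamma=, zeta=, eta=)` or
#'   `list(form="gp", sigma=, ell=)` (curve drawn once on the repeat grid,
#'   anchored at zero for first-timers).
#' @param repeat_effects optional named log-scale effects (keyed like
#'   `effects`) applied only to repeat rows, for per-subgroup fatigue
#'   scenarios.
#' @param time_trend `list(form="none")` or `list(form="gp", sigma=, ell=)`;
#'   a calendar-time curve drawn once on the wave-date grid (Matern-3/2,
#'   dates rescaled to `[0, 1]`).
#' @param retention_slope optional contact-dependent dropout knob: the
#'   per-wave stay probability is `plogis(qlogis(retention) +
#'   retention_slope * (log lambda_i - mean log lambda))`, so negative
#'   values make low-contact participants more likely to drop out.
#' @param seed default seed used by [simulate_panel()].
#' @return an object of class `simulation_config`.
#' @export
simulation_config <- function(n_initial, n_waves, wave_dates,
                              retention = 0.85, recruit_per_wave = 0,
                              prior_participation_probs = c("0" = 1),
                              covariate_freqs,
                              beta0 = log(3), effects = numeric(),
                              age_curve = NULL, phi = 2,
                              fatigue = list(form = "none"),
                              repeat_effects = NULL,
                              time_trend = list(form = "none"),
                              retention_slope = 0,
                              seed = 1L) {
  if (n_waves > length(wave_dates))
    stop("simulation_config: n_waves exceeds length of wave_dates")
  stopifnot(retention >= 0, retention <= 1, phi > 0)
  stopifnot(abs(sum(prior_participation_probs) - 1) < 1e-8)
  if (fatigue$form == "hill")
    stopifnot(fatigue$gamma > 0, fatigue$eta > 0)
  for (f in names(covariate_freqs)) {
    fr <- covariate_freqs[[f]]
    if (abs(sum(fr) - 1) > 1e-6 || any(fr < 0))
      stop("simulation_config: frequencies for '", f, "' must be a probability vector")
    if (!setequal(names(fr), survey_levels[[f]]))
      stop("simulation_config: levels for '", f, "' must match survey_levels")
  }
  structure(list(
    n_initial = n_initial, n_waves = n_waves,
    wave_dates = as.Date(wave_dates)[seq_len(n_waves)],
    retention = retention, recruit_per_wave = recruit_per_wave,
    prior_participation_probs = prior_participation_probs,
    covariate_freqs = covariate_freqs, beta0 = beta0, effects = effects,
    age_curve = age_curve, phi = phi, fatigue = fatigue,
    repeat_effects = repeat_effects, time_trend = time_trend,
    retention_slope = retention_slope, seed = seed
  ), class = "simulation_config")
}

# fatigue truth rho(r) on the grid r = 0..R (rho(0) = 0 always)
fatigue_truth_curve <- function(fatigue, R) {
  r <- 0:R
  rho <- switch(fatigue$form,
    none = numeric(R + 1),
    identical = c(0, rep(fatigue$rho, R)),
    independent = {
      if (length(fatigue$rhos) < R)
        stop("simulate_panel: independent fatigue truth needs values for r = 1..", R)
      c(0, fatigue$rhos[1:R])
    },
    hill = hill_rho(r, gamma = fatigue$gamma, zeta = fatigue$zeta,
                    eta = fatigue$eta),
    gp = {
      rt <- (r - mean(r)) / stats::sd(r)
      K <- kernel_matrix(rt, "squared_exponential", fatigue$sigma, fatigue$ell)
      z <- drop(chol(K) %*% stats::rnorm(R + 1))
      z - z[1]
    },
    stop("simulate_panel: unknown fatigue form '", fatigue$form, "'")
  )
  data.frame(r = r, rho = rho)
}

#' Simulate a longitudinal contact-survey panel
#'
#' Draws a participant roster (fixed covariates, quota-like margins),
#' evolves it over waves with absorbing dropout and fresh recruitment,
#' builds the per-row linear predictor (baseline, covariate effects,
#' optional smooth age curve, optional calendar-time Gaussian-process
#' trend, fatigue curve over repeat counts) and samples negative-binomial
#' contact counts. Counts are emitted un-truncated; the standard
#' preprocessing (band-based age reporting for minors, truncation at 50)
#' is exercised downstream exactly as with real data.
#'
#' @param config a [simulation_config()].
#' @param seed integer seed; defaults to `config$seed`.
#' @return list with `records` (data.frame in the survey CSV schema) and
#'   `truth` (per-row `lambda` and linear predictor, the fatigue curve on
#'   the repeat grid, the time curve on the wave grid, and the config).
#' @export
simulate_panel <- function(config, seed = config$seed) {
  stopifnot(inherits(config, "simulation_config"))
  set.seed(seed)
  cf <- config$covariate_freqs
  r0_max <- max(as.integer(names(config$prior_participation_probs)))
  R_max <- r0_max + config$n_waves - 1L

  n_total <- config$n_initial + config$recruit_per_wave * (config$n_waves - 1L)
  roster <- data.frame(
    participant_id = sprintf("P%05d", seq_len(n_total)),
    age_group = sample_level(n_total, cf$age_group),
    sex = sample_level(n_total, cf$sex),
    household_size = sample_level(n_total, cf$household_size),
    employment = sample_level(n_total, cf$employment),
    urban_type = sample_level(n_total, cf$urban_type),
    stringsAsFactors = FALSE
  )
  rng <- t(vapply(roster$age_group, function(g) .age_group_range[[g]], c(0, 0)))
  roster$age <- as.integer(floor(stats::runif(n_total, rng[, 1], rng[, 2] + 1)))
  roster$schooling_flag <- ifelse(
    roster$age_group == "Raised at home (0-5)", "raised at home",
    ifelse(roster$age_group == "Preschool (0-5)", "preschool", NA))
  entry_wave <- rep(1L, n_total)
  if (config$n_waves > 1L && config$recruit_per_wave > 0)
    entry_wave[(config$n_initial + 1):n_total] <-
      rep(2:config$n_waves, each = config$recruit_per_wave)
  r_at_entry <- integer(n_total)
  r_at_entry[entry_wave == 1L] <- as.integer(sample_level(
    config$n_initial, config$prior_participation_probs))

  # static part of each participant's log intensity (before time/fatigue)
  static_lp <- rep(config$beta0, n_total)
  if (!is.null(config$age_curve)) static_lp <- static_lp + config$age_curve(roster$age)
  add_effect <- function(lp, fac, lev) {
    keys <- paste0(fac, ":", lev)
    hit <- keys %in% names(config$effects)
    lp[hit] <- lp[hit] + config$effects[keys[hit]]
    lp
  }
  for (f in c("age_group", "sex", "household_size", "employment", "urban_type"))
    static_lp <- add_effect(static_lp, f, roster[[f]])

  rho_curve <- fatigue_truth_curve(config$fatigue, R_max)
  tau_curve <- data.frame(wave = seq_len(config$n_waves),
                          date = config$wave_dates, tau = 0)
  if (config$time_trend$form == "gp" && config$n_waves > 1L) {
    ts <- as.numeric(config$wave_dates - min(config$wave_dates))
    ts <- ts / max(ts)
    K <- kernel_matrix(ts, "matern32", config$time_trend$sigma,
                       config$time_trend$ell)
    tau_curve$tau <- drop(chol(K) %*% stats::rnorm(config$n_waves))
  }

  mean_static <- mean(static_lp)
  rows <- vector("list", config$n_waves)
  active <- entry_wave == 1L
  n_part <- integer(n_total) # participations completed within the panel
  for (w in seq_len(config$n_waves)) {
    if (w > 1L) {
      stay_p <- stats::plogis(stats::qlogis(config$retention) +
                                config$retention_slope * (static_lp - mean_static))
      active <- active & (stats::runif(n_total) < stay_p)
      active <- active | entry_wave == w
    }
    idx <- which(active)
    if (!length(idx)) next
    r <- r_at_entry[idx] + n_part[idx]
    lp <- static_lp[idx] + tau_curve$tau[w] + rho_curve$rho[r + 1L]
    if (!is.null(config$repeat_effects)) {
      rep_lp <- rep(0, length(idx))
      for (f in c("age_group", "sex", "household_size", "employment", "urban_type")) {
        keys <- paste0(f, ":", roster[[f]][idx])
        hit <- keys %in% names(config$repeat_effects)
        rep_lp[hit] <- rep_lp[hit] + config$repeat_effects[keys[hit]]
      }
      lp <- lp + rep_lp * (r >= 1)
    }
    lambda <- exp(lp)
    rows[[w]] <- data.frame(
      roster_row = idx, wave = w, repeat_count = r,
      day_type = sample_level(length(idx), cf$day_type),
      symptoms = sample_level(length(idx), cf$symptoms),
      lambda = lambda,
      contact_count = stats::rnbinom(length(idx), size = config$phi, mu = lambda),
      stringsAsFactors = FALSE
    )
    n_part[idx] <- n_part[idx] + 1L
  }
  panel <- do.call(rbind, rows)
  ri <- panel$roster_row

  minor <- roster$age[ri] < 18L
  band <- cut(roster$age[ri], breaks = c(0, 5, 10, 15, 19), right = FALSE,
              labels = survey_levels$age_band)
  records <- data.frame(
    participant_id = roster$participant_id[ri],
    wave = panel$wave,
    date = config$wave_dates[panel$wave],
    repeat_count = panel$repeat_count,
    age = ifelse(minor, NA_integer_, roster$age[ri]),
    age_band = ifelse(minor, as.character(band), NA_character_),
    sex = roster$sex[ri],
    household_size = roster$household_size[ri],
    employment = roster$employment[ri],
    symptoms = panel$symptoms,
    day_type = panel$day_type,
    urban_type = roster$urban_type[ri],
    contact_count = panel$contact_count,
    schooling_flag = roster$schooling_flag[ri],
    stringsAsFactors = FALSE
  )
  list(
    records = records,
    truth = list(
      lambda = panel$lambda,
      log_lambda = log(panel$lambda),
      true_age = roster$age[ri],
      rho_curve = rho_curve,
      tau_curve = tau_curve,
      config = config
    )
  )
}

#' Default multi-wave panel scenario
#'
#' A documented default configuration emulating a ten-wave window of a
#' pandemic-era German contact panel at the scale of roughly 2,500 unique
#' participants and 12-13 thousand records: biweekly waves, 85% per-wave
#' retention with fresh recruitment, an initial cohort that enters with up
#' to two prior participations (so the maximum achievable repeat count is
#' 11), quota-like covariate margins, a smooth age profile, log-scale
#' covariate effects in the directions reported for pandemic contact
#' intensities (working and student status and urban residence up,
#' stay-at-home/unemployed/long-term-sick/retired down), overdispersion
#' `phi = 2`, and Hill-shaped fatigue with truth
#' `gamma = 1.18, zeta = -1.90, eta = 1.16`.
#'
#' @param ... overrides passed to [simulation_config()] (e.g. smaller
#'   `n_initial` for quick tests).
#' @return a [simulation_config()].
#' @export
covimod_like_scenario <- function(...) {
  freqs <- list(
    age_group = c(61, 17, 34, 80, 103, 106, 216, 163, 271, 318, 311, 118, 48, 5),
    sex = c(965, 886),
    household_size = c(477, 435, 535, 206, 198),
    employment = c(508, 202, 89, 193, 462, 42, 82, 34, 47),
    symptoms = c(1383, 468),
    day_type = c(1579, 272),
    urban_type = c(282, 705, 864)
  )
  freqs <- Map(function(x, nm) stats::setNames(x / sum(x), survey_levels[[nm]]),
               freqs, names(freqs))
  effects <- c(
    "sex:female" = -0.06,
    "household_size:2" = 0.05, "household_size:3" = 0.10,
    "household_size:4" = 0.18, "household_size:5+" = 0.25,
    "employment:Full-time employed" = 0.20,
    "employment:Part-time employed" = 0.12,
    "employment:Self-employed" = 0.15,
    "employment:Student (15+)" = 0.25,
    "employment:Retired" = -0.15,
    "employment:Long-term sick" = -0.25,
    "employment:Unemployed (seeking)" = -0.12,
    "employment:Unemployed (not seeking)" = -0.15,
    "employment:Stay-at-home parent" = -0.30,
    "urban_type:intermediate" = 0.08, "urban_type:urban" = 0.12
  )
  age_curve <- function(a) {
    0.40 * exp(-((a - 12) / 10)^2) + 0.25 * exp(-((a - 45) / 18)^2) -
      0.50 * stats::plogis((a - 72) / 4)
  }
  defaults <- list(
    n_initial = 1500L, n_waves = 10L,
    wave_dates = seq(as.Date("2020-06-04"), by = 14, length.out = 10),
    retention = 0.85, recruit_per_wave = 130L,
    prior_participation_probs = c("0" = 0.40, "1" = 0.35, "2" = 0.25),
    covariate_freqs = freqs, beta0 = log(3), effects = effects,
    age_curve = age_curve, phi = 2,
    fatigue = list(form = "hill", gamma = 1.18, zeta = -1.90, eta = 1.16),
    time_trend = list(form = "none"), seed = 2020L
  )
  do.call(simulation_config, utils::modifyList(defaults, list(...)))
}

#' Single-wave scenario with a deep repeat ladder
#'
#' One survey wave mixing a large first-time group with repeat
#' participants whose prior participation counts reach 20, patterned on a
#' late-pandemic wave with roughly 950 first-time and 1,500 repeat
#' respondents. This is the input for the incremental repeat-inclusion
#' accuracy experiment.
#'
#' @param n_participants total sample size of the wave.
#' @param first_time_frac fraction of first-time respondents.
#' @param max_repeat deepest prior-participation count present.
#' @param ... further overrides passed to [simulation_config()].
#' @return a [simulation_config()].
#' @export
wave21_like_scenario <- function(n_participants = 2450L,
                                 first_time_frac = 0.39,
                                 max_repeat = 20L, ...) {
  base <- covimod_like_scenario()
  pr <- 0.87^(1:max_repeat)
  pr <- pr / sum(pr) * (1 - first_time_frac)
  probs <- stats::setNames(c(first_time_frac, pr), 0:max_repeat)
  do.call(simulation_config, utils::modifyList(
    list(
      n_initial = as.integer(n_participants), n_waves = 1L,
      wave_dates = as.Date("2021-05-05"),
      retention = 1, recruit_per_wave = 0L,
      prior_participation_probs = probs,
      covariate_freqs = base$covariate_freqs, beta0 = base$beta0,
      effects = base$effects, age_curve = base$age_curve, phi = base$phi,
      fatigue = base$fatigue, time_trend = list(form = "none"), seed = 2021L
    ), list(...)))
}

#' Deterministic synthetic population margins
#'
#' Smooth, plausible population margin tables (age-sex pyramid with an
#' old-age decline, household-size and urban-type margins) for use with
#' [build_poststrat_weights()] when no census tables are supplied. Labelled
#' synthetic: these are not census data.
#'
#' @return named list of margin data.frames (`age_sex`, `household_size`,
#'   `urban_type`).
#' @export
synthetic_pop_margins <- function() {
  ages <- 0:84
  pa <- ifelse(ages < 55, 1, pmax(0.25, 1 - 0.012 * (ages - 55)))
  age_sex <- data.frame(
    age = rep(ages, 2),
    sex = rep(survey_levels$sex, each = length(ages)),
    count = round(1000 * c(pa * 0.512, pa * 0.488))
  )
  list(
    age_sex = age_sex,
    household_size = data.frame(level = survey_levels$household_size,
                                count = c(420, 330, 120, 90, 40)),
    urban_type = data.frame(level = survey_levels$urban_type,
                            count = c(220, 400, 380))
  )
}
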