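## Sequential wave-by-wave estimation: the correction model is re-fit per
## wave with priors centred on the previous wave's posterior means, and
## population-weighted overall and subgroup contact intensities are
## post-stratified from each fit. Bootstrap and first-time-only
## comparators mirror the non-model baselines.

#' Population-weighted overall contact intensity
#'
#' Per posterior draw, sums
#' `v_ag v_h v_u v_j exp(beta0 + f(a) + beta_g + beta_h + beta_u + beta_j)`
#' over age (0-84), sex, household-size, urban-type and employment strata,
#' and summarises the draws by median and 95% interval.
#'
#' @param fit a [fit_correction()] result.
#' @param weights a [build_poststrat_weights()] table.
#' @return one-row data.frame with `median`, `lo`, `hi`.
#' @export
overall_intensity <- function(fit, weights) {
  stopifnot(inherits(weights, "poststrat_table"))
  if (abs(sum(weights$v_ag) - 1) > 1e-6)
    stop("overall_intensity: age-sex margin does not sum to 1")
  ages <- 0:84
  ef <- exp(hsgp_f_draws(fit, ages))            # S x 85
  sexcol <- function(lev) {
    col <- paste0("sex:", lev)
    if (col %in% colnames(fit$draws)) exp(fit$draws[, col]) else
      rep(1, nrow(fit$draws))
  }
  age_sex <- ef %*% weights$v_ag[, 1] * sexcol(survey_levels$sex[1]) +
    ef %*% weights$v_ag[, 2] * sexcol(survey_levels$sex[2])
  lam <- exp(fit$draws[, "beta0"]) * drop(age_sex) *
    margin_factor(fit, "household_size", weights$v_h) *
    margin_factor(fit, "urban_type", weights$v_u) *
    margin_factor(fit, "employment", weights$v_j)
  q <- stats::quantile(lam, c(0.025, 0.5, 0.975))
  data.frame(median = q[[2]], lo = q[[1]], hi = q[[3]])
}

#' Subgroup-specific contact intensity
#'
#' Restricts the age-sex margin to `age_range` (weights renormalised to
#' sum to one within the range) and, for each factor named in `fixed`,
#' replaces the margin sum by the effect of the fixed level (e.g.
#' stay-at-home parents aged 19-64).
#'
#' @param fit a [fit_correction()] result.
#' @param weights a [build_poststrat_weights()] table.
#' @param age_range integer vector of ages (within 0..84).
#' @param fixed named character vector, e.g.
#'   `c(employment = "Stay-at-home parent")`.
#' @param label subgroup label attached to the output.
#' @return one-row data.frame with `label`, `median`, `lo`, `hi`.
#' @export
subgroup_intensity <- function(fit, weights, age_range = 0:84,
                               fixed = NULL, label = "subgroup") {
  stopifnot(inherits(weights, "poststrat_table"))
  if (!length(age_range) || any(age_range < 0 | age_range > 84))
    stop("subgroup_intensity: age_range must be a non-empty subset of 0..84")
  v_ag <- weights$v_ag[as.character(age_range), , drop = FALSE]
  v_ag <- v_ag / sum(v_ag)
  ef <- exp(hsgp_f_draws(fit, age_range))
  sexcol <- function(lev) {
    col <- paste0("sex:", lev)
    if (col %in% colnames(fit$draws)) exp(fit$draws[, col]) else
      rep(1, nrow(fit$draws))
  }
  if (!is.null(fixed) && "sex" %in% names(fixed)) {
    v_sex_cond <- rowSums(v_ag) # collapse age margin, fix the sex effect
    age_sex <- drop(ef %*% v_sex_cond) * margin_factor(fit, "sex", NULL,
                                                       fix_level = fixed[["sex"]])
  } else {
    age_sex <- drop(ef %*% v_ag[, 1]) * sexcol(survey_levels$sex[1]) +
      drop(ef %*% v_ag[, 2]) * sexcol(survey_levels$sex[2])
  }
  mfac <- function(f, v) {
    if (!is.null(fixed) && f %in% names(fixed))
      margin_factor(fit, f, NULL, fix_level = fixed[[f]])
    else margin_factor(fit, f, v)
  }
  lam <- exp(fit$draws[, "beta0"]) * age_sex *
    mfac("household_size", weights$v_h) *
    mfac("urban_type", weights$v_u) *
    mfac("employment", weights$v_j)
  q <- stats::quantile(lam, c(0.025, 0.5, 0.975))
  data.frame(label = label, median = q[[2]], lo = q[[1]], hi = q[[3]])
}

#' Weighted participant bootstrap of mean contact intensity
#'
#' Non-parametric bootstrap over a wave's participants: each resample
#' draws participants with replacement and computes the
#' post-stratification-weighted mean contact count (participant weight
#' `v_ag v_h v_u v_j` of their stratum, normalised within the resample).
#'
#' @param records preprocessed records of one wave.
#' @param weights a [build_poststrat_weights()] table.
#' @param B number of bootstrap resamples (>= 200).
#' @param seed integer seed (resampling is reproducible).
#' @return one-row data.frame with `median`, `lo`, `hi` (2.5/50/97.5
#'   percentiles over resamples).
#' @export
bootstrap_intensity <- function(records, weights, B = 2000L, seed = 1L) {
  if (!nrow(records)) stop("bootstrap_intensity: empty wave")
  if (B < 200) stop("bootstrap_intensity: B must be at least 200")
  w <- weights$v_ag[cbind(as.character(records$age),
                          as.character(records$sex))] *
    weights$v_h[as.integer(records$household_size)] *
    weights$v_u[as.integer(records$urban_type)] *
    weights$v_j[as.integer(records$employment)]
  y <- records$contact_count
  set.seed(seed)
  est <- vapply(seq_len(B), function(b) {
    i <- sample.int(length(y), replace = TRUE)
    sum(w[i] * y[i]) / sum(w[i])
  }, 0)
  q <- stats::quantile(est, c(0.025, 0.5, 0.975))
  data.frame(median = q[[2]], lo = q[[1]], hi = q[[3]])
}

# build the carry-over prior list from the previous wave's posterior means
carry_priors <- function(prev_fit, carry_sds, eta_carry) {
  x_cols <- prev_fit$meta$x_cols
  q_names <- if (isTRUE(prev_fit$meta$adjust)) prev_fit$meta$q_names else character(0)
  m <- posterior_mean(prev_fit)
  pr <- list(beta = stats::setNames(lapply(x_cols, function(cl)
    prior_spec("normal", m[[cl]], carry_sds[["beta"]])), x_cols))
  if (length(q_names)) {
    pr$gamma <- stats::setNames(lapply(q_names, function(q)
      prior_spec("halfnormal", m[[paste0("gamma:", q)]],
                 carry_sds[["gamma"]])), q_names)
    pr$zeta <- stats::setNames(lapply(q_names, function(q)
      prior_spec("normal", m[[paste0("zeta:", q)]],
                 carry_sds[["zeta"]])), q_names)
    pr$eta <- stats::setNames(lapply(q_names, function(q) {
      centre <- m[[paste0("eta:", q)]]
      prior_spec("halfnormal",
                 if (eta_carry == "reciprocal") 1 / centre else centre,
                 carry_sds[["eta"]])
    }), q_names)
  }
  pr
}

#' Sequential multi-wave estimation with prior carry-over
#'
#' Fits the fatigue-correcting model wave by wave. Wave 1 uses the base
#' priors; from wave 2 onward the covariate and Hill priors are centred
#' on the previous wave's posterior means with the stated carry standard
#' deviations: `beta ~ N(hat, 0.3)`, `gamma ~ half-N(hat, 0.3)`,
#' `zeta ~ N(hat, 0.1)` and - literally as stated -
#' `eta ~ half-N(1/hat, 0.1)` (set `eta_carry = "direct"` for the
#' plausible-intent alternative centred on `hat` itself). Empty waves are
#' skipped with the carry state passed through unchanged.
#'
#' @param records preprocessed multi-wave records.
#' @param weights a [build_poststrat_weights()] table.
#' @param estimator `"adjusted"` (fatigue term included),
#'   `"unadjusted"` (refit without it) or `"first_time_only"` (adjusted
#'   machinery on first-time rows, only for waves with at least
#'   `min_first_time` of them).
#' @param fatigue_features,hill_init,covariates,hsgp_m,hsgp_c,mcmc passed
#'   to [fit_correction()].
#' @param carry_sds named numeric vector with entries `beta`, `gamma`,
#'   `zeta`, `eta`.
#' @param eta_carry `"reciprocal"` (literal rule) or `"direct"`.
#' @param min_first_time minimum first-time sample size for the
#'   first-time-only comparator.
#' @param keep_fits retain the per-wave `posterior_draws` objects.
#' @return object of class `wave_estimates`: `estimates` (data.frame with
#'   `wave`, `estimator`, `median`, `lo`, `hi`), the carry chain, and
#'   optionally the fits.
#' @export
run_waves <- function(records, weights,
                      estimator = c("adjusted", "unadjusted", "first_time_only"),
                      fatigue_features = "global", hill_init = NULL,
                      covariates = c("sex", "household_size", "urban_type",
                                     "employment"),
                      hsgp_m = 25, hsgp_c = 1.5, mcmc = mcmc_control(),
                      carry_sds = c(beta = 0.3, gamma = 0.3, zeta = 0.1,
                                    eta = 0.1),
                      eta_carry = c("reciprocal", "direct"),
                      min_first_time = 300L, keep_fits = FALSE) {
  estimator <- match.arg(estimator)
  eta_carry <- match.arg(eta_carry)
  adjust <- estimator == "adjusted" || estimator == "first_time_only"
  waves <- sort(unique(records$wave))
  est <- list()
  carries <- list()
  fits <- list()
  prev_fit <- NULL
  for (w in waves) {
    sub <- records[records$wave == w, , drop = FALSE]
    if (estimator == "first_time_only") {
      sub <- sub[sub$repeat_count == 0, , drop = FALSE]
      if (nrow(sub) < min_first_time) next
    }
    if (!nrow(sub)) {
      message("run_waves: wave ", w, " has no rows; carry state passed through")
      next
    }
    pr <- if (!is.null(prev_fit) && estimator != "first_time_only")
      carry_priors(prev_fit, carry_sds, eta_carry) else NULL
    fit <- fit_correction(sub, fatigue_features = fatigue_features,
                          hill_init = if (adjust) hill_init,
                          adjust = adjust && max(sub$repeat_count) > 0,
                          covariates = covariates, hsgp_m = hsgp_m,
                          hsgp_c = hsgp_c, priors = pr, mcmc = mcmc)
    oi <- overall_intensity(fit, weights)
    est[[length(est) + 1L]] <- cbind(wave = w, estimator = estimator, oi)
    if (estimator != "first_time_only") {
      prev_fit <- fit
      pm <- posterior_mean(fit)
      carries[[as.character(w)]] <-
        pm[grep("^(beta0$|sex:|household_size:|urban_type:|employment:|gamma:|zeta:|eta:)",
                names(pm))]
      bad <- grep("^(gamma|eta):", names(carries[[as.character(w)]]), value = TRUE)
      if (any(carries[[as.character(w)]][bad] <= 0))
        stop("run_waves: non-positive carry centre for a Hill parameter")
    }
    if (keep_fits) fits[[as.character(w)]] <- fit
  }
  structure(list(estimates = do.call(rbind, est), carries = carries,
                 fits = if (keep_fits) fits),
            class = "wave_estimates")
}

#' @export
print.wave_estimates <- function(x, ...) {
  cat("<wave_estimates>\n")
  print(transform(x$estimates, median = round(median, 3),
                  lo = round(lo, 3), hi = round(hi, 3)))
  invisible(x)
}
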