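## Age-resolved fatigue-correcting contact model: NB regression with a
## Hilbert-space approximate GP age effect, dummy-encoded control
## covariates, and a separate Hill fatigue curve per selected fatigue
## feature; post-stratified age-specific intensities and the incremental
## repeat-inclusion accuracy experiment.

# ages 0..84 rescaled to [-1, 1]
rescale_age <- function(a) (a - 42) / 42

# fatigue design matrix for the correction model: one-hot columns of the
# selected fatigue features, or a single always-on column ("global")
fatigue_design <- function(records, fatigue_features) {
  if (identical(fatigue_features, "global"))
    return(matrix(1, nrow(records), 1, dimnames = list(NULL, "global")))
  W <- encode_design(records, "w")$w
  miss <- setdiff(fatigue_features, colnames(W))
  if (length(miss))
    stop("fatigue_design: unknown fatigue feature(s): ",
         paste(miss, collapse = ", "))
  W[, fatigue_features, drop = FALSE]
}

# default / carry-over prior set for the correction model
correction_priors <- function(x_cols, q_names, hill_init, overrides = NULL) {
  pr <- list(
    beta0 = prior_spec("normal", 0, 5),
    beta = stats::setNames(rep(list(prior_spec("normal", 0, 1)),
                               length(x_cols)), x_cols)
  )
  if (length(q_names)) {
    pr$gamma <- stats::setNames(rep(list(prior_spec("halfnormal",
                                                    hill_init$gamma, 1)),
                                    length(q_names)), q_names)
    pr$zeta <- stats::setNames(rep(list(prior_spec("normal",
                                                   hill_init$zeta, 1)),
                                   length(q_names)), q_names)
    pr$eta <- stats::setNames(rep(list(prior_spec("exponential",
                                                  hill_init$eta)),
                                  length(q_names)), q_names)
  }
  if (!is.null(overrides)) pr <- utils::modifyList(pr, overrides)
  pr
}

#' Fit the age-resolved fatigue-correcting contact model
#'
#' Negative-binomial model of contact counts with a global intercept, a
#' zero-mean Hilbert-space approximate Gaussian process (squared
#' exponential kernel) over participant age, dummy-encoded control
#' covariates, and - when `adjust = TRUE` - a separate three-parameter
#' Hill fatigue curve for each selected fatigue feature, acting through
#' the feature's one-hot indicator. With `adjust = FALSE` the fatigue term
#' is omitted entirely (the unadjusted comparator is a refit, not a
#' post-hoc zeroing).
#'
#' Priors: `beta0 ~ N(0, 5)`, `beta_p ~ N(0, 1)`,
#' `1/phi ~ Exponential(1)`; per fatigue feature q,
#' `gamma_q ~ half-N(gamma_hat, 1)`, `zeta_q ~ N(zeta_hat, 1)`,
#' `eta_q ~ Exponential(eta_hat)` where the hats are posterior medians
#' from the longitudinal fatigue model; HSGP amplitude `half-N(0, 1)` and
#' lengthscale `inv-Gamma(3, 1)` on the `[-1, 1]`-rescaled age domain.
#' All priors can be overridden (used by the sequential wave pipeline).
#'
#' @param records preprocessed records of one analysis window.
#' @param fatigue_features character vector of fatigue one-hot columns
#'   (`"factor:level"`), or `"global"` for a single population-wide
#'   fatigue curve.
#' @param hill_init list with `gamma`, `zeta`, `eta`: posterior medians of
#'   the longitudinal Hill fit, used to centre the Hill priors. Required
#'   when `adjust = TRUE`.
#' @param adjust include the fatigue term?
#' @param covariates factor columns entered as dummy encodings.
#' @param hsgp_m,hsgp_c HSGP basis size and boundary factor.
#' @param priors optional list of prior overrides (elements `beta0`,
#'   `beta`, `gamma`, `zeta`, `eta`, shaped as in the default set).
#' @param mcmc an [mcmc_control()].
#' @return a `posterior_draws` object carrying the HSGP state (basis
#'   weights `zf[j]`, `sigma_f`, `ell_f`) and, when adjusted, per-feature
#'   Hill parameters `gamma:q`, `zeta:q`, `eta:q`.
#' @export
fit_correction <- function(records, fatigue_features = "global",
                           hill_init = NULL, adjust = TRUE,
                           covariates = c("sex", "household_size",
                                          "urban_type", "employment"),
                           hsgp_m = 25, hsgp_c = 1.5, priors = NULL,
                           mcmc = mcmc_control()) {
  y <- records$contact_count
  if (adjust && is.null(hill_init))
    stop("fit_correction: adjust = TRUE needs hill_init (longitudinal posterior medians)")
  X <- do.call(cbind, lapply(covariates, function(f)
    dummy_encode(as_canonical_factor(records[[f]], f), f)))
  W <- if (adjust) fatigue_design(records, fatigue_features) else
    matrix(0, length(y), 0)
  r <- records$repeat_count
  R <- max(r)
  a <- records$age

  cells <- aggregate_nb_cells(cbind(X, W), y, extra = cbind(r = r, age = a))
  # centring the dummy design decorrelates the intercept from the factor
  # coefficients (reparameterisation only; draws are mapped back)
  xbar <- colSums(cells$X[, seq_len(ncol(X)), drop = FALSE] * cells$n) /
    sum(cells$n)
  Xc <- sweep(cells$X[, seq_len(ncol(X)), drop = FALSE], 2, xbar)
  Wc <- cells$X[, ncol(X) + seq_len(ncol(W)), drop = FALSE]
  rc <- cells$extra[, "r"]
  ac <- cells$extra[, "age"]
  P <- ncol(X)
  Q <- ncol(W)
  q_names <- colnames(W)

  basis <- hsgp_basis(rescale_age(ac), m = hsgp_m, c = hsgp_c,
                      centre = 0, half_range = 1)
  # centring functional: the age effect is constrained to average zero over
  # the observed design ages, so the intercept carries the overall level
  m_phi <- colMeans(basis$phi)
  pr <- correction_priors(colnames(X), q_names, hill_init, priors)

  # per-feature parameter order: (log_gamma, zeta, log_eta) grouped by q,
  # matching the column-major fill of hill_idx
  theta_names <- c("beta0", colnames(X),
                   if (adjust && Q > 0)
                     as.vector(outer(c("log_gamma", "zeta", "log_eta"),
                                     q_names, paste, sep = ":")))
  d_theta <- length(theta_names)
  hill_idx <- if (adjust && Q > 0)
    matrix((P + 1) + seq_len(3 * Q), nrow = 3) else NULL # rows: lg, zeta, le

  rho_cells <- function(th) {
    if (is.null(hill_idx)) return(numeric(length(rc)))
    rho_mat <- matrix(vapply(seq_len(Q), function(q) {
      hill_rho(0:R, gamma = exp(th[hill_idx[1, q]]), zeta = th[hill_idx[2, q]],
               eta = exp(th[hill_idx[3, q]]))
    }, numeric(R + 1)), nrow = R + 1)
    rowSums(Wc * rho_mat[rc + 1L, , drop = FALSE])
  }

  run_chain <- function(chain_id) {
    set.seed(mcmc$seed + 1000L * chain_id)
    th <- stats::setNames(numeric(d_theta), theta_names)
    th["beta0"] <- log(mean(y) + 0.1) + stats::rnorm(1, 0, 0.1)
    if (!is.null(hill_idx)) {
      th[hill_idx[1, ]] <- log(max(hill_init$gamma, 0.1)) + stats::rnorm(Q, 0, 0.1)
      th[hill_idx[2, ]] <- hill_init$zeta + stats::rnorm(Q, 0, 0.1)
      th[hill_idx[3, ]] <- log(max(hill_init$eta, 0.1)) + stats::rnorm(Q, 0, 0.1)
    }
    zf <- numeric(hsgp_m)
    log_sf <- log(0.5)
    log_lf <- log(0.3)
    logphi <- 0

    f_cells <- function(zf, log_sf, log_lf) {
      wsp <- sqrt(basis$spd(exp(log_sf), exp(log_lf))) * zf
      drop(basis$phi %*% wsp) - drop(m_phi %*% wsp)
    }
    eta_x <- function(th) th[1] + drop(Xc %*% th[2:(P + 1)])
    ex <- eta_x(th)
    fc <- f_cells(zf, log_sf, log_lf)
    rhoc <- rho_cells(th)
    phi <- exp(logphi)
    llik <- function(ex, fc, rhoc, phi)
      nb_cell_loglik(cells, exp(ex + fc + rhoc), phi)
    ll <- llik(ex, fc, rhoc, phi)

    reg_i <- seq_len(P + 1)
    fac_groups <- split(seq_len(P), sub(":.*$", "", colnames(X)))
    fat_i <- if (!is.null(hill_idx)) as.vector(hill_idx) else integer()
    log_prior_reg <- function(rg) {
      lp <- log_dprior(pr$beta0, rg[1] - sum(xbar * rg[-1]))
      for (p in seq_len(P)) lp <- lp + log_dprior(pr$beta[[p]], rg[1 + p])
      lp
    }
    log_prior_hill <- function(th) {
      if (is.null(hill_idx)) return(0)
      lp <- 0
      for (q in seq_len(Q)) {
        lg <- th[hill_idx[1, q]]
        le <- th[hill_idx[3, q]]
        lp <- lp + log_dprior(pr$gamma[[q]], exp(lg)) + lg +
          log_dprior(pr$zeta[[q]], th[hill_idx[2, q]]) +
          log_dprior(pr$eta[[q]], exp(le)) + le
      }
      lp
    }
    blk_reg <- amb_init(P + 1)
    blk_hill <- if (length(fat_i)) amb_init(length(fat_i)) else NULL
    # baseline level vs fatigue asymptote ridge, one 2-d block per feature
    blk_bg <- if (length(fat_i))
      lapply(seq_len(Q), function(q) amb_init(2L, scale = 0.1))
    n_keep <- mcmc$iter
    total <- mcmc$warmup + n_keep * mcmc$thin
    par_names <- c(theta_names,
                   if (!is.null(hill_idx))
                     as.vector(outer(c("gamma", "eta"), q_names, paste,
                                     sep = ":")),
                   paste0("zf[", seq_len(hsgp_m), "]"),
                   "sigma_f", "ell_f", "phi")
    draws <- matrix(NA_real_, n_keep, length(par_names),
                    dimnames = list(NULL, par_names))
    keep_i <- 0L

    set_hill <- function(fv) {
      th[fat_i] <<- fv
      rhoc <<- rho_cells(th)
      ll <<- llik(ex, fc, rhoc, phi)
    }
    for (it in seq_len(total)) {
      adapting <- it <= mcmc$warmup
      # regression block, plus slice moves along each factor block's
      # shift direction (the reference-cell contrast is a soft mode)
      reg_lp <- function(v) {
        lpv <- log_prior_reg(v)
        if (!is.finite(lpv)) return(-Inf)
        llik(v[1] + drop(Xc %*% v[-1]), fc, rhoc, phi) + lpv
      }
      st <- amb_step(blk_reg, th[reg_i], reg_lp,
                     ll + log_prior_reg(th[reg_i]), it, adapting)
      blk_reg <- st$blk
      if (!identical(st$x, th[reg_i])) {
        th[reg_i] <- st$x
        ex <- eta_x(th)
        ll <- llik(ex, fc, rhoc, phi)
      }
      for (g in fac_groups) {
        cshift <- slice_sample1(0, function(c2) {
          v <- th[reg_i]
          v[1 + g] <- v[1 + g] + c2
          reg_lp(v)
        }, w = 0.2)
        if (cshift != 0) {
          th[reg_i][1 + g] <- th[reg_i][1 + g] + cshift
          ex <- eta_x(th)
          ll <- llik(ex, fc, rhoc, phi)
        }
      }
      # per-feature Hill block: joint proposal, then univariate slices
      if (length(fat_i)) {
        hill_lp <- function(fv) {
          thv <- th
          thv[fat_i] <- fv
          lpv <- log_prior_hill(thv)
          if (!is.finite(lpv)) return(-Inf)
          llik(ex, fc, rho_cells(thv), phi) + lpv
        }
        st <- amb_step(blk_hill, th[fat_i], hill_lp,
                       ll + log_prior_hill(th), it, adapting)
        blk_hill <- st$blk
        if (!identical(st$x, th[fat_i])) set_hill(st$x)
        for (k in seq_along(fat_i)) {
          fv <- th[fat_i]
          fv[k] <- slice_sample1(fv[k], function(x) {
            fv2 <- fv
            fv2[k] <- x
            hill_lp(fv2)
          }, w = 0.3)
          if (fv[k] != th[fat_i][k]) set_hill(fv)
        }
        # joint (beta0, log_gamma_q) ridge moves
        for (q in seq_len(Q)) {
          bg_i <- c(1L, hill_idx[1, q])
          bg_lp <- function(v) {
            thv <- th
            thv[bg_i] <- v
            lpv <- log_prior_reg(thv[reg_i]) + log_prior_hill(thv)
            if (!is.finite(lpv)) return(-Inf)
            llik(thv[1] + drop(Xc %*% thv[2:(P + 1)]), fc, rho_cells(thv),
                 phi) + lpv
          }
          st <- amb_step(blk_bg[[q]], th[bg_i], bg_lp,
                         ll + log_prior_reg(th[reg_i]) + log_prior_hill(th),
                         it, adapting)
          blk_bg[[q]] <- st$blk
          if (!identical(st$x, th[bg_i])) {
            th[bg_i] <- st$x
            ex <- eta_x(th)
            rhoc <- rho_cells(th)
            ll <- llik(ex, fc, rhoc, phi)
          }
        }
      }
      # several elliptical-slice passes per sweep: the whitened basis
      # weights are the slowest-mixing block
      for (pass in 1:3)
        zf <- ess_step(zf, function(z) llik(ex, f_cells(z, log_sf, log_lf),
                                            rhoc, phi))
      fc <- f_cells(zf, log_sf, log_lf)
      log_sf <- slice_sample1(log_sf, function(ls) {
        llik(ex, f_cells(zf, ls, log_lf), rhoc, phi) +
          log_dhalfnorm(exp(ls), 0, 1) + ls
      }, w = 0.5)
      log_lf <- slice_sample1(log_lf, function(lv) {
        llik(ex, f_cells(zf, log_sf, lv), rhoc, phi) +
          log_dinvgamma(exp(lv), 3, 1) + lv
      }, w = 0.5)
      fc <- f_cells(zf, log_sf, log_lf)
      logphi <- slice_sample1(logphi, function(lp) {
        llik(ex, fc, rhoc, exp(lp)) + log_prior_logphi(lp)
      }, w = 0.5)
      phi <- exp(logphi)
      ll <- llik(ex, fc, rhoc, phi)

      if (it > mcmc$warmup && (it - mcmc$warmup) %% mcmc$thin == 0L) {
        keep_i <- keep_i + 1L
        hills <- if (!is.null(hill_idx))
          as.vector(rbind(exp(th[hill_idx[1, ]]), exp(th[hill_idx[3, ]])))
        th_rep <- th
        th_rep[1] <- th[1] - sum(xbar * th[2:(P + 1)]) # original-scale intercept
        draws[keep_i, ] <- c(th_rep, hills, zf, exp(log_sf), exp(log_lf), phi)
      }
    }
    draws
  }

  draws <- do.call(rbind, lapply(seq_len(mcmc$chains), run_chain))
  chain_id <- rep(seq_len(mcmc$chains), each = mcmc$iter)
  meta <- list(adjust = adjust, covariates = covariates,
               x_cols = colnames(X), q_names = q_names, R = R,
               hsgp = list(m = hsgp_m, c = hsgp_c, m_phi = m_phi),
               n_rows = length(y),
               n_cells = length(cells$S), hill_init = hill_init,
               seed = mcmc$seed)
  new_posterior_draws(draws, chain_id,
                      if (adjust) "correction_adjusted" else "correction_unadjusted",
                      meta)
}

# posterior draws of the HSGP age effect at the given ages (S x length(ages))
hsgp_f_draws <- function(fit, ages) {
  m <- fit$meta$hsgp$m
  basis <- hsgp_basis(rescale_age(ages), m = m, c = fit$meta$hsgp$c,
                      centre = 0, half_range = 1)
  zf <- fit$draws[, paste0("zf[", seq_len(m), "]"), drop = FALSE]
  sf <- fit$draws[, "sigma_f"]
  lf <- fit$draws[, "ell_f"]
  spd <- t(vapply(seq_along(sf), function(s) sqrt(basis$spd(sf[s], lf[s])),
                  numeric(m)))
  f <- (zf * spd) %*% t(basis$phi)
  # apply the same centring functional used during fitting
  f - drop((zf * spd) %*% fit$meta$hsgp$m_phi)
}

# per-draw margin factor sum(v_level * exp(beta_level)); reference levels
# (absent from the draws) have coefficient zero; when `fix_level` is given
# the margin collapses to exp(beta_fix_level)
margin_factor <- function(fit, factor, v, fix_level = NULL) {
  levels <- survey_levels[[factor]]
  S <- nrow(fit$draws)
  coef_of <- function(lev) {
    col <- paste0(factor, ":", lev)
    if (col %in% colnames(fit$draws)) fit$draws[, col] else numeric(S)
  }
  if (!is.null(fix_level)) {
    if (!fix_level %in% levels)
      stop("margin_factor: unknown level '", fix_level, "' of ", factor)
    return(exp(coef_of(fix_level)))
  }
  if (abs(sum(v) - 1) > 1e-6)
    stop("margin_factor: weights for '", factor, "' do not sum to 1")
  out <- numeric(S)
  for (k in seq_along(levels)) out <- out + v[k] * exp(coef_of(levels[k]))
  out
}

#' Post-stratified age-specific contact intensity curve
#'
#' For each posterior draw, sums
#' `v_g v_h v_u v_j exp(beta0 + f(a) + beta_g + beta_h + beta_u + beta_j)`
#' over the sex, household-size, urban-type and employment margins, then
#' summarises the draws at each age by the median and 95% credible
#' interval.
#'
#' @param fit a [fit_correction()] result.
#' @param weights a [build_poststrat_weights()] table.
#' @param ages integer ages to evaluate (default 0..84).
#' @return data.frame of class `age_intensity_curve` with columns `age`,
#'   `median`, `lo`, `hi`.
#' @export
poststrat_age_curve <- function(fit, weights, ages = 0:84) {
  stopifnot(inherits(fit, "posterior_draws"),
            inherits(weights, "poststrat_table"))
  for (v in list(weights$v_g, weights$v_h, weights$v_u, weights$v_j))
    if (abs(sum(v) - 1) > 1e-6)
      stop("poststrat_age_curve: weight margin does not sum to 1")
  f <- hsgp_f_draws(fit, ages)
  marg <- margin_factor(fit, "sex", weights$v_g) *
    margin_factor(fit, "household_size", weights$v_h) *
    margin_factor(fit, "urban_type", weights$v_u) *
    margin_factor(fit, "employment", weights$v_j)
  lam <- exp(fit$draws[, "beta0"] + f) * marg
  q <- apply(lam, 2, stats::quantile, probs = c(0.025, 0.5, 0.975))
  structure(data.frame(age = ages, median = q[2, ], lo = q[1, ], hi = q[3, ],
                       row.names = NULL),
            class = c("age_intensity_curve", "data.frame"))
}

#' @export
plot.age_intensity_curve <- function(x, ...) {
  graphics::plot(x$age, x$median, type = "l", lwd = 2,
                 ylim = range(c(x$lo, x$hi)),
                 xlab = "age", ylab = "contacts per person per day", ...)
  graphics::lines(x$age, x$lo, lty = 2)
  graphics::lines(x$age, x$hi, lty = 2)
  invisible(x)
}

#' Mean absolute percentage error between two intensity curves
#'
#' `100 / A * sum_a |est(a) - ref(a)| / |ref(a)|` over the evaluation ages.
#'
#' @param est,ref numeric vectors (posterior-median curves on the same
#'   age grid).
#' @return MAPE in percent.
#' @export
mape_curve <- function(est, ref) {
  stopifnot(length(est) == length(ref))
  100 * mean(abs(est - ref) / abs(ref))
}

#' Empirical 95% coverage of a reference curve
#'
#' Fraction of ages at which the reference point estimate falls inside
#' the `[lo, hi]` credible band.
#'
#' @param ref reference curve values.
#' @param lo,hi interval bounds on the same grid.
#' @return coverage in `[0, 1]`.
#' @export
coverage95_curve <- function(ref, lo, hi) {
  stopifnot(length(ref) == length(lo), length(ref) == length(hi))
  mean(ref >= lo & ref <= hi)
}

#' Incremental repeat-inclusion accuracy experiment
#'
#' Fits the correction model to first-time participants only (the
#' fatigue-free baseline), then sequentially re-fits on all participants
#' with at most `r` repeats for each `r` in `steps` - both with and
#' without the fatigue adjustment - and quantifies the deviation of each
#' re-fit's post-stratified age curve from the baseline by MAPE and 95%
#' coverage.
#'
#' @param records preprocessed records of one wave (mixed repeat depths).
#' @param fatigue_features,hill_init,covariates,hsgp_m,hsgp_c,mcmc passed
#'   to [fit_correction()].
#' @param weights a [build_poststrat_weights()] table.
#' @param steps maximum-repeat values to include sequentially.
#' @param ages evaluation ages.
#' @return object of class `inclusion_result`: `metrics` (data.frame with
#'   `r`, `mape_adj`, `mape_unadj`, `cov_adj`, `cov_unadj`), the baseline
#'   curve and per-step curves.
#' @export
inclusion_experiment <- function(records, fatigue_features = "global",
                                 hill_init = NULL, weights,
                                 steps = 1:20, ages = 0:84,
                                 covariates = c("sex", "household_size",
                                                "urban_type", "employment"),
                                 hsgp_m = 25, hsgp_c = 1.5,
                                 mcmc = mcmc_control()) {
  first <- records[records$repeat_count == 0, , drop = FALSE]
  if (!nrow(first)) stop("inclusion_experiment: no first-time rows for the baseline")
  base_fit <- fit_correction(first, fatigue_features, hill_init,
                             adjust = TRUE, covariates = covariates,
                             hsgp_m = hsgp_m, hsgp_c = hsgp_c, mcmc = mcmc)
  base_curve <- poststrat_age_curve(base_fit, weights, ages)

  curves <- list()
  metrics <- data.frame(r = steps, mape_adj = NA_real_, mape_unadj = NA_real_,
                        cov_adj = NA_real_, cov_unadj = NA_real_)
  for (i in seq_along(steps)) {
    r <- steps[i]
    sub <- records[records$repeat_count <= r, , drop = FALSE]
    fit_a <- fit_correction(sub, fatigue_features, hill_init, adjust = TRUE,
                            covariates = covariates, hsgp_m = hsgp_m,
                            hsgp_c = hsgp_c, mcmc = mcmc)
    fit_u <- fit_correction(sub, fatigue_features, hill_init = NULL,
                            adjust = FALSE, covariates = covariates,
                            hsgp_m = hsgp_m, hsgp_c = hsgp_c, mcmc = mcmc)
    cv_a <- poststrat_age_curve(fit_a, weights, ages)
    cv_u <- poststrat_age_curve(fit_u, weights, ages)
    curves[[as.character(r)]] <- list(adjusted = cv_a, unadjusted = cv_u)
    metrics$mape_adj[i] <- mape_curve(cv_a$median, base_curve$median)
    metrics$mape_unadj[i] <- mape_curve(cv_u$median, base_curve$median)
    metrics$cov_adj[i] <- coverage95_curve(base_curve$median, cv_a$lo, cv_a$hi)
    metrics$cov_unadj[i] <- coverage95_curve(base_curve$median, cv_u$lo, cv_u$hi)
  }
  structure(list(metrics = metrics, baseline = base_curve, curves = curves),
            class = "inclusion_result")
}

#' @export
print.inclusion_result <- function(x, ...) {
  cat("<inclusion_result>\n")
  print(round(x$metrics, 3))
  invisible(x)
}
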