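#' Three-parameter Hill fatigue curve
#'
#' `rho(r) = -gamma e^zeta r^eta / (1 + e^zeta r^eta)`: a saturating
#' dose-response curve on the log-intensity scale where the "dose" is the
#' number of repeat participations and the response is under-reporting.
#' `gamma > 0` sets the asymptotic effect size (`rho -> -gamma` as
#' `r -> Inf`), while `zeta` (log rate) and `eta > 0` (shape) jointly
#' control how quickly the curve approaches the asymptote. `rho(0) = 0`:
#' first-time participants are fatigue-free.
#'
#' @param r non-negative repeat counts (vectorised).
#' @param gamma,zeta,eta Hill parameters (`gamma, eta > 0`).
#' @return log-scale fatigue effects in `(-gamma, 0]`.
#' @export
#' @examples
#' hill_rho(0:5, gamma = 1.18, zeta = -1.90, eta = 1.16)
hill_rho <- function(r, gamma, zeta, eta) {
  if (gamma <= 0 || eta <= 0) stop("hill_rho: gamma and eta must be positive")
  if (any(r < 0)) stop("hill_rho: repeat counts must be non-negative")
  h <- exp(zeta) * r^eta
  -gamma * h / (1 + h)
}

#' MCMC control settings
#'
#' @param chains number of chains.
#' @param warmup adaptation iterations discarded per chain.
#' @param iter retained iterations per chain (after thinning).
#' @param thin thinning interval.
#' @param seed integer seed.
#' @return list of class `mcmc_control`.
#' @export
mcmc_control <- function(chains = 2L, warmup = 2000L, iter = 2000L,
                         thin = 2L, seed = 1L) {
  structure(list(chains = as.integer(chains), warmup = as.integer(warmup),
                 iter = as.integer(iter), thin = as.integer(thin),
                 seed = as.integer(seed)), class = "mcmc_control")
}

# rho(r) on the grid 0..R given the form and its parameters
rho_grid_from_params <- function(form, pars, R, gp_state = NULL) {
  r <- 0:R
  switch(form,
    hill = hill_rho(r, gamma = exp(pars[["log_gamma"]]), zeta = pars[["zeta"]],
                    eta = exp(pars[["log_eta"]])),
    identical = c(0, rep(pars[["rho"]], R)),
    independent = c(0, pars[paste0("rho_", 1:R)]),
    gp = gp_state
  )
}

#' Fit the longitudinal survey-fatigue model
#'
#' Negative-binomial panel regression of reported contact counts on
#' dummy-encoded covariates, a zero-mean Matern-3/2 Gaussian-process
#' calendar-time trend, and a fatigue term `rho(r)` over the number of
#' repeat participations. Four functional forms for `rho` are supported:
#'
#' * `"identical"` - one fixed effect shared by all repeat rows;
#' * `"independent"` - a free effect per repeat count (`rho(0) = 0`);
#' * `"gp"` - a squared-exponential Gaussian process over standardised
#'   repeat counts, anchored at `rho(0) = 0`;
#' * `"hill"` - the three-parameter [hill_rho()] curve.
#'
#' Priors: `beta0 ~ N(0, 5)`, covariate effects `N(0, 1)`,
#' `1/phi ~ Exponential(1)`, time-GP hyperparameters
#' `sigma_tau ~ inv-Gamma(3, 1)` and `ell_tau ~ inv-Gamma(5, 1)` (calendar
#' time rescaled to `[0, 1]`), fatigue-GP hyperparameters
#' `inv-Gamma(5, 5)`; Hill parameters `gamma ~ half-N(0,1)`,
#' `zeta ~ N(0,1)`, `eta ~ Exponential(1)`; fixed-effect forms `N(0, 1)`.
#'
#' Rows with identical design, repeat count and date are aggregated into
#' exact sufficient-statistic cells before sampling.
#'
#' @param records preprocessed records spanning several waves (must carry
#'   `date` and `repeat_count`).
#' @param form fatigue functional form.
#' @param covariates factor columns entered as dummy (reference-dropped)
#'   encodings.
#' @param mcmc an [mcmc_control()].
#' @param waic keep pointwise log-likelihood draws for model comparison.
#' @return a `posterior_draws` object; fatigue-curve values are stored as
#'   `rho[0] ... rho[R]` columns alongside the model parameters.
#' @export
fit_longitudinal <- function(records,
                             form = c("hill", "gp", "identical", "independent"),
                             covariates = c("age_group", "sex", "household_size"),
                             mcmc = mcmc_control(), waic = FALSE) {
  form <- match.arg(form)
  stopifnot(all(c("date", "repeat_count", "contact_count") %in% names(records)))
  y <- records$contact_count
  X <- do.call(cbind, lapply(covariates, function(f)
    dummy_encode(as_canonical_factor(records[[f]], f), f)))
  r <- records$repeat_count
  R <- max(r)
  if (form == "independent" && R < 1)
    stop("fit_longitudinal: independent form needs repeat rows")
  dnum <- as.numeric(as.Date(records$date))
  udate <- sort(unique(dnum))
  has_time <- length(udate) >= 2L
  t_scaled <- if (has_time) (udate - min(udate)) / diff(range(udate)) else 0
  date_id <- match(dnum, udate)

  cells <- aggregate_nb_cells(X, y, extra = cbind(r = r, d = date_id))
  rc <- cells$extra[, "r"]
  dc <- cells$extra[, "d"]
  p <- ncol(X)
  nT <- length(udate)
  # centring the dummy design decorrelates the intercept from the factor
  # coefficients (pure reparameterisation: draws are mapped back and the
  # priors are evaluated on the original-scale intercept)
  xbar <- colSums(cells$X * cells$n) / sum(cells$n)
  Xc <- sweep(cells$X, 2, xbar)

  # standardisation of the repeat grid for the GP form uses the observed
  # row-level distribution of r (recorded in meta for reuse at prediction)
  r_mean <- mean(r)
  r_sd <- max(stats::sd(r), 1e-8)
  rt_grid <- ((0:R) - r_mean) / r_sd

  fac_groups <- split(seq_len(p), sub(":.*$", "", colnames(X)))
  reg_names <- c("beta0", colnames(X))
  fat_names <- switch(form,
                      hill = c("log_gamma", "zeta", "log_eta"),
                      identical = "rho",
                      independent = paste0("rho_", seq_len(R)),
                      gp = NULL)
  theta_names <- c(reg_names, fat_names)
  d_theta <- length(theta_names)
  reg_i <- seq_len(p + 1)
  fat_i <- if (length(fat_names)) (p + 1) + seq_along(fat_names) else integer()

  log_prior_reg <- function(rg) {
    stats::dnorm(rg[1] - sum(xbar * rg[-1]), 0, 5, log = TRUE) +
      sum(stats::dnorm(rg[-1], 0, 1, log = TRUE))
  }
  log_prior_fat <- function(ft) {
    if (form == "hill") {
      lg <- ft[[1]]; le <- ft[[3]]
      log_dhalfnorm(exp(lg), 0, 1) + lg +   # half-N(0,1) with log-scale Jacobian
        stats::dnorm(ft[[2]], 0, 1, log = TRUE) +
        stats::dexp(exp(le), 1, log = TRUE) + le
    } else if (length(ft)) {
      sum(stats::dnorm(ft, 0, 1, log = TRUE))
    } else 0
  }
  log_prior_theta <- function(th) {
    log_prior_reg(th[reg_i]) + log_prior_fat(th[fat_i])
  }

  # empirical fatigue curve (group means by repeat count) seeds the chains
  # near the data-supported ridge of the fatigue parameters
  m_by_r <- tapply(y, r, mean)
  obs_r <- as.integer(names(m_by_r))
  rho_emp <- pmin(log(pmax(as.numeric(m_by_r), 0.1) /
                        max(m_by_r[as.character(min(obs_r))], 0.1)), 0)
  hill_ls_init <- function() {
    fit <- tryCatch(
      stats::optim(c(log(0.5), -1, 0), function(p) {
        sum((hill_rho(obs_r, exp(p[1]), p[2], exp(p[3])) - rho_emp)^2)
      }),
      error = function(e) NULL)
    if (is.null(fit) || !all(is.finite(fit$par)) ||
          any(abs(fit$par) > 5)) c(log(0.5), -1, 0) else fit$par
  }

  run_chain <- function(chain_id) {
    set.seed(mcmc$seed + 1000L * chain_id)
    th <- stats::setNames(numeric(d_theta), theta_names)
    th["beta0"] <- log(mean(y[r == min(obs_r)]) + 0.1) + stats::rnorm(1, 0, 0.1)
    if (form == "hill")
      th[c("log_gamma", "zeta", "log_eta")] <-
        hill_ls_init() + stats::rnorm(3, 0, 0.15)
    if (form == "identical" && any(obs_r >= 1))
      th["rho"] <- mean(rho_emp[obs_r >= 1]) + stats::rnorm(1, 0, 0.05)
    if (form == "independent") {
      hit <- match(1:R, obs_r)
      th[paste0("rho_", 1:R)] <-
        ifelse(is.na(hit), 0, rho_emp[hit]) + stats::rnorm(R, 0, 0.05)
    }
    logphi <- stats::rnorm(1, 0, 0.3)
    z_tau <- numeric(nT)
    log_s_tau <- log(0.5); log_l_tau <- log(0.25)
    z_rho <- numeric(R + 1)
    log_s_rho <- log(1); log_l_rho <- log(1)

    chol_tau <- function() {
      if (!has_time) return(NULL)
      chol(kernel_matrix(t_scaled, "matern32", exp(log_s_tau), exp(log_l_tau)))
    }
    chol_rho <- function() {
      chol(kernel_matrix(rt_grid, "squared_exponential",
                         exp(log_s_rho), exp(log_l_rho)))
    }
    Lt <- chol_tau()
    Lr <- if (form == "gp") chol_rho() else NULL
    # GP values centred on the date grid: the calendar-time trend is a
    # deviation from the intercept, so its level is projected out
    gp_tau <- function(L, z) {
      v <- drop(crossprod(L, z))
      v - mean(v)
    }
    tau <- if (has_time) gp_tau(Lt, z_tau) else rep(0, nT)
    gp_rho <- function(Lr, z) { v <- drop(crossprod(Lr, z)); v - v[1] }
    rho_g <- if (form == "gp") gp_rho(Lr, z_rho) else
      rho_grid_from_params(form, th, R)

    eta_x <- function(th) th[1] + drop(Xc %*% th[2:(p + 1)])
    ex <- eta_x(th)
    loglik_parts <- function(ex, tau, rho_g, phi) {
      nb_cell_loglik(cells, exp(ex + tau[dc] + rho_g[rc + 1L]), phi)
    }
    phi <- exp(logphi)
    ll <- loglik_parts(ex, tau, rho_g, phi)

    blk_reg <- amb_init(p + 1)
    blk_fat <- if (length(fat_i)) amb_init(length(fat_i)) else NULL
    # the baseline level and the fatigue asymptote trade off along a narrow
    # ridge; a dedicated 2-d adaptive block proposes along it
    bg_i <- if (form == "hill") c(1L, fat_i[1]) else integer()
    blk_bg <- if (length(bg_i)) amb_init(2L, scale = 0.1) else NULL
    n_keep <- mcmc$iter
    total <- mcmc$warmup + n_keep * mcmc$thin
    extra_names <- c("phi",
                     if (has_time) c("sigma_tau", "ell_tau"),
                     if (form == "gp") c("sigma_rho", "ell_rho"),
                     if (form == "hill") c("gamma", "eta"),
                     paste0("rho[", 0:R, "]"))
    draws <- matrix(NA_real_, n_keep, d_theta + length(extra_names),
                    dimnames = list(NULL, c(theta_names, extra_names)))
    ll_draws <- if (waic) matrix(NA_real_, n_keep, length(cells$S)) else NULL
    keep_i <- 0L

    set_fat <- function(fv) {
      th[fat_i] <<- fv
      rho_g <<- rho_grid_from_params(form, th, R)
      ll <<- loglik_parts(ex, tau, rho_g, phi)
    }
    for (it in seq_len(total)) {
      adapting <- it <= mcmc$warmup
      # regression block (intercept + covariate effects); several passes
      # per sweep since this is the largest block
      reg_lp <- function(v) {
        lpv <- log_prior_reg(v)
        if (!is.finite(lpv)) return(-Inf)
        loglik_parts(v[1] + drop(Xc %*% v[-1]), tau, rho_g, phi) + lpv
      }
      for (pass in 1:2) {
        st <- amb_step(blk_reg, th[reg_i], reg_lp,
                       ll + log_prior_reg(th[reg_i]), it, adapting)
        blk_reg <- st$blk
        if (!identical(st$x, th[reg_i])) {
          th[reg_i] <- st$x
          ex <- eta_x(th)
          ll <- loglik_parts(ex, tau, rho_g, phi)
        }
      }
      # slice along each factor block's shift direction: with a small
      # reference level, the contrast between the reference cell and the
      # rest is a soft mode the block proposals traverse slowly
      for (g in fac_groups) {
        cshift <- slice_sample1(0, function(c2) {
          v <- th[reg_i]
          v[1 + g] <- v[1 + g] + c2
          reg_lp(v)
        }, w = 0.2)
        if (cshift != 0) {
          th[reg_i][1 + g] <- th[reg_i][1 + g] + cshift
          ex <- eta_x(th)
          ll <- loglik_parts(ex, tau, rho_g, phi)
        }
      }
      # fatigue-parameter block (joint, then robust univariate slices)
      if (length(fat_i)) {
        fat_lp <- function(fv) {
          lpv <- log_prior_fat(fv)
          if (!is.finite(lpv)) return(-Inf)
          thv <- th
          thv[fat_i] <- fv
          loglik_parts(ex, tau, rho_grid_from_params(form, thv, R), phi) + lpv
        }
        st <- amb_step(blk_fat, th[fat_i], fat_lp, ll + log_prior_fat(th[fat_i]),
                       it, adapting)
        blk_fat <- st$blk
        if (!identical(st$x, th[fat_i])) set_fat(st$x)
        if (form == "hill") {
          for (k in seq_along(fat_i)) {
            fv <- th[fat_i]
            fv[k] <- slice_sample1(fv[k], function(x) {
              fv2 <- fv
              fv2[k] <- x
              fat_lp(fv2)
            }, w = 0.3)
            if (fv[k] != th[fat_i][k]) set_fat(fv)
          }
          # joint (beta0, log_gamma) ridge move
          bg_lp <- function(v) {
            thv <- th
            thv[bg_i] <- v
            lpv <- log_prior_reg(thv[reg_i]) + log_prior_fat(thv[fat_i])
            if (!is.finite(lpv)) return(-Inf)
            loglik_parts(thv[1] + drop(Xc %*% thv[2:(p + 1)]), tau,
                         rho_grid_from_params(form, thv, R), phi) + lpv
          }
          st <- amb_step(blk_bg, th[bg_i], bg_lp,
                         ll + log_prior_reg(th[reg_i]) + log_prior_fat(th[fat_i]),
                         it, adapting)
          blk_bg <- st$blk
          if (!identical(st$x, th[bg_i])) {
            th[bg_i] <- st$x
            ex <- eta_x(th)
            rho_g <- rho_grid_from_params(form, th, R)
            ll <- loglik_parts(ex, tau, rho_g, phi)
          }
        }
      }
      # overdispersion
      logphi <- slice_sample1(logphi, function(lp) {
        loglik_parts(ex, tau, rho_g, exp(lp)) + log_prior_logphi(lp)
      }, w = 0.5)
      phi <- exp(logphi)
      ll <- loglik_parts(ex, tau, rho_g, phi)
      # calendar-time GP (whitened) + hyperparameters
      if (has_time) {
        z_tau <- ess_step(z_tau, function(z) {
          loglik_parts(ex, gp_tau(Lt, z), rho_g, phi)
        })
        tau <- gp_tau(Lt, z_tau)
        log_s_tau <- slice_sample1(log_s_tau, function(ls) {
          Ltp <- chol(kernel_matrix(t_scaled, "matern32", exp(ls), exp(log_l_tau)))
          loglik_parts(ex, gp_tau(Ltp, z_tau), rho_g, phi) +
            log_dinvgamma(exp(ls), 3, 1) + ls
        }, w = 0.5)
        log_l_tau <- slice_sample1(log_l_tau, function(ll2) {
          Ltp <- chol(kernel_matrix(t_scaled, "matern32", exp(log_s_tau), exp(ll2)))
          loglik_parts(ex, gp_tau(Ltp, z_tau), rho_g, phi) +
            log_dinvgamma(exp(ll2), 5, 1) + ll2
        }, w = 0.5)
        Lt <- chol_tau()
        tau <- gp_tau(Lt, z_tau)
        ll <- loglik_parts(ex, tau, rho_g, phi)
      }
      # fatigue GP (whitened) + hyperparameters
      if (form == "gp") {
        z_rho <- ess_step(z_rho, function(z) {
          loglik_parts(ex, tau, gp_rho(Lr, z), phi)
        })
        rho_g <- gp_rho(Lr, z_rho)
        log_s_rho <- slice_sample1(log_s_rho, function(ls) {
          Lp <- chol(kernel_matrix(rt_grid, "squared_exponential",
                                   exp(ls), exp(log_l_rho)))
          loglik_parts(ex, tau, gp_rho(Lp, z_rho), phi) +
            log_dinvgamma(exp(ls), 5, 5) + ls
        }, w = 0.5)
        log_l_rho <- slice_sample1(log_l_rho, function(ll2) {
          Lp <- chol(kernel_matrix(rt_grid, "squared_exponential",
                                   exp(log_s_rho), exp(ll2)))
          loglik_parts(ex, tau, gp_rho(Lp, z_rho), phi) +
            log_dinvgamma(exp(ll2), 5, 5) + ll2
        }, w = 0.5)
        Lr <- chol_rho()
        rho_g <- gp_rho(Lr, z_rho)
        ll <- loglik_parts(ex, tau, rho_g, phi)
      }

      if (it > mcmc$warmup && (it - mcmc$warmup) %% mcmc$thin == 0L) {
        keep_i <- keep_i + 1L
        extras <- c(phi,
                    if (has_time) c(exp(log_s_tau), exp(log_l_tau)),
                    if (form == "gp") c(exp(log_s_rho), exp(log_l_rho)),
                    if (form == "hill") c(exp(th[["log_gamma"]]), exp(th[["log_eta"]])),
                    rho_g)
        th_rep <- th
        th_rep[1] <- th[1] - sum(xbar * th[2:(p + 1)]) # original-scale intercept
        draws[keep_i, ] <- c(th_rep, extras)
        if (waic) {
          mu <- exp(ex + tau[dc] + rho_g[rc + 1L])
          ll_draws[keep_i, ] <- nb_cell_loglik_pointwise(cells, mu, phi)
        }
      }
    }
    list(draws = draws, ll = ll_draws)
  }

  chains <- lapply(seq_len(mcmc$chains), run_chain)
  draws <- do.call(rbind, lapply(chains, `[[`, "draws"))
  chain_id <- rep(seq_len(mcmc$chains), each = mcmc$iter)
  meta <- list(form = form, R = R, r_mean = r_mean, r_sd = r_sd,
               covariates = covariates, n_rows = length(y),
               n_cells = length(cells$S), seed = mcmc$seed,
               waic = if (waic)
                 waic_from_loglik(do.call(rbind, lapply(chains, `[[`, "ll"))))
  new_posterior_draws(draws, chain_id, paste0("longitudinal_", form), meta)
}

#' Percent-reduction fatigue curve
#'
#' Transforms the posterior fatigue curve `rho(r)` to percent change in
#' reported contact intensity, `100 (e^{rho(r)} - 1)`, and summarises it
#' by the posterior median and 95% interval.
#'
#' @param fit a [fit_longitudinal()] result.
#' @return data.frame of class `fatigue_curve` with columns `r`, `median`,
#'   `lo`, `hi` (log scale) and `pct_median`, `pct_lo`, `pct_hi`.
#' @export
percent_reduction_curve <- function(fit) {
  stopifnot(inherits(fit, "posterior_draws"))
  cols <- grep("^rho\\[", colnames(fit$draws), value = TRUE)
  if (!length(cols)) stop("percent_reduction_curve: no fatigue-curve draws in fit")
  rg <- as.integer(sub("^rho\\[(\\d+)\\]$", "\\1", cols))
  o <- order(rg)
  d <- fit$draws[, cols[o], drop = FALSE]
  q <- apply(d, 2, stats::quantile, probs = c(0.025, 0.5, 0.975))
  pq <- apply(100 * (exp(d) - 1), 2, stats::quantile, probs = c(0.025, 0.5, 0.975))
  structure(data.frame(
    r = rg[o], median = q[2, ], lo = q[1, ], hi = q[3, ],
    pct_median = pq[2, ], pct_lo = pq[1, ], pct_hi = pq[3, ],
    row.names = NULL
  ), class = c("fatigue_curve", "data.frame"))
}

#' @export
plot.fatigue_curve <- function(x, ...) {
  graphics::plot(x$r, x$pct_median, type = "b", pch = 16,
                 ylim = range(c(x$pct_lo, x$pct_hi, 0)),
                 xlab = "repeat participations",
                 ylab = "% change in reported contact intensity", ...)
  graphics::arrows(x$r, x$pct_lo, x$r, x$pct_hi, angle = 90, code = 3,
                   length = 0.03)
  graphics::abline(h = 0, lty = 3)
  invisible(x)
}

#' Compare fatigue functional forms
#'
#' Fits the longitudinal model under several fatigue forms on the same
#' records and reports, per form, the posterior-median percent-reduction
#' curve, WAIC (from pointwise cell log-likelihood draws) and the
#' sup-distance (log scale) of its median curve from the first form
#' listed.
#'
#' @param records preprocessed records.
#' @param forms character vector of forms to compare.
#' @param ... passed to [fit_longitudinal()].
#' @return list with `curves` (named list of [percent_reduction_curve()]
#'   results) and `table` (one row per form).
#' @export
compare_forms <- function(records, forms = c("hill", "gp", "identical",
                                             "independent"), ...) {
  fits <- lapply(forms, function(f) fit_longitudinal(records, form = f,
                                                     waic = TRUE, ...))
  names(fits) <- forms
  curves <- lapply(fits, percent_reduction_curve)
  ref <- curves[[1]]$median
  tab <- data.frame(
    form = forms,
    elpd_waic = vapply(fits, function(f) f$meta$waic[["elpd_waic"]], 0),
    waic = vapply(fits, function(f) f$meta$waic[["waic"]], 0),
    sup_dist = vapply(curves, function(cv) max(abs(cv$median - ref)), 0),
    max_rhat = vapply(fits, function(f) max(f$rhat, na.rm = TRUE), 0),
    row.names = NULL
  )
  list(curves = curves, table = tab)
}
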