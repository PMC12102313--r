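#' Log-scale selection thresholds for the +/- 5% rule
#'
#' A feature is deemed relevant when its posterior-median log-scale effect
#' moves the expected contact intensity by more than 5% relative to the
#' baseline: outside `(log 0.95, log 1.05) = (-0.0513, 0.0488)` for the
#' intensity model, or below `log 0.95` (a > 5% reduction) for the fatigue
#' model. The endpoints are computed, not hard-coded.
#'
#' @return named numeric vector `c(lower, upper)`.
#' @export
selection_thresholds <- function() {
  c(lower = log(0.95), upper = log(1.05))
}

# regularised-horseshoe coefficient transform (coordinate-wise)
rhs_beta <- function(z, log_lambda, log_tau, log_c2) {
  lam <- exp(log_lambda)
  tau <- exp(log_tau)
  c2 <- exp(log_c2)
  z * tau * sqrt(c2 * lam^2 / (c2 + tau^2 * lam^2))
}

# log prior of the RHS scale hierarchy, parameters on log scale
log_prior_rhs_scales <- function(log_lambda, log_tau, log_c2,
                                 local_df = 3, global_df = 2,
                                 global_scale = 1, slab_df = 4,
                                 slab_scale = 2) {
  sum(log_dhalft(exp(log_lambda), local_df, 1) + log_lambda) +
    log_dhalft(exp(log_tau), global_df, global_scale) + log_tau +
    log_dinvgamma(exp(log_c2), slab_df / 2, slab_df * slab_scale^2 / 2) + log_c2
}

#' Determinants of contact intensity among first-time participants
#'
#' Negative-binomial regression of first-time participants' contact
#' counts on full one-hot control blocks (age/schooling 14, sex 2,
#' household size 5) under sum-to-zero multivariate normal priors (scale
#' arguments 14/13, 2 and 3/2), and one-hot test blocks (employment 9,
#' symptoms 2, day type 2, urban type 3) under sum-to-zero regularised
#' horseshoe priors with block global scales `(8, 1, 1, 2) / sqrt(n)`.
#' `beta0 ~ N(0, 100)`, `1/phi ~ Exponential(1)`. The sum-to-zero
#' constraint is imposed by orthonormal null-space reparameterisation for
#' the normal blocks and by orthogonal projection for the horseshoe
#' blocks.
#'
#' @param records preprocessed records, all with `repeat_count == 0`.
#' @param mcmc an [mcmc_control()].
#' @param global_scales named numerator of each test block's global scale
#'   (divided by `sqrt(n)` internally).
#' @return a `posterior_draws` object; test-block columns are listed in
#'   `meta$test_cols`.
#' @export
fit_intensity_selection <- function(records, mcmc = mcmc_control(),
                                    global_scales = c(employment = 8,
                                                      symptoms = 1,
                                                      day_type = 1,
                                                      urban_type = 2)) {
  if (any(records$repeat_count != 0))
    stop("fit_intensity_selection: repeat rows present; use first-time participants only")
  y <- records$contact_count
  n0 <- length(y)
  enc <- encode_design(records, c("u", "v"))
  U <- enc$u
  V <- enc$v
  ctrl_dims <- c(age_group = 14L, sex = 2L, household_size = 5L)
  ctrl_scales <- c(age_group = 14 / 13, sex = 2, household_size = 3 / 2)
  test_dims <- c(employment = 9L, symptoms = 2L, day_type = 2L, urban_type = 3L)
  Qs <- lapply(ctrl_dims, sz_nullspace_basis)
  test_idx <- split(seq_len(sum(test_dims)), rep(names(test_dims), test_dims))
  test_idx <- test_idx[names(test_dims)]

  cells <- aggregate_nb_cells(cbind(U, V), y)
  Uc <- cells$X[, seq_len(ncol(U)), drop = FALSE]
  Vc <- cells$X[, ncol(U) + seq_len(ncol(V)), drop = FALSE]

  xi_dims <- ctrl_dims - 1L
  d_ctrl <- 1L + sum(xi_dims)
  Kv <- ncol(V)

  alpha_from_xi <- function(xi) {
    out <- numeric(ncol(U))
    pos_a <- 0L
    pos_x <- 0L
    for (b in names(ctrl_dims)) {
      K <- ctrl_dims[[b]]
      out[pos_a + 1:K] <- Qs[[b]] %*% xi[pos_x + 1:(K - 1)]
      pos_a <- pos_a + K
      pos_x <- pos_x + K - 1L
    }
    out
  }
  beta_from_state <- function(z, llam, ltau, lc2) {
    raw <- numeric(Kv)
    for (b in names(test_dims)) {
      i <- test_idx[[b]]
      raw[i] <- sz_projection(rhs_beta(z[i], llam[i], ltau[[b]], lc2[[b]]))
    }
    raw
  }
  log_prior_ctrl <- function(cv) {
    lp <- stats::dnorm(cv[1], 0, 100, log = TRUE)
    pos <- 1L
    for (b in names(ctrl_dims)) {
      K <- ctrl_dims[[b]] - 1L
      lp <- lp + sum(stats::dnorm(cv[pos + 1:K], 0,
                                  sqrt(ctrl_scales[[b]]), log = TRUE))
      pos <- pos + K
    }
    lp
  }

  run_chain <- function(chain_id) {
    set.seed(mcmc$seed + 1000L * chain_id)
    cv <- c(log(mean(y) + 0.1) + stats::rnorm(1, 0, 0.1),
            stats::rnorm(sum(xi_dims), 0, 0.05))
    z <- stats::rnorm(Kv, 0, 0.1)
    llam <- stats::rnorm(Kv, 0, 0.2)
    ltau <- lapply(global_scales, function(s) log(s / sqrt(n0)))
    lc2 <- lapply(test_dims, function(...) log(4))
    logphi <- 0

    u_part <- function(cv) cv[1] + drop(Uc %*% alpha_from_xi(cv[-1]))
    v_part <- function(beta) drop(Vc %*% beta)
    beta <- beta_from_state(z, llam, ltau, lc2)
    up <- u_part(cv)
    vp <- v_part(beta)
    phi <- exp(logphi)
    llik <- function(up, vp, phi) nb_cell_loglik(cells, exp(up + vp), phi)
    ll <- llik(up, vp, phi)

    log_prior_scales_all <- function(llam, ltau, lc2) {
      s <- 0
      for (b in names(test_dims)) {
        i <- test_idx[[b]]
        s <- s + log_prior_rhs_scales(llam[i], ltau[[b]], lc2[[b]],
                                      global_scale = global_scales[[b]] / sqrt(n0))
      }
      s
    }

    blk_ctrl <- amb_init(d_ctrl)
    blk_z <- amb_init(Kv)
    blk_lam <- amb_init(Kv, scale = 0.5)
    blk_glob <- amb_init(2L * length(test_dims), scale = 0.3)
    glob_vec <- function() c(unlist(ltau), unlist(lc2))
    n_keep <- mcmc$iter
    total <- mcmc$warmup + n_keep * mcmc$thin
    par_names <- c("beta0", colnames(U), colnames(V), "phi",
                   paste0("tau:", names(test_dims)),
                   paste0("c2:", names(test_dims)))
    draws <- matrix(NA_real_, n_keep, length(par_names),
                    dimnames = list(NULL, par_names))
    keep_i <- 0L

    for (it in seq_len(total)) {
      adapting <- it <= mcmc$warmup
      # control block (beta0 + null-space coordinates)
      st <- amb_step(blk_ctrl, cv, function(v) {
        llik(u_part(v), vp, phi) + log_prior_ctrl(v)
      }, ll + log_prior_ctrl(cv), it, adapting)
      blk_ctrl <- st$blk
      if (!identical(st$x, cv)) {
        cv <- st$x
        up <- u_part(cv)
        ll <- llik(up, vp, phi)
      }
      # test-block raw coefficients
      st <- amb_step(blk_z, z, function(zv) {
        bv <- beta_from_state(zv, llam, ltau, lc2)
        llik(up, v_part(bv), phi) + sum(stats::dnorm(zv, log = TRUE))
      }, ll + sum(stats::dnorm(z, log = TRUE)), it, adapting)
      blk_z <- st$blk
      if (!identical(st$x, z)) {
        z <- st$x
        beta <- beta_from_state(z, llam, ltau, lc2)
        vp <- v_part(beta)
        ll <- llik(up, vp, phi)
      }
      # local shrinkage scales
      lp_sc <- function(lv) {
        bv <- beta_from_state(z, lv, ltau, lc2)
        llik(up, v_part(bv), phi) + log_prior_scales_all(lv, ltau, lc2)
      }
      st <- amb_step(blk_lam, llam, lp_sc, lp_sc(llam), it, adapting)
      blk_lam <- st$blk
      llam <- st$x
      # global + slab scales (per block)
      gv <- glob_vec()
      lp_gl <- function(g) {
        nb <- length(test_dims)
        ltau2 <- as.list(g[seq_len(nb)])
        names(ltau2) <- names(test_dims)
        lc22 <- as.list(g[nb + seq_len(nb)])
        names(lc22) <- names(test_dims)
        bv <- beta_from_state(z, llam, ltau2, lc22)
        llik(up, v_part(bv), phi) + log_prior_scales_all(llam, ltau2, lc22)
      }
      st <- amb_step(blk_glob, gv, lp_gl, lp_gl(gv), it, adapting)
      blk_glob <- st$blk
      if (!identical(st$x, gv)) {
        nb <- length(test_dims)
        ltau <- as.list(st$x[seq_len(nb)])
        names(ltau) <- names(test_dims)
        lc2 <- as.list(st$x[nb + seq_len(nb)])
        names(lc2) <- names(test_dims)
      }
      beta <- beta_from_state(z, llam, ltau, lc2)
      vp <- v_part(beta)
      ll <- llik(up, vp, phi)
      # overdispersion
      logphi <- slice_sample1(logphi, function(lp) {
        llik(up, vp, exp(lp)) + log_prior_logphi(lp)
      }, w = 0.5)
      phi <- exp(logphi)
      ll <- llik(up, vp, phi)

      if (it > mcmc$warmup && (it - mcmc$warmup) %% mcmc$thin == 0L) {
        keep_i <- keep_i + 1L
        draws[keep_i, ] <- c(cv[1], alpha_from_xi(cv[-1]), beta, phi,
                             exp(unlist(ltau)), exp(unlist(lc2)))
      }
    }
    draws
  }

  draws <- do.call(rbind, lapply(seq_len(mcmc$chains), run_chain))
  chain_id <- rep(seq_len(mcmc$chains), each = mcmc$iter)
  meta <- list(n = n0, control_cols = colnames(U), test_cols = colnames(V),
               global_scales = global_scales, seed = mcmc$seed)
  new_posterior_draws(draws, chain_id, "intensity_selection", meta)
}

#' Determinants of survey fatigue among repeat participants
#'
#' Extends the intensity model with fatigue test features: the intercept,
#' control effects and selected test effects from the intensity fit enter
#' as fixed offsets (posterior medians, not re-estimated), and one-hot
#' fatigue blocks (age/schooling, sex, household size, employment, urban
#' type; 33 columns) act only on rows with `repeat_count >= 1` -
#' first-time rows anchor the subgroup baselines. Because fatigue can only
#' reduce reported contacts, the concatenated fatigue coefficients get the
#' negative-domain half regularised horseshoe prior with global scale
#' `32 / sqrt(n1)`, `n1` the number of repeat rows.
#'
#' @param records preprocessed records containing both first-time and
#'   repeat rows.
#' @param plugin a [select_features()] result from the intensity model.
#' @param mcmc an [mcmc_control()].
#' @return a `posterior_draws` object; fatigue columns are `meta$test_cols`.
#' @export
fit_fatigue_selection <- function(records, plugin, mcmc = mcmc_control()) {
  stopifnot(inherits(plugin, "selection_result"))
  y <- records$contact_count
  rep_ind <- as.numeric(records$repeat_count >= 1)
  n1 <- sum(rep_ind)
  if (n1 == 0) stop("fit_fatigue_selection: no repeat rows in records")

  enc <- encode_design(records, c("u", "v", "w"))
  need <- c("beta0", plugin$control_cols, plugin$selected)
  have <- c("beta0", colnames(enc$u), colnames(enc$v))
  if (!all(need %in% have))
    stop("fit_fatigue_selection: plugin refers to unknown column(s): ",
         paste(setdiff(need, have), collapse = ", "))
  offset <- rep(plugin$plugin_estimates[["beta0"]], length(y)) +
    drop(enc$u %*% plugin$plugin_estimates[plugin$control_cols])
  if (length(plugin$selected))
    offset <- offset +
      drop(enc$v[, plugin$selected, drop = FALSE] %*%
             plugin$plugin_estimates[plugin$selected])

  W <- enc$w * rep_ind
  Kw <- ncol(W)
  cells <- aggregate_nb_cells(W, y, extra = cbind(offset = offset))
  Wc <- cells$X
  off_c <- cells$extra[, "offset"]
  gscale <- 32 / sqrt(n1)

  run_chain <- function(chain_id) {
    set.seed(mcmc$seed + 1000L * chain_id)
    z <- stats::rnorm(Kw, 0, 0.1)
    llam <- stats::rnorm(Kw, 0, 0.2)
    ltau <- log(gscale)
    lc2 <- log(4)
    logphi <- 0
    gamma_of <- function(z, llam, ltau, lc2) -abs(rhs_beta(z, llam, ltau, lc2))
    llik <- function(gam, phi) {
      nb_cell_loglik(cells, exp(off_c + drop(Wc %*% gam)), phi)
    }
    gam <- gamma_of(z, llam, ltau, lc2)
    phi <- exp(logphi)
    ll <- llik(gam, phi)

    blk_z <- amb_init(Kw)
    blk_lam <- amb_init(Kw, scale = 0.5)
    blk_glob <- amb_init(2L, scale = 0.3)
    n_keep <- mcmc$iter
    total <- mcmc$warmup + n_keep * mcmc$thin
    par_names <- c(colnames(enc$w), "phi", "tau", "c2")
    draws <- matrix(NA_real_, n_keep, length(par_names),
                    dimnames = list(NULL, par_names))
    keep_i <- 0L
    for (it in seq_len(total)) {
      adapting <- it <= mcmc$warmup
      st <- amb_step(blk_z, z, function(zv) {
        llik(gamma_of(zv, llam, ltau, lc2), phi) + sum(stats::dnorm(zv, log = TRUE))
      }, ll + sum(stats::dnorm(z, log = TRUE)), it, adapting)
      blk_z <- st$blk
      z <- st$x
      lp_sc <- function(lv) {
        llik(gamma_of(z, lv, ltau, lc2), phi) +
          log_prior_rhs_scales(lv, ltau, lc2, global_scale = gscale)
      }
      st <- amb_step(blk_lam, llam, lp_sc, lp_sc(llam), it, adapting)
      blk_lam <- st$blk
      llam <- st$x
      lp_gl <- function(g) {
        llik(gamma_of(z, llam, g[1], g[2]), phi) +
          log_prior_rhs_scales(llam, g[1], g[2], global_scale = gscale)
      }
      st <- amb_step(blk_glob, c(ltau, lc2), lp_gl, lp_gl(c(ltau, lc2)), it,
                     adapting)
      blk_glob <- st$blk
      ltau <- st$x[1]
      lc2 <- st$x[2]
      gam <- gamma_of(z, llam, ltau, lc2)
      ll <- llik(gam, phi)
      logphi <- slice_sample1(logphi, function(lp) {
        llik(gam, exp(lp)) + log_prior_logphi(lp)
      }, w = 0.5)
      phi <- exp(logphi)
      ll <- llik(gam, phi)
      if (it > mcmc$warmup && (it - mcmc$warmup) %% mcmc$thin == 0L) {
        keep_i <- keep_i + 1L
        draws[keep_i, ] <- c(gam, phi, exp(ltau), exp(lc2))
      }
    }
    draws
  }

  draws <- do.call(rbind, lapply(seq_len(mcmc$chains), run_chain))
  chain_id <- rep(seq_len(mcmc$chains), each = mcmc$iter)
  meta <- list(n_repeat = n1, test_cols = colnames(enc$w),
               global_scale = gscale, seed = mcmc$seed)
  new_posterior_draws(draws, chain_id, "fatigue_selection", meta)
}

#' Apply the +/- 5% selection rule
#'
#' @param fit a [fit_intensity_selection()] or [fit_fatigue_selection()]
#'   result.
#' @param mode `"intensity"` selects test columns whose posterior median
#'   lies outside `(log 0.95, log 1.05)`; `"fatigue"` selects columns with
#'   median below `log 0.95` (a reduction of more than 5%).
#' @return object of class `selection_result`: a `table` data.frame
#'   (column, median, q2.5, q97.5, selected), the threshold interval, the
#'   selected column names, and plug-in posterior medians (`beta0`,
#'   controls, test effects) for downstream models.
#' @export
select_features <- function(fit, mode = c("intensity", "fatigue")) {
  mode <- match.arg(mode)
  stopifnot(inherits(fit, "posterior_draws"))
  if (nrow(fit$draws) == 0) stop("select_features: empty draws")
  cols <- fit$meta$test_cols
  thr <- selection_thresholds()
  q <- t(apply(fit$draws[, cols, drop = FALSE], 2, stats::quantile,
               probs = c(0.025, 0.5, 0.975)))
  med <- q[, 2]
  selected <- if (mode == "intensity")
    med < thr[["lower"]] | med > thr[["upper"]]
  else
    med < thr[["lower"]]
  table <- data.frame(column = cols, median = med, q2.5 = q[, 1],
                      q97.5 = q[, 3], selected = selected, row.names = NULL)
  plug_cols <- intersect(c("beta0", fit$meta$control_cols, cols),
                         colnames(fit$draws))
  structure(list(
    table = table,
    mode = mode,
    threshold = if (mode == "intensity") thr else c(lower = -Inf, upper = thr[["lower"]]),
    selected = cols[selected],
    control_cols = fit$meta$control_cols,
    plugin_estimates = posterior_median(fit)[plug_cols]
  ), class = "selection_result")
}

#' @export
print.selection_result <- function(x, ...) {
  cat("<selection_result> mode:", x$mode, "\n")
  cat(sprintf("  %d/%d columns selected (threshold interval %.4f .. %.4f)\n",
              length(x$selected), nrow(x$table),
              x$threshold[["lower"]], x$threshold[["upper"]]))
  if (length(x$selected)) cat("  ", paste(x$selected, collapse = ", "), "\n")
  invisible(x)
}

#' Union of selected features across waves
#'
#' The final feature set is the union of per-wave selections; both results
#' must cover the same column universe.
#'
#' @param res_a,res_b `selection_result` objects (same mode, same columns).
#' @return character vector of selected columns (union, in column order).
#' @export
union_selected <- function(res_a, res_b) {
  stopifnot(inherits(res_a, "selection_result"),
            inherits(res_b, "selection_result"))
  if (!identical(res_a$table$column, res_b$table$column))
    stop("union_selected: selection results cover different column sets")
  res_a$table$column[res_a$table$selected | res_b$table$selected]
}
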