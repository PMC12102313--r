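#' @title Adaptive Metropolis-within-Gibbs building blocks
#'
#' @description
#' The package fits all of its negative-binomial contact models with a
#' compact Metropolis-within-Gibbs sampler composed of three updates:
#'
#' * adaptive multivariate random-walk Metropolis blocks for regression and
#'   dose-response parameters (Haario-style empirical covariance with
#'   Robbins-Monro scaling toward the usual 0.234 / 0.44 acceptance
#'   targets; adaptation frozen after warmup),
#' * elliptical slice sampling for whitened Gaussian latent vectors
#'   (Gaussian-process values, Hilbert-space basis weights),
#' * univariate stepping-out slice sampling for scalar scale parameters
#'   (overdispersion, kernel hyperparameters, shrinkage scales).
#'
#' These are internal primitives; users interact with the model-level
#' fitting functions which assemble them.
#'
#' @name fatiguecast-mcmc
#' @keywords internal
NULL

## ---- adaptive multivariate random-walk Metropolis block -------------------

amb_init <- function(d, scale = NULL) {
  list(
    d = d,
    log_scale = log(if (is.null(scale)) 2.38 / sqrt(d) else scale),
    mean = numeric(d),
    m2 = diag(d) * 1e-4,
    chol = diag(d),
    n = 0L,
    target = if (d == 1L) 0.44 else 0.234
  )
}

amb_adapt <- function(blk, x, accept_prob, iter) {
  gam <- 1 / (20 + iter)^0.6
  blk$log_scale <- blk$log_scale + gam * (accept_prob - blk$target)
  n <- blk$n + 1L
  delta <- x - blk$mean
  blk$mean <- blk$mean + delta / n
  blk$m2 <- blk$m2 + tcrossprod(delta, x - blk$mean)
  blk$n <- n
  if (n >= 2L * blk$d + 10L && n %% 25L == 0L) {
    cov <- (blk$m2 + t(blk$m2)) / (2 * (n - 1))
    ch <- tryCatch(chol(cov + diag(1e-10 + 1e-6 * mean(diag(cov)), blk$d)),
                   error = function(e) NULL)
    if (!is.null(ch)) blk$chol <- ch
  }
  blk
}

# One RWM step for the parameter sub-vector `x` with log-posterior `logpost`.
# `lp_cur` caches logpost(x). Adaptation happens only while `adapting`.
amb_step <- function(blk, x, logpost, lp_cur, iter, adapting = TRUE) {
  prop <- x + exp(blk$log_scale) * drop(crossprod(blk$chol, stats::rnorm(blk$d)))
  lp_prop <- logpost(prop)
  acc_p <- if (is.finite(lp_prop)) exp(min(0, lp_prop - lp_cur)) else 0
  if (acc_p > 0 && stats::runif(1) < acc_p) {
    x <- prop
    lp_cur <- lp_prop
  }
  if (adapting) blk <- amb_adapt(blk, x, acc_p, iter)
  list(blk = blk, x = x, lp = lp_cur)
}

## ---- univariate stepping-out slice sampler --------------------------------

slice_sample1 <- function(x0, logf, w = 1, lower = -Inf, upper = Inf,
                          max_steps = 30L) {
  f0 <- logf(x0)
  if (!is.finite(f0)) stop("slice_sample1: log density not finite at current value")
  z <- f0 - stats::rexp(1)
  L <- x0 - stats::runif(1) * w
  R <- L + w
  j <- floor(stats::runif(1) * max_steps)
  k <- max_steps - 1 - j
  while (j > 0 && L > lower && logf(L) > z) {
    L <- L - w
    j <- j - 1
  }
  while (k > 0 && R < upper && logf(R) > z) {
    R <- R + w
    k <- k - 1
  }
  L <- max(L, lower)
  R <- min(R, upper)
  for (i in 1:100) {
    x1 <- stats::runif(1, L, R)
    if (logf(x1) > z) return(x1)
    if (x1 < x0) L <- x1 else R <- x1
    if (R - L < 1e-12) break
  }
  x0
}

## ---- elliptical slice sampling (standard-normal prior) --------------------

ess_step <- function(z, loglik) {
  nu <- stats::rnorm(length(z))
  threshold <- loglik(z) - stats::rexp(1)
  theta <- stats::runif(1, 0, 2 * pi)
  lo <- theta - 2 * pi
  hi <- theta
  repeat {
    zp <- z * cos(theta) + nu * sin(theta)
    if (loglik(zp) > threshold) return(zp)
    if (theta < 0) lo <- theta else hi <- theta
    if (hi - lo < 1e-10) return(z)
    theta <- stats::runif(1, lo, hi)
  }
}

## ---- scalar log-density helpers -------------------------------------------

# half-Normal^+(mu, sd): normal truncated to (0, Inf); unnormalised is fine
# within a fit (the normalising constant does not involve the parameter).
log_dhalfnorm <- function(x, mu, sd) {
  ifelse(x > 0, stats::dnorm(x, mu, sd, log = TRUE), -Inf)
}

log_dinvgamma <- function(x, shape, scale) {
  ifelse(x > 0, shape * log(scale) - lgamma(shape) - (shape + 1) * log(x) - scale / x, -Inf)
}

# log prior density of log(phi) when 1/phi ~ Exponential(1)
log_prior_logphi <- function(logphi) -exp(-logphi) - logphi

# half-t density (x > 0), scale `s`, df `nu`; unnormalised
log_dhalft <- function(x, nu, s) {
  ifelse(x > 0, stats::dt(x / s, df = nu, log = TRUE) - log(s), -Inf)
}

## ---- scalar prior specifications ------------------------------------------

#' Scalar prior specification
#'
#' Light-weight container for the scalar priors that appear in the
#' correction model and the sequential wave-carry rules: `normal(mean, sd)`,
#' `halfnormal(mean, sd)` (normal truncated to the positive axis),
#' `exponential(rate)`.
#'
#' @param family one of `"normal"`, `"halfnormal"`, `"exponential"`.
#' @param par1,par2 distribution parameters (mean/sd or rate).
#' @return an object of class `prior_spec`.
#' @export
prior_spec <- function(family = c("normal", "halfnormal", "exponential"),
                       par1 = 0, par2 = 1) {
  family <- match.arg(family)
  stopifnot(is.finite(par1), is.finite(par2))
  if (family %in% c("normal", "halfnormal") && par2 <= 0)
    stop("prior_spec: sd must be positive")
  if (family == "exponential" && par1 <= 0)
    stop("prior_spec: rate must be positive")
  structure(list(family = family, par1 = par1, par2 = par2),
            class = "prior_spec")
}

log_dprior <- function(spec, x) {
  switch(spec$family,
    normal = stats::dnorm(x, spec$par1, spec$par2, log = TRUE),
    halfnormal = log_dhalfnorm(x, spec$par1, spec$par2),
    exponential = stats::dexp(x, rate = spec$par1, log = TRUE)
  )
}

## ---- convergence diagnostics ----------------------------------------------

# Split-Rhat of a single parameter's draws across chains (each chain split
# in half), per the standard formulation.
split_rhat <- function(x, chain) {
  halves <- lapply(split(x, chain), function(v) {
    h <- length(v) %/% 2
    list(v[seq_len(h)], v[(h + 1):(2 * h)])
  })
  segs <- unlist(halves, recursive = FALSE)
  m <- length(segs)
  n <- length(segs[[1]])
  if (n < 2L) return(NA_real_)
  means <- vapply(segs, mean, 0)
  vars <- vapply(segs, stats::var, 0)
  b <- n * stats::var(means)
  w <- mean(vars)
  if (w <= 0) return(1)
  sqrt(((n - 1) / n * w + b / n) / w)
}

## ---- posterior draws container --------------------------------------------

#' Posterior draws container
#'
#' All model fits return a `posterior_draws` object: a draws matrix
#' (iterations stacked over chains, one named column per quantity), the
#' chain index of each row, split-Rhat and effective-sample-size
#' diagnostics, and model metadata (seed, problem size, cached design
#' information used by downstream summaries).
#'
#' @param draws numeric matrix, one column per parameter (named).
#' @param chain integer vector, chain index per row of `draws`.
#' @param model character tag naming the model.
#' @param meta list of model-specific metadata.
#' @return an object of class `posterior_draws`.
#' @keywords internal
new_posterior_draws <- function(draws, chain, model, meta = list()) {
  stopifnot(is.matrix(draws), nrow(draws) == length(chain),
            !is.null(colnames(draws)))
  rhat <- apply(draws, 2, split_rhat, chain = chain)
  ess <- tryCatch(
    colSums(do.call(rbind, lapply(split(seq_along(chain), chain), function(i) {
      coda::effectiveSize(coda::mcmc(draws[i, , drop = FALSE]))
    }))),
    error = function(e) rep(NA_real_, ncol(draws))
  )
  structure(
    list(draws = draws, chain = chain, model = model, meta = meta,
         rhat = rhat, ess = ess,
         converged = all(rhat < 1.05, na.rm = TRUE)),
    class = "posterior_draws"
  )
}

#' @export
print.posterior_draws <- function(x, ...) {
  cat("<posterior_draws> model:", x$model, "\n")
  cat(sprintf("  %d draws x %d quantities, %d chain(s)\n",
              nrow(x$draws), ncol(x$draws), length(unique(x$chain))))
  cat(sprintf("  max split-Rhat %.3f, min ESS %.0f, converged flag: %s\n",
              max(x$rhat, na.rm = TRUE), min(x$ess, na.rm = TRUE),
              x$converged))
  invisible(x)
}

#' Summarise posterior draws
#'
#' @param object a [new_posterior_draws()] object.
#' @param pars optional regular expression selecting quantities.
#' @param ... unused.
#' @return a data.frame with median, 95% interval, split-Rhat and ESS per
#'   quantity.
#' @export
summary.posterior_draws <- function(object, pars = NULL, ...) {
  keep <- colnames(object$draws)
  if (!is.null(pars)) keep <- grep(pars, keep, value = TRUE)
  d <- object$draws[, keep, drop = FALSE]
  q <- t(apply(d, 2, stats::quantile, probs = c(0.025, 0.5, 0.975)))
  data.frame(
    param = keep,
    median = q[, 2], q2.5 = q[, 1], q97.5 = q[, 3],
    rhat = object$rhat[keep], ess = object$ess[keep],
    row.names = NULL
  )
}

#' Posterior medians of selected quantities
#'
#' @param fit a `posterior_draws` object.
#' @param pars optional regular expression; default all quantities.
#' @return named numeric vector of posterior medians.
#' @export
posterior_median <- function(fit, pars = NULL) {
  stopifnot(inherits(fit, "posterior_draws"))
  keep <- colnames(fit$draws)
  if (!is.null(pars)) keep <- grep(pars, keep, value = TRUE)
  apply(fit$draws[, keep, drop = FALSE], 2, stats::median)
}

#' Posterior means of selected quantities
#'
#' Used by the sequential wave-carry rule, which centres next-wave priors
#' on posterior means.
#'
#' @inheritParams posterior_median
#' @return named numeric vector of posterior means.
#' @export
posterior_mean <- function(fit, pars = NULL) {
  stopifnot(inherits(fit, "posterior_draws"))
  keep <- colnames(fit$draws)
  if (!is.null(pars)) keep <- grep(pars, keep, value = TRUE)
  colMeans(fit$draws[, keep, drop = FALSE])
}

#' @export
as.matrix.posterior_draws <- function(x, ...) x$draws

## ---- negative binomial likelihood on aggregated cells ---------------------

# Rows with identical (design row, repeat count, date, age) share one mean,
# so the row-level NB log-likelihood decomposes into cell statistics plus a
# term depending on the counts only through their overall frequency table:
#   sum_i log NB(y_i; mu_c, phi) =
#     sum_c [ n_c phi (log phi - log(phi + mu_c)) +
#             S_c (log mu_c - log(phi + mu_c)) ]
#     + sum_v freq_v lgamma(v + phi) - n lgamma(phi) - sum_i lgamma(y_i + 1)
# with S_c the cell count sum and n_c the cell size. This is the exact
# likelihood (including the phi-dependent terms) at O(cells + distinct y)
# cost per evaluation.
aggregate_nb_cells <- function(X, y, extra = NULL) {
  key_mat <- if (is.null(extra)) X else cbind(X, extra)
  key <- do.call(paste, c(as.data.frame(key_mat), sep = "\r"))
  idx <- match(key, unique(key))
  ord <- which(!duplicated(idx))
  y_vals <- sort(unique(y))
  list(
    X = X[ord, , drop = FALSE],
    extra = if (is.null(extra)) NULL else extra[ord, , drop = FALSE],
    S = as.numeric(tapply(y, idx, sum)[as.character(idx[ord])]),
    n = as.numeric(tapply(y, idx, length)[as.character(idx[ord])]),
    row_cell = idx,
    y = y,
    y_vals = y_vals,
    y_freq = as.numeric(table(factor(y, levels = y_vals))),
    n_total = length(y),
    const = -sum(lgamma(y + 1))
  )
}

nb_cell_loglik <- function(cells, mu, phi) {
  ld <- log(phi + mu)
  lq_term <- ifelse(cells$S > 0, cells$S * (log(mu) - ld), 0)
  sum(cells$n * phi * (log(phi) - ld) + lq_term) +
    sum(cells$y_freq * lgamma(cells$y_vals + phi)) -
    cells$n_total * lgamma(phi) + cells$const
}

# Pointwise (per-cell) log-likelihood, used for WAIC model comparison; the
# cell is the observation unit and the sum over cells equals
# nb_cell_loglik.
nb_cell_loglik_pointwise <- function(cells, mu, phi) {
  ld <- log(phi + mu)
  base <- cells$n * phi * (log(phi) - ld) +
    ifelse(cells$S > 0, cells$S * (log(mu) - ld), 0) -
    cells$n * lgamma(phi)
  lg <- rowsum(lgamma(cells$y + phi) - lgamma(cells$y + 1), cells$row_cell)
  base + drop(lg)
}

# WAIC from an S x ncell matrix of pointwise log-likelihood draws.
waic_from_loglik <- function(ll) {
  mx <- apply(ll, 2, max)
  lpd <- sum(mx + log(colMeans(exp(sweep(ll, 2, mx)))))
  p_waic <- sum(apply(ll, 2, stats::var))
  c(elpd_waic = lpd - p_waic, p_waic = p_waic, waic = -2 * (lpd - p_waic))
}
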