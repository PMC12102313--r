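#' Matern-3/2 covariance function
#'
#' `k(t, t') = sigma^2 (1 + sqrt(3)|t - t'| / ell) exp(-sqrt(3)|t - t'| / ell)`,
#' used for the calendar-time trend in the longitudinal model.
#'
#' @param t,t2 numeric inputs (vectorised).
#' @param sigma amplitude (> 0).
#' @param ell lengthscale (> 0).
#' @return covariance value(s).
#' @export
#' @examples
#' matern32(0, 1, sigma = 1, ell = 1) # (1 + sqrt(3)) * exp(-sqrt(3))
matern32 <- function(t, t2, sigma, ell) {
  if (any(sigma <= 0) || any(ell <= 0)) stop("matern32: sigma and ell must be positive")
  d <- sqrt(3) * abs(t - t2) / ell
  sigma^2 * (1 + d) * exp(-d)
}

#' Squared-exponential covariance function
#'
#' `k(x, x') = sigma^2 exp(-(x - x')^2 / (2 ell^2))`, used for the fatigue
#' curve over repeat counts and (via its Hilbert-space approximation) the
#' age effect.
#'
#' @inheritParams matern32
#' @param x,x2 numeric inputs (vectorised).
#' @return covariance value(s).
#' @export
sq_exp <- function(x, x2, sigma, ell) {
  if (any(sigma <= 0) || any(ell <= 0)) stop("sq_exp: sigma and ell must be positive")
  sigma^2 * exp(-(x - x2)^2 / (2 * ell^2))
}

#' Kernel matrix on a grid
#'
#' @param x numeric grid.
#' @param family `"matern32"` or `"squared_exponential"`.
#' @param sigma,ell kernel hyperparameters.
#' @param jitter value added to the diagonal for numerical stability.
#' @return a symmetric positive (semi-)definite matrix.
#' @export
kernel_matrix <- function(x, family = c("matern32", "squared_exponential"),
                          sigma = 1, ell = 1, jitter = 1e-8) {
  family <- match.arg(family)
  dmat <- outer(x, x, function(a, b) a - b)
  k <- switch(family,
    matern32 = matern32(dmat, 0, sigma, ell),
    squared_exponential = sq_exp(dmat, 0, sigma, ell)
  )
  k + diag(jitter, length(x))
}

#' Orthogonal sum-to-zero projection
#'
#' Projects a coefficient vector onto the zero-sum subspace by subtracting
#' its mean. Together with [sz_nullspace_basis()] this provides the two
#' interchangeable mechanisms used for sum-to-zero identifiability: the
#' projection is applied to regularised-horseshoe draws (whose shrinkage
#' structure is coordinate-wise), while the sum-to-zero multivariate normal
#' blocks are reparameterised through the orthonormal null-space basis.
#'
#' @param x numeric vector (or matrix, projected row-wise) of length >= 2.
#' @return object of the same shape whose (row) sums are zero.
#' @export
sz_projection <- function(x) {
  if (is.matrix(x)) {
    if (ncol(x) < 2) stop("sz_projection: need dimension >= 2")
    return(sweep(x, 1, rowMeans(x)))
  }
  if (length(x) < 2) stop("sz_projection: need dimension >= 2")
  x - mean(x)
}

#' Orthonormal null-space basis of the sum constraint
#'
#' Returns a `K x (K-1)` matrix `Q` with orthonormal columns orthogonal to
#' the ones vector, so that `alpha = Q %*% xi` sums to zero for any free
#' `xi` and `xi ~ N(0, s2 I)` induces the sum-to-zero multivariate normal
#' distribution with covariance `s2 (I - J/K)` (marginal variance
#' `s2 (K-1)/K` per coordinate).
#'
#' @param K factor dimension (>= 2).
#' @return `K x (K-1)` orthonormal basis matrix.
#' @export
sz_nullspace_basis <- function(K) {
  if (K < 2) stop("sz_nullspace_basis: need K >= 2")
  qr.Q(qr(cbind(rep(1, K), diag(K))))[, 2:K, drop = FALSE]
}

#' Draw from the sum-to-zero multivariate normal prior
#'
#' @param n number of draws.
#' @param K factor dimension.
#' @param scale variance argument `s2`; the values used by the selection
#'   model (`14/13`, `2`, `3/2`) give unit marginal prior variance when
#'   `s2 = K/(K-1)`.
#' @return `n x K` matrix of draws, each row summing to zero.
#' @export
szmvnormal_draw <- function(n, K, scale) {
  stopifnot(K >= 2, scale > 0)
  Q <- sz_nullspace_basis(K)
  xi <- matrix(stats::rnorm(n * (K - 1), sd = sqrt(scale)), n, K - 1)
  xi %*% t(Q)
}

#' Regularised horseshoe specification
#'
#' @param local_df,global_df,slab_df degrees of freedom of the local
#'   half-t scales, the global half-t scale, and the slab.
#' @param slab_scale slab scale (limits the magnitude of unshrunk
#'   coefficients).
#' @param global_scale scale of the global shrinkage parameter; the
#'   selection models use `s / sqrt(n)` with `s` block-specific.
#' @param constraint `"sum_to_zero"` (orthogonal projection applied to the
#'   draw), `"negative_half"` (magnitudes mapped to the negative axis) or
#'   `"none"`.
#' @return an object of class `rhs_spec`.
#' @export
rhs_spec <- function(local_df = 3, global_df = 2, slab_df = 4,
                     slab_scale = 2, global_scale = 1,
                     constraint = c("sum_to_zero", "negative_half", "none")) {
  constraint <- match.arg(constraint)
  vals <- c(local_df, global_df, slab_df, slab_scale, global_scale)
  if (any(!is.finite(vals)) || any(vals <= 0))
    stop("rhs_spec: all degrees of freedom and scales must be positive")
  structure(list(local_df = local_df, global_df = global_df,
                 slab_df = slab_df, slab_scale = slab_scale,
                 global_scale = global_scale, constraint = constraint),
            class = "rhs_spec")
}

#' Draw from the (constrained) regularised horseshoe prior
#'
#' Hierarchy: local scales `lambda_k ~ half-t(local_df)`, global scale
#' `tau ~ half-t(global_df, global_scale)`, slab
#' `c^2 ~ Inv-Gamma(slab_df/2, slab_df slab_scale^2 / 2)`, regularised
#' local scale `lt_k^2 = c^2 lambda_k^2 / (c^2 + tau^2 lambda_k^2)` and
#' `beta_k = z_k tau lt_k`, `z_k ~ N(0,1)`. The constraint named in `spec`
#' is applied afterwards.
#'
#' @param n number of draws.
#' @param K coefficient dimension.
#' @param spec an [rhs_spec()].
#' @return `n x K` matrix of prior draws.
#' @export
rhs_prior_draw <- function(n, K, spec) {
  stopifnot(inherits(spec, "rhs_spec"), K >= 1)
  lambda <- matrix(abs(stats::rt(n * K, df = spec$local_df)), n, K)
  tau <- abs(stats::rt(n, df = spec$global_df)) * spec$global_scale
  c2 <- spec$slab_df * spec$slab_scale^2 / stats::rchisq(n, df = spec$slab_df)
  lt2 <- c2 * lambda^2 / (c2 + tau^2 * lambda^2)
  beta <- matrix(stats::rnorm(n * K), n, K) * tau * sqrt(lt2)
  switch(spec$constraint,
    sum_to_zero = sz_projection(beta),
    negative_half = -abs(beta),
    none = beta
  )
}

#' Hilbert-space approximate Gaussian process basis
#'
#' Laplacian eigenfunctions on the boundary-extended interval
#' `[-L, L]`, `L = c * max |x - centre|`, with the squared-exponential
#' spectral density. A function draw is
#' `f = Phi %*% (sqrt(spd(sigma, ell)) * z)` with `z ~ N(0, I_m)`.
#'
#' @param x input locations (the model rescales age 0-84 to `[-1, 1]`).
#' @param m number of basis functions (>= 10 recommended).
#' @param c boundary inflation factor (> 1).
#' @param centre centre of the domain; defaults to `mean(range(x))`.
#' @param half_range fixed half-width of the (centred) input domain; by
#'   default the observed `max(abs(x - centre))`. Supplying it makes the
#'   basis independent of which inputs happen to be observed.
#' @return a list with the basis matrix `phi` (`length(x) x m`), the
#'   spectral frequencies `omega`, `L`, and `spd(sigma, ell)`, a function
#'   returning the `m` spectral densities.
#' @export
hsgp_basis <- function(x, m = 40, c = 1.5, centre = NULL, half_range = NULL) {
  if (c <= 1) stop("hsgp_basis: boundary factor c must exceed 1")
  if (m < 10) warning("hsgp_basis: fewer than 10 basis functions is a coarse approximation")
  if (is.null(centre)) centre <- mean(range(x))
  xc <- x - centre
  if (is.null(half_range)) half_range <- max(abs(xc))
  if (any(abs(xc) > c * half_range))
    stop("hsgp_basis: inputs outside the boundary-extended domain")
  L <- c * half_range
  if (L <= 0) stop("hsgp_basis: degenerate domain")
  j <- seq_len(m)
  omega <- j * pi / (2 * L)
  phi <- sqrt(1 / L) * sin(outer(xc + L, omega))
  spd <- function(sigma, ell) sigma^2 * sqrt(2 * pi) * ell * exp(-(ell * omega)^2 / 2)
  list(phi = phi, omega = omega, L = L, centre = centre, m = m, spd = spd)
}

# Covariance implied by an HSGP basis (for accuracy checks against the
# exact kernel): Phi diag(spd) Phi'.
hsgp_cov <- function(basis, sigma, ell) {
  s <- basis$spd(sigma, ell)
  basis$phi %*% (s * t(basis$phi))
}
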