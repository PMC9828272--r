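# Lower-layer spatial Gaussian processes: the log-timescale and log-variance
# fields are sparse GPs anchored at an inducing grid, with a whitened
# variational posterior q(nu) = N(whitened_mean, scale scale') over the
# standard-normal coordinates nu of the inducing values u = m(Z) + L nu,
# where K_ZZ = L L'. Whitening makes the KL to the prior independent of the
# kernel hyperparameters and conditions the optimisation well.

#' Radial basis function kernel
#'
#' `amplitude^2 * exp(-||x - x'||^2 / (2 lengthscale^2))` between rows of two
#' planar location matrices.
#'
#' @param X,X2 Matrices with two columns of planar coordinates.
#' @param hyper A [field_hyper()] object (uses `amplitude`, `lengthscale`).
#' @return A `nrow(X) x nrow(X2)` covariance matrix.
#' @export
rbf_kernel <- function(X, X2, hyper) {
  X <- .as_locations(X); X2 <- .as_locations(X2)
  d2 <- outer(rowSums(X^2), rowSums(X2^2), "+") - 2 * tcrossprod(X, X2)
  d2[d2 < 0] <- 0
  hyper$amplitude^2 * exp(-d2 / (2 * hyper$lengthscale^2))
}

#' Periodic kernel
#'
#' `amplitude^2 * exp(-2 * sum_d sin^2(pi (x_d - x'_d) / period) / lengthscale^2)`.
#' Exactly invariant under translation of either argument by `period` along
#' either axis, which matches a simulation environment with periodic
#' boundaries (the field tiles the plane).
#'
#' @inheritParams rbf_kernel
#' @return A `nrow(X) x nrow(X2)` covariance matrix.
#' @export
periodic_kernel <- function(X, X2, hyper) {
  if (is.null(hyper$period)) {
    stop("periodic kernel requires 'period' in the hyperparameters",
         call. = FALSE)
  }
  X <- .as_locations(X); X2 <- .as_locations(X2)
  s2 <- 0
  for (d in 1:2) {
    s2 <- s2 + sin(pi * outer(X[, d], X2[, d], "-") / hyper$period)^2
  }
  hyper$amplitude^2 * exp(-2 * s2 / hyper$lengthscale^2)
}

.as_locations <- function(X) {
  X <- as.matrix(X)
  if (is.null(dim(X)) || ncol(X) != 2) {
    stop("locations must be a matrix with two columns", call. = FALSE)
  }
  storage.mode(X) <- "double"
  X
}

#' Hyperparameters of a latent spatial field
#'
#' @param mu Scalar prior mean of the log-scale field.
#' @param beta Covariate coefficients on the log scale, per standard
#'   deviation of each covariate (empty for a constant mean).
#' @param amplitude Kernel amplitude (> 0), the prior standard deviation of
#'   the log-scale field.
#' @param lengthscale Kernel lengthscale (> 0); distance units for the RBF
#'   kernel, dimensionless for the periodic kernel (it acts on the sine
#'   features).
#' @param kernel `"rbf"` or `"periodic"`.
#' @param period Domain length for the periodic kernel (required when
#'   `kernel = "periodic"`).
#' @return An object of class `crwgp_hyper`.
#' @export
field_hyper <- function(mu = 0, beta = numeric(0), amplitude = 1,
                        lengthscale = 1, kernel = c("rbf", "periodic"),
                        period = NULL) {
  kernel <- match.arg(kernel)
  .check_pos(amplitude, "amplitude")
  .check_pos(lengthscale, "lengthscale")
  if (kernel == "periodic") .check_pos(period, "period")
  structure(list(mu = mu, beta = beta, amplitude = amplitude,
                 lengthscale = lengthscale, kernel = kernel, period = period),
            class = "crwgp_hyper")
}

.kernel_matrix <- function(X, X2, hyper) {
  switch(hyper$kernel,
         rbf = rbf_kernel(X, X2, hyper),
         periodic = periodic_kernel(X, X2, hyper))
}

#' Regular inducing grid over a rectangular domain
#'
#' @param xlim,ylim Domain extents.
#' @param nx,ny Grid resolution per axis (default 15).
#' @return An `m x 2` matrix of locations (row-major over the lattice) with
#'   the domain stored in attributes `xlim`, `ylim`.
#' @export
inducing_grid <- function(xlim, ylim, nx = 15, ny = 15) {
  if (nx * ny < 4) stop("inducing grid needs at least 4 points", call. = FALSE)
  Z <- as.matrix(expand.grid(x = seq(xlim[1], xlim[2], length.out = nx),
                             y = seq(ylim[1], ylim[2], length.out = ny)))
  dimnames(Z) <- NULL
  attr(Z, "xlim") <- xlim
  attr(Z, "ylim") <- ylim
  attr(Z, "dim_grid") <- c(nx, ny)
  Z
}

# Cholesky with jitter escalation; returns lower factor.
.chol_lower <- function(K, jitter = NULL) {
  d <- mean(diag(K))
  j <- if (is.null(jitter)) 1e-8 * d else jitter
  for (k in -1:6) {
    jk <- if (k < 0) 0 else j * 10^k
    R <- tryCatch(chol(K + diag(jk, nrow(K))), error = function(e) NULL)
    if (!is.null(R)) return(t(R))
  }
  stop("Cholesky factorisation failed after jitter escalation", call. = FALSE)
}

#' Variational posterior of a latent spatial field
#'
#' Bundles the inducing grid, hyperparameters, and whitened variational
#' parameters, and caches the prior Cholesky factor of the inducing-point
#' covariance.
#'
#' @param grid An [inducing_grid()] matrix.
#' @param hyper A [field_hyper()] object.
#' @param whitened_mean Length-m variational mean in whitened coordinates
#'   (default zero, the prior).
#' @param whitened_scale m x m lower-triangular scale factor with positive
#'   diagonal (default identity, the prior).
#' @return An object of class `crwgp_field`.
#' @export
latent_field_posterior <- function(grid, hyper,
                                   whitened_mean = NULL,
                                   whitened_scale = NULL) {
  grid <- .as_locations(grid)
  m <- nrow(grid)
  if (is.null(whitened_mean)) whitened_mean <- rep(0, m)
  if (is.null(whitened_scale)) whitened_scale <- diag(m)
  stopifnot(length(whitened_mean) == m,
            all(dim(whitened_scale) == c(m, m)))
  if (any(diag(whitened_scale) <= 0)) {
    stop("whitened scale must have a strictly positive diagonal",
         call. = FALSE)
  }
  whitened_scale[upper.tri(whitened_scale)] <- 0
  Lzz <- .chol_lower(.kernel_matrix(grid, grid, hyper))
  structure(list(grid = grid, hyper = hyper,
                 whitened_mean = as.numeric(whitened_mean),
                 whitened_scale = whitened_scale, Lzz = Lzz),
            class = "crwgp_field")
}

#' Mean function of a latent field
#'
#' Constant `mu`, plus `beta . e(x)` when an environmental covariate stack is
#' attached; covariates enter standardised (zero mean, unit variance over
#' their raster cells), so coefficients are per standard deviation.
#'
#' @param X Locations (matrix with two columns).
#' @param hyper A [field_hyper()] object.
#' @param covs Optional [covariate_stack()].
#' @return Numeric vector of prior means at the rows of `X`.
#' @export
mean_function <- function(X, hyper, covs = NULL) {
  X <- .as_locations(X)
  m <- rep(hyper$mu, nrow(X))
  if (length(hyper$beta)) {
    if (is.null(covs)) {
      stop("hyperparameters carry covariate coefficients but no covariate ",
           "stack was supplied", call. = FALSE)
    }
    E <- covariate_lookup(covs, X)
    if (ncol(E) != length(hyper$beta)) {
      stop("length of 'beta' must match the number of covariates",
           call. = FALSE)
    }
    m <- m + as.numeric(E %*% hyper$beta)
  }
  m
}

# Internal: conditioning of field values at Xstar on the whitened inducing
# coordinates. Returns the linear map A_w (n* x m) with
#   f(Xstar) | nu  ~  N(mean_fn + A_w nu, diag(rvar)),
# rvar the per-point conditional (Nystrom residual) variance.
.field_conditioning <- function(post, Xstar, covs = NULL) {
  Xstar <- .as_locations(Xstar)
  Kzx <- .kernel_matrix(post$grid, Xstar, post$hyper)   # m x n*
  V <- forwardsolve(post$Lzz, Kzx)                      # L^{-1} K_Zx
  rvar <- pmax(post$hyper$amplitude^2 - colSums(V^2), 0)
  list(Aw = t(V), rvar = rvar,
       mean0 = mean_function(Xstar, post$hyper, covs))
}

#' Predictive marginals of a latent field
#'
#' Sparse whitened-GP predictive mean and variance at query locations:
#' `mean = m(x) + K_xZ L^-T nu_mean` and
#' `var = k(x,x) - ||L^-1 K_Zx||^2 + ||S' L^-1 K_Zx||^2`, with `L` the prior
#' factor at the inducing grid and `S` the whitened scale.
#'
#' @param post A [latent_field_posterior()].
#' @param Xstar Query locations (matrix with two columns).
#' @param covs Optional [covariate_stack()] for the mean function.
#' @return A list with numeric vectors `mean` and `var` (var clamped at 0).
#' @export
conditional_marginals <- function(post, Xstar, covs = NULL) {
  cond <- .field_conditioning(post, Xstar, covs)
  S <- post$whitened_scale
  B <- crossprod(S, t(cond$Aw))          # S' L^-1 K_Zx, m x n*
  list(mean = cond$mean0 + as.numeric(cond$Aw %*% post$whitened_mean),
       var = pmax(cond$rvar + colSums(B^2), 0))
}

#' Sample latent field values at query locations
#'
#' Draws from the per-location predictive marginals (locations are sampled
#' independently; joint draws across locations are handled inside the model
#' through the shared inducing coordinates).
#'
#' @inheritParams conditional_marginals
#' @param n_samples Number of draws.
#' @return An `n_samples x nrow(Xstar)` matrix of log-scale field values.
#' @export
sample_field_values <- function(post, Xstar, covs = NULL, n_samples = 1) {
  stopifnot(n_samples >= 1)
  cm <- conditional_marginals(post, Xstar, covs)
  nx <- length(cm$mean)
  z <- matrix(stats::rnorm(n_samples * nx), n_samples, nx)
  sweep(z, 2, sqrt(cm$var), "*") + matrix(cm$mean, n_samples, nx,
                                          byrow = TRUE)
}

#' Exponential link from log-scale fields to positive movement parameters
#'
#' Log-scale values are clipped to +/- 20 before exponentiation to guard
#' against overflow during early optimisation steps.
#'
#' @param values Numeric log-scale field values.
#' @return Strictly positive values `exp(clip(values))`.
#' @export
link_positive <- function(values) {
  exp(pmin(pmax(values, -20), 20))
}
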