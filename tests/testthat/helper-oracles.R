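# Independent oracles used across tests. These deliberately use plain dense
# linear algebra (solve/determinant) rather than the package's Cholesky
# paths, so that agreement is informative.

# Multivariate normal log-density, dense and direct.
dense_mvn_logpdf <- function(x, mean, Sigma) {
  r <- x - mean
  -0.5 * as.numeric(crossprod(r, solve(Sigma, r))) -
    0.5 * as.numeric(determinant(Sigma, logarithm = TRUE)$modulus) -
    0.5 * length(x) * log(2 * pi)
}

# Textbook sparse-GP predictive marginals computed densely from the joint
# Gaussian, for checking the whitened implementation.
dense_conditional_oracle <- function(post, Xstar) {
  hyper <- post$hyper
  Z <- post$grid
  Kzz <- crwgp:::.kernel_matrix(Z, Z, hyper)
  Kzx <- crwgp:::.kernel_matrix(Z, Xstar, hyper)
  Kxx <- crwgp:::.kernel_matrix(Xstar, Xstar, hyper)
  L <- t(chol(Kzz))
  Svar <- tcrossprod(post$whitened_scale)
  # q(u) in natural coordinates: N(m0 + L wm, L Svar L')
  qu_mean_dev <- L %*% post$whitened_mean
  qu_cov <- L %*% Svar %*% t(L)
  A <- t(solve(Kzz, Kzx))                       # K_xZ K_ZZ^-1
  mean <- mean_function(Xstar, hyper) + as.numeric(A %*% qu_mean_dev)
  cov <- Kxx - A %*% Kzx + A %*% qu_cov %*% t(A)
  list(mean = mean, var = pmax(diag(cov), 0))
}

# Random small kernel instance for property tests.
random_kernel_instance <- function(n_max = 8) {
  n <- sample(3:n_max, 1)
  t <- cumsum(c(0, runif(n - 1, 0.2, 1.5)))
  list(t = t, tau = runif(n - 1, 0.1, 5), sigma2 = runif(n - 1, 0.1, 5))
}

# Random whitened posterior with positive-diagonal lower-triangular scale.
random_posterior <- function(grid, hyper) {
  m <- nrow(grid)
  S <- matrix(rnorm(m * m, 0, 0.2), m, m)
  S[upper.tri(S)] <- 0
  diag(S) <- exp(rnorm(m, 0, 0.3))
  latent_field_posterior(grid, hyper, rnorm(m), S)
}
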