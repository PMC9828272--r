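# Top-layer likelihood and the stochastic variational objective.
#
# A trajectory segment y (n x 2) is modelled, per coordinate dimension, as a
# Gaussian process with mean equal to the first observed position and
# covariance K_NS + omega2 I, where K_NS is the non-stationary integrated OU
# matrix built from the per-interval parameters tau_p = exp(g_tau_p),
# sigma2_p = exp(g_sig_p) evaluated at between-fix midpoints. The two
# coordinate dimensions are conditionally independent given the latent
# fields and share the kernel, so log-densities sum over dimensions.
#
# Gradients are analytic. Writing K[i, j] as the 2-D prefix sum over the
# interval-pair term matrix A[q, p], the adjoint of A is the 2-D suffix sum
# of G = dL/dK, and dA/d(tau_p, sigma2_p) has closed form, so a full
# gradient costs the same order as the likelihood itself.

#' Construct a trajectory segment
#'
#' @param t Strictly increasing observation times (length n >= 2).
#' @param y n x 2 matrix of planar positions.
#' @param id Optional individual identifier.
#' @return A list of class `crwgp_segment` with fields `id`, `t`, `y`, `y0`
#'   (the first position) and `midpoints` (the n-1 straight-line midpoints of
#'   consecutive observed fixes, where spatial fields are evaluated).
#' @export
trajectory_segment <- function(t, y, id = NA) {
  .check_times(t)
  y <- as.matrix(y)
  if (nrow(y) != length(t) || ncol(y) != 2 || any(!is.finite(y))) {
    stop("'y' must be a finite n x 2 matrix matching 't'", call. = FALSE)
  }
  n <- length(t)
  structure(list(id = id, t = t, y = y, y0 = y[1, ],
                 midpoints = (y[-n, , drop = FALSE] +
                                y[-1, , drop = FALSE]) / 2),
            class = "crwgp_segment")
}

#' Log-likelihood of a trajectory segment
#'
#' Sum over the two coordinate dimensions of the multivariate normal
#' log-density with mean `y0` and covariance `K_NS + omega2 I`, `K_NS` from
#' [integrated_ou_cov()] at the given per-interval parameters. A jitter of
#' `1e-6` times the mean diagonal is added before factorisation because the
#' anchored kernel is singular at the first observation.
#'
#' @param seg A [trajectory_segment()].
#' @param tau,sigma2 Per-interval parameters (length n-1).
#' @param omega2 Observation-noise variance (> 0).
#' @return Scalar log-likelihood.
#' @export
segment_loglik <- function(seg, tau, sigma2, omega2) {
  .check_pos(omega2, "omega2")
  .segment_loglik_core(seg, log(tau), log(sigma2), omega2,
                       want_grad = FALSE)$loglik
}

# Core likelihood/gradient. g_tau, g_sig are LOG-scale per-interval values;
# returns gradients with respect to them and to log(omega2).
.segment_loglik_core <- function(seg, g_tau, g_sig, omega2,
                                 want_grad = TRUE) {
  t <- seg$t
  n <- length(t)
  tau <- link_positive(g_tau)
  s2 <- link_positive(g_sig)
  terms <- .iou_terms(t, tau, s2)
  A <- .iou_A(terms)
  K <- matrix(0, n, n)
  K[-1, -1] <- .prefix2(A)
  K <- (K + t(K)) / 2
  jit <- 1e-6 * mean(diag(K))
  Sig <- K + diag(omega2 + jit, n)
  Lc <- .chol_lower(Sig, jitter = jit)
  R <- seg$y - matrix(seg$y0, n, 2, byrow = TRUE)
  W <- forwardsolve(Lc, R)                       # L^-1 R, n x 2
  ll <- -0.5 * sum(W^2) - 2 * sum(log(diag(Lc))) - n * log(2 * pi)
  if (!want_grad) return(list(loglik = ll))

  alpha <- backsolve(t(Lc), W)                   # Sig^-1 R
  P <- chol2inv(t(Lc))                           # Sig^-1
  G <- 0.5 * tcrossprod(alpha) - P               # dL/dSigma (2 dims summed)
  dlog_omega2 <- omega2 * sum(diag(G))

  # the jitter is 1e-6 * mean(diag(K)) and so itself depends on the
  # parameters; its exact adjoint folds back into the diagonal of G
  G <- G + diag(1e-6 * sum(diag(G)) / n, n)

  # adjoint of the interval-pair matrix: B[q, p] = sum_{i > q, j > p} G[i, j]
  C <- apply(G, 2, function(col) rev(cumsum(rev(col))))
  D <- t(apply(C, 1, function(row) rev(cumsum(rev(row)))))
  B <- D[-1, -1, drop = FALSE]

  # single-slot derivatives of A[q, p] wrt tau_p and sigma2_p (columns);
  # diagonal double-counts naturally because tau_p occupies both slots there.
  tau_pq <- terms$tau_pq
  c_pq <- terms$c_pq
  Tfull <- terms$Tmat
  dT_dtau <- (terms$D1 * terms$E1 - terms$D2 * terms$E2 -
                terms$D3 * terms$E3 + terms$D4 * terms$E4) / tau_pq^2
  # same-interval Kronecker part lives only on the diagonal
  dly <- 2 * terms$dt / diag(tau_pq)
  Tdiag <- Tfull
  diag(Tdiag) <- diag(Tdiag) + dly
  dT_dtau_diag <- dT_dtau
  diag(dT_dtau_diag) <- diag(dT_dtau_diag) - dly / diag(tau_pq)

  dc_slot <- sweep(1 / terms$S2, 2, tau, "*") +
    matrix(1 / (2 * tau), nrow(c_pq), length(tau), byrow = TRUE)
  Dslot_tau <- c_pq * (dc_slot * Tdiag +
                         dT_dtau_diag * sweep(1 / (2 * tau_pq), 2, tau, "*"))
  grad_tau_nat <- 2 * colSums(B * Dslot_tau)
  Afull <- c_pq * Tdiag
  grad_s2_nat <- colSums(B * Afull) / s2

  # chain through the exponential link (clipped values have zero gradient)
  act_t <- as.numeric(g_tau > -20 & g_tau < 20)
  act_s <- as.numeric(g_sig > -20 & g_sig < 20)
  list(loglik = ll,
       d_g_tau = grad_tau_nat * tau * act_t,
       d_g_sig = grad_s2_nat * s2 * act_s,
       d_log_omega2 = dlog_omega2)
}

#' KL divergence of a whitened inducing-point posterior from its prior
#'
#' In whitened coordinates the prior is standard normal, so
#' `KL = 0.5 (||m||^2 + tr(S S') - m_dim - log det(S S'))`, which is zero
#' exactly when the posterior equals the prior (`m = 0`, `S = I`) and is
#' independent of the kernel hyperparameters.
#'
#' @param post A [latent_field_posterior()].
#' @return Non-negative scalar.
#' @export
kl_inducing <- function(post) {
  m <- post$whitened_mean
  S <- post$whitened_scale
  d <- diag(S)
  if (any(d <= 0)) stop("whitened scale must have positive diagonal",
                        call. = FALSE)
  0.5 * (sum(m^2) + sum(S^2) - length(m) - 2 * sum(log(d)))
}

# Internal: per-segment draw of log-scale field values given whitened noise.
#   g = mean0 + Aw (wm + S eps) + sqrt(rvar) * zeta
# The residual (Nystrom) term zeta carries the conditional uncertainty not
# captured by the inducing points; it does not depend on the variational
# parameters, so gradients flow only through the linear map.
.draw_field <- function(cond, post, eps, zeta) {
  u <- post$whitened_mean + post$whitened_scale %*% eps
  as.numeric(cond$mean0 + cond$Aw %*% u) + sqrt(cond$rvar) * zeta
}

#' Stochastic evidence lower bound
#'
#' Doubly stochastic minibatch estimate of the ELBO: the expected segment
#' log-likelihood is approximated by `n_mc` joint reparameterised draws of
#' both latent fields at the segment midpoints, summed over the batch,
#' rescaled by `total_segments / length(batch)`, minus the two inducing-point
#' KL terms.
#'
#' @param batch List of [trajectory_segment()]s.
#' @param post_tau,post_sig [latent_field_posterior()]s of the log-timescale
#'   and log-variance fields.
#' @param omega2 Observation-noise variance.
#' @param total_segments Total number of segments in the data set (the
#'   minibatch rescaling factor is `total_segments / length(batch)`).
#' @param n_mc Monte Carlo samples per segment (default 1).
#' @param covs Optional [covariate_stack()].
#' @return Scalar ELBO estimate; reproducible under a fixed RNG seed.
#' @export
elbo_estimate <- function(batch, post_tau, post_sig, omega2,
                          total_segments = length(batch), n_mc = 1,
                          covs = NULL) {
  stopifnot(length(batch) >= 1, n_mc >= 1)
  m <- nrow(post_tau$grid)
  ell <- 0
  for (seg in batch) {
    cond_t <- .field_conditioning(post_tau, seg$midpoints, covs)
    cond_s <- .field_conditioning(post_sig, seg$midpoints, covs)
    np <- nrow(seg$midpoints)
    acc <- 0
    for (k in seq_len(n_mc)) {
      g_t <- .draw_field(cond_t, post_tau, stats::rnorm(m), stats::rnorm(np))
      g_s <- .draw_field(cond_s, post_sig, stats::rnorm(m), stats::rnorm(np))
      acc <- acc + .segment_loglik_core(seg, g_t, g_s, omega2,
                                        want_grad = FALSE)$loglik
    }
    ell <- ell + acc / n_mc
  }
  (total_segments / length(batch)) * ell -
    kl_inducing(post_tau) - kl_inducing(post_sig)
}
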