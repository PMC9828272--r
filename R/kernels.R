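# Non-stationary integrated Ornstein-Uhlenbeck covariance construction.
#
# The velocity of a continuous-time correlated random walk is an OU process
# with local timescale tau (directional persistence) and local stationary
# variance sigma2 (speed). Positions are the time-integral of velocity, so the
# position covariance is the double integral of the velocity covariance.
# With parameters held constant within each between-fix interval, the double
# integral reduces to a sum of closed-form terms over interval pairs; local
# parameters from two intervals are combined with the Paciorek-Schervish
# blending rule, which keeps the kernel positive semi-definite.

.check_pos <- function(x, name) {
  if (!is.numeric(x) || any(!is.finite(x)) || any(x <= 0)) {
    stop(sprintf("'%s' must be finite and strictly positive", name),
         call. = FALSE)
  }
  invisible(x)
}

.check_times <- function(t) {
  if (!is.numeric(t) || length(t) < 2 || any(!is.finite(t))) {
    stop("'times' must be a finite numeric vector with n >= 2", call. = FALSE)
  }
  if (any(diff(t) <= 0)) {
    stop("'times' must be strictly increasing", call. = FALSE)
  }
  invisible(t)
}

#' Non-stationary exponential velocity covariance
#'
#' Covariance between velocities at two time points whose local OU parameters
#' differ, using the Paciorek-Schervish construction: the two local
#' (timescale, variance) pairs are blended into a single pair and plugged into
#' the stationary exponential kernel.
#'
#' @param tau_s,tau_t Local velocity-autocorrelation timescales (time units).
#' @param sigma2_s,sigma2_t Local stationary velocity variances
#'   (distance^2/time^2).
#' @param lag Non-negative time separation.
#' @return Covariance value. Symmetric in the two local parameter sets; when
#'   the parameters agree it reduces to `sigma2 * exp(-lag/tau)`.
#' @seealso [pairwise_blend()] for the blended parameters themselves.
#' @export
#' @examples
#' nonstationary_velocity_cov(2, 2, 3, 3, lag = 2) # 3 * exp(-1)
nonstationary_velocity_cov <- function(tau_s, tau_t, sigma2_s, sigma2_t, lag) {
  .check_pos(tau_s, "tau_s"); .check_pos(tau_t, "tau_t")
  .check_pos(sigma2_s, "sigma2_s"); .check_pos(sigma2_t, "sigma2_t")
  if (any(lag < 0)) stop("'lag' must be non-negative", call. = FALSE)
  b <- pairwise_blend(tau_s, tau_t, sigma2_s, sigma2_t)
  b$sigma2 * exp(-lag / b$tau)
}

#' Blend two local OU parameter sets
#'
#' Combines the per-interval parameters of two between-fix intervals into the
#' single (timescale, variance) pair used by the non-stationary kernel:
#' `tau_pq = sqrt((tau_p^2 + tau_q^2)/2)` and
#' `sigma2_pq = sqrt(sigma2_p * sigma2_q) * sqrt(2 tau_p tau_q / (tau_p^2 + tau_q^2))`.
#'
#' @param tau_p,tau_q Positive timescales.
#' @param sigma2_p,sigma2_q Positive velocity variances.
#' @return A list with elements `tau` and `sigma2`. The operation is symmetric
#'   in p and q and is the identity when the two parameter sets agree.
#' @export
pairwise_blend <- function(tau_p, tau_q, sigma2_p, sigma2_q) {
  .check_pos(tau_p, "tau_p"); .check_pos(tau_q, "tau_q")
  .check_pos(sigma2_p, "sigma2_p"); .check_pos(sigma2_q, "sigma2_q")
  s2 <- tau_p^2 + tau_q^2
  list(tau = sqrt(s2 / 2),
       sigma2 = sqrt(sigma2_p * sigma2_q) * sqrt(2 * tau_p * tau_q / s2))
}

# Internal: shared terms of the interval-pair decomposition.
# Returns, for intervals indexed [q, p] (rows q, columns p):
#   c_pq   = sigma2_pq * tau_pq^2  (prefactor)
#   Tmat   = bracket term WITHOUT the same-interval Kronecker part
#   tau_pq = blended timescale matrix
#   plus the |time difference| matrices and their exponentials, needed for
#   analytic gradients.
.iou_terms <- function(t, tau, sigma2) {
  n <- length(t)
  tp <- t[-n]      # interval start times t_p
  tp1 <- t[-1]     # interval end times t_{p+1}
  tau2 <- tau^2
  S2 <- outer(tau2, tau2, "+")            # tau_q^2 + tau_p^2
  tau_pq <- sqrt(S2 / 2)
  sig2_pq <- sqrt(outer(sigma2, sigma2)) * sqrt(2 * outer(tau, tau) / S2)
  c_pq <- sig2_pq * tau_pq^2
  # D*[q, p]: absolute time differences entering the bracket of the
  # interval-pair term; rows follow q, columns follow p.
  D1 <- abs(outer(tp1, tp, function(a, b) b - a))    # |t_p     - t_{q+1}|
  D2 <- abs(outer(tp1, tp1, function(a, b) b - a))   # |t_{p+1} - t_{q+1}|
  D3 <- abs(outer(tp, tp, function(a, b) b - a))     # |t_p     - t_q|
  D4 <- abs(outer(tp, tp1, function(a, b) b - a))    # |t_{p+1} - t_q|
  E1 <- exp(-D1 / tau_pq); E2 <- exp(-D2 / tau_pq)
  E3 <- exp(-D3 / tau_pq); E4 <- exp(-D4 / tau_pq)
  # evaluate via expm1: the +1 terms cancel exactly (two plus, two minus),
  # and the remaining first-order cancellation is then benign, which keeps
  # c_pq * Tmat accurate when tau_pq is much larger than the time spans
  Tmat <- expm1(-D1 / tau_pq) - expm1(-D2 / tau_pq) -
    expm1(-D3 / tau_pq) + expm1(-D4 / tau_pq)
  dt <- tp1 - tp
  list(n = n, dt = dt, S2 = S2, tau_pq = tau_pq, c_pq = c_pq, Tmat = Tmat,
       D1 = D1, D2 = D2, D3 = D3, D4 = D4,
       E1 = E1, E2 = E2, E3 = E3, E4 = E4)
}

# Internal: interval-pair term matrix A[q, p]; Cov(f_i, f_j) is the 2-D
# prefix sum of A over q < i, p < j.
.iou_A <- function(terms) {
  A <- terms$c_pq * terms$Tmat
  diag(A) <- diag(A) + diag(terms$c_pq) * 2 * terms$dt / diag(terms$tau_pq)
  A
}

.prefix2 <- function(A) {
  # 2-D cumulative sum; input is symmetric so no transpose bookkeeping needed
  if (nrow(A) == 1L) return(A)
  B <- apply(A, 2, cumsum)
  t(apply(B, 1, cumsum))
}

#' Position covariance of the non-stationary integrated OU process
#'
#' Builds the n x n covariance matrix of positions observed at `times` for a
#' correlated velocity model whose timescale and variance are constant within
#' each between-fix interval (evaluated at straight-line midpoints) but vary
#' between intervals. The process is anchored at the first observation, so the
#' first row and column are identically zero.
#'
#' @param times Strictly increasing numeric vector of n observation times.
#' @param tau Vector of n-1 positive per-interval timescales.
#' @param sigma2 Vector of n-1 positive per-interval velocity variances.
#' @return An n x n symmetric positive semi-definite matrix (distance^2
#'   units), first row/column zero.
#' @export
#' @examples
#' integrated_ou_cov(c(0, 1), tau = 1, sigma2 = 1) # Var = 2 * exp(-1)
integrated_ou_cov <- function(times, tau, sigma2) {
  .check_times(times)
  n <- length(times)
  if (length(tau) != n - 1 || length(sigma2) != n - 1) {
    stop("'tau' and 'sigma2' must have length n - 1", call. = FALSE)
  }
  .check_pos(tau, "tau"); .check_pos(sigma2, "sigma2")
  A <- .iou_A(.iou_terms(times, tau, sigma2))
  K <- matrix(0, n, n)
  K[-1, -1] <- .prefix2(A)
  # exact symmetry (prefix sums accumulate in different orders)
  (K + t(K)) / 2
}

#' Stationary integrated OU position covariance (closed form)
#'
#' Analytic covariance of an integrated OU position process with constant
#' parameters, anchored at the first observation:
#' `Cov(f_i, f_j) = sigma2 * tau * (2 s + tau * (exp(-s/tau) - 1 - exp(-(r-s)/tau) + exp(-r/tau)))`
#' with `s <= r` the elapsed times since the first observation. Serves as an
#' independent check of the interval-sum construction in the
#' constant-parameter limit.
#'
#' @inheritParams integrated_ou_cov
#' @param tau,sigma2 Scalar positive parameters.
#' @return An n x n covariance matrix.
#' @export
stationary_iou_cov <- function(times, tau, sigma2) {
  .check_times(times)
  .check_pos(tau, "tau"); .check_pos(sigma2, "sigma2")
  if (length(tau) != 1L || length(sigma2) != 1L) {
    stop("'tau' and 'sigma2' must be scalar", call. = FALSE)
  }
  s <- times - times[1]
  lo <- outer(s, s, pmin)
  hi <- outer(s, s, pmax)
  sigma2 * tau * (2 * lo + tau * (exp(-lo / tau) - 1 -
                                    exp(-(hi - lo) / tau) + exp(-hi / tau)))
}

#' Brute-force quadrature oracle for the position covariance
#'
#' Evaluates each entry of the position covariance by adaptive numerical
#' double integration of the blended piecewise-constant velocity covariance,
#' interval pair by interval pair, splitting the inner integral at the
#' diagonal kink. Intended as an independent numerical check of
#' [integrated_ou_cov()] at small n; it is orders of magnitude slower.
#'
#' @inheritParams integrated_ou_cov
#' @param rel_tol Relative tolerance passed to [stats::integrate()].
#' @return An n x n covariance matrix.
#' @export
quadrature_oracle <- function(times, tau, sigma2, rel_tol = 1e-9) {
  .check_times(times)
  n <- length(times)
  if (n > 10) stop("quadrature oracle is limited to n <= 10", call. = FALSE)
  if (length(tau) != n - 1 || length(sigma2) != n - 1) {
    stop("'tau' and 'sigma2' must have length n - 1", call. = FALSE)
  }
  .check_pos(tau, "tau"); .check_pos(sigma2, "sigma2")

  pair_integral <- function(lo_u, hi_u, lo_r, hi_r, tau_pq, sig2_pq) {
    inner <- function(r) {
      vapply(r, function(rr) {
        g <- function(u) exp(-abs(rr - u) / tau_pq)
        if (rr > lo_u && rr < hi_u) {
          stats::integrate(g, lo_u, rr, rel.tol = rel_tol)$value +
            stats::integrate(g, rr, hi_u, rel.tol = rel_tol)$value
        } else {
          stats::integrate(g, lo_u, hi_u, rel.tol = rel_tol)$value
        }
      }, 0)
    }
    sig2_pq * stats::integrate(inner, lo_r, hi_r, rel.tol = rel_tol,
                               subdivisions = 200L)$value
  }

  K <- matrix(0, n, n)
  for (i in 2:n) {
    for (j in i:n) {
      v <- 0
      for (q in seq_len(i - 1)) {
        for (p in seq_len(j - 1)) {
          b <- pairwise_blend(tau[p], tau[q], sigma2[p], sigma2[q])
          v <- v + pair_integral(times[q], times[q + 1],
                                 times[p], times[p + 1], b$tau, b$sigma2)
        }
      }
      K[i, j] <- v
      K[j, i] <- v
    }
  }
  K
}
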