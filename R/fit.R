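# Model fitting: trajectory segmentation, the stochastic variational
# training loop (Adam with analytic gradients), early stopping, posterior
# field prediction, and covariate-effect summaries.

#' Split trajectories into equal-length segments
#'
#' Each individual's trajectory is cut into consecutive non-overlapping
#' segments of exactly `segment_length` observations, treated downstream as
#' conditionally independent given the latent fields. A final remainder is
#' kept if it has at least `max(2, segment_length/5)` observations and is
#' dropped otherwise, so almost all data are retained while segments stay
#' essentially equal-sized.
#'
#' @param trajectories List of per-individual `data.frame`s with columns
#'   `time`, `x`, `y` (and optionally `id`), or one `data.frame` with an
#'   `id` column.
#' @param segment_length Target observations per segment (>= 2).
#' @return A list of [trajectory_segment()]s.
#' @export
segment_trajectories <- function(trajectories, segment_length = 500) {
  if (segment_length < 2) stop("'segment_length' must be >= 2",
                               call. = FALSE)
  trajs <- .as_traj_list(trajectories)
  out <- list()
  for (nm in names(trajs)) {
    tr <- trajs[[nm]]
    n <- nrow(tr)
    if (n < 2) next
    n_full <- n %/% segment_length
    starts <- if (n_full > 0) (0:(n_full - 1)) * segment_length + 1 else
      integer(0)
    ends <- starts + segment_length - 1
    rem <- n - n_full * segment_length
    if (rem >= max(2, segment_length / 5)) {
      starts <- c(starts, n_full * segment_length + 1)
      ends <- c(ends, n)
    }
    for (k in seq_along(starts)) {
      idx <- starts[k]:ends[k]
      out[[length(out) + 1L]] <- trajectory_segment(
        t = tr$time[idx], y = cbind(tr$x[idx], tr$y[idx]), id = nm)
    }
  }
  out
}

.as_traj_list <- function(trajectories) {
  if (is.data.frame(trajectories)) {
    if (!"id" %in% names(trajectories)) trajectories$id <- 1
    ids <- unique(trajectories$id)
    trajs <- lapply(ids, function(i) {
      tr <- trajectories[trajectories$id == i, , drop = FALSE]
      tr[order(tr$time), , drop = FALSE]
    })
    names(trajs) <- as.character(ids)
    return(trajs)
  }
  if (!is.list(trajectories) || !length(trajectories)) return(list())
  if (is.null(names(trajectories))) {
    names(trajectories) <- as.character(seq_along(trajectories))
  }
  trajectories
}

#' Fitting configuration
#'
#' @param segment_length Observations per trajectory segment.
#' @param batch_size Trajectory segments per stochastic-gradient step.
#' @param learning_rate Adam learning rate.
#' @param max_epochs Maximum passes through the segment set.
#' @param patience Early-stopping patience: training halts when the
#'   epoch-mean loss has not decreased over this many epochs.
#' @param n_mc Monte Carlo draws of the latent fields per segment and step.
#' @param seed Integer seed; all randomness in [crwgp()] flows from it.
#' @param grid_nx,grid_ny Inducing-grid resolution.
#' @param grid_expand Fractional expansion of the data bounding box used for
#'   the default inducing grid.
#' @param amplitude,lengthscale Kernel hyperparameters of both latent-field
#'   priors (held fixed during optimisation; see the package vignette).
#' @param omega2 If non-`NULL`, the observation-noise variance is fixed at
#'   this value; otherwise it is learned (log-parameterised).
#' @param clip_norm Global gradient-norm ceiling per optimisation step;
#'   occasional extreme reparameterised draws otherwise produce gradient
#'   spikes that can destabilise long runs.
#' @param q_diag Use a diagonal (mean-field) whitened variational scale
#'   instead of a full lower-triangular one; far fewer parameters and much
#'   lower gradient noise, at the cost of ignoring posterior correlations
#'   between inducing values.
#' @return A list of class `crwgp_config`.
#' @export
crwgp_config <- function(segment_length = 500, batch_size = 4,
                         learning_rate = 0.01, max_epochs = 100,
                         patience = 5, n_mc = 1, seed = 1,
                         grid_nx = 15, grid_ny = 15, grid_expand = 0.05,
                         amplitude = 1, lengthscale = 1, omega2 = NULL,
                         clip_norm = 5000, q_diag = TRUE) {
  cfg <- as.list(environment())
  stopifnot(cfg$segment_length >= 2, cfg$batch_size >= 1,
            cfg$learning_rate > 0, cfg$max_epochs >= 1, cfg$patience >= 1,
            cfg$n_mc >= 1, cfg$grid_nx >= 2, cfg$grid_ny >= 2)
  class(cfg) <- "crwgp_config"
  cfg
}

# Early-stopping rule: TRUE once the minimum of the last `patience` epoch
# losses is no lower than the minimum of all earlier epochs, i.e. the loss
# has not decreased over `patience` epochs.
.early_stop <- function(losses, patience) {
  n <- length(losses)
  if (n <= patience) return(FALSE)
  min(losses[(n - patience + 1):n]) >= min(losses[1:(n - patience)])
}

.make_S <- function(Tr) {
  S <- Tr
  diag(S) <- exp(diag(Tr))
  S[upper.tri(S)] <- 0
  S
}

.adam_step <- function(state, grads, lr, b1 = 0.9, b2 = 0.999, eps = 1e-8) {
  state$t <- state$t + 1
  for (nm in names(grads)) {
    g <- grads[[nm]]
    state$m[[nm]] <- b1 * state$m[[nm]] + (1 - b1) * g
    state$v[[nm]] <- b2 * state$v[[nm]] + (1 - b2) * g^2
    mhat <- state$m[[nm]] / (1 - b1^state$t)
    vhat <- state$v[[nm]] / (1 - b2^state$t)
    state$par[[nm]] <- state$par[[nm]] - lr * mhat / (sqrt(vhat) + eps)
  }
  state
}

.zeros_like <- function(par) lapply(par, function(x) x * 0)

#' Fit the hierarchical movement model
#'
#' Fits the two-layer Gaussian process model: a non-stationary integrated
#' Ornstein-Uhlenbeck likelihood for each trajectory segment, whose
#' per-interval persistence timescale and velocity variance come from two
#' latent spatial fields with sparse whitened variational posteriors on an
#' inducing grid. The negative evidence lower bound is minimised by Adam
#' with minibatches of segments, reshuffled every epoch, and training halts
#' early once the epoch-mean loss has not decreased over `patience` epochs.
#'
#' @param trajectories Trajectories as accepted by [segment_trajectories()]
#'   (e.g. the `obs` element of [simulate_crw()] or the output of
#'   [read_trajectories()]).
#' @param covariates Optional [covariate_stack()]; adds linear covariate
#'   terms (with mean-field Gaussian posteriors over the coefficients) to
#'   the latent-field means.
#' @param kernel Lower-layer kernel: `"rbf"` for open landscapes,
#'   `"periodic"` for environments that tile with period `period`.
#' @param period Domain length for the periodic kernel.
#' @param config A [crwgp_config()].
#' @param domain Optional list with `xlim`, `ylim` for the inducing grid
#'   (default: data bounding box expanded by `grid_expand`).
#' @param verbose Print the loss once per epoch.
#' @return An object of class `crwgp` with the two fitted
#'   [latent_field_posterior()]s (`post_tau`, `post_sig`), the noise
#'   variance `omega2`, the per-epoch `loss_trace`, the inducing `grid`, and
#'   the resolved `config`. Methods: [print.crwgp()], [summary.crwgp()],
#'   [coef.crwgp()], [predict.crwgp()], [plot.crwgp()].
#' @export
crwgp <- function(trajectories, covariates = NULL,
                  kernel = c("rbf", "periodic"), period = NULL,
                  config = crwgp_config(), domain = NULL, verbose = FALSE) {
  kernel <- match.arg(kernel)
  stopifnot(inherits(config, "crwgp_config"))
  set.seed(config$seed)
  t_start <- proc.time()[["elapsed"]]

  segments <- segment_trajectories(trajectories, config$segment_length)
  nseg <- length(segments)
  if (nseg < 1) stop("no usable trajectory segments", call. = FALSE)

  allxy <- do.call(rbind, lapply(segments, function(s) s$y))
  if (is.null(domain)) {
    ex <- config$grid_expand
    rx <- range(allxy[, 1]); ry <- range(allxy[, 2])
    domain <- list(xlim = rx + c(-1, 1) * ex * diff(rx),
                   ylim = ry + c(-1, 1) * ex * diff(ry))
  }
  grid <- inducing_grid(domain$xlim, domain$ylim, config$grid_nx,
                        config$grid_ny)
  m <- nrow(grid)
  hyper <- field_hyper(mu = 0, amplitude = config$amplitude,
                       lengthscale = config$lengthscale, kernel = kernel,
                       period = period)
  proto <- latent_field_posterior(grid, hyper)   # shared prior factor

  nk <- if (is.null(covariates)) 0L else length(covariates$rasters)
  # per-segment conditioning is constant (hyperparameters fixed): cache it
  cache <- lapply(segments, function(seg) {
    cond <- .field_conditioning(proto, seg$midpoints, covs = NULL)
    list(Aw = cond$Aw, rvar = cond$rvar, rsd = sqrt(cond$rvar),
         E = if (nk) covariate_lookup(covariates, seg$midpoints) else NULL,
         np = nrow(seg$midpoints))
  })

  # observation-noise initialisation: a few percent of the mean squared
  # between-fix displacement (learned unless fixed in the config)
  msd <- mean(unlist(lapply(segments, function(s) diff(s$y[, 1])^2 +
                              diff(s$y[, 2])^2))) / 2
  fix_om <- !is.null(config$omega2)
  om2_0 <- if (fix_om) config$omega2 else 0.05 * msd

  # warm start for the field means from crude whole-data moments: the
  # empirical variance and lag-1 autocorrelation of the finite-difference
  # velocities give order-of-magnitude estimates of sigma2 and tau
  vhat <- lapply(segments, function(s) {
    dt <- diff(s$t)
    cbind(diff(s$y[, 1]) / dt, diff(s$y[, 2]) / dt)
  })
  V <- do.call(rbind, vhat)
  s2_hat <- max(mean(apply(V, 2, stats::var)), 1e-12)
  rho1 <- mean(vapply(vhat, function(v) {
    n <- nrow(v)
    if (n < 3) return(NA_real_)
    mean(v[-1, ] * v[-n, ]) / mean(v^2)
  }, 0), na.rm = TRUE)
  dt_med <- stats::median(unlist(lapply(segments, function(s) diff(s$t))))
  tau_hat <- if (is.finite(rho1) && rho1 > 0.05 && rho1 < 1) {
    -dt_med / log(rho1)
  } else {
    dt_med
  }
  clip3 <- function(x) min(max(x, -3), 3)

  par <- list(wm_t = rep(0, m), Tr_t = matrix(0, m, m),
              wm_s = rep(0, m), Tr_s = matrix(0, m, m),
              mu_t = clip3(log(tau_hat)), mu_s = clip3(log(s2_hat)),
              log_om = log(om2_0))
  if (nk) {
    par$bm_t <- rep(0, nk); par$bls_t <- rep(log(0.1), nk)
    par$bm_s <- rep(0, nk); par$bls_s <- rep(log(0.1), nk)
  }
  adam <- list(par = par, m = .zeros_like(par), v = .zeros_like(par), t = 0)

  kl_whitened <- function(wm, S) {
    0.5 * (sum(wm^2) + sum(S^2) - m - 2 * sum(log(diag(S))))
  }
  kl_beta <- function(bm, bsd) sum(0.5 * (bm^2 + bsd^2 - 1) - log(bsd))

  losses <- numeric(0)
  for (epoch in seq_len(config$max_epochs)) {
    ord <- sample.int(nseg)
    iter_losses <- numeric(0)
    for (b0 in seq(1, nseg, by = config$batch_size)) {
      idx <- ord[b0:min(b0 + config$batch_size - 1, nseg)]
      sf <- nseg / length(idx)
      p <- adam$par
      S_t <- .make_S(p$Tr_t); S_s <- .make_S(p$Tr_s)
      om2 <- exp(p$log_om)
      bsd_t <- if (nk) exp(p$bls_t) else NULL
      bsd_s <- if (nk) exp(p$bls_s) else NULL

      g <- .zeros_like(p)
      ll_sum <- 0
      for (si in idx) {
        seg <- segments[[si]]
        ca <- cache[[si]]
        for (k in seq_len(config$n_mc)) {
          eps_t <- stats::rnorm(m); eps_s <- stats::rnorm(m)
          zt <- stats::rnorm(ca$np); zs <- stats::rnorm(ca$np)
          bt <- bs <- NULL
          mean_t <- p$mu_t; mean_s <- p$mu_s
          if (nk) {
            eb_t <- stats::rnorm(nk); eb_s <- stats::rnorm(nk)
            bt <- p$bm_t + bsd_t * eb_t
            bs <- p$bm_s + bsd_s * eb_s
            mean_t <- mean_t + as.numeric(ca$E %*% bt)
            mean_s <- mean_s + as.numeric(ca$E %*% bs)
          }
          u_t <- p$wm_t + as.numeric(S_t %*% eps_t)
          u_s <- p$wm_s + as.numeric(S_s %*% eps_s)
          g_t <- mean_t + as.numeric(ca$Aw %*% u_t) + ca$rsd * zt
          g_s <- mean_s + as.numeric(ca$Aw %*% u_s) + ca$rsd * zs
          core <- .segment_loglik_core(seg, g_t, g_s, om2)
          w <- sf / config$n_mc
          ll_sum <- ll_sum + core$loglik / config$n_mc
          at <- as.numeric(crossprod(ca$Aw, core$d_g_tau))   # Aw' dg
          as_ <- as.numeric(crossprod(ca$Aw, core$d_g_sig))
          g$wm_t <- g$wm_t - w * at
          g$wm_s <- g$wm_s - w * as_
          g$Tr_t <- g$Tr_t - w * tcrossprod(at, eps_t)
          g$Tr_s <- g$Tr_s - w * tcrossprod(as_, eps_s)
          g$mu_t <- g$mu_t - w * sum(core$d_g_tau)
          g$mu_s <- g$mu_s - w * sum(core$d_g_sig)
          if (!fix_om) g$log_om <- g$log_om - w * core$d_log_omega2
          if (nk) {
            et <- as.numeric(crossprod(ca$E, core$d_g_tau))
            es <- as.numeric(crossprod(ca$E, core$d_g_sig))
            g$bm_t <- g$bm_t - w * et
            g$bm_s <- g$bm_s - w * es
            g$bls_t <- g$bls_t - w * et * bsd_t * eb_t
            g$bls_s <- g$bls_s - w * es * bsd_s * eb_s
          }
        }
      }
      # chain the likelihood dS diagonal to the log-diagonal parameterisation
      diag(g$Tr_t) <- diag(g$Tr_t) * diag(S_t)
      diag(g$Tr_s) <- diag(g$Tr_s) * diag(S_s)
      g$Tr_t[upper.tri(g$Tr_t)] <- 0
      g$Tr_s[upper.tri(g$Tr_s)] <- 0
      # KL gradients (already in log-diagonal coordinates)
      g$wm_t <- g$wm_t + p$wm_t
      g$wm_s <- g$wm_s + p$wm_s
      dTr_t <- S_t; diag(dTr_t) <- diag(S_t)^2 - 1
      dTr_s <- S_s; diag(dTr_s) <- diag(S_s)^2 - 1
      dTr_t[upper.tri(dTr_t)] <- 0
      dTr_s[upper.tri(dTr_s)] <- 0
      g$Tr_t <- g$Tr_t + dTr_t
      g$Tr_s <- g$Tr_s + dTr_s
      if (config$q_diag) {
        # mean-field scale: only the (log-)diagonal is free
        g$Tr_t[lower.tri(g$Tr_t)] <- 0
        g$Tr_s[lower.tri(g$Tr_s)] <- 0
      }
      kl <- kl_whitened(p$wm_t, S_t) + kl_whitened(p$wm_s, S_s)
      if (nk) kl <- kl + kl_beta(p$bm_t, bsd_t) + kl_beta(p$bm_s, bsd_s)
      if (nk) {
        g$bm_t <- g$bm_t + p$bm_t
        g$bm_s <- g$bm_s + p$bm_s
        g$bls_t <- g$bls_t + (bsd_t^2 - 1)
        g$bls_s <- g$bls_s + (bsd_s^2 - 1)
      }
      loss <- -(sf * ll_sum) + kl
      if (!is.finite(loss)) {
        stop("training loss became non-finite at epoch ", epoch,
             "; consider a smaller learning rate", call. = FALSE)
      }
      gn <- sqrt(sum(vapply(g, function(x) sum(x^2), 0)))
      if (is.finite(gn) && gn > config$clip_norm) {
        g <- lapply(g, function(x) x * (config$clip_norm / gn))
      }
      adam <- .adam_step(adam, g, config$learning_rate)
      iter_losses <- c(iter_losses, loss)
    }
    losses <- c(losses, mean(iter_losses))
    if (verbose) {
      message(sprintf("epoch %3d  loss %.3f", epoch, losses[epoch]))
    }
    if (.early_stop(losses, config$patience)) break
  }

  p <- adam$par
  hyper_t <- field_hyper(mu = p$mu_t,
                         beta = if (nk) p$bm_t else numeric(0),
                         amplitude = config$amplitude,
                         lengthscale = config$lengthscale,
                         kernel = kernel, period = period)
  hyper_s <- field_hyper(mu = p$mu_s,
                         beta = if (nk) p$bm_s else numeric(0),
                         amplitude = config$amplitude,
                         lengthscale = config$lengthscale,
                         kernel = kernel, period = period)
  post_tau <- latent_field_posterior(grid, hyper_t, p$wm_t, .make_S(p$Tr_t))
  post_sig <- latent_field_posterior(grid, hyper_s, p$wm_s, .make_S(p$Tr_s))
  beta_post <- if (nk) {
    list(tau = list(mean = p$bm_t, sd = exp(p$bls_t)),
         sig = list(mean = p$bm_s, sd = exp(p$bls_s)))
  } else NULL

  structure(list(post_tau = post_tau, post_sig = post_sig,
                 omega2 = if (fix_om) config$omega2 else exp(p$log_om),
                 beta_post = beta_post,
                 covariates = covariates, grid = grid, domain = domain,
                 loss_trace = losses, n_segments = nseg,
                 n_obs = nrow(allxy), config = config,
                 elapsed = proc.time()[["elapsed"]] - t_start,
                 call = match.call()),
            class = "crwgp")
}

#' Posterior field maps over a grid
#'
#' Monte Carlo summaries of the movement parameters at each grid location:
#' directional persistence `tau = exp(g_tau)` and the speed scale derived
#' from the velocity variance `sigma2 = exp(g_sig)`. Reported speed is
#' `sigma * sqrt(pi/2)`, the mean speed of a two-dimensional isotropic
#' Gaussian velocity with per-axis standard deviation `sigma`; raw `sigma`
#' is also exported.
#'
#' @param post_tau,post_sig Fitted [latent_field_posterior()]s.
#' @param grid Locations (matrix with two columns).
#' @param covs Optional [covariate_stack()].
#' @param n_samples Monte Carlo draws per location.
#' @param ci_levels Credible-interval levels (possibly empty).
#' @param seed Seed making the Monte Carlo summaries reproducible.
#' @return A `data.frame` of class `crwgp_maps` with columns `x`, `y`,
#'   `persistence_mean/sd`, `speed_mean/sd`, `sigma_mean/sd`, and per level
#'   `persistence_lo_XX/hi_XX`, `speed_lo_XX/hi_XX`.
#' @export
predict_fields <- function(post_tau, post_sig, grid, covs = NULL,
                           n_samples = 2000, ci_levels = c(0.5, 0.9),
                           seed = 1) {
  grid <- .as_locations(grid)
  set.seed(seed)
  cm_t <- conditional_marginals(post_tau, grid, covs)
  cm_s <- conditional_marginals(post_sig, grid, covs)
  samp_t <- link_positive(sample_field_values(post_tau, grid, covs,
                                              n_samples))
  samp_s2 <- link_positive(sample_field_values(post_sig, grid, covs,
                                               n_samples))
  sig <- sqrt(samp_s2)
  speed <- sig * sqrt(pi / 2)
  out <- data.frame(x = grid[, 1], y = grid[, 2],
                    persistence_mean = colMeans(samp_t),
                    persistence_sd = apply(samp_t, 2, stats::sd),
                    speed_mean = colMeans(speed),
                    speed_sd = apply(speed, 2, stats::sd),
                    sigma_mean = colMeans(sig),
                    sigma_sd = apply(sig, 2, stats::sd),
                    log_tau_mean = cm_t$mean, log_tau_sd = sqrt(cm_t$var),
                    log_sigma2_mean = cm_s$mean,
                    log_sigma2_sd = sqrt(cm_s$var))
  for (lv in ci_levels) {
    a <- (1 - lv) / 2
    tag <- sprintf("%02d", round(100 * lv))
    out[[paste0("persistence_lo_", tag)]] <- apply(samp_t, 2,
                                                   stats::quantile, a)
    out[[paste0("persistence_hi_", tag)]] <- apply(samp_t, 2,
                                                   stats::quantile, 1 - a)
    out[[paste0("speed_lo_", tag)]] <- apply(speed, 2, stats::quantile, a)
    out[[paste0("speed_hi_", tag)]] <- apply(speed, 2, stats::quantile,
                                             1 - a)
  }
  class(out) <- c("crwgp_maps", "data.frame")
  out
}

#' Predict method for fitted movement models
#'
#' @param object A fitted [crwgp()] model.
#' @param grid Locations at which to evaluate the fields (default: the
#'   model's inducing grid).
#' @param n_samples,ci_levels,seed Passed to [predict_fields()].
#' @param ... Unused.
#' @return A `crwgp_maps` data frame; see [predict_fields()].
#' @export
predict.crwgp <- function(object, grid = NULL, n_samples = 2000,
                          ci_levels = c(0.5, 0.9), seed = 1, ...) {
  if (is.null(grid)) grid <- object$grid
  predict_fields(object$post_tau, object$post_sig, grid,
                 covs = object$covariates, n_samples = n_samples,
                 ci_levels = ci_levels, seed = seed)
}

#' Covariate response curves
#'
#' For each covariate, the natural-scale response of a movement parameter to
#' the covariate through the latent-field mean: `exp(mu + beta * e)` over a
#' grid of standardised covariate values, with credible bands from the
#' mean-field posterior over `beta`. The model intercept is `exp(mu)`.
#'
#' @param object A fitted [crwgp()] model trained with covariates.
#' @param field `"persistence"` (timescale field) or `"variance"` (velocity
#'   variance field).
#' @param n_points Number of covariate values per curve.
#' @param range_sd Curves span `+/- range_sd` standard deviations of each
#'   covariate.
#' @param level Credible level for the bands.
#' @param n_samples Posterior draws of `beta`.
#' @param seed Seed for the posterior draws.
#' @return A `data.frame` with columns `covariate`, `value` (original
#'   units), `response`, `lo`, `hi`, with the intercept `exp(mu)` in
#'   attribute `"intercept"`.
#' @export
covariate_effects <- function(object, field = c("persistence", "variance"),
                              n_points = 50, range_sd = 2, level = 0.9,
                              n_samples = 4000, seed = 1) {
  field <- match.arg(field)
  if (is.null(object$beta_post)) {
    stop("model was fitted without covariates", call. = FALSE)
  }
  set.seed(seed)
  bp <- if (field == "persistence") object$beta_post$tau else
    object$beta_post$sig
  mu <- if (field == "persistence") object$post_tau$hyper$mu else
    object$post_sig$hyper$mu
  covs <- object$covariates
  a <- (1 - level) / 2
  out <- list()
  for (j in seq_along(covs$rasters)) {
    nm <- names(covs$rasters)[j]
    st <- covs$stats[[nm]]
    e_std <- seq(-range_sd, range_sd, length.out = n_points)
    bsamp <- stats::rnorm(n_samples, bp$mean[j], bp$sd[j])
    resp <- exp(mu + outer(bsamp, e_std))     # n_samples x n_points
    out[[nm]] <- data.frame(
      covariate = nm,
      value = st$mean + st$sd * e_std,
      response = colMeans(resp),
      lo = apply(resp, 2, stats::quantile, a),
      hi = apply(resp, 2, stats::quantile, 1 - a))
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  attr(res, "intercept") <- exp(mu)
  res
}
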