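# S3 methods for fitted models and field maps.

#' @export
print.crwgp <- function(x, ...) {
  cat("Hierarchical continuous-time movement model (non-stationary",
      "integrated OU)\n")
  cat(sprintf("  %d observations in %d segments; inducing grid %d x %d\n",
              x$n_obs, x$n_segments, attr(x$grid, "dim_grid")[1],
              attr(x$grid, "dim_grid")[2]))
  cat(sprintf("  lower-layer kernel: %s (amplitude %.3g, lengthscale %.3g)\n",
              x$post_tau$hyper$kernel, x$post_tau$hyper$amplitude,
              x$post_tau$hyper$lengthscale))
  cat(sprintf("  epochs run: %d, final loss %.3f\n",
              length(x$loss_trace), utils::tail(x$loss_trace, 1)))
  cat(sprintf("  observation noise sd: %.4g\n", sqrt(x$omega2)))
  invisible(x)
}

#' @export
summary.crwgp <- function(object, ...) {
  maps <- predict.crwgp(object, n_samples = 500, ci_levels = numeric(0))
  out <- list(
    n_obs = object$n_obs, n_segments = object$n_segments,
    epochs = length(object$loss_trace),
    final_loss = utils::tail(object$loss_trace, 1),
    omega = sqrt(object$omega2),
    persistence = summary(maps$persistence_mean),
    speed = summary(maps$speed_mean),
    coef = coef.crwgp(object))
  class(out) <- "summary.crwgp"
  out
}

#' @export
print.summary.crwgp <- function(x, ...) {
  cat(sprintf("Fitted on %d observations (%d segments), %d epochs, final",
              x$n_obs, x$n_segments, x$epochs),
      sprintf("loss %.3f\n", x$final_loss))
  cat("Posterior-mean directional persistence over the grid:\n")
  print(x$persistence)
  cat("Posterior-mean speed over the grid:\n")
  print(x$speed)
  cat("Coefficients:\n")
  print(x$coef)
  invisible(x)
}

#' Coefficients of a fitted movement model
#'
#' Returns the scalar parameters: the latent-field prior means on the log
#' scale (`mu_log_tau`, `mu_log_sigma2`), the observation-noise variance
#' `omega2`, and any covariate coefficients (per covariate standard
#' deviation, posterior means).
#'
#' @param object A fitted [crwgp()] model.
#' @param ... Unused.
#' @return Named numeric vector.
#' @export
coef.crwgp <- function(object, ...) {
  out <- c(mu_log_tau = object$post_tau$hyper$mu,
           mu_log_sigma2 = object$post_sig$hyper$mu,
           omega2 = object$omega2)
  bp <- object$beta_post
  if (!is.null(bp)) {
    nms <- names(object$covariates$rasters)
    bt <- bp$tau$mean; names(bt) <- paste0("beta_tau.", nms)
    bs <- bp$sig$mean; names(bs) <- paste0("beta_sigma2.", nms)
    out <- c(out, bt, bs)
  }
  out
}

#' Plot posterior field maps
#'
#' Draws image maps of the posterior-mean directional persistence and speed
#' over the prediction grid, plus the training-loss trace.
#'
#' @param x A fitted [crwgp()] model.
#' @param maps Optional precomputed [predict.crwgp()] output.
#' @param ... Passed to [graphics::image()].
#' @return `x`, invisibly.
#' @export
plot.crwgp <- function(x, maps = NULL, ...) {
  if (is.null(maps)) maps <- predict.crwgp(x, ci_levels = numeric(0))
  xs <- sort(unique(maps$x)); ys <- sort(unique(maps$y))
  shape <- function(v) matrix(v[order(maps$y, maps$x)], length(xs),
                              length(ys))
  op <- graphics::par(mfrow = c(1, 3), mar = c(4, 4, 3, 1))
  on.exit(graphics::par(op))
  graphics::image(xs, ys, shape(maps$persistence_mean),
                  col = grDevices::hcl.colors(64, "viridis"),
                  xlab = "x", ylab = "y",
                  main = "posterior mean persistence", ...)
  graphics::image(xs, ys, shape(maps$speed_mean),
                  col = grDevices::hcl.colors(64, "viridis"),
                  xlab = "x", ylab = "y", main = "posterior mean speed", ...)
  graphics::plot(seq_along(x$loss_trace), x$loss_trace, type = "l",
                 xlab = "epoch", ylab = "loss", main = "training loss")
  invisible(x)
}
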