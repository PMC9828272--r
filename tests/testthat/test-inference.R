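# Segmentation, the early-stopping rule, training-loop contracts, field
# prediction and covariate-effect summaries.

test_that("trajectories split into full segments plus a kept-or-dropped remainder", {
  traj <- function(n) data.frame(id = "w", time = seq_len(n),
                                 x = cumsum(rnorm(n)), y = cumsum(rnorm(n)))
  set.seed(1)
  expect_length(segment_trajectories(traj(4000), 500), 8)
  expect_length(segment_trajectories(traj(500), 500), 1)
  segs <- segment_trajectories(traj(1250), 500)
  expect_length(segs, 3)
  expect_equal(vapply(segs, function(s) length(s$t), 0), c(500, 500, 250))
  # remainder below segment_length / 5 is dropped
  expect_length(segment_trajectories(traj(1090), 500), 2)
  # short remainders above the absolute floor of 2 are kept
  expect_length(segment_trajectories(traj(7), 5), 2)
  expect_length(segment_trajectories(list(), 500), 0)
  expect_error(segment_trajectories(traj(10), 1), ">= 2")
})

test_that("early stopping fires exactly when the loss plateaus", {
  es <- crwgp:::.early_stop
  expect_false(es(c(10, 9, 8, 7, 6, 5), 5))       # still decreasing
  expect_true(es(c(5, 6, 6, 6, 6, 6), 5))         # plateau after epoch 1
  expect_false(es(c(10, 9, 8, 7.5, 7.5, 7.5), 5)) # a recent epoch improved
  expect_true(es(c(10, 9, 8, 7.5, 7.5, 7.5, 7.5, 7.5, 7.5), 5))
  expect_false(es(c(3, 3, 3), 5))                 # shorter than patience
  # noisy-but-improving traces keep training
  expect_false(es(c(10, 8, 9, 7, 8, 6, 7, 5), 5))
})

tiny_fit <- function(seed = 2, n_ind = 4, n_obs = 80, epochs = 3, ...) {
  sim <- simulate_crw(sim_config(n_individuals = n_ind, n_obs = n_obs,
                                 seed = 7))
  crwgp(sim$obs,
        config = crwgp_config(segment_length = 40, max_epochs = epochs,
                              seed = seed, grid_nx = 5, grid_ny = 5, ...))
}

test_that("fitting is reproducible under a fixed seed and bounded by max_epochs", {
  f1 <- tiny_fit()
  f2 <- tiny_fit()
  expect_identical(f1$loss_trace, f2$loss_trace)
  expect_identical(f1$post_tau$whitened_mean, f2$post_tau$whitened_mean)
  expect_identical(f1$omega2, f2$omega2)
  expect_lte(length(f1$loss_trace), 3)
  expect_true(all(is.finite(f1$loss_trace)))
  f3 <- tiny_fit(seed = 9)
  expect_false(identical(f1$loss_trace, f3$loss_trace))
})

test_that("a spatially constant simulation yields near-flat posterior fields", {
  sim <- simulate_crw(sim_config(n_individuals = 30, n_obs = 300,
                                 a_levels = c(1, 1),
                                 b_levels = c(sqrt(2), sqrt(2)), seed = 14))
  fit <- crwgp(sim$obs, kernel = "periodic", period = 4,
               config = crwgp_config(max_epochs = 25, patience = 25,
                                     seed = 3, grid_nx = 6, grid_ny = 6),
               domain = list(xlim = c(0, 4 - 4 / 6),
                             ylim = c(0, 4 - 4 / 6)))
  cm_t <- conditional_marginals(fit$post_tau, fit$grid)
  cm_s <- conditional_marginals(fit$post_sig, fit$grid)
  # posterior-median fields over the grid stay within a 1.5x band and at
  # the simulated constant levels (tau = 1, sigma2 = 1)
  expect_lt(exp(max(cm_t$mean) - min(cm_t$mean)), 1.5)
  expect_lt(exp(max(cm_s$mean) - min(cm_s$mean)), 1.5)
  expect_lt(abs(mean(cm_t$mean)), 0.35)
  expect_lt(abs(mean(cm_s$mean)), 0.35)
})

test_that("fixed-noise configuration bypasses noise learning", {
  f <- tiny_fit(epochs = 2, omega2 = 0.123)
  expect_identical(f$omega2, 0.123)
})

test_that("field maps summarise lognormal posteriors correctly", {
  grid <- inducing_grid(c(0, 1), c(0, 1), 3, 3)
  m <- nrow(grid)
  h0 <- field_hyper(mu = 0, amplitude = 1, lengthscale = 0.6)
  # near point-mass posterior at log tau = 0 across the grid
  pm <- latent_field_posterior(grid, h0, rep(0, m), diag(1e-8, m))
  maps <- predict_fields(pm, pm, grid, n_samples = 200)
  expect_equal(maps$persistence_mean, rep(1, m), tolerance = 1e-3)
  expect_lt(max(maps$persistence_sd), 1e-3)
  expect_true(all(maps$persistence_lo_90 <= maps$persistence_mean + 1e-9))
  expect_true(all(maps$persistence_hi_90 >= maps$persistence_mean - 1e-9))
  # diffuse posterior: Monte Carlo mean matches the lognormal moment
  # exp(mu + v/2) within Monte Carlo error
  post <- latent_field_posterior(grid, h0)
  maps2 <- predict_fields(post, post, grid, n_samples = 10000, seed = 4)
  cm <- conditional_marginals(post, grid)
  mom <- exp(cm$mean + cm$var / 2)
  se <- sqrt((exp(cm$var) - 1) * exp(2 * cm$mean + cm$var) / 10000)
  expect_lt(max(abs(maps2$persistence_mean - mom) / se), 4)
  # CI columns appear only when levels are requested
  expect_false(any(grepl("lo_", names(predict_fields(pm, pm, grid,
                                                     n_samples = 50,
                                                     ci_levels = NULL)))))
})

test_that("covariate responses follow exp(mu + beta e) with a flat null", {
  r <- structure(list(x0 = 0, y0 = 0, cellsize = 1,
                      values = matrix(rnorm(25), 5)), class = "crwgp_raster")
  covs <- covariate_stack(list(ndvi = r))
  mock <- structure(list(
    post_tau = list(hyper = field_hyper(mu = 0.4)),
    post_sig = list(hyper = field_hyper(mu = 0)),
    beta_post = list(tau = list(mean = 0, sd = 1e-12),
                     sig = list(mean = 1, sd = 1e-12)),
    covariates = covs), class = "crwgp")
  flat <- covariate_effects(mock, "persistence", n_points = 5)
  expect_equal(flat$response, rep(exp(0.4), 5), tolerance = 1e-6)
  expect_equal(attr(flat, "intercept"), exp(0.4))
  curve <- covariate_effects(mock, "variance", n_points = 5)
  e_std <- seq(-2, 2, length.out = 5)
  expect_equal(curve$response, exp(e_std), tolerance = 1e-6)
  expect_true(all(diff(curve$response) > 0))      # monotone at point mass
  expect_error(covariate_effects(structure(list(beta_post = NULL),
                                           class = "crwgp")),
               "without covariates")
})

test_that("fitted models print, summarise and expose coefficients", {
  f <- tiny_fit(epochs = 2)
  expect_output(print(f), "integrated OU")
  expect_named(coef(f), c("mu_log_tau", "mu_log_sigma2", "omega2"))
  s <- summary(f)
  expect_s3_class(s, "summary.crwgp")
  expect_output(print(s), "persistence")
  path <- tempfile(fileext = ".png")
  grDevices::png(path)
  plot(f)
  grDevices::dev.off()
  expect_true(file.exists(path))
})
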