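# The parameter-recovery study is the most expensive fixture; it is run at
# most once per test session and shared between the tests that examine it.

recovery_env <- new.env(parent = emptyenv())

recovery_fixture <- function() {
  if (!is.null(recovery_env$result)) return(recovery_env$result)
  L <- 4
  nx <- 15
  sim <- simulate_crw(sim_config(n_individuals = 40, n_obs = 400, seed = 11))
  cfg <- crwgp_config(max_epochs = 150, patience = 15, seed = 2)
  # the inducing grid spans one period of the torus; including both 0 and L
  # would duplicate rows under the periodic kernel
  dom <- list(xlim = c(0, L - L / nx), ylim = c(0, L - L / nx))
  fit <- crwgp(sim$obs, kernel = "periodic", period = L, config = cfg,
               domain = dom)
  gt <- ground_truth_on_grid(sim$fields, fit$grid)
  interior <- function(v) {
    m <- v %% (L / 2)
    pmin(m, L / 2 - m) >= 0.1 * L
  }
  keep <- interior(gt$x) & interior(gt$y)
  cm_t <- conditional_marginals(fit$post_tau, fit$grid)
  cm_s <- conditional_marginals(fit$post_sig, fit$grid)
  recovery_env$result <- list(sim = sim, fit = fit, gt = gt, keep = keep,
                              cm_t = cm_t, cm_s = cm_s, L = L)
  recovery_env$result
}

recovery_metrics <- function(r) {
  rel_t <- abs(exp(r$cm_t$mean) - r$gt$tau) / r$gt$tau
  rel_s <- abs(exp(r$cm_s$mean) - r$gt$sigma2) / r$gt$sigma2
  in_band <- function(cm, truth) {
    lo <- cm$mean - 1.645 * sqrt(cm$var)
    hi <- cm$mean + 1.645 * sqrt(cm$var)
    log(truth) >= lo & log(truth) <= hi
  }
  list(rel_err_tau = mean(rel_t[r$keep]),
       rel_err_sigma2 = mean(rel_s[r$keep]),
       coverage = mean(c(in_band(r$cm_t, r$gt$tau)[r$keep],
                         in_band(r$cm_s, r$gt$sigma2)[r$keep])))
}
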