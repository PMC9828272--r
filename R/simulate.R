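# Synthetic non-stationary correlated-random-walk generator. Individuals
# follow df = v dt, dv = -a(f) v dt + b(f) dW over a square environment built
# from warped sine waves. The environment has periodic boundaries: field
# lookups wrap modulo the domain length while recorded positions stay
# unwrapped, so animals see an infinitely tiled landscape and the domain
# edges never influence movement.

#' Warped sine wave
#'
#' `wsin(v) = sin(2 pi v) * sqrt((1 + alpha^2) / (1 + alpha^2 sin^2(2 pi v)))`.
#' Odd, period 1, bounded in \[-1, 1\] with the extremes at v = 0.25 and
#' 0.75. `alpha = 0` recovers the plain sinusoid; larger `alpha` flattens the
#' wave towards a square profile, giving patch-like environments.
#'
#' @param v Position in units of the domain length (any real number).
#' @param alpha Warp parameter (>= 0).
#' @return Values in \[-1, 1\].
#' @export
warped_sine <- function(v, alpha = 2) {
  if (any(alpha < 0)) stop("'alpha' must be non-negative", call. = FALSE)
  s <- sin(2 * pi * v)
  s * sqrt((1 + alpha^2) / (1 + alpha^2 * s^2))
}

#' Simulation configuration
#'
#' Defaults define the reference synthetic study: a patch-like two-level
#' environment (`alpha = 2`) on a square domain, mean-reversion `a` between
#' 0.5 and 2 (so the persistence timescale `tau = 1/a` spans 0.5-2 time
#' units) and volatility `b` chosen so the stationary velocity variance
#' `sigma2 = b^2/(2a)` also spans 0.5-2. Observations are taken every 0.1
#' time units with additive Gaussian error.
#'
#' @param domain_length Side length L of the square environment.
#' @param alpha Warp parameter of the environment waves.
#' @param a_levels Length-2 vector, (low, high) mean-reversion rates (1/time).
#' @param b_levels Length-2 vector, (low, high) volatilities.
#' @param n_individuals Number of simulated animals.
#' @param n_obs Positional observations collected per animal.
#' @param obs_interval Time between observations.
#' @param substeps Euler-Maruyama integration steps per observation interval.
#' @param obs_noise_sd Standard deviation of the observation error (distance).
#' @param seed Integer seed; all randomness in [simulate_crw()] flows from it.
#' @return An object of class `crwgp_simconfig`.
#' @export
sim_config <- function(domain_length = 4, alpha = 2,
                       a_levels = c(0.5, 2),
                       b_levels = c(sqrt(0.5), sqrt(8)),
                       n_individuals = 200, n_obs = 500,
                       obs_interval = 0.1, substeps = 10,
                       obs_noise_sd = 0.02, seed = 1) {
  cfg <- list(domain_length = domain_length, alpha = alpha,
              a_levels = a_levels, b_levels = b_levels,
              n_individuals = as.integer(n_individuals),
              n_obs = as.integer(n_obs),
              obs_interval = obs_interval, substeps = as.integer(substeps),
              obs_noise_sd = obs_noise_sd, seed = as.integer(seed))
  .check_pos(cfg$domain_length, "domain_length")
  .check_pos(cfg$a_levels, "a_levels")
  if (any(cfg$b_levels < 0)) stop("'b_levels' must be non-negative",
                                  call. = FALSE)
  .check_pos(cfg$obs_interval, "obs_interval")
  if (cfg$substeps < 1) stop("'substeps' must be >= 1", call. = FALSE)
  if (cfg$n_individuals < 1 || cfg$n_obs < 2) {
    stop("need at least 1 individual and 2 observations", call. = FALSE)
  }
  structure(cfg, class = "crwgp_simconfig")
}

#' Ground-truth spatial fields of a simulation environment
#'
#' Each field is `low + (high - low) * (1 + wsin(x/L) wsin(y/L)) / 2`, a
#' product of one-dimensional warped sines rescaled to the configured levels;
#' it is exactly periodic with period L in both axes. Also exposes the
#' movement parameters the model targets: `tau(x) = 1/a(x)` and
#' `sigma2(x) = b(x)^2 / (2 a(x))`.
#'
#' @param config A [sim_config()].
#' @return A list of vectorised functions `a(x, y)`, `b(x, y)`, `tau(x, y)`,
#'   `sigma2(x, y)`, class `crwgp_truth`.
#' @export
make_fields <- function(config) {
  L <- config$domain_length
  alpha <- config$alpha
  lvl <- function(levels) {
    force(levels)
    function(x, y) {
      w <- warped_sine(x / L, alpha) * warped_sine(y / L, alpha)
      levels[1] + (levels[2] - levels[1]) * (1 + w) / 2
    }
  }
  a_fun <- lvl(config$a_levels)
  b_fun <- lvl(config$b_levels)
  structure(list(
    a = a_fun, b = b_fun,
    tau = function(x, y) 1 / a_fun(x, y),
    sigma2 = function(x, y) b_fun(x, y)^2 / (2 * a_fun(x, y))
  ), class = "crwgp_truth")
}

#' Simulate non-stationary correlated-random-walk trajectories
#'
#' Integrates `df = v dt, dv = -a(f) v dt + b(f) dW` by Euler-Maruyama with
#' `substeps` steps per observation interval, looking fields up at the true
#' position wrapped modulo the domain length. Initial positions are uniform
#' over the domain; initial velocities are drawn from the local stationary
#' velocity distribution `N(0, b^2/(2a))` so trajectories start without
#' transients. Observations are the true positions plus i.i.d. Gaussian
#' error.
#'
#' @param config A [sim_config()].
#' @return A list of class `crwgp_sim` with elements
#'   `obs` (`data.frame` `id,time,x,y`, one row per observation),
#'   `truth` (`data.frame` `id,time,f_x,f_y,v_x,v_y` of latent states),
#'   `fields` (the [make_fields()] ground truth), and `config`.
#' @export
simulate_crw <- function(config) {
  stopifnot(inherits(config, "crwgp_simconfig"))
  set.seed(config$seed)
  fields <- make_fields(config)
  L <- config$domain_length
  ni <- config$n_individuals
  nt <- config$n_obs
  dt <- config$obs_interval / config$substeps

  wrap <- function(x) x - L * floor(x / L)
  Fx <- stats::runif(ni, 0, L); Fy <- stats::runif(ni, 0, L)
  a0 <- fields$a(Fx, Fy); b0 <- fields$b(Fx, Fy)
  sd0 <- b0 / sqrt(2 * a0)
  Vx <- stats::rnorm(ni, 0, sd0); Vy <- stats::rnorm(ni, 0, sd0)

  FX <- matrix(0, nt, ni); FY <- matrix(0, nt, ni)
  VX <- matrix(0, nt, ni); VY <- matrix(0, nt, ni)
  FX[1, ] <- Fx; FY[1, ] <- Fy; VX[1, ] <- Vx; VY[1, ] <- Vy
  sq <- sqrt(dt)
  for (k in seq_len(nt - 1)) {
    for (s in seq_len(config$substeps)) {
      ax <- fields$a(wrap(Fx), wrap(Fy))
      bx <- fields$b(wrap(Fx), wrap(Fy))
      Fx <- Fx + Vx * dt
      Fy <- Fy + Vy * dt
      Vx <- Vx - ax * Vx * dt + bx * sq * stats::rnorm(ni)
      Vy <- Vy - ax * Vy * dt + bx * sq * stats::rnorm(ni)
    }
    if (any(!is.finite(Fx)) || any(!is.finite(Fy))) {
      stop("simulation diverged (non-finite state); reduce the integration ",
           "step via 'substeps'", call. = FALSE)
    }
    FX[k + 1, ] <- Fx; FY[k + 1, ] <- Fy
    VX[k + 1, ] <- Vx; VY[k + 1, ] <- Vy
  }

  times <- (seq_len(nt) - 1) * config$obs_interval
  id <- rep(seq_len(ni), each = nt)
  tvec <- rep(times, ni)
  fx <- as.numeric(FX); fy <- as.numeric(FY)
  obs <- data.frame(
    id = id, time = tvec,
    x = fx + stats::rnorm(ni * nt, 0, config$obs_noise_sd),
    y = fy + stats::rnorm(ni * nt, 0, config$obs_noise_sd))
  truth <- data.frame(id = id, time = tvec, f_x = fx, f_y = fy,
                      v_x = as.numeric(VX), v_y = as.numeric(VY))
  structure(list(obs = obs, truth = truth, fields = fields, config = config),
            class = "crwgp_sim")
}

#' Tabulate ground-truth fields on a grid
#'
#' @param fields A [make_fields()] object.
#' @param grid Locations (matrix with two columns), e.g. an
#'   [inducing_grid()].
#' @return A `data.frame` with columns `x, y, a, b, tau, sigma2`.
#' @export
ground_truth_on_grid <- function(fields, grid) {
  grid <- .as_locations(grid)
  a <- fields$a(grid[, 1], grid[, 2])
  b <- fields$b(grid[, 1], grid[, 2])
  data.frame(x = grid[, 1], y = grid[, 2], a = a, b = b,
             tau = 1 / a, sigma2 = b^2 / (2 * a))
}
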