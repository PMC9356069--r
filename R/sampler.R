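#' Sampler configuration presets
#'
#' The four sampler variants compared throughout: the fractional sampler with
#' momentum (`"fns"`, alpha = 1.2, beta = 1), the fractional sampler without
#' momentum (`"fractional_no_momentum"`, alpha = 1.2, beta = 0), Hamiltonian
#' Monte Carlo (`"hmc"`, alpha = 2, beta = 1) and Langevin sampling
#' (`"langevin"`, alpha = 2, beta = 0). All presets use noise strength
#' `gamma = 1` and step size `dt = 0.001`.
#'
#' @param name one of `"fns"`, `"fractional_no_momentum"`, `"hmc"`,
#'   `"langevin"`.
#' @param ... overrides for any configuration field (e.g. `n_steps`,
#'   `n_chains`, `x0_mode`, `burn_in`).
#' @return a `"sampler_config"` list with fields `alpha`, `beta`,
#'   `gamma_noise`, `dt`, `n_steps`, `n_chains`, `x0_mode`, `burn_in`,
#'   `record_every`.
#' @export
sampler_variant <- function(name = c("fns", "fractional_no_momentum", "hmc",
                                     "langevin"), ...) {
  name <- match.arg(name)
  ab <- switch(name,
    fns = c(1.2, 1),
    fractional_no_momentum = c(1.2, 0),
    hmc = c(2, 1),
    langevin = c(2, 0))
  cfg <- sampler_config(alpha = ab[1], beta = ab[2], ...)
  cfg$variant <- name
  cfg
}

#' @rdname sampler_variant
#' @param alpha tail index of the driving Levy motion, in (1, 2].
#' @param beta damping/momentum coefficient, >= 0.
#' @param gamma_noise noise strength gamma.
#' @param dt integration step in model time units.
#' @param n_steps number of integration steps.
#' @param n_chains number of independent chains.
#' @param x0_mode `"target"` (draw initial positions from the target),
#'   `"mode"` (start all chains at the first mode) or a numeric value.
#' @param v0_mode `"gauss"` (standard normal momenta, the classical kinetic
#'   start; for `alpha = 2` this is also the stationary momentum law),
#'   `"stationary"` (draw from the heavy-tailed SaS(alpha, 1/alpha) momentum
#'   marginal of the fractional Hamiltonian) or `"zero"`.
#' @param burn_in number of initial steps discarded by downstream analyses.
#' @param record_every record every k-th step (thinning of the stored path;
#'   running means are always accumulated at full resolution).
#' @export
sampler_config <- function(alpha = 1.2, beta = 1, gamma_noise = 1, dt = 0.001,
                           n_steps = 1e4, n_chains = 1, x0_mode = "target",
                           v0_mode = "gauss", burn_in = 0, record_every = 1L) {
  stopifnot(dt > 0, alpha > 1, alpha <= 2, beta >= 0, gamma_noise > 0,
            n_steps >= 1, n_chains >= 1, record_every >= 1)
  structure(list(alpha = alpha, beta = beta, gamma_noise = gamma_noise,
                 dt = dt, n_steps = as.integer(n_steps),
                 n_chains = as.integer(n_chains), x0_mode = x0_mode,
                 v0_mode = v0_mode, burn_in = as.integer(burn_in),
                 record_every = as.integer(record_every)),
            class = "sampler_config")
}

#' Integrate the Levy-driven sampler SDE
#'
#' Euler-Maruyama integration of
#' `dx = gamma b(x) dt + beta v dt + gamma^(1/alpha) dL^alpha` and
#' `dv = beta b(x) dt`, where the per-step Levy increment is drawn as a
#' SaS(alpha, dt) variate (so its magnitude scales as `dt^(1/alpha)`).
#' Momentum receives no noise. The run is reproducible under [set.seed()].
#'
#' @param drift a `"drift_field"` from [drift_from_target()]; its `alpha`
#'   must match the configuration.
#' @param config a `"sampler_config"`.
#' @return a `"trajectory"` object: list with `times` (recorded time stamps),
#'   `positions` (matrix, time x chain), `running_mean` (same shape),
#'   `momenta` (matrix or `NULL` when `beta = 0`), `config`.
#' @export
simulate_fns <- function(drift, config) {
  stopifnot(inherits(drift, "drift_field"), inherits(config, "sampler_config"))
  if (!isTRUE(all.equal(drift$alpha, config$alpha))) {
    stop("drift field alpha (", drift$alpha,
         ") does not match sampler alpha (", config$alpha, ")", call. = FALSE)
  }
  nc <- config$n_chains
  x0 <- if (is.numeric(config$x0_mode)) {
    rep_len(config$x0_mode, nc)
  } else if (identical(config$x0_mode, "target")) {
    .sample_from_field(drift, nc)
  } else if (identical(config$x0_mode, "mode")) {
    rep(drift$grid[which.max(drift$density)], nc)
  } else {
    stop("unknown x0_mode", call. = FALSE)
  }
  v0 <- if (config$beta == 0) {
    numeric(nc)
  } else {
    switch(config$v0_mode,
      zero = numeric(nc),
      gauss = stats::rnorm(nc),
      stationary = sample_sas(nc, config$alpha, 1 / config$alpha),
      stop("unknown v0_mode", call. = FALSE))
  }
  out <- fns_simulate_cpp(drift$grid, drift$drift, config$alpha, config$beta,
                          config$gamma_noise, config$dt, config$n_steps, x0,
                          v0, config$record_every)
  times <- config$dt * config$record_every * seq_len(nrow(out$positions))
  structure(list(times = times, positions = out$positions,
                 running_mean = out$running_mean,
                 momenta = if (config$beta != 0) out$momenta else NULL,
                 grid_range = range(drift$grid),
                 config = config),
            class = "trajectory")
}

#' @export
print.trajectory <- function(x, ...) {
  cat(sprintf("trajectory: %d chains x %d recorded steps, T = %g (dt = %g)\n",
              ncol(x$positions), nrow(x$positions), max(x$times),
              x$config$dt))
  invisible(x)
}

#' Mean-squared error of the running sample mean
#'
#' For an ensemble of chains, computes `MSE(T)`, the ensemble average of
#' `(mean of x over [0, T] - true_value)^2`, as a function of the averaging
#' horizon, together with the half-maximum time `T_HM`: the first horizon at
#' which the MSE falls to half its maximum, located by linear interpolation
#' between recorded horizons.
#'
#' @param traj a `"trajectory"` from [simulate_fns()] (chains should be
#'   initialized from the target so that `MSE(0+)` equals the target
#'   variance), or a running-mean matrix (time x chain).
#' @param true_value the true mean being estimated.
#' @param times recorded horizons; taken from `traj` when it is a trajectory.
#' @param censor_at_grid_exit if `TRUE`, chains are dropped from the ensemble
#'   once their position leaves the tabulated drift grid. For `alpha < 2` the
#'   clipped drift cannot instantly rein in the rare giant Levy jumps that
#'   carry a chain off the grid, and the squared running-mean contribution of
#'   such excursions has infinite expectation, so the uncensored ensemble MSE
#'   does not converge with the number of chains. Censoring at the grid edge
#'   (where the drift field stops being the constructed one anyway) restores
#'   a well-defined curve; it is a no-op for Gaussian-driven variants.
#' @param half_level reference level whose crossing defines `t_hm`
#'   (attribute). Default `NULL` uses half the curve maximum; pass half the
#'   target variance to use the analytic `MSE(0+)` instead.
#' @return a data frame with columns `T` and `mse`, with attribute `t_hm`.
#' @export
running_mean_mse <- function(traj, true_value = 0, times = NULL,
                             censor_at_grid_exit = FALSE, half_level = NULL) {
  if (inherits(traj, "trajectory")) {
    rm_mat <- traj$running_mean
    times <- traj$times
    if (censor_at_grid_exit && !is.null(traj$grid_range)) {
      ok <- colSums(traj$positions < traj$grid_range[1] |
                      traj$positions > traj$grid_range[2]) == 0L
      if (!any(ok)) stop("all chains left the drift grid", call. = FALSE)
      rm_mat <- rm_mat[, ok, drop = FALSE]
    }
  } else {
    rm_mat <- as.matrix(traj)
    if (is.null(times)) stop("`times` required for matrix input",
                             call. = FALSE)
  }
  if (ncol(rm_mat) < 1L) stop("empty ensemble", call. = FALSE)
  mse <- rowMeans((rm_mat - true_value)^2)
  out <- data.frame(T = times, mse = mse)
  attr(out, "t_hm") <- if (is.null(half_level)) {
    half_maximum_time(times, mse)
  } else {
    half_maximum_time(times, mse, level = half_level)
  }
  attr(out, "n_chains") <- ncol(rm_mat)
  out
}

#' Half-maximum time of a decaying curve
#'
#' First abscissa at which the curve falls to half its maximum, linearly
#' interpolated between samples. Returns 0 when the curve starts at or below
#' half-maximum, and `NA` when it never reaches it.
#'
#' @param t abscissa values (increasing).
#' @param y curve values.
#' @param level crossing level; defaults to half the curve maximum.
#' @return the interpolated half-maximum time.
#' @export
half_maximum_time <- function(t, y, level = NULL) {
  stopifnot(length(t) == length(y))
  target <- if (is.null(level)) max(y) / 2 else level
  below <- which(y <= target)
  if (!length(below)) return(NA_real_)
  i <- below[1]
  if (i == 1L) return(if (y[1] <= target) 0 else t[1])
  t[i - 1L] + (t[i] - t[i - 1L]) * (y[i - 1L] - target) / (y[i - 1L] - y[i])
}

#' Mode occupancy of a sampled trajectory on a bimodal target
#'
#' Assigns each retained sample to the nearest mode by the sign of `x` (ties
#' at `x = 0` inherit the previous assignment) and reports the fraction of
#' time in the positive mode and the number of mode switches.
#'
#' @param traj a `"trajectory"` or numeric vector of positions.
#' @param burn_in_frac fraction of initial samples discarded.
#' @return list with `occupancy_positive`, `n_switches`, `both_visited`.
#' @export
mode_occupancy <- function(traj, burn_in_frac = 0) {
  x <- if (inherits(traj, "trajectory")) as.vector(traj$positions) else
    as.numeric(traj)
  if (burn_in_frac > 0) x <- x[-seq_len(floor(burn_in_frac * length(x)))]
  s <- sign(x)
  # ties inherit the previous side
  for (i in which(s == 0)) s[i] <- if (i > 1) s[i - 1] else 1
  switches <- sum(diff(s) != 0)
  list(occupancy_positive = mean(s > 0), n_switches = switches,
       both_visited = any(s > 0) && any(s < 0))
}
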