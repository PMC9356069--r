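#' Benchmark the four sampler variants
#'
#' Runs the fractional-with-momentum, fractional-without-momentum,
#' Hamiltonian and Langevin samplers on the standard normal target, and
#' reports stationary histograms (KS distance to the target), sample-path
#' autocorrelations, running-mean MSE curves and their half-maximum times.
#' Chains start from the target; momenta (where present) start from the
#' standard normal core. The MSE reference level is half the target variance
#' (the analytic `MSE(0+)` under stationary initialization), and chains are
#' censored at their first exit from the drift grid (see
#' [running_mean_mse()]).
#'
#' @param n_chains chains per variant (>= 100 for stable curves).
#' @param t_total averaging horizon in model time units.
#' @param dt integration step.
#' @param record_every recording stride.
#' @return list with `t_hm` (named per variant), `mse` (list of curves),
#'   `autocorr` (list of acf data frames), `ks` (named KS distances).
#' @export
run_sampler_benchmark <- function(n_chains = 1000, t_total = 8, dt = 0.001,
                                  record_every = 4L) {
  variants <- c("fns", "hmc", "fractional_no_momentum", "langevin")
  tg <- normal_target()
  t_hm <- numeric(0)
  mse_l <- list()
  ac_l <- list()
  ks <- numeric(0)
  for (v in variants) {
    cfg <- sampler_variant(v, n_steps = round(t_total / dt),
                           n_chains = n_chains, dt = dt,
                           record_every = record_every)
    dr <- drift_from_target(tg, cfg$alpha)
    tr <- simulate_fns(dr, cfg)
    mse <- running_mean_mse(tr, true_value = 0, censor_at_grid_exit = TRUE,
                            half_level = 0.5)
    t_hm[v] <- attr(mse, "t_hm")
    mse_l[[v]] <- mse
    # stationary histogram check on retained positions (within-grid chains)
    xs <- as.vector(tr$positions)
    xs <- xs[xs > -6 & xs < 6]
    if (length(xs) > 5e4) xs <- xs[seq(1, length(xs), length.out = 5e4)]
    ks[v] <- suppressWarnings(stats::ks.test(xs, "pnorm")$statistic)
    ac <- stats::acf(tr$positions[, 1], lag.max = 200, plot = FALSE)
    ac_l[[v]] <- data.frame(lag = ac$lag[, 1, 1] * dt * record_every,
                            acf = ac$acf[, 1, 1])
  }
  list(t_hm = t_hm, mse = mse_l, autocorr = ac_l, ks = ks)
}

#' Exit-time scaling of the sampler variants on the bimodal target
#'
#' Measures mean exit times on equal-weight Gaussian mixtures as the modal
#' separation grows, for a fractional (`alpha = 1.2`) and/or Gaussian
#' (`alpha = 2`) variant, and fits the scaling: linear growth for the
#' Levy-driven sampler versus exponential (log-linear) growth for
#' Brownian-driven samplers.
#'
#' @param delta_s_values modal separations (`2 s*`) to test.
#' @param variants subset of the four variant names.
#' @param n_trials chains per separation.
#' @param t_total horizon per trial (model time units).
#' @param sigma mode width.
#' @param dt step size.
#' @return list with `table` (variant, delta_s, mean_exit, n_switches) and
#'   `fits` (per variant: linear and log-linear R^2).
#' @export
run_exit_time_scaling <- function(delta_s_values = c(3, 4, 5, 6, 7),
                                  variants = c("fns",
                                               "fractional_no_momentum"),
                                  n_trials = 8, t_total = 1000,
                                  sigma = 0.32, dt = 0.001) {
  rows <- list()
  for (v in variants) {
    for (ds in delta_s_values) {
      tg <- mixture_target(s_star = ds / 2, sigma = sigma)
      cfg <- sampler_variant(v, n_steps = round(t_total / dt),
                             n_chains = n_trials, dt = dt,
                             record_every = 10L, x0_mode = ds / 2)
      dr <- drift_from_target(tg, cfg$alpha)
      tr <- simulate_fns(dr, cfg)
      durs <- c()
      nsw <- 0L
      for (ch in seq_len(n_trials)) {
        et <- exit_times(tr$positions[, ch], -ds / 2, ds / 2,
                         dt = dt * cfg$record_every)
        durs <- c(durs, et$durations)
        nsw <- nsw + length(et$durations)
      }
      rows[[length(rows) + 1L]] <- data.frame(
        variant = v, delta_s = ds,
        mean_exit = if (length(durs)) mean(durs) else NA_real_,
        n_switches = nsw)
    }
  }
  tab <- do.call(rbind, rows)
  fits <- lapply(split(tab, tab$variant), function(d) {
    d <- d[is.finite(d$mean_exit), ]
    if (nrow(d) < 3) return(list(r2_linear = NA, r2_loglinear = NA))
    f1 <- stats::lm(mean_exit ~ delta_s, data = d)
    f2 <- stats::lm(log(mean_exit) ~ delta_s, data = d)
    list(r2_linear = summary(f1)$r.squared,
         r2_loglinear = summary(f2)$r.squared)
  })
  list(table = tab, fits = fits)
}

#' Unimodal-stimulus circuit experiment
#'
#' Drives a calibrated network with a unimodal feedforward bump and collects
#' the sampling statistics: center-of-mass tail index and diffusion
#' exponent, sample-path autocorrelation fit, per-contrast sample variance,
#' Fano-factor tuning, and the population-rate spectrum.
#'
#' @param net a `"network_topology"` (built at the transition I-E ratio).
#' @param contrasts contrast levels for the variance curve.
#' @param duration per-contrast simulation length (ms).
#' @param n_trials trials per contrast.
#' @return list of tidy tables (`summary`, `variance_vs_contrast`,
#'   `fano_tuning`, `autocorr`, `psd`).
#' @export
run_unimodal <- function(net, contrasts = c(0.5, 1, 2), duration = 5000,
                         n_trials = 2) {
  var_rows <- list()
  fano_tab <- NULL
  ac_fit <- NULL
  psd <- NULL
  alpha <- NA_real_
  eta <- NA_real_
  for (cc in contrasts) {
    stim <- stimulus_spec("unimodal", contrasts = cc)
    for (tr in seq_len(n_trials)) {
      spk <- simulate_circuit(net, stim, duration)
      com <- com_trajectory(spk, step = 5)
      m <- com_unwrapped(com)
      # variance of the sampled positions around the stimulus: use the
      # wrapped coordinate (the stimulus sits at the origin, so the torus
      # and linear variances agree where it matters)
      var_rows[[length(var_rows) + 1L]] <- data.frame(
        contrast = cc, trial = tr,
        sample_variance = mean(sample_path_variance(
          list(com$x[!is.na(com$x)]))))
      if (cc == 1 && tr == 1) {
        fano_tab <- fano_factor(spk, stim_center = c(0, 0))
        ac_fit <- path_autocorrelation_fit(m[stats::complete.cases(m), ],
                                           dt = 5, max_lag = 400)
        psd <- population_rate_psd(spk,
                                   segment = min(2000, duration / 2))
        com15 <- com_trajectory(spk)
        ft <- try(increment_tail_index(com_unwrapped(com15)),
                  silent = TRUE)
        if (!inherits(ft, "try-error")) alpha <- ft$alpha
        me <- try(msd_and_eta(m, dt = 5,
                              lags = unique(round(exp(seq(log(3), log(60),
                                                          length.out = 12))))),
                  silent = TRUE)
        if (!inherits(me, "try-error")) eta <- me$eta
      }
    }
  }
  list(summary = data.frame(alpha = alpha, eta = eta,
                            ac_model = ac_fit$model, ac_tau = ac_fit$tau,
                            ac_f_hz = if (is.na(ac_fit$f)) NA else
                              1000 * ac_fit$f,
                            psd_peak = psd$peak_freq,
                            psd_tail = psd$tail_exponent),
       variance_vs_contrast = do.call(rbind, var_rows),
       fano_tuning = fano_tab, autocorr = ac_fit$acf, psd = psd$psd)
}

#' Bimodal-stimulus circuit experiment (rivalry protocol)
#'
#' Presents two feedforward bumps (default separated by `pi` in the hue
#' coordinate, the opponent-color rivalry arrangement), tracks the activity
#' pattern, and returns dwell (dominance) durations per mode together with
#' Burr/gamma fits when enough durations accumulate.
#'
#' @param net a `"network_topology"`.
#' @param s1,s2 stimulus centers.
#' @param c1,c2 contrasts.
#' @param duration per-trial length (ms).
#' @param n_trials number of trials.
#' @param min_duration outlier cutoff (ms) for the distribution fit.
#' @return list with `durations` (per mode), `mean_exit` per mode, and
#'   `fit` (a `"duration_fit_set"` or `NULL`).
#' @export
run_bimodal <- function(net, s1 = c(-pi / 2, 0), s2 = c(pi / 2, 0),
                        c1 = 1, c2 = 1, duration = 5000, n_trials = 2,
                        min_duration = 29) {
  stim <- stimulus_spec("bimodal", centers = rbind(s1, s2),
                        contrasts = c(c1, c2), widths = c(0.6, 0.6))
  durs1 <- c(); durs2 <- c()
  for (tr in seq_len(n_trials)) {
    spk <- simulate_circuit(net, stim, duration)
    com <- com_trajectory(spk, step = 5)
    ok <- stats::complete.cases(com)
    et <- exit_times(cbind(com$x, com$y)[ok, ], s1, s2, dt = 5,
                     torus = TRUE)
    if (length(et$durations)) {
      modes <- rle(et$assignments)$values
      modes <- modes[-length(modes)]
      durs1 <- c(durs1, et$durations[modes == 1L])
      durs2 <- c(durs2, et$durations[modes == 2L])
    }
  }
  all_durs <- c(durs1, durs2)
  fit <- NULL
  if (sum(all_durs >= min_duration) >= 200) {
    fit <- fit_dominance_distribution(all_durs, min_duration = min_duration)
  }
  list(durations = list(mode1 = durs1, mode2 = durs2),
       mean_exit = c(mode1 = mean(durs1), mode2 = mean(durs2)),
       fit = fit)
}

#' Perceptual-inference experiment (prior plus evidence)
#'
#' Embeds a prior at `s0` by perturbing the excitatory weights, presents a
#' unimodal stimulus at `s1`, and reads out the perceptual estimate as the
#' pattern's center of mass in the final tracking window of each short
#' presentation.
#'
#' @param params base [circuit_params()].
#' @param s1 stimulus center (length-2).
#' @param c1 stimulus contrast.
#' @param c0 prior (weight perturbation) strength.
#' @param s0 prior center.
#' @param n_trials number of presentations.
#' @param presentation duration of each presentation (ms).
#' @param window tracking window for the readout (ms).
#' @return data frame with one row per trial: `estimate_x`, `estimate_y`.
#' @export
run_inference <- function(params = circuit_params(), s1 = c(pi / 2, 0),
                          c1 = 0.5, c0 = 0.002, s0 = c(0, 0),
                          n_trials = 20, presentation = 300, window = 15) {
  stim <- stimulus_spec("unimodal", centers = matrix(s1, 1),
                        contrasts = c1)
  out <- matrix(NA_real_, n_trials, 2)
  for (tr in seq_len(n_trials)) {
    net <- build_network(params)
    net <- apply_prior_perturbation(net, c0 = c0, s0 = s0)
    spk <- simulate_circuit(net, stim, duration = presentation)
    est <- try(center_of_mass(spk, t = presentation, window = window),
               silent = TRUE)
    if (!inherits(est, "try-error")) out[tr, ] <- est
  }
  data.frame(estimate_x = out[, 1], estimate_y = out[, 2])
}
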