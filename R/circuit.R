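#' Parameters of the spiking E-I circuit
#'
#' Biophysical and architectural constants of the two-dimensional
#' conductance-based spiking network. Membrane and synaptic constants follow
#' standard cortical values: capacitance 0.25 nF, leak 16.7 nS (membrane
#' time constant 15 ms), threshold -50 mV, reset -60 mV, refractory 4 ms,
#' spike-frequency adaptation as a potassium conductance (increment 10 nS,
#' decay 80 ms, reversal -85 mV, excitatory neurons only). The excitatory
#' population sits on a 63 x 63 grid spanning the feature torus
#' `[-pi, pi)^2`; 1000 inhibitory neurons are placed uniformly at random.
#' Connection probability decays exponentially with torus distance, with
#' spatial scales (grid units) 8 for E->E, 10 for E->I and 20 for I->E and
#' I->I. The receiver-side inhibition-to-excitation weight ratio `xi` is the
#' control parameter of the network's state transition.
#'
#' In-degrees, per-block total weights, synaptic kinetics and the
#' feedforward synaptic weight are not uniquely determined by the
#' architecture; they are exposed here, with defaults calibrated (see
#' [calibrate_spontaneous_rate()]) so that spontaneous excitatory rates fall in the
#' 1-10 Hz range at `xi = 3.4` and the network sits in the fluctuation-
#' dominated transition regime between asynchronous firing and a coherent
#' propagating wave.
#'
#' @param xi receiver-side I-E ratio (default 3.4, the transition point).
#' @param N_I number of inhibitory neurons.
#' @param n_side side length of the excitatory grid (N_E = n_side^2).
#' @param K_EE,K_IE,K_EI,K_II in-degrees per block (receiver <- sender
#'   populations E<-E, I<-E, E<-I, I<-I).
#' @param J_tot_EE,J_tot_IE,J_tot_II summed incoming weight (nS) per
#'   receiver for the E<-E, I<-E and I<-I blocks ("reverse pooling": the
#'   receiver's total is fixed and split equally across its sampled
#'   partners). The E<-I total is set by `xi` times the E<-E total.
#' @param J_ffwd synaptic weight (nS) of one feedforward Poisson input
#'   event.
#' @param ffwd_I_scale multiplier on the feedforward rate received by
#'   inhibitory neurons. Whether interneurons share the full feature-tuned
#'   feedforward drive is not architecturally determined; with the full
#'   drive the interneurons fire regardless of excitatory activity and
#'   clamp the sheet, so the calibrated default lets them receive a reduced
#'   copy and otherwise track the excitatory population recurrently.
#' @param tau_d_E,tau_d_I synaptic decay constants (ms) of excitatory and
#'   inhibitory synapses; `tau_r` the (brief) rise time.
#' @param delay_max maximal conduction delay (ms), drawn uniformly on
#'   `[0, delay_max]`.
#' @param dt integration step (ms).
#' @param C,g_L,V_L,V_th,V_rt,tau_f,V_K,delta_g_K,tau_K,V_rev_E,V_rev_I
#'   biophysical constants, see Description.
#' @param tau_D_EE,tau_D_IE,tau_D_EI,tau_D_II connectivity spatial scales in
#'   grid units.
#' @return a `"circuit_params"` list.
#' @export
circuit_params <- function(xi = 3.4, N_I = 1000, n_side = 63,
                           K_EE = 200, K_IE = 200, K_EI = 50, K_II = 50,
                           J_tot_EE = 600, J_tot_IE = 850, J_tot_II = 60,
                           J_ffwd = 2.4, ffwd_I_scale = 0, tau_d_E = 2, tau_d_I = 5,
                           tau_r = 0.5, delay_max = 4, dt = 0.1,
                           C = 0.25, g_L = 16.7, V_L = -70, V_th = -50,
                           V_rt = -60, tau_f = 4, V_K = -85,
                           delta_g_K = 10, tau_K = 80, V_rev_E = 0,
                           V_rev_I = -80, tau_D_EE = 8, tau_D_IE = 10,
                           tau_D_EI = 20, tau_D_II = 20) {
  stopifnot(xi > 0, n_side >= 9, V_rt < V_th, dt > 0,
            all(c(C, g_L, tau_f, tau_K, tau_d_E, tau_d_I, tau_r) > 0))
  structure(as.list(environment()), class = "circuit_params")
}

.torus_dist_gu <- function(x1, y1, x2, y2, grid_unit) {
  dx <- .wrap_diff(x1 - x2)
  dy <- .wrap_diff(y1 - y2)
  sqrt(dx^2 + dy^2) / grid_unit
}

# weighted sampling of k partners without replacement (exponential-key trick)
.sample_partners <- function(weights, k) {
  keys <- stats::rexp(length(weights)) / weights
  order(keys)[seq_len(k)]
}

#' Build the network topology
#'
#' Places neurons, samples the distance-dependent connectivity with fixed
#' in-degrees (partners drawn without replacement with probability
#' proportional to `exp(-D / tau_D)` in torus distance), assigns weights by
#' receiver normalization, calibrates the per-neuron I-E ratio `xi_i`
#' (mean `xi`, coefficient of variation 25% by construction) and draws
#' conduction delays uniformly on `[0, delay_max]` ms (one delay per
#' presynaptic neuron and receiver block, quantized to the integration
#' step).
#'
#' @param params a [circuit_params()] object.
#' @return a `"network_topology"` list with `positions` (data frame `id`,
#'   `pop`, `x`, `y`), per-block CSR connectivity over presynaptic index,
#'   `xi_i`, and `params`.
#' @export
build_network <- function(params = circuit_params()) {
  p <- params
  NE <- p$n_side^2
  NI <- p$N_I
  gu <- 2 * pi / p$n_side
  gx <- rep(seq_len(p$n_side) - 1L, times = p$n_side)
  gy <- rep(seq_len(p$n_side) - 1L, each = p$n_side)
  ex <- -pi + gx * gu
  ey <- -pi + gy * gu
  ix <- stats::runif(NI, -pi, pi)
  iy <- stats::runif(NI, -pi, pi)
  positions <- data.frame(
    id = seq_len(NE + NI),
    pop = rep(c("E", "I"), c(NE, NI)),
    x = c(ex, ix), y = c(ey, iy))

  # per-neuron E<-I weight value, shared across that neuron's EI synapses:
  # mean xi * J_tot_EE / K_EI, sd 25% of the mean, truncated at a small
  # positive floor; this makes xi_i = K_EI v_i / J_tot_EE with CV 25%
  m_ei <- p$xi * p$J_tot_EE / p$K_EI
  v_ei <- pmax(stats::rnorm(NE, m_ei, 0.25 * m_ei), 0.01 * m_ei)

  sample_block <- function(post_x, post_y, pre_x, pre_y, tau_D, K, w_fun,
                           same_pop = FALSE) {
    n_post <- length(post_x)
    n_pre <- length(pre_x)
    if (K > n_pre - same_pop) stop("in-degree exceeds available partners",
                                   call. = FALSE)
    pre_l <- vector("list", n_post)
    for (i in seq_len(n_post)) {
      om <- exp(-.torus_dist_gu(post_x[i], post_y[i], pre_x, pre_y, gu) /
                  tau_D)
      if (same_pop) om[i] <- 0
      pre_l[[i]] <- .sample_partners(om, K)
    }
    pre <- unlist(pre_l)
    post <- rep(seq_len(n_post), each = K)
    w <- w_fun(post)
    o <- order(pre)
    pre <- pre[o]; post <- post[o]; w <- w[o]
    ptr <- c(0L, cumsum(tabulate(pre, nbins = n_pre)))
    list(ptr = as.integer(ptr), tgt = as.integer(post), w = w)
  }

  ee <- sample_block(ex, ey, ex, ey, p$tau_D_EE, p$K_EE,
                     function(post) rep(p$J_tot_EE / p$K_EE, length(post)),
                     same_pop = TRUE)
  ie <- sample_block(ix, iy, ex, ey, p$tau_D_IE, p$K_IE,
                     function(post) rep(p$J_tot_IE / p$K_IE, length(post)))
  ei <- sample_block(ex, ey, ix, iy, p$tau_D_EI, p$K_EI,
                     function(post) v_ei[post])
  ii <- sample_block(ix, iy, ix, iy, p$tau_D_II, p$K_II,
                     function(post) rep(p$J_tot_II / p$K_II, length(post)),
                     same_pop = TRUE)

  delay_steps <- function(n) {
    as.integer(round(stats::runif(n, 0, p$delay_max) / p$dt))
  }
  topo <- list(
    NE = NE, NI = NI, positions = positions, grid_unit = gu,
    block_npre = as.integer(c(NE, NE, NI, NI)),
    block_ptr = list(ee$ptr, ie$ptr, ei$ptr, ii$ptr),
    block_tgt = list(ee$tgt, as.integer(ie$tgt + NE), ei$tgt,
                     as.integer(ii$tgt + NE)),
    block_w = list(ee$w, ie$w, ei$w, ii$w),
    block_delay = list(delay_steps(NE), delay_steps(NE), delay_steps(NI),
                       delay_steps(NI)),
    xi_i = p$K_EI * v_ei / p$J_tot_EE,
    params = p)
  class(topo) <- "network_topology"
  topo
}

#' @export
print.network_topology <- function(x, ...) {
  cat(sprintf(
    "network: %d E (%dx%d grid) + %d I; xi = %.3g (mean xi_i = %.3f, CV = %.2f)\n",
    x$NE, x$params$n_side, x$params$n_side, x$NI, x$params$xi,
    mean(x$xi_i), stats::sd(x$xi_i) / mean(x$xi_i)))
  invisible(x)
}

#' Embed a prior by perturbing excitatory weights
#'
#' Adds `c0 * phi(s_i) * phi(s_j)` to each existing E->E weight
#' (postsynaptic `i`, presynaptic `j`), where
#' `phi(s; s0, d) = exp[(cos(x - x0) + cos(y - y0)) / d^2]` is a
#' two-dimensional bell on the torus centered at the prior mean `s0` with
#' width `d`. Only existing connections are modified; no new synapses are
#' created.
#'
#' @param topology a `"network_topology"` object.
#' @param c0 perturbation magnitude (nS).
#' @param s0 prior center, length-2 (default the origin).
#' @param d width parameter (default 1.3).
#' @return the modified topology.
#' @export
apply_prior_perturbation <- function(topology, c0, s0 = c(0, 0), d = 1.3) {
  stopifnot(d > 0)
  if (c0 == 0) return(topology)
  pos <- topology$positions
  phi <- prior_bell(pos$x[seq_len(topology$NE)], pos$y[seq_len(topology$NE)],
                    s0, d)
  ptr <- topology$block_ptr[[1]]
  pre <- rep(seq_len(topology$NE), diff(ptr))
  post <- topology$block_tgt[[1]]
  topology$block_w[[1]] <- topology$block_w[[1]] + c0 * phi[pre] * phi[post]
  topology$prior <- list(c0 = c0, s0 = s0, d = d)
  topology
}

#' @rdname apply_prior_perturbation
#' @param x,y feature coordinates at which to evaluate the bell.
#' @export
prior_bell <- function(x, y, s0 = c(0, 0), d = 1.3) {
  exp((cos(x - s0[1]) + cos(y - s0[2])) / d^2)
}

#' Feedforward stimulus specification
#'
#' A probabilistic population code: every neuron receives independent
#' Poisson input whose rate is a baseline plus Gaussian bumps at the
#' stimulus features, with heights proportional to the contrasts. The
#' unimodal default uses baseline 0.85 kHz and width 0.6; the bimodal form
#' reduces the baseline to 0.5 kHz so that the region between the modes
#' stays at low probability.
#'
#' @param mode `"unimodal"` or `"bimodal"` (sets the default baseline).
#' @param r0 baseline rate in kHz; `NULL` picks the mode default.
#' @param centers matrix (one row per component) of feature-space centers.
#' @param contrasts nonnegative contrast per component.
#' @param widths Gaussian width per component.
#' @return a `"stimulus_spec"` list.
#' @export
stimulus_spec <- function(mode = c("unimodal", "bimodal"), r0 = NULL,
                          centers = NULL, contrasts = NULL, widths = NULL) {
  mode <- match.arg(mode)
  if (is.null(r0)) r0 <- if (mode == "unimodal") 0.85 else 0.5
  if (is.null(centers)) {
    centers <- if (mode == "unimodal") matrix(c(0, 0), 1) else
      rbind(c(-pi / 2, 0), c(pi / 2, 0))
  }
  centers <- matrix(centers, ncol = 2)
  k <- nrow(centers)
  if (is.null(contrasts)) contrasts <- rep(1, k)
  if (is.null(widths)) widths <- rep(0.6, k)
  if (any(contrasts < -1)) stop("contrast below -1 would give negative rates",
                                call. = FALSE)
  stopifnot(all(widths > 0), r0 >= 0, length(contrasts) == k,
            length(widths) == k)
  structure(list(mode = mode, r0 = r0, centers = centers,
                 contrasts = contrasts, widths = widths),
            class = "stimulus_spec")
}

#' Per-neuron feedforward Poisson rates
#'
#' Evaluates `lambda_i = r0 [1 + sum_k c_k exp(-||s_i - s_k||^2 /
#' (2 sigma_k^2))]` with the minimal-image (torus) metric.
#'
#' @param stimulus a [stimulus_spec()] object.
#' @param positions data frame with columns `x`, `y` (feature coordinates).
#' @return numeric vector of rates in kHz (events per ms).
#' @export
poisson_input_rates <- function(stimulus, positions) {
  s <- stimulus
  lam <- rep(1, nrow(positions))
  for (k in seq_len(nrow(s$centers))) {
    dx <- .wrap_diff(positions$x - s$centers[k, 1])
    dy <- .wrap_diff(positions$y - s$centers[k, 2])
    lam <- lam + s$contrasts[k] * exp(-(dx^2 + dy^2) / (2 * s$widths[k]^2))
  }
  s$r0 * lam
}

#' Simulate the spiking circuit
#'
#' Runs the conductance-based network for `duration` ms. With
#' `adaptation = FALSE` the potassium current is removed entirely and the
#' inhibitory synaptic strengths are rescaled by `inh_scale` (default 1.2)
#' to restore the dynamics to the transition regime. Feedforward input is
#' delivered as independent Poisson trains onto excitatory-type synapses
#' (all neurons receive the stimulus-tuned rates). Reproducible under
#' [set.seed()].
#'
#' @param topology a `"network_topology"`.
#' @param stimulus a [stimulus_spec()], or `NULL` for spontaneous activity
#'   (uniform 0.85 kHz baseline).
#' @param duration simulation length (ms), at least 100.
#' @param adaptation include spike-frequency adaptation (default `TRUE`).
#' @param inh_scale inhibitory rescaling used when adaptation is off.
#' @param record_v optional neuron id whose membrane potential is recorded.
#' @return a `"spike_data"` object (attribute `saturated` flags runaway
#'   firing; such runs abort rather than return misleading statistics).
#' @export
simulate_circuit <- function(topology, stimulus = NULL, duration = 1000,
                             adaptation = TRUE, inh_scale = 1.2,
                             record_v = NA) {
  stopifnot(inherits(topology, "network_topology"))
  if (duration < 100) stop("duration must be at least 100 ms", call. = FALSE)
  if (is.null(stimulus)) stimulus <- stimulus_spec("unimodal", contrasts = 0)
  lam <- poisson_input_rates(stimulus, topology$positions)
  isI <- topology$positions$pop == "I"
  lam[isI] <- lam[isI] * topology$params$ffwd_I_scale
  out <- circuit_simulate_cpp(topology, lam, duration, topology$params$dt,
                              adaptation, if (adaptation) 1.0 else inh_scale,
                              topology$params, ifelse(is.na(record_v), 0,
                                                      record_v))
  if (out$saturated) {
    stop("network firing rate saturated (unstable parameters)",
         call. = FALSE)
  }
  sd <- spike_data(out$times, out$ids, topology$positions, duration,
                   topology$params$dt)
  if (!is.na(record_v)) attr(sd, "vtrace") <- out$vtrace
  attr(sd, "stimulus") <- stimulus
  sd
}

#' Sweep the I-E ratio across the state transition
#'
#' For each `xi`, builds networks and simulates spontaneous activity, then
#' reports the mean local pairwise spike-count correlation (coherence of the
#' activity pattern) and the tail index fitted to center-of-mass increments.
#' Low correlation marks the asynchronous state, high correlation the
#' propagating-wave state; in the transition regime between them the
#' increment distribution becomes heavy-tailed (`alpha < 2`).
#'
#' @param xi_values I-E ratios to test (at least 3).
#' @param duration simulation length per trial (ms).
#' @param n_trials independent network realizations per `xi`.
#' @param params base [circuit_params()] (its `xi` field is overridden).
#' @param window_com center-of-mass tracking window (ms).
#' @return data frame with one row per `xi`: `xi`, `correlation`, `alpha`,
#'   `rate_e`.
#' @export
phase_sweep <- function(xi_values, duration = 4000, n_trials = 2,
                        params = circuit_params(), window_com = 15) {
  stopifnot(length(xi_values) >= 3)
  rows <- lapply(xi_values, function(xi) {
    params$xi <- xi
    cors <- numeric(n_trials)
    rates <- numeric(n_trials)
    incs <- c()
    for (tr in seq_len(n_trials)) {
      net <- build_network(params)
      spk <- simulate_circuit(net, NULL, duration)
      cors[tr] <- local_pairwise_correlation(spk)
      rates[tr] <- sum(spk$neurons$pop[spk$ids] == "E") / net$NE /
        duration * 1000
      com <- com_trajectory(spk, window = window_com)
      com <- com[stats::complete.cases(com), ]
      incs <- c(incs, diff(unwrap(com$x)), diff(unwrap(com$y)))
    }
    alpha <- if (length(incs) >= 100) fit_sas_mle(incs)$alpha else NA_real_
    data.frame(xi = xi, correlation = mean(cors), alpha = alpha,
               rate_e = mean(rates))
  })
  do.call(rbind, rows)
}

#' Locate the empirical state-transition point
#'
#' The transition I-E ratio is taken as the location of the trough of the
#' fitted tail index across a sweep (the most strongly fractional regime),
#' which coincides with the knee of the correlation curve.
#'
#' @param sweep a data frame from [phase_sweep()].
#' @return the `xi` at the alpha trough.
#' @export
locate_transition <- function(sweep) {
  sweep$xi[which.min(sweep$alpha)]
}

#' Serialize a network topology to a sparse triplet table
#'
#' @param topology a `"network_topology"`.
#' @param path output path; a tab-separated table with columns `pre`,
#'   `post`, `weight`, `delay_ms`, `block`.
#' @return `path`, invisibly.
#' @export
write_network <- function(topology, path) {
  blocks <- c("EE", "IE", "EI", "II")
  pre_off <- c(0L, 0L, topology$NE, topology$NE)
  tabs <- lapply(1:4, function(b) {
    ptr <- topology$block_ptr[[b]]
    npre <- topology$block_npre[b]
    pre <- rep(seq_len(npre), diff(ptr)) + pre_off[b]
    data.frame(pre = pre, post = topology$block_tgt[[b]],
               weight = topology$block_w[[b]],
               delay_ms = topology$block_delay[[b]][pre - pre_off[b]] *
                 topology$params$dt,
               block = blocks[b])
  })
  utils::write.table(do.call(rbind, tabs), path, row.names = FALSE,
                     sep = "\t", quote = FALSE)
  invisible(path)
}

#' Calibrate the feedforward drive against a target spontaneous rate
#'
#' Bisection on a scalar drive parameter (default the feedforward weight)
#' until the spontaneous excitatory firing rate falls inside a target band.
#' Used once to fix package defaults; exposed so alternative architectures
#' can be recalibrated.
#'
#' @param params starting [circuit_params()].
#' @param target_rate length-2 band of acceptable E rates (Hz).
#' @param what name of the scalar parameter to bisect on.
#' @param bounds search interval.
#' @param duration probe simulation length (ms).
#' @param max_iter bisection iterations.
#' @return the calibrated `circuit_params`, with attribute `rate`.
#' @export
calibrate_spontaneous_rate <- function(params = circuit_params(),
                                       target_rate = c(1, 10),
                                       what = "J_ffwd",
                                       bounds = c(0.5, 8),
                                       duration = 2000, max_iter = 8) {
  probe <- function(val) {
    params[[what]] <- val
    net <- build_network(params)
    spk <- try(simulate_circuit(net, NULL, duration), silent = TRUE)
    if (inherits(spk, "try-error")) return(Inf)
    sum(spk$neurons$pop[spk$ids] == "E") / net$NE / duration * 1000
  }
  lo <- bounds[1]; hi <- bounds[2]
  mid <- params[[what]]
  rate <- probe(mid)
  for (it in seq_len(max_iter)) {
    if (rate >= target_rate[1] && rate <= target_rate[2]) break
    if (rate < target_rate[1]) lo <- mid else hi <- mid
    mid <- (lo + hi) / 2
    rate <- probe(mid)
  }
  params[[what]] <- mid
  attr(params, "rate") <- rate
  params
}
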