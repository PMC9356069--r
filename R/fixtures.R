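#' Synthetic datasets with known ground truth
#'
#' Generators that emulate the statistical structures the analysis
#' operations assume, so every estimator can be validated by round-trip
#' without running the full spiking circuit. Each dataset carries its
#' generating parameters as the `ground_truth` attribute.
#'
#' Kinds:
#' \describe{
#'   \item{`sas_walk`}{random walk with SaS(alpha, gamma_step) increments;
#'     truth: `alpha`, `gamma_step`.}
#'   \item{`brownian_walk`}{Gaussian random walk; truth: `sd_step`.}
#'   \item{`torus_walk`}{2-D Brownian walk wrapped onto `[-pi, pi)^2`;
#'     truth: `sd_step`.}
#'   \item{`damped_cosine_process`}{stationary Gaussian process with
#'     autocorrelation `exp(-lag/tau) cos(2 pi f lag)`; truth: `tau`, `f`.}
#'   \item{`poisson_trains`}{independent homogeneous Poisson spike trains as
#'     a `"spike_data"`; truth: `rate_hz`.}
#'   \item{`modulated_poisson`}{doubly stochastic Poisson trains whose
#'     common rate switches between two levels (OU-free telegraph
#'     modulation); truth: rates and the closed-form Fano factor.}
#'   \item{`burr_durations`, `gamma_durations`}{i.i.d. durations from the
#'     named family; truth: the parameters.}
#' }
#'
#' @param kind one of the generator names above.
#' @param n number of samples / neurons / durations.
#' @param ... generator parameters (see Details above; all have defaults).
#' @return dataset in the type the matching analysis expects, with
#'   attribute `ground_truth`.
#' @export
generate_fixture <- function(kind = c("sas_walk", "brownian_walk",
                                      "torus_walk", "damped_cosine_process",
                                      "poisson_trains", "modulated_poisson",
                                      "burr_durations", "gamma_durations"),
                             n = 1e4, ...) {
  kind <- match.arg(kind)
  args <- list(...)
  g <- function(name, default) if (!is.null(args[[name]])) args[[name]] else
    default
  out <- switch(kind,
    sas_walk = {
      alpha <- g("alpha", 1.28); gam <- g("gamma_step", 1)
      x <- cumsum(sample_sas(n, alpha, gam))
      attr(x, "ground_truth") <- list(alpha = alpha, gamma_step = gam)
      x
    },
    brownian_walk = {
      sd_step <- g("sd_step", 1)
      x <- cumsum(stats::rnorm(n, sd = sd_step))
      attr(x, "ground_truth") <- list(sd_step = sd_step)
      x
    },
    torus_walk = {
      sd_step <- g("sd_step", 0.1)
      xy <- apply(matrix(stats::rnorm(2 * n, sd = sd_step), ncol = 2), 2,
                  cumsum)
      wrapped <- (xy + pi) %% (2 * pi) - pi
      attr(wrapped, "ground_truth") <- list(sd_step = sd_step,
                                            unwrapped = xy)
      wrapped
    },
    damped_cosine_process = {
      tau <- g("tau", 36); f <- g("f", 5.5e-3); dt <- g("dt", 1)
      # exact target autocorrelation exp(-|k| dt/tau) cos(2 pi f k dt),
      # realized by circulant spectral synthesis (Gaussian, stationary)
      m <- stats::nextn(2L * n, 2)
      k <- c(0:(m %/% 2), (m %/% 2 - 1):1)
      acf_target <- exp(-k * dt / tau) * cos(2 * pi * f * k * dt)
      spec <- pmax(Re(stats::fft(acf_target)), 0)
      z <- stats::rnorm(m) + 1i * stats::rnorm(m)
      x <- Re(stats::fft(sqrt(spec) * z, inverse = TRUE))[seq_len(n)] /
        sqrt(2 * m)
      attr(x, "ground_truth") <- list(tau = tau, f = f, dt = dt)
      x
    },
    poisson_trains = {
      rate <- g("rate_hz", 5); dur <- g("duration", 1e4)
      counts <- stats::rpois(n, rate * dur / 1000)
      times <- stats::runif(sum(counts), 0, dur)
      ids <- rep(seq_len(n), counts)
      nn <- data.frame(id = seq_len(n), pop = "E",
                       x = stats::runif(n, -pi, pi),
                       y = stats::runif(n, -pi, pi))
      sd <- spike_data(times, ids, nn, dur)
      attr(sd, "ground_truth") <- list(rate_hz = rate)
      sd
    },
    modulated_poisson = {
      # telegraph rate: common to all neurons, switching between r_lo and
      # r_hi with mean dwell `dwell` ms; closed-form Fano factor for long
      # windows: 1 + var(rate)/mean(rate) * window correction
      r_lo <- g("r_lo", 2); r_hi <- g("r_hi", 10); dwell <- g("dwell", 200)
      dur <- g("duration", 2e4); dt <- 1
      nsteps <- ceiling(dur / dt)
      state <- logical(nsteps); s <- FALSE
      pr <- dt / dwell
      flips <- stats::runif(nsteps) < pr
      for (i in seq_len(nsteps)) { if (flips[i]) s <- !s; state[i] <- s }
      rate <- ifelse(state, r_hi, r_lo) / 1000 # per ms
      times <- c(); ids <- c()
      for (j in seq_len(n)) {
        k <- which(stats::runif(nsteps) < rate * dt)
        times <- c(times, k * dt - stats::runif(length(k), 0, dt))
        ids <- c(ids, rep(j, length(k)))
      }
      nn <- data.frame(id = seq_len(n), pop = "E",
                       x = stats::runif(n, -pi, pi),
                       y = stats::runif(n, -pi, pi))
      sd <- spike_data(times, ids, nn, dur)
      attr(sd, "ground_truth") <- list(r_lo = r_lo, r_hi = r_hi,
                                       dwell = dwell)
      sd
    },
    burr_durations = {
      cc <- g("c", 8.05); kk <- g("k", 0.528); lam <- g("lambda", 65)
      x <- rburr(n, cc, kk, lam)
      attr(x, "ground_truth") <- list(c = cc, k = kk, lambda = lam)
      x
    },
    gamma_durations = {
      kk <- g("k", 10.4); th <- g("theta", 7.51)
      x <- stats::rgamma(n, shape = kk, scale = th)
      attr(x, "ground_truth") <- list(k = kk, theta = th)
      x
    })
  attr(out, "fixture_kind") <- kind
  out
}
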