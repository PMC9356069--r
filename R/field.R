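#' Neural-field parameters
#'
#' Parameters of the one-dimensional neural field reduction used for the
#' closed-form drift and sampled-distribution results. Lengths are in
#' feature units, time in the field's intrinsic units.
#'
#' @param a width of the homogeneous (translation-invariant) synaptic
#'   coupling.
#' @param d1 width of the stimulus-dependent feedforward input.
#' @param d0 width of the synaptic-weight perturbation that embeds the
#'   prior.
#' @param r0_height height of the localized activity (bump) profile.
#' @param tau field time constant.
#' @param gamma_noise noise strength gamma of the sampler SDE the field
#'   reduces to.
#' @param c_alpha the alpha-dependent proportionality constant of the
#'   stationary-variance formulas; treated as a free positive constant
#'   (default 1).
#' @param c1 stimulus contrast. @param c0 synaptic perturbation strength.
#' @param s1 stimulus center. @param s0 prior center.
#' @return a `"field_params"` list.
#' @export
field_params <- function(a = 0.5, d1 = 0.6, d0 = 1.3, r0_height = 1,
                         tau = 1, gamma_noise = 1, c_alpha = 1,
                         c1 = 1, c0 = 0.002, s1 = 0, s0 = 0) {
  stopifnot(a > 0, d1 > 0, d0 > 0, tau > 0, gamma_noise > 0, c_alpha > 0,
            c1 >= 0, c0 >= 0, r0_height > 0)
  structure(as.list(environment()), class = "field_params")
}

#' Closed-form drift induced by input and synaptic perturbation
#'
#' The analytic drift of the bump center: two Gaussian-windowed linear
#' restoring terms, one centered on the stimulus `s1` with magnitude
#' proportional to contrast `c1`, one centered on the prior `s0` with
#' magnitude proportional to the perturbation strength `c0`:
#' \deqn{\gamma b(x) = -c_1 \frac{2\sqrt2 a^2 d_1}{\tau (a^2+d_1^2)^{3/2}}
#'   (x-s_1) e^{-(x-s_1)^2 / [4(a^2+d_1^2)]}
#'   - c_0 r_0 \frac{4\sqrt\pi a^3 d_0^2}{\tau (a^2+d_0^2)^2}
#'   (x-s_0) e^{-(x-s_0)^2 / [\frac43 (a^2+d_0^2)]}.}
#'
#' @param x numeric vector of positions.
#' @param params a [field_params()] object.
#' @return numeric vector `b(x)` (the expression above divided by `gamma`).
#' @export
analytic_drift <- function(x, params) {
  p <- params
  t1 <- -p$c1 * 2 * sqrt(2) * p$a^2 * p$d1 /
    (p$tau * (p$a^2 + p$d1^2)^1.5) * (x - p$s1) *
    exp(-(x - p$s1)^2 / (4 * (p$a^2 + p$d1^2)))
  t0 <- -p$c0 * p$r0_height * 4 * sqrt(pi) * p$a^3 * p$d0^2 /
    (p$tau * (p$a^2 + p$d0^2)^2) * (x - p$s0) *
    exp(-(x - p$s0)^2 / (4 / 3 * (p$a^2 + p$d0^2)))
  (t1 + t0) / p$gamma_noise
}

#' Laplace-approximated sampled mixture
#'
#' For well-separated `s1` and `s0`, the stationary sampled distribution is
#' a two-component Gaussian mixture: the evidence mode at `s1` with variance
#' `kappa1 / c1` and the prior mode at `s0` with variance `kappa0 / c0`,
#' \deqn{\kappa_1 = \frac{\gamma c_\alpha \tau (a^2+d_1^2)^{3/2}}
#'   {2\sqrt2\, a^2 d_1}, \qquad
#'   \kappa_0 = \frac{\gamma c_\alpha \tau (a^2+d_0^2)^2}
#'   {4\sqrt\pi\, a^3 d_0^2 r_0},}
#' with mixture weights proportional to
#' `w1 = sqrt(2 pi kappa1/c1) exp[c1/(gamma c_alpha tau) * 4 sqrt2 a^2 d1 /
#' sqrt(a^2+d1^2)]` and
#' `w0 = sqrt(2 pi kappa0/c0) exp[c0/(gamma c_alpha tau) * 8 sqrt(pi) a^3
#' d0^2 r0 / (3 (a^2+d0^2))]`. Setting `c1 = 0` or `c0 = 0` drops the
#' corresponding mode. The approximation is flagged when the mode separation
#' is not large relative to the mode widths.
#'
#' @param x numeric vector of positions.
#' @param params a [field_params()] object.
#' @return list with `density` (values at `x`), `kappa1`, `kappa0`, `w1`,
#'   `w0`, `weight1` (normalized), `var1`, `var0`, `laplace_ok`.
#' @export
sampled_mixture <- function(x, params) {
  p <- params
  gct <- p$gamma_noise * p$c_alpha * p$tau
  kappa1 <- gct * (p$a^2 + p$d1^2)^1.5 / (2 * sqrt(2) * p$a^2 * p$d1)
  kappa0 <- gct * (p$a^2 + p$d0^2)^2 /
    (4 * sqrt(pi) * p$a^3 * p$d0^2 * p$r0_height)
  if (p$c1 == 0 && p$c0 == 0) {
    stop("both contrasts are zero: no sampled distribution", call. = FALSE)
  }
  w1 <- if (p$c1 > 0) {
    sqrt(2 * pi * kappa1 / p$c1) *
      exp(p$c1 / gct * 4 * sqrt(2) * p$a^2 * p$d1 / sqrt(p$a^2 + p$d1^2))
  } else 0
  w0 <- if (p$c0 > 0) {
    sqrt(2 * pi * kappa0 / p$c0) *
      exp(p$c0 / gct * 8 * sqrt(pi) * p$a^3 * p$d0^2 * p$r0_height /
            (3 * (p$a^2 + p$d0^2)))
  } else 0
  var1 <- if (p$c1 > 0) kappa1 / p$c1 else NA_real_
  var0 <- if (p$c0 > 0) kappa0 / p$c0 else NA_real_
  dens <- numeric(length(x))
  if (p$c1 > 0) dens <- dens + w1 * stats::dnorm(x, p$s1, sqrt(var1))
  if (p$c0 > 0) dens <- dens + w0 * stats::dnorm(x, p$s0, sqrt(var0))
  dens <- dens / (w1 + w0)
  sep <- abs(p$s1 - p$s0)
  widths <- sqrt(c(if (p$c1 > 0) var1, if (p$c0 > 0) var0))
  laplace_ok <- (p$c1 == 0 || p$c0 == 0) || sep > 3 * max(widths)
  if (!laplace_ok) {
    warning("mode separation is small relative to mode widths; ",
            "Laplace approximation may be inaccurate", call. = FALSE)
  }
  list(density = dens, kappa1 = kappa1, kappa0 = kappa0, w1 = w1, w0 = w0,
       weight1 = w1 / (w1 + w0), var1 = var1, var0 = var0,
       laplace_ok = laplace_ok)
}

#' Numerically integrate the one-dimensional neural field
#'
#' Integrates `tau du/dt = -u + Int J(x, x') F[u](x') rho dx' + I(x)` on a
#' periodic grid with exponential-Euler time stepping. The coupling is
#' `J = Jbar(x - x') + c0 Jtilde(x, x')` with a Gaussian homogeneous kernel
#' of width `a` and a separable Gaussian perturbation of width `d0`; the
#' input is `I = Ibar + c1 Itilde(x; s1) + xi(x, t)` with a Gaussian bump of
#' width `d1` and spatially smooth, temporally white noise. The activation
#' is quadratic with divisive normalization,
#' `F[u] = u+^2 / (1 + k_div rho Int u+^2)`. These kernel and activation
#' shapes are modelling choices of this package (only the resulting
#' closed-form drift/mixture expressions are fixed); they are exposed here
#' so the bump dynamics can be cross-checked against [analytic_drift()].
#'
#' @param params a [field_params()] object.
#' @param n_x grid points (default `2^10`) on `[-pi, pi)`.
#' @param dt_field time step. @param duration total integration time.
#' @param J0 homogeneous coupling strength. @param Ibar background input.
#' @param k_div divisive-normalization constant.
#' @param noise_sd amplitude of the additive noise.
#' @param noise_width spatial correlation length of the noise.
#' @param u0 initial condition (default: small bump at `s1`).
#' @param record_every record every k-th step.
#' @return list with `x` (grid), `u` (matrix time x space), `times`,
#'   `center` (bump-peak trajectory, via the population vector), `params`.
#' @export
integrate_field <- function(params, n_x = 2L^10L, dt_field = 0.01,
                            duration = 50, J0 = 8, Ibar = 0.1, k_div = 0.5,
                            noise_sd = 0, noise_width = 0.5, u0 = NULL,
                            record_every = 10L) {
  p <- params
  x <- seq(-pi, pi, length.out = n_x + 1L)[seq_len(n_x)]
  dx <- x[2] - x[1]
  rho <- 1 / dx # unit neuron density per grid cell
  wrapd <- function(d) (d + pi) %% (2 * pi) - pi
  Jbar <- J0 * exp(-wrapd(x - x[1])^2 / (2 * p$a^2))
  fftJ <- stats::fft(Jbar)
  phi0 <- exp(-wrapd(x - p$s0)^2 / (2 * p$d0^2))
  Itil <- exp(-wrapd(x - p$s1)^2 / (2 * p$d1^2))
  smooth_kernel <- exp(-wrapd(x - x[1])^2 / (2 * noise_width^2))
  fftS <- stats::fft(smooth_kernel)
  if (is.null(u0)) u0 <- 0.1 + 0.5 * exp(-wrapd(x - p$s1)^2 / (2 * p$a^2))
  u <- u0
  n_steps <- ceiling(duration / dt_field)
  n_rec <- n_steps %/% record_every
  U <- matrix(NA_real_, n_rec, n_x)
  centers <- numeric(n_rec)
  r <- 0L
  decay <- exp(-dt_field / p$tau)
  for (s in seq_len(n_steps)) {
    up <- pmax(u, 0)
    f <- up^2 / (1 + k_div * sum(up^2) * dx)
    rec <- Re(stats::fft(stats::fft(f) * fftJ, inverse = TRUE)) / n_x * dx *
      rho
    rec <- rec + p$c0 * phi0 * sum(phi0 * f) * dx * rho
    inp <- Ibar + p$c1 * Itil
    if (noise_sd > 0) {
      white <- stats::rnorm(n_x)
      xi <- Re(stats::fft(stats::fft(white) * fftS, inverse = TRUE)) / n_x
      inp <- inp + noise_sd * xi / stats::sd(xi) / sqrt(dt_field)
    }
    u_inf <- rec + inp
    u <- u_inf + (u - u_inf) * decay
    if (s %% record_every == 0L) {
      r <- r + 1L
      U[r, ] <- u
      centers[r] <- Arg(sum(pmax(u, 0) * exp(1i * x)))
    }
  }
  list(x = x, u = U, times = dt_field * record_every * seq_len(n_rec),
       center = centers, params = p)
}
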