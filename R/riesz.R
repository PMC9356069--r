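#' Riesz fractional derivatives and sampler drift fields
#'
#' The Riesz fractional derivative is the Fourier-multiplier operator
#' `D^mu[f] = F^-1 |k|^mu F[f]`. For `mu = 2` it equals the negated second
#' derivative. On a uniform grid it is approximated by the fractional centered
#' difference scheme with coefficients
#' `g_k = (-1)^k Gamma(mu+1) / (Gamma(mu/2 - k + 1) Gamma(mu/2 + k + 1))`,
#' so that `D^mu f(x_i) ~ h^-mu sum_k g_k f(x_(i-k))`. The scheme is valid for
#' any order `mu > -1`, which covers both the diffusion operator (`mu = alpha`
#' with `1 < alpha <= 2`) and the fractional integral of order `alpha - 2`
#' used to build the sampler drift.
#'
#' @name riesz
#' @keywords internal
NULL

# Fractional centered difference coefficients g_0..g_K for order mu > -1,
# via the stable recurrence g_(k+1) = g_k (k - mu/2) / (k + 1 + mu/2).
.riesz_coeffs <- function(mu, K) {
  g <- numeric(K + 1L)
  g[1] <- gamma(mu + 1) / gamma(mu / 2 + 1)^2
  k <- seq_len(K)
  ratio <- (k - 1 - mu / 2) / (k + mu / 2)
  g[-1] <- g[1] * cumprod(ratio)
  g
}

# Apply the fractional centered difference of order mu to `values` on a grid
# with step `spacing`, treating the function as zero outside the array.
# Implemented as an FFT-based convolution with the (symmetric) coefficient
# kernel truncated at the array length or where |g_k| < 1e-12 |g_0|,
# whichever comes first.
.riesz_apply <- function(values, mu, spacing) {
  n <- length(values)
  g <- .riesz_coeffs(mu, n - 1L)
  cut <- which(abs(g) < 1e-12 * abs(g[1]))
  if (length(cut)) g <- g[seq_len(min(cut))]
  K <- length(g) - 1L
  kern <- c(rev(g[-1]), g) # indices -K..K
  # constants are annihilated by the operator for mu > 0 (zero multiplier at
  # k = 0); subtract an edge-level reference before convolving so that holds
  # exactly despite kernel truncation and the implicit zero padding
  ref <- if (mu > 0) (values[1] + values[n]) / 2 else 0
  vals <- values - ref
  m <- stats::nextn(n + 2L * K, 2)
  fv <- stats::fft(c(vals, numeric(m - n)))
  fk <- stats::fft(c(kern, numeric(m - length(kern))))
  conv <- Re(stats::fft(fv * fk, inverse = TRUE)) / m
  # kernel index -K aligns with offset 0: output i sits at position i + K
  conv[K + seq_len(n)] * spacing^(-mu)
}

#' Riesz fractional derivative on a uniform grid
#'
#' Approximates `D^alpha[f] = F^-1 |k|^alpha F[f]` by the fractional centered
#' difference scheme. For `alpha = 2` this reduces (exactly, to machine
#' precision in the coefficients) to the negated second central difference.
#' Values outside the supplied array are treated as zero, so accuracy near
#' the array boundary degrades for functions that do not vanish there; supply
#' a padded grid when that matters.
#'
#' @param values numeric vector of function values on a uniform grid
#'   (length >= 8).
#' @param alpha derivative order in (1, 2].
#' @param spacing grid step, positive.
#' @return numeric vector of the same length as `values`.
#' @export
riesz_derivative <- function(values, alpha, spacing) {
  if (!is.numeric(alpha) || length(alpha) != 1L || alpha <= 1 || alpha > 2) {
    stop("`alpha` must be in (1, 2]", call. = FALSE)
  }
  if (length(values) < 8L) stop("need at least 8 grid points", call. = FALSE)
  stopifnot(spacing > 0)
  .riesz_apply(values, alpha, spacing)
}

#' Construct the sampler drift field for a target density
#'
#' Builds the drift `b(x) = D^(alpha-2)[pi(x) d/dx log pi(x)] / pi(x)`
#' whose Levy-driven dynamics have stationary law `pi(x)`. The working grid
#' is padded on both sides by 25% of its extent (the target density is
#' evaluated analytically on the padding) before the fractional centered
#' difference of order `alpha - 2` is applied; the drift is reported on the
#' interior and clipped to `[-b_max, b_max]`. For `alpha = 2` the operator is
#' the identity and the drift reduces to the score `d/dx log pi`.
#'
#' @param target either a target object created by [normal_target()] /
#'   [mixture_target()], or a function evaluating the (normalized or
#'   unnormalized) density.
#' @param alpha tail index of the driving Levy motion, in (1, 2].
#' @param b_max clipping bound on `|b|` (default 500), guarding against
#'   numeric overflow of the fractional derivative where the density is tiny.
#' @param extent half-width of the working grid. Default `NULL` auto-sizes it
#'   to cover all but `1e-6` of the target mass.
#' @param n_grid number of interior grid points (default `2^12`).
#' @return an object of class `"drift_field"`: a list with `grid`, `density`,
#'   `log_density` (`-log pi`), `drift`, `alpha`, `b_max`, `spacing`.
#' @examples
#' df <- drift_from_target(normal_target(), alpha = 2)
#' max(abs(df$drift + df$grid)) # score of N(0,1) is -x
#' @export
drift_from_target <- function(target, alpha, b_max = 500, extent = NULL,
                              n_grid = 2L^12L) {
  if (!is.numeric(alpha) || length(alpha) != 1L || alpha <= 1 || alpha > 2) {
    stop("`alpha` must be in (1, 2]", call. = FALSE)
  }
  stopifnot(b_max > 0)
  dens_fun <- if (is.function(target)) target else target$density
  if (is.null(extent)) {
    extent <- if (is.function(target)) 10 else target$extent
  }
  pad <- ceiling(0.25 * n_grid)
  h <- 2 * extent / (n_grid - 1L)
  grid_full <- seq(-extent - pad * h, extent + pad * h, by = h)
  dens_full <- dens_fun(grid_full)
  if (any(dens_full < 0)) stop("target density has negative values",
                               call. = FALSE)
  if (all(dens_full == 0)) stop("target density is identically zero",
                                call. = FALSE)
  # normalize on the working grid
  dens_full <- dens_full / (sum(dens_full) * h)
  n_full <- length(grid_full)
  if (alpha == 2) {
    # D^0 is the identity, so b is the score d/dx log pi; the central
    # difference of log pi is exact for Gaussian targets
    ld <- log(pmax(dens_full, 1e-300))
    b_full <- numeric(n_full)
    b_full[2:(n_full - 1L)] <- (ld[3:n_full] - ld[1:(n_full - 2L)]) / (2 * h)
  } else {
    # f = pi * d/dx log pi = d/dx pi, by central differences on the padded grid
    dpi <- numeric(n_full)
    dpi[2:(n_full - 1L)] <- (dens_full[3:n_full] -
                               dens_full[1:(n_full - 2L)]) / (2 * h)
    num <- .riesz_apply(dpi, alpha - 2, h)
    b_full <- num / pmax(dens_full, .Machine$double.xmin)
  }
  b_full[!is.finite(b_full)] <- 0
  b_full <- pmin(pmax(b_full, -b_max), b_max)
  interior <- seq(pad + 1L, pad + n_grid)
  structure(list(
    grid = grid_full[interior],
    density = dens_full[interior],
    log_density = -log(pmax(dens_full[interior], 1e-300)),
    drift = b_full[interior],
    alpha = alpha,
    b_max = b_max,
    spacing = h
  ), class = "drift_field")
}

#' @export
print.drift_field <- function(x, ...) {
  cat(sprintf(
    "drift field: alpha = %g, %d points on [%.3g, %.3g], b_max = %g (clipped at %d points)\n",
    x$alpha, length(x$grid), min(x$grid), max(x$grid), x$b_max,
    sum(abs(x$drift) >= x$b_max)))
  invisible(x)
}

#' Serialize a drift field to a delimited table with JSON header
#'
#' Writes a two-column table `(x, b)` preceded by commented JSON metadata
#' (`alpha`, `b_max`, `spacing`).
#'
#' @param field a `"drift_field"` object.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_drift_field <- function(field, path) {
  hdr <- jsonlite::toJSON(list(alpha = field$alpha, b_max = field$b_max,
                               spacing = field$spacing), auto_unbox = TRUE)
  writeLines(paste0("# ", as.character(hdr)), path)
  suppressWarnings(
    utils::write.table(data.frame(x = field$grid, b = field$drift), path,
                       append = TRUE, row.names = FALSE, col.names = TRUE,
                       sep = "\t", quote = FALSE))
  invisible(path)
}

#' Verify the fractional momentum identity
#'
#' With the momentum marginal `psi(v)` chosen as the SaS(alpha, 1/alpha)
#' density and kinetic potential `T(v) = -log psi(v)`, the fractional drift
#' of the momentum coordinate collapses to the identity map:
#' `D_v^(alpha-2)[psi(v) T'(v)] / psi(v) = v`. This is what licenses writing
#' the position update's momentum coupling as `beta * v` in the sampler. The
#' check evaluates the left-hand side numerically on a padded grid and
#' returns the sup-norm deviation from `v` on the requested interior.
#'
#' @param alpha tail index in (1, 2].
#' @param v_max interior half-width on which the deviation is measured.
#' @param n_grid number of grid points for the evaluation.
#' @return maximum absolute deviation from the identity on `|v| <= v_max`.
#' @export
momentum_drift_identity_check <- function(alpha, v_max = 3, n_grid = 2L^12L) {
  psi <- function(v) sas_pdf(v, alpha, gamma = 1 / alpha)
  field <- drift_from_target(psi, alpha, b_max = Inf, extent = 4 * v_max,
                             n_grid = n_grid)
  # psi * T'(v) = -psi'(v), so the identity's left side is minus the drift
  # field built from psi as a target
  keep <- abs(field$grid) <= v_max
  max(abs(-field$drift[keep] - field$grid[keep]))
}
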