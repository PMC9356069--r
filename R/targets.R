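#' Target distributions for the mathematical sampler
#'
#' @description
#' `normal_target()` is the standard normal benchmark. `mixture_target()` is
#' the equal-weight two-Gaussian mixture with modes at `+/- s_star` and
#' common width `sigma`; the defaults (`s_star = 2.5`, `sigma = 0.32`) place
#' the modes far apart relative to their width, so the inter-modal region is
#' a high potential barrier `U(x) = -log pi(x)` that Brownian-driven samplers
#' essentially cannot cross.
#'
#' @param mean,sd mean and standard deviation of the normal target.
#' @param s_star half the modal separation of the mixture.
#' @param sigma common mode width.
#' @return a `"sampling_target"` object: list with `density` (vectorized
#'   function), `mean` (true mean), `extent` (half-width covering all but
#'   1e-6 of the mass), and mixture metadata where applicable.
#' @examples
#' tg <- mixture_target()
#' integrate(tg$density, -10, 10)$value
#' @export
normal_target <- function(mean = 0, sd = 1) {
  structure(list(
    density = function(x) stats::dnorm(x, mean, sd),
    mean = mean,
    sd = sd,
    extent = abs(mean) + 6 * sd,
    kind = "normal"
  ), class = "sampling_target")
}

#' @rdname normal_target
#' @export
mixture_target <- function(s_star = 2.5, sigma = 0.32) {
  stopifnot(sigma > 0)
  structure(list(
    density = function(x) {
      0.5 * stats::dnorm(x, -s_star, sigma) +
        0.5 * stats::dnorm(x, s_star, sigma)
    },
    mean = 0,
    s_star = s_star,
    sigma = sigma,
    modes = c(-s_star, s_star),
    extent = s_star + 6 * sigma,
    kind = "mixture"
  ), class = "sampling_target")
}

# inverse-CDF sampling from the tabulated density of a drift field
.sample_from_field <- function(field, n) {
  cdf <- cumsum(field$density)
  cdf <- cdf / cdf[length(cdf)]
  u <- stats::runif(n)
  idx <- findInterval(u, cdf) + 1L
  idx <- pmin(idx, length(field$grid))
  jitter <- stats::runif(n, -0.5, 0.5) * field$spacing
  field$grid[idx] + jitter
}
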