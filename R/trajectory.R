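#' Unwrap a trajectory on the circle
#'
#' Converts wrapped coordinates in `[-pi, pi)` to continuous linear
#' coordinates: each increment is taken as the minimal-image displacement
#' (the representative of the step in `(-pi, pi]`), and the cumulative sum
#' reconstructs a continuous path so that distances across the periodic
#' boundary are handled correctly.
#'
#' @param x numeric vector of wrapped coordinates.
#' @return numeric vector of unwrapped coordinates, starting at `x[1]`.
#' @examples
#' unwrap(c(3.0, -3.0))  # increment is +0.283, not -6
#' @export
unwrap <- function(x) {
  if (length(x) < 2L) return(x)
  d <- diff(x)
  d <- (d + pi) %% (2 * pi) - pi
  x[1] + c(0, cumsum(d))
}

# minimal-image displacement on [-pi, pi)
.wrap_diff <- function(d) (d + pi) %% (2 * pi) - pi

#' Mean squared displacement and diffusion exponent
#'
#' Computes `MSD(lag) = <|| s(t + lag) - s(t) ||^2>` over all overlapping
#' pairs of an (unwrapped) trajectory, and fits the anomalous-diffusion
#' exponent `eta` in `MSD ~ lag^eta` by least squares on the log-log curve
#' over `fit_range`. `eta = 1` is Brownian motion; `eta > 1` superdiffusion.
#'
#' @param traj numeric matrix (rows = time points, columns = coordinates) or
#'   vector; coordinates must already be unwrapped.
#' @param dt sampling interval of the trajectory (time units per row).
#' @param lags integer vector of lags (in samples) at which to evaluate the
#'   MSD.
#' @param fit_range numeric length-2: time-lag interval used for the eta fit.
#' @param mode `"time"` (default): displacement pairs pooled over all start
#'   times, the usual single-recording estimator, with the matrix columns
#'   treated as coordinates of one path. `"ensemble"`: columns are
#'   independent realizations and the MSD at lag L is taken across
#'   realizations of the displacement from the common origin. For walks with
#'   i.i.d. heavy-tailed increments the time-averaged MSD is linear in the
#'   lag regardless of the tail (ergodicity breaking), so superdiffusion is
#'   only visible in the ensemble statistic.
#' @param statistic `"mean"` or `"median"` (median is robust for
#'   infinite-variance increments; it estimates the squared typical
#'   displacement, whose scaling exponent is the same).
#' @return list with `msd` (data frame `lag`, `msd`), `eta`, and the fit.
#' @export
msd_and_eta <- function(traj, dt = 1, lags = NULL,
                        fit_range = c(min(lags) * dt, max(lags) * dt),
                        mode = c("time", "ensemble"),
                        statistic = c("mean", "median")) {
  mode <- match.arg(mode)
  statistic <- match.arg(statistic)
  stat <- if (statistic == "mean") {
    function(v) mean(v, na.rm = TRUE)
  } else {
    function(v) stats::median(v, na.rm = TRUE)
  }
  m <- as.matrix(traj)
  n <- nrow(m)
  if (is.null(lags)) lags <- unique(round(exp(seq(0, log(n / 10),
                                                  length.out = 30L))))
  lags <- lags[lags >= 1 & lags < n]
  if (n < 100L) stop("trajectory too short for MSD", call. = FALSE)
  msd <- vapply(lags, function(L) {
    if (mode == "time") {
      d <- m[(L + 1L):n, , drop = FALSE] - m[1:(n - L), , drop = FALSE]
      stat(rowSums(d^2))
    } else {
      stat((m[1L + L, ] - m[1L, ])^2)
    }
  }, numeric(1))
  tl <- lags * dt
  sel <- tl >= fit_range[1] & tl <= fit_range[2] & msd > 0
  if (sum(sel) < 3L) stop("fewer than 3 lags in the fitting range",
                          call. = FALSE)
  fit <- stats::lm(log(msd[sel]) ~ log(tl[sel]))
  list(msd = data.frame(lag = tl, msd = msd),
       eta = unname(stats::coef(fit)[2]), fit = fit)
}

#' Tail index of trajectory increments
#'
#' Takes non-overlapping increments of the trajectory at interval `dt_step`
#' samples (by default the coordinates are pooled) and fits a symmetric
#' alpha-stable law by maximum likelihood.
#'
#' @param traj matrix (time x coordinates) of unwrapped positions, or vector.
#' @param dt_step increment interval in samples (non-overlapping).
#' @param pool if `TRUE` (default) the increments of all coordinates are
#'   pooled into one fit; otherwise a list of per-coordinate fits is
#'   returned.
#' @return a `"sas_fit"` (or list of them when `pool = FALSE`).
#' @export
increment_tail_index <- function(traj, dt_step = 1L, pool = TRUE) {
  m <- as.matrix(traj)
  idx <- seq(1L, nrow(m), by = dt_step)
  incs <- apply(m[idx, , drop = FALSE], 2, diff)
  # rows with undefined positions (e.g. silent tracking windows) yield NA
  # increments on both sides of the gap and are excluded from the fit
  if (pool) {
    fit_sas_mle(as.vector(incs)[is.finite(as.vector(incs))])
  } else {
    apply(incs, 2, function(v) fit_sas_mle(v[is.finite(v)]),
          simplify = FALSE)
  }
}

#' Dwell times between the modes of a bimodal trajectory
#'
#' Assigns every time point to the nearer of two mode centers and returns the
#' dwell (exit) durations between alternations: the time the path stays
#' closer to one center before first becoming strictly closer to the other.
#' Equidistant points inherit the previous assignment. The first and last
#' (censored) dwell intervals are reported separately so that completed
#' durations plus censored tails exactly partition the trajectory.
#'
#' @param traj positions: a numeric vector (1-D), or a two-column matrix
#'   (2-D feature coordinates).
#' @param s1,s2 mode centers (scalars in 1-D, length-2 in 2-D).
#' @param dt sampling interval (duration units per step).
#' @param torus if `TRUE`, distances use the minimal-image (torus) metric on
#'   `[-pi, pi)^2`; use for circuit trajectories, not the open-boundary
#'   mathematical model.
#' @return an `"exit_times"` object: list with `durations` (completed dwell
#'   times), `censored` (first and last partial intervals), `assignments`,
#'   `mean_exit`, `total_time`.
#' @export
exit_times <- function(traj, s1, s2, dt = 1, torus = FALSE) {
  m <- as.matrix(traj)
  if (identical(as.numeric(s1), as.numeric(s2))) {
    stop("mode centers must be distinct", call. = FALSE)
  }
  dfun <- function(center) {
    d <- sweep(m, 2, center)
    if (torus) d <- .wrap_diff(d)
    rowSums(d^2)
  }
  closer1 <- dfun(s1) < dfun(s2)
  equid <- dfun(s1) == dfun(s2)
  a <- ifelse(closer1, 1L, 2L)
  for (i in which(equid)) a[i] <- if (i > 1L) a[i - 1L] else 1L
  r <- rle(a)
  n_runs <- length(r$lengths)
  if (n_runs == 1L) {
    return(structure(list(durations = numeric(0),
                          censored = r$lengths * dt,
                          assignments = a, mean_exit = NA_real_,
                          total_time = length(a) * dt,
                          switched = FALSE), class = "exit_times"))
  }
  # each dwell that ends in a switch is a completed exit time (including the
  # first: the exit clock starts at t = 0); only the final dwell is censored
  completed <- r$lengths[1:(n_runs - 1L)] * dt
  structure(list(
    durations = as.numeric(completed),
    censored = r$lengths[n_runs] * dt,
    assignments = a,
    mean_exit = if (length(completed)) mean(completed) else NA_real_,
    total_time = length(a) * dt,
    switched = TRUE
  ), class = "exit_times")
}

#' @export
print.exit_times <- function(x, ...) {
  cat(sprintf("exit times: %d completed dwells, mean = %.3g (total T = %.3g)\n",
              length(x$durations), x$mean_exit, x$total_time))
  invisible(x)
}

#' Fit a damped-cosine (or pure exponential) path autocorrelation
#'
#' Computes the autocorrelation of the mean-subtracted trajectory (averaged
#' over coordinates) and fits `exp(-lag/tau) * cos(2 pi f lag)` by bounded
#' nonlinear least squares with a multi-start over `f`. A pure exponential
#' (`f = 0`) is also fitted; the model with the lower AICc is selected, so an
#' oscillation is only reported when the data support one.
#'
#' @param traj matrix (time x coordinates) or vector; stationary segment.
#' @param dt sampling interval.
#' @param max_lag largest lag (in time units) entering the fit.
#' @param f_starts initial frequencies for the multi-start.
#' @return list with `tau`, `f` (`NA` when the exponential wins), `model`
#'   (`"damped_cosine"` or `"exponential"`), `acf` (data frame `lag`, `acf`),
#'   and both fits.
#' @export
path_autocorrelation_fit <- function(traj, dt = 1, max_lag = NULL,
                                     f_starts = NULL) {
  m <- as.matrix(traj)
  n <- nrow(m)
  if (is.null(max_lag)) max_lag <- n * dt / 10
  nl <- min(n - 2L, ceiling(max_lag / dt))
  ac <- rowMeans(vapply(seq_len(ncol(m)), function(j) {
    a <- stats::acf(m[, j], lag.max = nl, plot = FALSE,
                    demean = TRUE)$acf[, 1, 1]
    a
  }, numeric(nl + 1L)))
  lag <- dt * (0:nl)
  df <- data.frame(lag = lag, acf = ac)
  w <- lag > 0
  rss_exp <- function(tau) sum((ac[w] - exp(-lag[w] / tau))^2)
  opt_exp <- stats::optimize(rss_exp, c(dt / 10, max_lag * 10))
  nobs <- sum(w)
  aicc <- function(rss, k) {
    nobs * log(rss / nobs) + 2 * k + 2 * k * (k + 1) / (nobs - k - 1)
  }
  if (is.null(f_starts)) f_starts <- c(0.5, 1, 2, 4, 8, 16) / max_lag
  best <- NULL
  for (f0 in f_starts) {
    fit <- try(stats::nls(
      y ~ exp(-x / tau) * cos(2 * pi * f * x),
      data = data.frame(x = lag[w], y = ac[w]),
      start = list(tau = opt_exp$minimum, f = f0),
      lower = c(tau = dt / 10, f = 0), upper = c(tau = Inf, f = 0.5 / dt),
      algorithm = "port",
      control = stats::nls.control(warnOnly = TRUE)), silent = TRUE)
    if (!inherits(fit, "try-error")) {
      rss <- sum(stats::residuals(fit)^2)
      if (is.null(best) || rss < best$rss) {
        best <- list(fit = fit, rss = rss)
      }
    }
  }
  # require a genuine oscillation: at least half a cycle must fit inside
  # the fitted lag window, otherwise the cosine is just re-fitting a slow
  # trend and the exponential model is reported
  use_cos <- !is.null(best) &&
    aicc(best$rss, 2) < aicc(opt_exp$objective, 1) - 2 &&
    stats::coef(best$fit)[["f"]] * max_lag >= 0.5
  if (use_cos) {
    cf <- stats::coef(best$fit)
    list(tau = unname(cf["tau"]), f = unname(cf["f"]),
         model = "damped_cosine", acf = df, fit = best$fit,
         tau_exponential = opt_exp$minimum)
  } else {
    list(tau = opt_exp$minimum, f = NA_real_, model = "exponential",
         acf = df, fit = NULL, tau_exponential = opt_exp$minimum)
  }
}

#' Empirical drift field from an ensemble of trajectories
#'
#' Estimates the deterministic drift `b(x)` by binning single-step increments
#' of the (unwrapped) coordinate by position and averaging `increment / dt`
#' within bins, across time and trials; the Levy noise averages out while the
#' drift survives. Empty bins are reported as `NA`, not zero.
#'
#' @param trajs list of numeric vectors (one coordinate per trial), or a
#'   matrix with one column per trial.
#' @param dt time step between consecutive positions.
#' @param breaks bin boundaries for the position axis.
#' @param trim per-bin trimming fraction applied to the increment mean,
#'   guarding the estimate against rare giant Levy jumps (default 0.01).
#' @return data frame with `x` (bin centers), `b` (mean increment rate),
#'   `se`, `n`.
#' @export
estimate_drift_field <- function(trajs, dt, breaks, trim = 0.01) {
  if (is.matrix(trajs)) trajs <- asplit(trajs, 2)
  xs <- unlist(lapply(trajs, function(x) x[-length(x)]))
  dx <- unlist(lapply(trajs, diff))
  bin <- cut(xs, breaks = breaks, labels = FALSE)
  centers <- (breaks[-1] + breaks[-length(breaks)]) / 2
  out <- data.frame(x = centers, b = NA_real_, se = NA_real_, n = 0L)
  for (k in seq_along(centers)) {
    v <- dx[which(bin == k)] / dt
    out$n[k] <- length(v)
    if (length(v) >= 2L) {
      out$b[k] <- mean(v, trim = trim)
      out$se[k] <- stats::sd(v) / sqrt(length(v))
    }
  }
  out
}

#' Time-averaged sample variance of trajectories
#'
#' For each trajectory, the variance of the path around its own time average,
#' `(1/T) Int (x_t - xbar_T)^2 dt` - the spread of the sampled distribution.
#'
#' @param trajs list of numeric vectors or a matrix with one column per
#'   trial.
#' @return numeric vector of per-trial sample variances.
#' @export
sample_path_variance <- function(trajs) {
  if (is.matrix(trajs)) trajs <- asplit(trajs, 2)
  vapply(trajs, function(x) mean((x - mean(x))^2), numeric(1))
}
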