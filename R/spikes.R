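#' Spike data container
#'
#' A light container for spike events plus per-neuron metadata.
#'
#' @param times spike times in ms.
#' @param ids integer neuron ids (1-based).
#' @param neurons data frame with one row per neuron: columns `id`, `pop`
#'   (`"E"` or `"I"`), `x`, `y` (feature coordinates in `[-pi, pi)`).
#' @param duration total recording duration in ms.
#' @param dt simulation step in ms.
#' @return a `"spike_data"` object.
#' @export
spike_data <- function(times, ids, neurons, duration, dt = NA_real_) {
  stopifnot(length(times) == length(ids))
  o <- order(times)
  structure(list(times = as.numeric(times)[o], ids = as.integer(ids)[o],
                 neurons = neurons, duration = duration, dt = dt),
            class = "spike_data")
}

#' @export
print.spike_data <- function(x, ...) {
  cat(sprintf("spike data: %d events from %d neurons over %.0f ms (%.2f Hz/neuron)\n",
              length(x$times), nrow(x$neurons), x$duration,
              1000 * length(x$times) / nrow(x$neurons) / x$duration))
  invisible(x)
}

#' Write spike data as delimited text with a JSON sidecar
#'
#' @param spikes a `"spike_data"` object.
#' @param path output path for the two-column event table
#'   (`time_ms`, `neuron_id`); neuron metadata goes to `<path>.json`.
#' @return `path`, invisibly.
#' @export
write_spike_data <- function(spikes, path) {
  utils::write.table(data.frame(time_ms = spikes$times,
                                neuron_id = spikes$ids),
                     path, row.names = FALSE, sep = "\t", quote = FALSE)
  meta <- list(duration = spikes$duration, dt = spikes$dt,
               neurons = spikes$neurons)
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

# spike-count matrix: neurons x windows
.count_matrix <- function(spikes, window, ids = NULL, t0 = 0,
                          t1 = spikes$duration) {
  if (is.null(ids)) ids <- spikes$neurons$id
  edges <- seq(t0, t1, by = window)
  nw <- length(edges) - 1L
  sel <- spikes$ids %in% ids & spikes$times >= t0 & spikes$times < edges[nw + 1L]
  wi <- findInterval(spikes$times[sel], edges, rightmost.closed = FALSE)
  ni <- match(spikes$ids[sel], ids)
  counts <- matrix(0L, length(ids), nw)
  if (any(sel)) {
    tab <- table(factor(ni, levels = seq_along(ids)),
                 factor(wi, levels = seq_len(nw)))
    counts <- matrix(as.integer(tab), length(ids), nw)
  }
  dimnames(counts) <- NULL
  counts
}

#' Population-vector center of mass of a spiking pattern
#'
#' The circular mean of spike positions in a trailing window:
#' `x_hat = Arg sum_j n_j exp(i x_j)` over excitatory neurons (and likewise
#' for `y`), where `n_j` counts neuron `j`'s spikes in `[t - window, t)`.
#' This is the complex (population-vector) estimator, equivalent to a
#' least-squares cosine fit to the spike counts. A zero resultant (perfectly
#' cancelling counts) has no defined argument and raises an error rather than
#' returning a silent 0.
#'
#' @param spikes a `"spike_data"` object.
#' @param t evaluation time (ms).
#' @param window trailing window length in ms (default 15).
#' @return named numeric `c(x, y)` in `[-pi, pi)`.
#' @export
center_of_mass <- function(spikes, t, window = 15) {
  sel <- spikes$times >= (t - window) & spikes$times < t &
    spikes$neurons$pop[spikes$ids] == "E"
  if (!any(sel)) stop("no excitatory spikes in window", call. = FALSE)
  ids <- spikes$ids[sel]
  zx <- sum(exp(1i * spikes$neurons$x[ids]))
  zy <- sum(exp(1i * spikes$neurons$y[ids]))
  if (Mod(zx) < 1e-12 || Mod(zy) < 1e-12) {
    stop("zero resultant: center of mass undefined", call. = FALSE)
  }
  c(x = Arg(zx), y = Arg(zy))
}

#' Center-of-mass trajectory
#'
#' Evaluates the population-vector center of mass on a regular grid of times;
#' times whose window holds no excitatory spike (or a zero resultant) yield
#' `NA` and are flagged.
#'
#' @inheritParams center_of_mass
#' @param step spacing of evaluation times in ms.
#' @return data frame with columns `t`, `x`, `y`, `n` (spikes in window).
#' @export
com_trajectory <- function(spikes, window = 15, step = window) {
  e_ids <- spikes$neurons$id[spikes$neurons$pop == "E"]
  sel <- spikes$ids %in% e_ids
  st <- spikes$times[sel]
  sx <- spikes$neurons$x[spikes$ids[sel]]
  sy <- spikes$neurons$y[spikes$ids[sel]]
  ts <- seq(window, spikes$duration, by = step)
  o <- order(st)
  st <- st[o]; sx <- sx[o]; sy <- sy[o]
  lo <- findInterval(ts - window, st) + 1L
  hi <- findInterval(ts - 1e-9, st)
  ex <- cumsum(exp(1i * sx)); ey <- cumsum(exp(1i * sy))
  ex <- c(0, ex); ey <- c(0, ey)
  zx <- ex[hi + 1L] - ex[lo]
  zy <- ey[hi + 1L] - ey[lo]
  n <- hi - lo + 1L
  bad <- n < 1L | Mod(zx) < 1e-12 | Mod(zy) < 1e-12
  data.frame(t = ts, x = ifelse(bad, NA_real_, Arg(zx)),
             y = ifelse(bad, NA_real_, Arg(zy)), n = n)
}

#' Mean local pairwise spike-count correlation
#'
#' Divides the excitatory grid into non-overlapping square patches (default
#' 9 x 9 grid units, 49 patches for a 63 x 63 sheet), computes all pairwise
#' Pearson correlations of spike counts (100 ms windows) within each patch,
#' and averages. Weak values indicate asynchronous firing; strong values a
#' spatially coherent pattern. Silent neurons (zero count variance) are
#' excluded from pairs.
#'
#' @param spikes a `"spike_data"` object whose E population sits on a square
#'   grid.
#' @param patch patch side length in grid units (default 9).
#' @param window spike-count window in ms (default 100).
#' @return mean correlation coefficient (scalar).
#' @export
local_pairwise_correlation <- function(spikes, patch = 9L, window = 100) {
  en <- spikes$neurons[spikes$neurons$pop == "E", ]
  side <- round(sqrt(nrow(en)))
  # grid indices 0..side-1 recovered from feature coordinates
  gx <- round((en$x + pi) / (2 * pi) * side) %% side
  gy <- round((en$y + pi) / (2 * pi) * side) %% side
  px <- gx %/% patch
  py <- gy %/% patch
  counts <- .count_matrix(spikes, window, ids = en$id)
  if (ncol(counts) < 10L) stop("need at least 10 count windows",
                               call. = FALSE)
  patches <- split(seq_len(nrow(en)), paste(px, py))
  cors <- unlist(lapply(patches, function(rows) {
    cm <- t(counts[rows, , drop = FALSE])
    keep <- apply(cm, 2, stats::sd) > 0
    if (sum(keep) < 2L) return(NULL)
    cc <- stats::cor(cm[, keep, drop = FALSE])
    cc[upper.tri(cc)]
  }))
  mean(cors)
}

#' Spike-count Fano factors
#'
#' Variance over mean of per-neuron spike counts in fixed windows (default
#' 100 ms). Neurons with zero mean count are excluded (`NA`). When a
#' stimulus center is given, each neuron's torus distance between its
#' preferred feature (its coordinates) and the stimulus is attached, giving
#' the Fano-factor tuning curve.
#'
#' @param spikes a `"spike_data"` object.
#' @param window window length in ms.
#' @param stim_center optional length-2 feature-space stimulus center.
#' @param pop population to include (default `"E"`).
#' @return data frame with `id`, `ff`, `mean_count` and (with a stimulus)
#'   `dist`.
#' @export
fano_factor <- function(spikes, window = 100, stim_center = NULL,
                        pop = "E") {
  nn <- spikes$neurons[spikes$neurons$pop %in% pop, ]
  counts <- .count_matrix(spikes, window, ids = nn$id)
  if (ncol(counts) < 20L) stop("need at least 20 windows", call. = FALSE)
  mu <- rowMeans(counts)
  va <- apply(counts, 1, stats::var)
  out <- data.frame(id = nn$id, ff = ifelse(mu > 0, va / mu, NA_real_),
                    mean_count = mu)
  if (!is.null(stim_center)) {
    dx <- .wrap_diff(nn$x - stim_center[1])
    dy <- .wrap_diff(nn$y - stim_center[2])
    out$dist <- sqrt(dx^2 + dy^2)
  }
  out
}

#' Power spectral density of the population firing rate
#'
#' Bins the population rate (default 1 ms), splits it into 50%-overlapping
#' segments (default 2 s), and averages Hann-windowed modified periodograms.
#' Reports the peak frequency in a low-frequency band (default 3-8 Hz,
#' theta) and the power-law exponent of the high-frequency tail from a
#' log-log fit (default 15-100 Hz).
#'
#' @param spikes a `"spike_data"` object (or a numeric vector already binned
#'   at `bin` ms).
#' @param bin rate bin in ms.
#' @param segment segment length in ms.
#' @param peak_band frequency band (Hz) searched for the spectral peak.
#' @param tail_band frequency band (Hz) for the power-law tail fit.
#' @return list with `psd` (data frame `freq`, `power`), `peak_freq`,
#'   `tail_exponent`.
#' @export
population_rate_psd <- function(spikes, bin = 1, segment = 2000,
                                peak_band = c(3, 8),
                                tail_band = c(15, 100)) {
  rate <- if (inherits(spikes, "spike_data")) {
    edges <- seq(0, spikes$duration, by = bin)
    tabulate(findInterval(spikes$times, edges, rightmost.closed = FALSE),
             nbins = length(edges) - 1L) / (bin / 1000)
  } else {
    as.numeric(spikes)
  }
  nseg <- floor(segment / bin)
  if (length(rate) < 2L * nseg) stop("recording too short for the segment length",
                                     call. = FALSE)
  hop <- nseg %/% 2L
  starts <- seq(1L, length(rate) - nseg + 1L, by = hop)
  win <- 0.5 * (1 - cos(2 * pi * seq_len(nseg) / (nseg + 1)))
  fs <- 1000 / bin
  acc <- NULL
  for (s in starts) {
    seg <- rate[s:(s + nseg - 1L)]
    seg <- (seg - mean(seg)) * win
    pg <- Mod(stats::fft(seg))^2 / (sum(win^2) * fs)
    acc <- if (is.null(acc)) pg else acc + pg
  }
  pg <- acc / length(starts)
  freq <- fs * (seq_len(nseg) - 1L) / nseg
  keep <- freq > 0 & freq <= fs / 2
  psd <- data.frame(freq = freq[keep], power = 2 * pg[keep])
  pk <- psd[psd$freq >= peak_band[1] & psd$freq <= peak_band[2], ]
  peak_freq <- pk$freq[which.max(pk$power)]
  tl <- psd[psd$freq >= tail_band[1] & psd$freq <= tail_band[2] &
              psd$power > 0, ]
  fit <- stats::lm(log(power) ~ log(freq), data = tl)
  list(psd = psd, peak_freq = peak_freq,
       tail_exponent = unname(stats::coef(fit)[2]))
}

#' Unwrapped center-of-mass path with gaps preserved
#'
#' Unwraps the `x` and `y` columns of a [com_trajectory()] data frame onto
#' the line using minimal-image steps between consecutive defined windows
#' (a gap is crossed with a single minimal-image step), keeping `NA` rows
#' where the pattern was untrackable so downstream lag statistics can skip
#' them.
#'
#' @param com data frame from [com_trajectory()].
#' @return two-column matrix (`x`, `y`) of unwrapped coordinates with `NA`s.
#' @export
com_unwrapped <- function(com) {
  ok <- stats::complete.cases(com[, c("x", "y")])
  ux <- rep(NA_real_, nrow(com))
  uy <- ux
  ux[ok] <- unwrap(com$x[ok])
  uy[ok] <- unwrap(com$y[ok])
  cbind(x = ux, y = uy)
}
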