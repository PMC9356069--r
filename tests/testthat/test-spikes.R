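make_spikes <- function(times, ids, nn, duration) {
  spike_data(times, ids, nn, duration)
}

test_that("center of mass reduces to the position of a lone active neuron", {
  nn <- data.frame(id = 1:2, pop = "E", x = c(1.2, -2), y = c(-0.4, 2))
  spk <- make_spikes(c(5, 8, 11), c(1, 1, 1), nn, 20)
  expect_equal(center_of_mass(spk, t = 15), c(x = 1.2, y = -0.4))
})

test_that("zero resultant raises an error instead of returning zero", {
  nn <- data.frame(id = 1:2, pop = "E", x = c(-pi / 2, pi / 2), y = c(0, 0))
  spk <- make_spikes(c(5, 6), c(1, 2), nn, 20)
  expect_error(center_of_mass(spk, t = 10), "resultant")
  # and no spikes at all
  expect_error(center_of_mass(spk, t = 300), "no excitatory spikes")
})

test_that("cosine-profile counts give back the profile center", {
  # counts n_j ~ 1 + cos(x_j - mu): the population vector equals mu, the
  # least-squares cosine fit location
  side <- 60
  xs <- seq(-pi, pi, length.out = side + 1)[1:side]
  mu <- 0.83
  nn <- data.frame(id = seq_len(side), pop = "E", x = xs, y = 0.3)
  counts <- round(50 * (1 + cos(xs - mu)))
  spk <- make_spikes(rep(5, sum(counts)), rep(seq_len(side), counts), nn, 20)
  com <- center_of_mass(spk, t = 10)
  expect_equal(unname(com["x"]), mu, tolerance = 2 * pi / side)
  # independent oracle: least-squares cosine fit on the binned counts
  ls_fit <- optimize(function(m) {
    a <- sum(counts * cos(xs - m)) / sum(cos(xs - m)^2)
    sum((counts - mean(counts) - a * cos(xs - m))^2)
  }, c(mu - 1, mu + 1))$minimum
  expect_equal(unname(com["x"]), ls_fit, tolerance = 2 * pi / side)
})

test_that("com_trajectory marks untrackable windows as NA and unwraps with gaps", {
  nn <- data.frame(id = 1:2, pop = c("E", "I"), x = c(0.5, 1), y = c(0, 0))
  spk <- make_spikes(c(10, 11, 80, 81), c(1, 1, 1, 1), nn, 100)
  com <- com_trajectory(spk, window = 15, step = 15)
  expect_true(any(is.na(com$x)))
  expect_true(any(!is.na(com$x)))
  m <- com_unwrapped(com)
  expect_equal(m[!is.na(m[, 1]), 1], rep(0.5, sum(!is.na(m[, 1]))))
})

test_that("Fano factor of homogeneous Poisson trains is one", {
  set.seed(21)
  spk <- generate_fixture("poisson_trains", n = 200, rate_hz = 8,
                          duration = 1e5)
  ff <- fano_factor(spk)
  expect_equal(mean(ff$ff, na.rm = TRUE), 1, tolerance = 0.05)
})

test_that("rate-modulated trains are over-dispersed", {
  set.seed(22)
  spk <- generate_fixture("modulated_poisson", n = 60, r_lo = 1, r_hi = 15,
                          dwell = 500, duration = 3e4)
  ff <- fano_factor(spk)
  expect_gt(mean(ff$ff, na.rm = TRUE), 1.3)
})

test_that("Fano tuning attaches torus distances to the stimulus", {
  nn <- data.frame(id = 1:3, pop = "E", x = c(0, 3, -3), y = 0)
  set.seed(23)
  spk <- make_spikes(runif(600, 0, 5000), sample(1:3, 600, TRUE), nn, 5000)
  ff <- fano_factor(spk, stim_center = c(0, 0))
  expect_equal(ff$dist[1], 0)
  # x = 3 and x = -3 are both ~0.28 on the torus... no: distance to 0 is 3
  expect_equal(ff$dist[2], 3)
  expect_equal(ff$dist[3], 3)
})

test_that("local pairwise correlation separates independent from co-modulated populations", {
  side <- 18
  nn <- data.frame(id = seq_len(side^2), pop = "E",
                   x = rep(seq(-pi, pi, length.out = side + 1)[1:side],
                           each = side),
                   y = rep(seq(-pi, pi, length.out = side + 1)[1:side],
                           times = side))
  dur <- 2e4
  set.seed(24)
  # independent Poisson
  counts <- rpois(side^2, 5 * dur / 1000)
  spk_ind <- make_spikes(runif(sum(counts), 0, dur),
                         rep(seq_len(side^2), counts), nn, dur)
  c_ind <- local_pairwise_correlation(spk_ind, patch = 6L)
  expect_lt(abs(c_ind), 0.02)
  # common telegraph rate modulation
  set.seed(25)
  nwin <- dur / 100
  gain <- rep(rbinom(nwin, 1, 0.5) * 28 + 2, each = 100) / 1000
  tgrid <- seq_len(dur) - 0.5
  times <- c(); ids <- c()
  for (j in seq_len(side^2)) {
    k <- which(runif(dur) < gain)
    times <- c(times, tgrid[k]); ids <- c(ids, rep(j, length(k)))
  }
  spk_mod <- make_spikes(times, ids, nn, dur)
  c_mod <- local_pairwise_correlation(spk_mod, patch = 6L)
  expect_gt(c_mod, 0.3)
})

test_that("population-rate spectrum finds a planted oscillation", {
  set.seed(26)
  dur <- 3e4
  rate <- 40 * (1 + 0.8 * sin(2 * pi * 6 * seq_len(dur) / 1000)) / 1000
  counts <- rpois(dur, rate * 200)  # 200 neurons pooled
  ps <- population_rate_psd(counts, bin = 1)
  expect_equal(ps$peak_freq, 6, tolerance = 0.1)
  # white-noise rate: flat spectrum
  set.seed(27)
  ps2 <- population_rate_psd(rpois(3e4, 5), bin = 1)
  expect_lt(abs(ps2$tail_exponent), 0.1)
})

test_that("spike data round-trips through the text format", {
  nn <- data.frame(id = 1:3, pop = c("E", "E", "I"), x = c(0, 1, 2),
                   y = c(0, -1, 2))
  spk <- make_spikes(c(3.5, 1.2, 9.9), c(2, 1, 3), nn, 10)
  path <- tempfile(fileext = ".tsv")
  write_spike_data(spk, path)
  tab <- read.delim(path)
  expect_equal(tab$time_ms, c(1.2, 3.5, 9.9))
  meta <- jsonlite::fromJSON(paste0(path, ".json"))
  expect_equal(meta$duration, 10)
  expect_equal(meta$neurons$pop, c("E", "E", "I"))
})
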