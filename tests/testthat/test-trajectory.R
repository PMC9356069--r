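test_that("unwrapping takes minimal-image steps across the boundary", {
  u <- unwrap(c(3.0, -3.0))
  expect_equal(diff(u), 2 * pi - 6, tolerance = 1e-12)
  expect_equal(unwrap(rep(1.3, 5)), rep(1.3, 5))
  # a wrapped Brownian walk unwraps to (approximately) the original line path
  set.seed(1)
  steps <- rnorm(5000, sd = 0.1)
  path <- cumsum(steps)
  wrapped <- (path + pi) %% (2 * pi) - pi
  expect_equal(unwrap(wrapped), path - path[1] + wrapped[1],
               tolerance = 1e-9)
})

test_that("MSD of Brownian motion is linear (eta = 1)", {
  set.seed(2)
  w <- generate_fixture("brownian_walk", n = 2e4)
  res <- msd_and_eta(w, dt = 1, lags = round(exp(seq(0, log(200),
                                                     length.out = 15))))
  expect_equal(res$eta, 1, tolerance = 0.05)
})

test_that("Levy walks are superdiffusive and the tail index round-trips", {
  # superdiffusion of iid-increment Levy walks lives in the ensemble MSD
  # (the time-averaged MSD is linear for any iid increments); the median
  # across realizations estimates the typical squared displacement, which
  # scales as lag^(2/alpha)
  etas <- c(); alphas <- c()
  for (s in 1:5) {
    set.seed(s)
    ens <- replicate(500, generate_fixture("sas_walk", n = 250, alpha = 1.5))
    res <- msd_and_eta(ens, dt = 1,
                       lags = round(exp(seq(0, log(200), length.out = 15))),
                       mode = "ensemble", statistic = "median")
    etas <- c(etas, res$eta)
    set.seed(s + 50)
    w <- generate_fixture("sas_walk", n = 2e4, alpha = 1.5, gamma_step = 1)
    alphas <- c(alphas, increment_tail_index(w)$alpha)
  }
  expect_true(all(etas > 1.2))
  expect_equal(mean(etas), 2 / 1.5, tolerance = 0.1)
  expect_lt(max(abs(alphas - 1.5)), 0.06)
})

test_that("exit times partition a constructed path", {
  # 50 steps at mode 1, 30 at mode 2, 20 back at mode 1
  path <- c(rep(-2.5, 50), rep(2.5, 30), rep(-2.5, 20))
  et <- exit_times(path, -2.5, 2.5, dt = 1)
  expect_equal(et$durations, c(50, 30))
  expect_equal(et$censored, 20)
  expect_equal(sum(et$durations) + sum(et$censored), et$total_time)
  expect_equal(et$mean_exit, 40)
})

test_that("a non-switching path yields a censored record, not durations", {
  et <- exit_times(rep(1, 100), 2, -2, dt = 0.5)
  expect_false(et$switched)
  expect_length(et$durations, 0)
  expect_equal(et$censored, 50)
})

test_that("equidistant points inherit the previous assignment", {
  path <- c(-1, 0, 0, 1)  # zeros are equidistant from -1 and 1... using modes +-1
  et <- exit_times(path, -1, 1, dt = 1)
  # first two zeros stay with mode 1, so one switch at the end
  expect_equal(et$durations, 3)
  expect_equal(et$censored, 1)
})

test_that("torus metric changes assignments near the boundary", {
  # point at 3.0 is closer to -pi/2... on the torus it is closer to a center
  # at -3.0 (distance ~0.28) than to 0 (distance 3.0)
  et <- exit_times(matrix(c(3.0, 0), 1), c(-3.0, 0), c(0, 0), torus = TRUE)
  expect_equal(et$assignments, 1L)
  et2 <- exit_times(matrix(c(3.0, 0), 1), c(-3.0, 0), c(0, 0), torus = FALSE)
  expect_equal(et2$assignments, 2L)
})

test_that("damped-cosine autocorrelation parameters are recovered", {
  set.seed(3)
  x <- generate_fixture("damped_cosine_process", n = 6e4, tau = 36,
                        f = 5.5e-3, dt = 1)
  fit <- suppressWarnings(path_autocorrelation_fit(x, dt = 1, max_lag = 400))
  expect_equal(fit$model, "damped_cosine")
  expect_equal(fit$tau, 36, tolerance = 0.12)
  expect_equal(fit$f, 5.5e-3, tolerance = 0.1)
})

test_that("an AR(1) path selects the pure exponential model", {
  set.seed(4)
  x <- as.numeric(arima.sim(list(ar = 0.95), 2e4))
  fit <- suppressWarnings(path_autocorrelation_fit(x, dt = 1, max_lag = 200))
  expect_equal(fit$model, "exponential")
  expect_true(is.na(fit$f))
  expect_equal(fit$tau, -1 / log(0.95), tolerance = 0.2)
})

test_that("empirical drift recovers the generator's field", {
  set.seed(5)
  tg <- normal_target()
  dr <- drift_from_target(tg, 2)
  cfg <- sampler_variant("langevin", n_steps = 2e4, n_chains = 30)
  tr <- simulate_fns(dr, cfg)
  breaks <- seq(-2, 2, by = 0.5)
  est <- estimate_drift_field(tr$positions, dt = cfg$dt, breaks = breaks)
  truth <- -est$x
  ok <- is.finite(est$b)
  expect_true(all(abs(est$b[ok] - truth[ok]) < pmax(3 * est$se[ok], 0.05)))
})

test_that("pure noise shows no significant drift", {
  set.seed(6)
  trajs <- replicate(30, cumsum(rnorm(500, sd = 0.1)), simplify = FALSE)
  est <- estimate_drift_field(trajs, dt = 1, breaks = seq(-2, 2, by = 1),
                              trim = 0)
  ok <- is.finite(est$b) & est$n > 50
  expect_true(all(abs(est$b[ok]) < 3 * est$se[ok]))
})

test_that("sample-path variance scales with planted noise amplitude", {
  set.seed(7)
  v <- sapply(c(1, 2), function(s) {
    mean(sample_path_variance(replicate(20, rnorm(2000, sd = s),
                                        simplify = FALSE)))
  })
  expect_equal(v[2] / v[1], 4, tolerance = 0.1)
})
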