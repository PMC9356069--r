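# one small network shared across the structural tests
set.seed(101)
net_small <- build_network(small_circuit_params())

test_that("network construction honours counts, placement and calibration", {
  p <- net_small$params
  expect_equal(net_small$NE, 225L)
  expect_equal(net_small$NI, 60L)
  pos <- net_small$positions
  expect_true(all(pos$x >= -pi & pos$x < pi))
  # E population forms the square grid
  ex <- sort(unique(pos$x[pos$pop == "E"]))
  expect_length(ex, 15L)
  expect_equal(diff(ex), rep(2 * pi / 15, 14), tolerance = 1e-12)
  # fixed in-degrees per block: E<-E block has K_EE edges per receiver
  expect_equal(length(net_small$block_tgt[[1]]), 225L * p$K_EE)
  expect_equal(length(net_small$block_tgt[[3]]), 225L * p$K_EI)
  expect_equal(max(table(net_small$block_tgt[[1]])), p$K_EE)
  # receiver normalization: summed E<-E weight equals J_tot_EE
  w_by_post <- tapply(net_small$block_w[[1]], net_small$block_tgt[[1]], sum)
  expect_equal(as.numeric(w_by_post), rep(p$J_tot_EE, 225L), tolerance = 1e-9)
})

test_that("full-size network matches the published architecture and xi calibration", {
  set.seed(102)
  net <- build_network(circuit_params())
  expect_equal(net$NE, 3969L)
  expect_equal(net$NI, 1000L)
  expect_equal(mean(net$xi_i), 3.4, tolerance = 0.03 / 3.4)
  cv <- sd(net$xi_i) / mean(net$xi_i)
  expect_equal(cv, 0.25, tolerance = 0.15)
})

test_that("connection frequency decays exponentially with torus distance", {
  # pool the E<-E edges of several small networks and compare the
  # distance histogram against the sampling weight exp(-D / tau_D)
  set.seed(103)
  p <- small_circuit_params()
  dists <- c()
  for (r in 1:5) {
    net <- build_network(p)
    pre <- rep(seq_len(net$NE), diff(net$block_ptr[[1]]))
    post <- net$block_tgt[[1]]
    pos <- net$positions
    dx <- ((pos$x[pre] - pos$x[post] + pi) %% (2 * pi)) - pi
    dy <- ((pos$y[pre] - pos$y[post] + pi) %% (2 * pi)) - pi
    dists <- c(dists, sqrt(dx^2 + dy^2) / net$grid_unit)
  }
  h <- hist(dists, breaks = seq(0, 11, by = 0.5), plot = FALSE)
  # divide out the annulus measure (~ 2 pi D) to recover the kernel
  kern <- h$density / pmax(h$mids, 0.25)
  keep <- h$mids > 0.5 & h$mids < 6 & kern > 0
  slope <- coef(lm(log(kern[keep]) ~ h$mids[keep]))[2]
  expect_equal(unname(slope), -1 / p$tau_D_EE, tolerance = 0.2)
})

test_that("prior perturbation follows the separable bell on the torus", {
  d <- 1.3
  # bell value at the center and at the antipode
  expect_equal(prior_bell(0, 0, c(0, 0), d), exp(2 / d^2))
  expect_equal(prior_bell(pi, pi, c(0, 0), d), exp(-2 / d^2))
  net2 <- apply_prior_perturbation(net_small, c0 = 0.5, s0 = c(0, 0), d = d)
  # only E->E weights change, additively by c0 * phi_i * phi_j
  expect_identical(net2$block_w[[3]], net_small$block_w[[3]])
  pre <- rep(seq_len(net_small$NE), diff(net_small$block_ptr[[1]]))
  post <- net_small$block_tgt[[1]]
  pos <- net_small$positions
  dw <- net2$block_w[[1]] - net_small$block_w[[1]]
  expect_equal(dw, 0.5 * prior_bell(pos$x[pre], pos$y[pre], c(0, 0), d) *
                 prior_bell(pos$x[post], pos$y[post], c(0, 0), d),
               tolerance = 1e-12)
  expect_true(all(dw > 0))
  # c0 = 0 is the identity
  net3 <- apply_prior_perturbation(net_small, c0 = 0)
  expect_identical(net3$block_w[[1]], net_small$block_w[[1]])
})

test_that("feedforward rates follow the population-code profile", {
  pos <- net_small$positions
  # zero contrast: uniform baseline 0.85 kHz
  lam0 <- poisson_input_rates(stimulus_spec("unimodal", contrasts = 0), pos)
  expect_true(all(lam0 == 0.85))
  # a neuron at the stimulus center sees rate r0 (1 + c)
  # center the stimulus on an actual grid neuron
  ctr <- c(pos$x[5], pos$y[5])
  stim <- stimulus_spec("unimodal", centers = ctr, contrasts = 1)
  lam <- poisson_input_rates(stim, pos)
  expect_equal(lam[5], 2 * 0.85)
  # profile value at a known offset follows the Gaussian in torus distance
  d5_8 <- sqrt(min(abs(pos$x[8] - ctr[1]), 2 * pi - abs(pos$x[8] - ctr[1]))^2 +
               min(abs(pos$y[8] - ctr[2]), 2 * pi - abs(pos$y[8] - ctr[2]))^2)
  expect_equal(lam[8], 0.85 * (1 + exp(-d5_8^2 / (2 * 0.6^2))))
  # bimodal default baseline is 0.5 kHz
  lamb <- poisson_input_rates(stimulus_spec("bimodal",
                                            contrasts = c(0, 0)), pos)
  expect_true(all(lamb == 0.5))
  # the profile respects the torus metric: antipodal neuron sees the same
  # rate as one 2*pi away
  expect_error(stimulus_spec("unimodal", contrasts = -1.5), "contrast")
})

test_that("simulation semantics: silence, refractoriness, determinism", {
  # no input and no initial suprathreshold state: no spikes at all
  quiet <- stimulus_spec("unimodal", r0 = 0, contrasts = 0)
  set.seed(104)
  spk0 <- simulate_circuit(net_small, quiet, duration = 300)
  expect_length(spk0$times, 0L)
  # with drive: every inter-spike interval respects the 4 ms refractory time
  set.seed(105)
  spk <- simulate_circuit(net_small, NULL, duration = 1500)
  expect_gt(length(spk$times), 100L)
  isis <- unlist(tapply(spk$times, spk$ids, function(t) diff(sort(t))))
  expect_gte(min(isis), 4)
  # bit-for-bit reproducibility under the seed
  set.seed(106); a <- simulate_circuit(net_small, NULL, duration = 400)
  set.seed(106); b <- simulate_circuit(net_small, NULL, duration = 400)
  expect_identical(a$times, b$times)
  expect_identical(a$ids, b$ids)
  expect_error(simulate_circuit(net_small, NULL, duration = 50),
               "at least 100")
})

test_that("runaway firing is flagged, not silently returned", {
  p <- small_circuit_params(J_ffwd = 40, J_tot_IE = 1, xi = 0.01,
                            ffwd_I_scale = 1)  # absurd drive
  set.seed(107)
  net <- build_network(p)
  expect_error(simulate_circuit(net, NULL, duration = 1000), "saturated")
})
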