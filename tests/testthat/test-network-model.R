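test_that("connectivity matrix honours its construction contract", {
  cfg <- net_config(n = 196, sigma = 4, lambda = 0.9, seed = 3)
  wm <- build_weights(cfg)
  # eigenvalue scaling: largest |eigenvalue| equals lambda
  ev <- max(Mod(eigen(wm$w, only.values = TRUE)$values))
  expect_lt(abs(ev - 0.9), 1e-6)
  expect_true(all(diag(wm$w) == 0))
  # inhibitory columns non-positive, excitatory non-negative
  expect_true(all(wm$w[, wm$inhibitory] <= 0))
  expect_true(all(wm$w[, !wm$inhibitory] >= 0))
  # determinism
  expect_identical(wm$w, build_weights(cfg)$w)

  cfg_big <- net_config(n = 1600, alpha_inh = 0.2, seed = 1)
  wm_big <- build_weights(cfg_big)
  expect_equal(sum(wm_big$inhibitory), 320)
  expect_equal(sum(!wm_big$inhibitory), 1280)

  expect_error(net_config(n = 1500), "perfect square")
})

test_that("weights fall off with torus distance as a Gaussian of width sigma", {
  cfg <- net_config(n = 1600, sigma = 4, alpha_inh = 0, lambda = 1,
                    seed = 5)
  wm <- build_weights(cfg)
  pos <- grid_positions(1600, 40)
  r <- torus_dist(pos, pos, 40)
  m1 <- mean(wm$w[r == 1])
  m20 <- mean(wm$w[r == 20])
  # expected ratio exp(-1/32) / exp(-400/32) for sigma = 4
  expect_lt(abs(log(m1 / m20) - (400 - 1) / 32), 0.5)
})

test_that("firing probabilities implement the clamped input sum", {
  w <- matrix(c(0, -2, 0.5, 0,
                0, 0, 0, 0,
                0, 0, 0, 0,
                3, 0, 0, 0), 4, 4, byrow = TRUE)
  s <- c(0, 1, 1, 0)
  p <- firing_probabilities(w, s)
  expect_equal(p, c(0, 0, 0, 0))          # sum <= 0 -> 0; no input -> 0
  s2 <- c(1, 0, 1, 0)
  expect_equal(firing_probabilities(w, s2), c(0.5, 0, 0, 1))  # >= 1 -> 1
  # arbitrary weights never leave [0, 1]
  set.seed(6)
  wr <- matrix(rnorm(100, sd = 5), 10, 10)
  for (i in 1:20) {
    p <- firing_probabilities(wr, rbinom(10, 1, 0.5))
    expect_true(all(p >= 0 & p <= 1))
  }
})

test_that("single-step Bernoulli rates match their probabilities", {
  w <- matrix(c(0, 0.5, 0, 0), 2, 2, byrow = TRUE)  # w[1,2] = 0.5
  s <- c(0, 1)
  set.seed(8)
  fired <- replicate(1e4, net_step(s, w)[1])
  expect_lt(abs(mean(fired) - 0.5), 0.02)
})

test_that("phase behaviour matches the eigenvalue regime", {
  # lambda = 0: no propagation, only the driven neuron fires
  cfg0 <- net_config(n = 64, lambda = 0, max_t = 50, n_monitor = 0,
                     seed = 2)
  tr0 <- simulate_net(build_weights(cfg0), seed = 3)
  expect_true(all(tr0$S == 1 / 64))

  cfg_sup <- net_config(lambda = 1.5, max_t = 400, seed = 1)
  tr_sup <- simulate_net(build_weights(cfg_sup), max_t = 400, seed = 2)
  expect_gt(mean(tr_sup$S[201:400, 1]), 0.5)

  cfg_sub <- net_config(lambda = 0.7, max_t = 400, seed = 1)
  tr_sub <- simulate_net(build_weights(cfg_sub), max_t = 400, seed = 2)
  expect_lt(mean(tr_sub$S[, 1]), 0.05)
})

test_that("simulation is reproducible under a fixed seed", {
  cfg <- net_config(n = 100, lambda = 0.9, max_t = 200, n_monitor = 10,
                    seed = 4)
  wm <- build_weights(cfg)
  t1 <- simulate_net(wm, runs = 3, seed = 7)
  t2 <- simulate_net(wm, runs = 3, seed = 7)
  expect_identical(t1$S, t2$S)
  expect_identical(t1$monitor, t2$monitor)
  expect_false(identical(t1$S, simulate_net(wm, runs = 3, seed = 8)$S))
})

test_that("expected activity matches exhaustive enumeration on 4 neurons", {
  cfg <- net_config(n = 4, sigma = 4, alpha_inh = 0.25, lambda = 0.8,
                    max_t = 3, n_monitor = 0, seed = 9)
  wm <- build_weights(cfg)
  expected <- enumerate_expected_activity(wm$w, steps = 3)
  tr <- simulate_net(wm, runs = 1e5, max_t = 3, seed = 10)
  observed <- rowMeans(tr$S)
  # Monte-Carlo error: sd(S) <= 0.5 at N = 4, so SE <= 0.0016
  expect_true(all(abs(observed - expected) < 0.008))
})

test_that("model TC uses the half-decay rule on the activity trace", {
  # shuffled trace: floor of one step
  set.seed(11)
  s <- abs(rnorm(2000))
  expect_equal(model_tc(sample(s))$value, 1)
  expect_error(model_tc(rep(0.5, 2000)), "variance")
  # slowly decaying trace yields larger TC than white noise
  ar <- as.numeric(arima.sim(list(ar = 0.98), 2000))
  expect_gt(model_tc(ar)$value, model_tc(s)$value)
})

test_that("model SC pools monitored-pair correlations by torus distance", {
  set.seed(12)
  pos <- cbind(c(0, 1, 20, 21), c(0, 0, 0, 0))
  base <- rbinom(2000, 1, 0.3)
  mon <- cbind(base, base, 1 - base, 1 - base)
  # identical near pair and identical far pair, anti-correlated across
  sc_near <- model_sc(mon, pos, k = 40, interval = c(1, 2))
  expect_equal(sc_near, 1)
  # shuffled traces: near zero
  mon_sh <- apply(mon, 2, sample)
  expect_lt(abs(model_sc(mon_sh, pos, k = 40, interval = c(1, 30))), 0.1)
  expect_error(model_sc(matrix(1, 100, 3), pos[1:3, ], k = 40), "constant")
})

test_that("reduced excitability lowers TC and SC at criticality", {
  ac <- aed_contrast(cfg = net_config(lambda = 1, max_t = 1200),
                     runs = 40, seed = 21)
  expect_lt(ac$summary$mean_tc[2], ac$summary$mean_tc[1])
  expect_lt(ac$summary$mean_sc[2], ac$summary$mean_sc[1])
  expect_error(aed_contrast(runs = 10), "at least 30")
})

test_that("raising inhibition acts like reduced excitability", {
  ac <- aed_contrast(cfg = net_config(lambda = 1, max_t = 1200),
                     f_exc_values = NULL, f_inh_values = c(1, 1.25),
                     runs = 40, seed = 22)
  expect_lt(ac$summary$mean_tc[2], ac$summary$mean_tc[1])
  expect_lt(ac$summary$mean_sc[2], ac$summary$mean_sc[1])
})

test_that("power iteration agrees with dense eigendecomposition", {
  set.seed(13)
  for (i in 1:3) {
    m <- matrix(runif(400), 20, 20) - 0.1
    expect_lt(abs(spectral_radius(m) -
                    max(Mod(eigen(m, only.values = TRUE)$values))), 1e-7)
  }
})
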