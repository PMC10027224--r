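test_that("segment grids match the overlap settings", {
  # 10-min series at 8 Hz
  segs <- segment_indices(4800, 8, 120, 0.75)
  expect_equal(nrow(segs), 17)             # (600 - 120) / 30 + 1
  expect_equal(diff(segs$start_s[1:2]), 30)
  segs0 <- segment_indices(4800, 8, 120, 0)
  expect_equal(nrow(segs0), 5)
  expect_equal(nrow(segment_indices(480, 8, 120, 0.75)), 0)  # 60-s series
  # validity propagates from dropped samples
  valid <- rep(TRUE, 4800)
  valid[1000] <- FALSE
  segs_v <- segment_indices(4800, 8, 120, 0, valid = valid)
  expect_equal(segs_v$valid, c(TRUE, FALSE, TRUE, TRUE, TRUE))
})

test_that("autocorrelation estimator matches the AR(1) closed form", {
  set.seed(2)
  x <- as.numeric(arima.sim(list(ar = 0.9), 960))
  curve <- acf_curve(x, fs = 8)
  expect_equal(curve$values[1], 1)
  expect_lt(max(abs(curve$values[2:11] - 0.9^(1:10))), 0.1)
  expect_error(acf_curve(rep(1, 960)), "variance")
})

test_that("shuffled segments stay inside the white-noise band", {
  set.seed(4)
  x <- rnorm(960)
  curve <- acf_curve(x, fs = 8)
  frac <- mean(abs(curve$values[-1]) < 3 / sqrt(960))
  expect_gte(frac, 0.95)
})

test_that("half-decay rule honours floor, crossing and cap", {
  lags <- (0:480) / 8
  # exponential decay, tau = 2 s, fixed zero baseline: first grid point at
  # or past 0.125 + 2 log 2 (threshold crossing solved in closed form)
  curve <- structure(list(lags = lags, values = exp(-lags / 2),
                          baseline = 0), class = "acf_curve")
  tc <- tc_half_decay(curve)
  expect_equal(tc$value, 1.625)
  expect_false(tc$floor)
  expect_false(tc$capped)

  # first-lag value below the baseline: floor at one lag
  a <- c(1, 0.05, rep(0.4, 479))
  tcf <- tc_half_decay(structure(list(lags = lags, values = a,
                                      baseline = c(40, 60)),
                                 class = "acf_curve"))
  expect_equal(tcf$value, 0.125)
  expect_true(tcf$floor)

  # no crossing: capped at the maximum lag
  tcc <- tc_half_decay(structure(list(lags = lags, values = rep(1, 481),
                                      baseline = c(40, 60)),
                                 class = "acf_curve"))
  expect_equal(tcc$value, 60)
  expect_true(tcc$capped)

  expect_error(tc_half_decay(structure(
    list(lags = (0:80) / 8, values = rep(1, 81), baseline = c(40, 60)),
    class = "acf_curve")), "baseline")
})

test_that("no input yields TC below one lag", {
  set.seed(7)
  for (maker in list(function() rnorm(960),
                     function() as.numeric(arima.sim(list(ar = 0.95), 960)),
                     function() cumsum(rnorm(960)),
                     function() rep(c(0, 1), 480) + rnorm(960, sd = 0.01))) {
    tc <- tc_half_decay(acf_curve(maker(), fs = 8))
    expect_gte(tc$value, 0.125)
  }
})

test_that("distance-binned correlations recover degenerate geometries", {
  el <- gen_electrodes(8, "grid", seed = 3)
  # identical channels: every populated bin at 1
  base <- rnorm(960)
  ps_same <- power_series(matrix(base, 960, 8))
  prof <- cross_corr_by_distance(ps_same, el)
  expect_true(all(abs(prof$mean_r - 1) < 1e-12))

  # independent channels: pooled bin means near zero
  el64 <- gen_electrodes(64, "grid", seed = 1)
  ps_ind <- power_series(matrix(rnorm(4800 * 64), 4800, 64))
  prof_ind <- cross_corr_by_distance(ps_ind, el64)
  big <- prof_ind$n_values >= 50
  expect_true(any(big))
  expect_true(all(abs(prof_ind$mean_r[big]) < 0.05))

  # shared signal with equal noise: pairwise r -> 0.5
  sh <- rnorm(4800)
  ps_sh <- power_series(sh + matrix(rnorm(4800 * 16), 4800, 16))
  prof_sh <- cross_corr_by_distance(ps_sh, gen_electrodes(16, "grid",
                                                          seed = 2))
  big <- prof_sh$n_values >= 50
  expect_true(all(abs(prof_sh$mean_r[big] - 0.5) < 0.05))
})

test_that("SC averages populated bins inside the interval", {
  prof <- data.frame(center = c(5.5, 10.5, 30.5, 78.5, 85.5),
                     mean_r = c(0.9, 0.3, 0.3, 0.3, 0.9),
                     n_pairs = 1, n_values = 1)
  class(prof) <- c("dist_profile", "data.frame")
  expect_equal(as.numeric(sc_mean(prof)), 0.3)
  expect_equal(attr(sc_mean(prof), "n_bins"), 3)
  # interval variants are configuration
  expect_equal(as.numeric(sc_mean(prof, c(9, 50))), 0.3)
  expect_equal(as.numeric(sc_mean(prof, c(50, 79))), 0.3)
  expect_error(sc_mean(prof, c(95, 99)), "no populated bins")
})

test_that("DFA recovers known Hurst exponents", {
  set.seed(11)
  wn <- rnorm(4000)
  expect_lt(abs(dfa_hurst(wn)$H - 0.5), 0.1)
  pink <- make_pink_noise(4000, seed = 12)
  expect_lt(abs(dfa_hurst(pink)$H - 1), 0.15)
  # shuffling whitens any series
  shuffled <- sample(pink)
  expect_lt(abs(dfa_hurst(shuffled)$H - 0.5), 0.1)
  expect_error(dfa_hurst(rnorm(1500)), "shorter")
  expect_gte(length(dfa_hurst(wn)$scales), 5)
})

test_that("TC ranking is robust to the baseline window choice", {
  # segments spanning a genuine range of timescales
  el <- gen_electrodes(6, "grid", seed = 2)
  tc_a <- tc_b <- tc_c <- numeric(0)
  for (tau in seq(1, 8, length.out = 8)) {
    cfg <- synth_config(n_channels = 6, duration = 240, tau_env = tau,
                        seed = 130 + round(10 * tau))
    ps <- envelope_power_series(cfg, el)
    tc_a <- c(tc_a, tc_series(ps, baseline = c(40, 60))$tc)
    tc_b <- c(tc_b, tc_series(ps, baseline = c(15, 30))$tc)
    tc_c <- c(tc_c, tc_series(ps, baseline = 0)$tc)
  }
  expect_gt(cor(tc_a, tc_b, method = "spearman"), 0.9)
  expect_gt(cor(tc_a, tc_c, method = "spearman"), 0.9)
})

test_that("TC and SC co-vary under a common slow modulator", {
  el <- gen_electrodes(12, "grid", seed = 2)
  set.seed(14)
  m <- runif(30)
  tc <- sc <- numeric(30)
  for (i in seq_along(m)) {
    cfg <- synth_config(n_channels = 12, duration = 120,
                        tau_env = 1 + 7 * m[i], ell_space = 5 + 40 * m[i],
                        seed = 300 + i)
    ps <- envelope_power_series(cfg, el)
    tc[i] <- mean(tc_series(ps)$tc, na.rm = TRUE)
    sc[i] <- as.numeric(sc_mean(cross_corr_by_distance(ps, el)))
  }
  expect_gt(cor(tc, sc, method = "spearman"), 0.5)
  # destroyed by shuffling the pairing
  set.seed(15)
  expect_lt(abs(cor(tc, sample(sc), method = "spearman")), 0.45)
})
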