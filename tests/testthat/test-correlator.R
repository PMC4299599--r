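test_that("multi-tau equals the brute-force estimator on shared lags", {
  set.seed(101)
  n <- 2e4
  x <- rpois(n, 2) + c(rep(0, n / 2), rpois(n / 2, 0.5))  # non-stationary
  y <- rpois(n, 1.5)
  mt <- fccstools:::cpp_multitau(as.numeric(x), as.numeric(y), 1e-5, 16L,
                                 max_lag = 0.02)
  direct <- correlate_direct(as.numeric(x), as.numeric(y), 1:32)
  # level-0 lags (pre-coarsening) must agree to float tolerance
  expect_equal(mt$G[1:32], direct, tolerance = 1e-12)
  expect_equal(mt$lags[1:32], (1:32) * 1e-5)
})

test_that("constant and empty signals give zero correlation", {
  const <- rep(7, 5000)
  mt <- fccstools:::cpp_multitau(const, const, 1e-5, 16L, 1e-3)
  expect_true(all(abs(mt$G) < 1e-12))
  zero <- rep(0, 5000)
  mt0 <- fccstools:::cpp_multitau(zero, zero, 1e-5, 16L, 1e-3)
  expect_true(all(mt0$G == 0))
})

test_that("independent Poisson channels show no cross-correlation", {
  set.seed(55)
  tr <- photon_trace(rpois(2e5, 1.2), rpois(2e5, 0.8), 1e-5)
  cv <- correlate(tr, pair = "gr")
  z <- cv$G / cv$G_sem
  expect_gt(mean(abs(z) < 3), 0.97)
  expect_lt(abs(mean(z)), 0.5)
})

test_that("cross-correlation is symmetric in the channel order", {
  sp <- fccs_species("ab", D = 2, concentration = 5e-8, brightness_g = 9000,
                     brightness_r = 5000)
  spec <- fccs_simspec(sp, fccs_optics(), duration = 4, seed = 31)
  tr <- simulate_trace(spec)
  gr <- correlate(tr, pair = "gr")
  rg <- correlate(tr, pair = "rg")
  sem <- sqrt(gr$G_sem^2 + rg$G_sem^2)
  expect_gt(mean(abs(gr$G - rg$G) < 3 * sem), 0.97)
})

test_that("detrending is a no-op on a stationary trace", {
  sp <- fccs_species("x", D = 3, concentration = 1e-7, brightness_g = 9000)
  spec <- fccs_simspec(sp, fccs_optics(), duration = 6, seed = 13)
  tr <- simulate_trace(spec)
  det <- detrend_local_average(tr, window = 2)
  expect_equal(mean(det$counts_g), mean(tr$counts_g), tolerance = 0.01)
  cv0 <- correlate(tr, pair = "gg")
  cv1 <- correlate(det, pair = "gg")
  idx <- 1:30
  expect_true(all(abs(cv1$G[idx] - cv0$G[idx]) <
                    pmax(cv0$G_sem[idx], 1e-6)))
  # reported mean rate must reflect the uncorrected photon flux
  expect_equal(cv1$mean_rate_i, mean(tr$counts_g) / tr$bin_width)
})

test_that("a noise-free exponential decay detrends to a constant", {
  bw <- 1e-3
  t <- (0:9999) * bw
  f <- 100 * exp(-0.022 * t)  # ~20% loss over 10 s
  tr <- photon_trace(f, f, bw)
  det <- detrend_local_average(tr, window = 1)
  # constant at the trace mean, up to shrinking-edge-window residue
  f0 <- mean(f)
  expect_lt(max(abs(det$counts_g - f0)) / f0, 0.02)
  interior <- det$counts_g[1000:9000]
  expect_lt((max(interior) - min(interior)) / mean(interior), 5e-3)
})

test_that("detrending removes a 20% photobleaching trend", {
  sp <- fccs_species("x", D = 3, concentration = 1e-7, brightness_g = 9000,
                     bleach_rate = 0.028)  # ~20% loss over 8 s
  spec <- fccs_simspec(sp, fccs_optics(), duration = 8, seed = 14)
  tr <- simulate_trace(spec)
  det <- detrend_local_average(tr, window = 2)
  wm <- colMeans(matrix(det$counts_g, nrow = 4e4))  # 0.4 s windows
  p <- summary(lm(wm ~ seq_along(wm)))$coefficients[2, 4]
  expect_gt(p, 0.05)
  # while the raw trace does trend
  wm0 <- colMeans(matrix(tr$counts_g, nrow = 4e4))
  p0 <- summary(lm(wm0 ~ seq_along(wm0)))$coefficients[2, 4]
  expect_lt(p0, 0.01)
})

test_that("detrend window validation", {
  tr <- photon_trace(rpois(1000, 1), rpois(1000, 1), 1e-3)
  expect_error(detrend_local_average(tr, window = 10), "longer than trace")
  expect_error(detrend_local_average(tr, window = 0.05), "100 bins")
})

test_that("artifact scan keeps clean traces and removes bursts", {
  sp <- fccs_species("x", D = 3, concentration = 5e-8, brightness_g = 9000)
  spec <- fccs_simspec(sp, fccs_optics(), duration = 4, seed = 15)
  tr <- simulate_trace(spec)
  clean <- reject_artifacts(tr, window = 0.2, z_threshold = 5)
  expect_false(clean$discard)
  expect_equal(clean$retained_fraction, 1)
  expect_equal(nrow(clean$intervals), 1)

  # inject a 0.5 s vesicle-like burst at 10x the mean rate
  burst <- tr
  i0 <- round(2.0 / tr$bin_width); i1 <- round(2.5 / tr$bin_width)
  burst$counts_g[i0:i1] <- burst$counts_g[i0:i1] +
    rpois(i1 - i0 + 1, 10 * mean(tr$counts_g))
  mask <- reject_artifacts(burst, window = 0.2, z_threshold = 5)
  expect_false(mask$discard)
  expect_lt(mask$retained_fraction, 1)
  expect_gt(mask$retained_fraction, 0.6)
  rej <- mask$rejected
  expect_true(any(rej$start <= 2.0 & rej$end >= 2.5))
})

test_that("a trace dominated by a long bright plateau is discarded", {
  set.seed(77)
  n <- 2e4  # 4 s at 0.2 ms bins; plateau spans 45% of the trace
  x <- rpois(n, 1)
  idx <- 6001:15000
  x[idx] <- x[idx] + rpois(length(idx), 10)
  tr <- photon_trace(x, rpois(n, 1), 2e-4)
  mask <- reject_artifacts(tr, window = 0.2, z_threshold = 5)
  # plateau windows plus their padding push survival below 50%
  expect_lt(mask$retained_fraction, 0.5)
  expect_true(mask$discard)
  expect_error(correlate(tr, mask, "gg"), "discard")
})

test_that("small-lag amplitude equals 1/N_eff across concentrations", {
  vol <- true_volume()
  for (N_target in c(1, 10, 100)) {
    conc <- N_target / (N_AVOGADRO * vol$V_eff_g)
    sp <- fccs_species("x", D = 3, concentration = conc,
                       brightness_g = 2e4)
    dur <- if (N_target >= 100) 4 else 5
    spec <- fccs_simspec(sp, fccs_optics(), duration = dur,
                         seed = 900 + N_target)
    cv <- correlate(simulate_trace(spec), pair = "gg")
    fit <- fit_curve(cv, kind = "free", fit_triplet = FALSE, volume = vol)
    expect_equal(1 / fit$model$N, 1 / N_target, tolerance = 0.10)
  }
})
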