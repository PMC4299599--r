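test_that("background-only traces are Poisson at the requested rate", {
  sp <- fccs_species("none", D = 1, concentration = 0, brightness_g = 100)
  spec <- fccs_simspec(sp, fccs_optics(background_g = 1000),
                       duration = 10, time_step = 1e-3, bin_width = 1e-3,
                       seed = 2)
  tr <- simulate_trace(spec)
  x <- tr$counts_g
  expect_equal(length(x), 1e4)
  expect_equal(mean(x), 1.0, tolerance = 0.05)
  # index-of-dispersion test: (n-1) s^2 / xbar ~ chisq(n-1) under Poisson
  stat <- (length(x) - 1) * var(x) / mean(x)
  p <- 2 * min(pchisq(stat, length(x) - 1),
               pchisq(stat, length(x) - 1, lower.tail = FALSE))
  expect_gt(p, 0.01)
})

test_that("an immobile particle at the beam center emits q per second", {
  sp <- fccs_species("pin", D = 1e-6, concentration = 0, brightness_g = 5000)
  spec <- fccs_simspec(sp, fccs_optics(), duration = 3, time_step = 1e-3,
                       bin_width = 1e-3, seed = 3)
  pin <- data.frame(x = 0, y = 0, z = 0, species = 1L)
  tr <- simulate_trace(spec, particles = pin)
  # mean bin count = q * bin_width = 5, Poisson SE ~ 0.041
  expect_equal(mean(tr$counts_g), 5, tolerance = 0.04)
})

test_that("mean molecular rate matches the analytic Gaussian integral", {
  sp <- fccs_species("x", D = 3, concentration = 1e-7, brightness_g = 9000)
  ratios <- vapply(1:3, function(s) {
    spec <- fccs_simspec(sp, fccs_optics(), duration = 4, seed = 40 + s)
    tr <- simulate_trace(spec)
    tr$metadata$mol_rate_g / expected_molecular_rate(spec, "g")
  }, numeric(1))
  expect_equal(mean(ratios), 1, tolerance = 0.06)
})

test_that("displacement sampler gives MSD = 6 D t", {
  D <- 3; dt <- 1e-5
  z <- fccstools:::cpp_rnorm(2000 * 60 * 3, seed = 9)
  steps <- array(sqrt(2 * D * dt) * z, dim = c(60, 3, 2000))
  for (k in c(10, 30, 60)) {
    disp2 <- apply(steps, c(2, 3), function(v) sum(v[1:k]))^2
    msd <- mean(colSums(disp2))
    expect_equal(msd, 6 * D * k * dt, tolerance = 0.05)
  }
})

test_that("photobleaching decays the windowed mean exponentially", {
  sp <- fccs_species("x", D = 3, concentration = 1e-7, brightness_g = 9000,
                     bleach_rate = 0.05)
  spec <- fccs_simspec(sp, fccs_optics(), duration = 8, seed = 5)
  tr <- simulate_trace(spec)
  wm <- colMeans(matrix(tr$counts_g, nrow = 5e4))  # 0.5 s windows
  t_mid <- (seq_along(wm) - 0.5) * 0.5
  fit <- lm(log(wm) ~ t_mid)
  k_eff <- -coef(fit)[2]
  expect_gt(k_eff, 0.05 * 0.6)
  expect_lt(k_eff, 0.05 * 1.4)
})

test_that("without bleaching the trace is stationary", {
  sp <- fccs_species("x", D = 3, concentration = 1e-7, brightness_g = 9000)
  spec <- fccs_simspec(sp, fccs_optics(), duration = 8, seed = 6)
  tr <- simulate_trace(spec)
  wm <- colMeans(matrix(tr$counts_g, nrow = 5e4))
  t_mid <- seq_along(wm)
  p <- summary(lm(wm ~ t_mid))$coefficients[2, 4]
  expect_gt(p, 0.01)
})

test_that("traces are reproducible from the seed", {
  sp <- fccs_species("x", D = 3, concentration = 3e-8, brightness_g = 9000,
                     theta = 0.15, bleach_rate = 0.01)
  spec <- fccs_simspec(sp, fccs_optics(background_g = 500), duration = 2,
                       seed = 7)
  t1 <- simulate_trace(spec)
  t2 <- simulate_trace(spec)
  expect_identical(t1$counts_g, t2$counts_g)
  expect_identical(t1$counts_r, t2$counts_r)
  spec2 <- spec; spec2$seed <- 8
  expect_false(identical(simulate_trace(spec2)$counts_g, t1$counts_g))
})

test_that("an explicit initial configuration reproduces the default one", {
  sp <- fccs_species("x", D = 3, concentration = 3e-8, brightness_g = 9000)
  spec <- fccs_simspec(sp, fccs_optics(), duration = 1, seed = 12)
  tr_a <- simulate_trace(spec)
  tr_b <- simulate_trace(spec, particles = populate_box(spec))
  expect_identical(tr_a$counts_g, tr_b$counts_g)
})

test_that("green-to-red crosstalk adds the expected red rate", {
  opt <- fccs_optics(background_r = 200, crosstalk_g_to_r = 0.1)
  sp <- fccs_species("x", D = 3, concentration = 1e-7, brightness_g = 9000)
  spec <- fccs_simspec(sp, opt, duration = 4, seed = 8)
  tr <- simulate_trace(spec)
  red_rate <- mean(tr$counts_r) / tr$bin_width
  expect_equal(red_rate, 0.1 * tr$metadata$mol_rate_g + 200,
               tolerance = 0.03)
})

test_that("triplet blinking reduces the mean emission by 1 - theta", {
  mk <- function(theta, seed) {
    sp <- fccs_species("x", D = 3, concentration = 1e-7, brightness_g = 9000,
                       theta = theta, tau_triplet = 5e-5)
    spec <- fccs_simspec(sp, fccs_optics(), duration = 4, seed = seed)
    tr <- simulate_trace(spec)
    tr$metadata$mol_rate_g
  }
  ratio <- mean(sapply(21:23, function(s) mk(0.3, s))) /
           mean(sapply(21:23, function(s) mk(0, s)))
  expect_equal(ratio, 0.7, tolerance = 0.06)
})
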