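test_that("model_G satisfies its amplitude identities", {
  expect_equal(model_G(0, N = 10, tau_diff = 1e-3), 0.1)
  # 2-D limit: G(tau_diff) = 1/(2N) when kappa -> Inf
  expect_equal(model_G(1e-3, N = 10, tau_diff = 1e-3, kappa = 1e9),
               1 / 20, tolerance = 1e-9)
  # triplet factor at zero lag: (1/N) / (1 - theta)
  expect_equal(model_G(0, N = 10, tau_diff = 1e-3, theta = 0.2),
               0.1 / 0.8)
  # monotone decreasing for theta = 0
  g <- model_G(10^seq(-6, 0, by = 0.1), N = 5, tau_diff = 1e-3,
               alpha = 0.8, kappa = 5)
  expect_true(all(diff(g) < 0))
})

.synthetic_curve <- function(lags, ..., sem = NA_real_) {
  structure(list(pair = "gg", lags = lags, G = model_G(lags, ...),
                 G_sem = rep(sem, length(lags)), mean_rate_i = 1e5,
                 mean_rate_j = 1e5, effective_duration = 20,
                 n_segments = 10, bin_width = lags[1]),
            class = "correlation_curve")
}

test_that("fitting recovers its own model exactly on noiseless curves", {
  lags <- 10^seq(-5, -0.5, length.out = 80)
  cv <- .synthetic_curve(lags, N = 10, tau_diff = 1e-3, alpha = 1,
                         theta = 0.15, tau_triplet = 1e-5, kappa = 5)
  f <- fit_curve(cv, kind = "anomalous", kappa = 5,
                 lag_range = c(1e-5, Inf))
  expect_true(f$converged)
  expect_equal(f$model$N, 10, tolerance = 1e-6)
  expect_equal(f$model$tau_diff, 1e-3, tolerance = 1e-6)
  expect_equal(f$model$theta, 0.15, tolerance = 1e-4)
  expect_equal(f$model$alpha, 1, tolerance = 1e-5)
})

test_that("free and anomalous fits agree on free-diffusion curves", {
  lags <- 10^seq(-5, -0.5, length.out = 60)
  cv <- .synthetic_curve(lags, N = 25, tau_diff = 3e-3, kappa = 5)
  ff <- fit_curve(cv, kind = "free", fit_triplet = FALSE, kappa = 5)
  fa <- fit_curve(cv, kind = "anomalous", fit_triplet = FALSE, kappa = 5)
  expect_equal(ff$model$N, fa$model$N, tolerance = 1e-4)
  expect_equal(ff$model$tau_diff, fa$model$tau_diff, tolerance = 1e-3)
  expect_gte(fa$model$alpha, 0.99)
})

test_that("degenerate curves are rejected as infeasible", {
  lags <- 10^seq(-5, -1, length.out = 40)
  flat <- .synthetic_curve(lags, N = 1e8, tau_diff = 1e-3)
  flat$G <- rep(-0.01, length(lags))
  expect_error(fit_curve(flat), "fit-infeasible")
})

test_that("fit on a simulated cytoplasmic trace recovers N, tau and alpha", {
  vol <- true_volume()
  sp <- fccs_species("x", D = 3, concentration = 1e-7, brightness_g = 9000)
  spec <- fccs_simspec(sp, fccs_optics(), duration = 8, seed = 19)
  cv <- correlate(simulate_trace(spec), pair = "gg")
  f <- fit_curve(cv, kind = "anomalous", fit_triplet = FALSE, volume = vol)
  expect_true(f$converged)
  expect_equal(f$model$N, n_eff(1e-7), tolerance = 0.15)
  expect_equal(f$model$tau_diff, 0.2^2 / (4 * 3), tolerance = 0.15)
  expect_gte(f$model$alpha, 0.9)
})

test_that("dye calibration recovers the observation geometry", {
  # synthetic dye session: three channels, same kappa, known D
  tau <- function(D) 0.2^2 / (4 * D)
  lags <- 10^seq(-6, -2.7, length.out = 70)
  curves <- list(
    g = .synthetic_curve(lags, N = 0.3, tau_diff = tau(435), kappa = 5),
    r = .synthetic_curve(lags, N = 0.3, tau_diff = tau(341), kappa = 5),
    x = .synthetic_curve(lags, N = 0.3, tau_diff = tau(420), kappa = 5))
  vol <- calibrate_volume(curves, c(g = 435, r = 341, x = 420))
  expect_equal(vol$w_xy_g, 0.2, tolerance = 1e-3)
  expect_equal(vol$w_xy_r, 0.2, tolerance = 1e-3)
  expect_equal(vol$kappa_g, 5, tolerance = 0.01)
  expect_equal(vol$V_eff_g, effective_volume(0.2, 5), tolerance = 0.01)
  expect_equal(vol$V_rg, vol$V_eff_g, tolerance = 0.01)
  expect_equal(vol$overlap_factor, 1, tolerance = 0.01)
})

test_that("calibration arithmetic: w_xy from known D and fitted tau", {
  # D = 400 um^2/s, tau = 20 us -> w = sqrt(4 * 400 * 2e-5) = 0.1789 um
  lags <- 10^seq(-6, -2.7, length.out = 70)
  curves <- list(
    g = .synthetic_curve(lags, N = 0.3, tau_diff = 2e-5, kappa = 5),
    r = .synthetic_curve(lags, N = 0.3, tau_diff = 2e-5, kappa = 5),
    x = .synthetic_curve(lags, N = 0.3, tau_diff = 2e-5, kappa = 5))
  vol <- calibrate_volume(curves, c(g = 400, r = 400, x = 400))
  expect_equal(vol$w_xy_g, sqrt(4 * 400 * 2e-5), tolerance = 1e-3)
  expect_equal(vol$w_xy_g, 0.1789, tolerance = 1e-3)
})

test_that("failed dye fits abort the calibration", {
  lags <- 10^seq(-6, -2.7, length.out = 50)
  bad <- .synthetic_curve(lags, N = 0.3, tau_diff = 2e-5, kappa = 5)
  bad$G <- rep(0, length(lags))
  curves <- list(g = bad, r = bad, x = bad)
  expect_error(calibrate_volume(curves, c(g = 400, r = 400, x = 400)),
               "calibration error")
})

test_that("fit reports serialize one row per curve", {
  lags <- 10^seq(-5, -1, length.out = 50)
  cv <- .synthetic_curve(lags, N = 10, tau_diff = 1e-3, kappa = 5)
  f <- fit_curve(cv, kind = "free", fit_triplet = FALSE, kappa = 5)
  path <- file.path(tempdir(), "fits.tsv")
  write_fit_report(list(gg = f, rr = f), path)
  rep <- read.delim(path)
  expect_equal(nrow(rep), 2)
  expect_equal(rep$curve, c("gg", "rr"))
  expect_true(all(rep$converged))
  expect_equal(rep$N, c(10, 10), tolerance = 1e-4)
})
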