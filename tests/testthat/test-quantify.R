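test_that("background correction follows the squared-rate-ratio law", {
  expect_equal(correct_background(40, 1e5, 0), 40)
  expect_equal(correct_background(40, 1e5, 5e4), 10)
  expect_lt(correct_background(12, 8e4, 1e4), 12)
  expect_error(correct_background(40, 1e5, 1e5), "B < F")
  expect_error(correct_background(40, 1e5, -1), "B < F")
})

test_that("particle numbers convert to molar concentrations", {
  expect_equal(compute_concentration(6.02214076, 1e-15), 1e-8)
  expect_equal(compute_concentration(0, 1e-15), 0)
  expect_error(compute_concentration(1, 0), "positive")
})

test_that("cpps is the background-corrected rate per particle", {
  expect_equal(compute_cpps(1e5, 0, 10), 1e4)
  expect_equal(compute_cpps(1.1e5, 1e4, 20), 5e3)
  expect_error(compute_cpps(1e5, 0, 0), "positive")
})

test_that("diffusion coefficient from the focal dwell time", {
  expect_equal(compute_D(1e-2, 0.2), 1.0)
  # doubling w quadruples D at fixed tau
  expect_equal(compute_D(1e-2, 0.4), 4 * compute_D(1e-2, 0.2))
  expect_error(compute_D(0, 0.2), "positive")
})

test_that("crosstalk correction inverts the bleed-through algebra exactly", {
  # forward model: true amplitudes and rates -> measured quantities
  beta <- 0.12
  F_g <- 9e4; F_r_true <- 5e4
  c_gg <- 0.025 * F_g^2
  c_rr <- 0.04 * F_r_true^2
  c_gr <- 0.008 * F_g * F_r_true
  F_r_m <- F_r_true + beta * F_g
  c_gr_m <- c_gr + beta * c_gg
  c_rr_m <- c_rr + 2 * beta * c_gr + beta^2 * c_gg
  out <- correct_crosstalk(G_gg0 = c_gg / F_g^2,
                           G_rr0 = c_rr_m / F_r_m^2,
                           G_gr0 = c_gr_m / (F_g * F_r_m),
                           F_g = F_g, F_r = F_r_m, beta = beta)
  expect_equal(out$F_r, F_r_true, tolerance = 1e-12)
  expect_equal(out$G_rr0, c_rr / F_r_true^2, tolerance = 1e-12)
  expect_equal(out$G_gr0, c_gr / (F_g * F_r_true), tolerance = 1e-12)
  # identity at beta = 0
  id <- correct_crosstalk(0.025, 0.04, 0.008, F_g, F_r_true, 0)
  expect_equal(id$G_rr0, 0.04)
  expect_equal(id$G_gr0, 0.008)
  expect_error(correct_crosstalk(0.025, 0.04, 0.008, 1e5, 1e4, 0.2),
               "non-positive")
})

test_that("complex concentration follows the FCCS amplitude relation", {
  vol <- true_volume()
  # fully bound dual-labeled species: all amplitudes equal 1/(V C N_A)
  C <- 2e-7
  G0 <- 1 / (vol$V_eff_g * C * N_AVOGADRO)
  cc <- complex_concentration(G0, G0, G0, vol)
  expect_equal(cc$C_AB, C, tolerance = 1e-10)
  expect_false(cc$clipped)
  # zero cross-amplitude
  expect_equal(complex_concentration(G0, G0, 0, vol)$C_AB, 0)
  # negative amplitude clips to zero with a flag
  neg <- complex_concentration(G0, G0, -0.1 * G0, vol)
  expect_equal(neg$C_AB, 0)
  expect_true(neg$clipped)
  expect_error(complex_concentration(0, G0, G0, vol), "positive")
})

test_that("apparent K_D inverts the binding equilibrium", {
  # C_A = C_B = 2 C_AB  ->  K_D = C_AB
  expect_equal(apparent_KD(2e-7, 2e-7, 1e-7), 1e-7)
  # the mid-affinity screening point: 300/300 nM totals, C_AB = 89.02 nM
  ab <- solve_binding_equilibrium(3e-7, 3e-7, 5e-7)
  expect_equal(apparent_KD(3e-7, 3e-7, ab), 5e-7, tolerance = 1e-9)
  # sentinels
  expect_true(is_above_range(apparent_KD(2e-7, 2e-7, 0)))
  expect_true(is_above_range(apparent_KD(2e-7, 2e-7, 5e-9, C_AB_se = 6e-9)))
  expect_false(is_above_range(apparent_KD(2e-7, 2e-7, 5e-8, C_AB_se = 1e-8)))
})

test_that("molecules per cell match the yeast cytoplasm conversion", {
  # 16 nM in 70 um^3 at 29% cytoplasm: 195.6 -> within 1 of 195
  expect_lte(abs(molecules_per_cell(16e-9) - 195), 1)
  expect_equal(molecules_per_cell(10e-9), 122)
  expect_lt(molecules_per_cell(10e-9), 200)
  expect_equal(molecules_per_cell(0), 0)
  expect_error(molecules_per_cell(1e-9, cytoplasmic_fraction = 2),
               "invalid")
})

test_that("all corrections are identities at neutral parameter values", {
  vol <- true_volume()
  fit_gg <- structure(list(
    model = list(N = 20, tau_diff = 3e-3, alpha = 1, theta = 0),
    converged = TRUE, se = c(N = 0.1)), class = "fit_result")
  fit_rr <- structure(list(
    model = list(N = 25, tau_diff = 3e-3, alpha = 1, theta = 0),
    converged = TRUE, se = c(N = 0.1)), class = "fit_result")
  amp <- list(amplitude = 0.001, se = 1e-5)
  rates <- list(F_g = 8e4, F_r = 5e4)
  cm <- quantify_cell(fit_gg, fit_rr, amp, rates, vol,
                      correction_config(), strain = "s")
  expect_equal(cm$N_g, 20)
  expect_equal(cm$N_r, 25)
  expect_equal(cm$C_g, 20 / (vol$V_eff_g * N_AVOGADRO))
  expect_equal(cm$cpps_g, 8e4 / 20)
  expect_equal(cm$C_AB,
               0.001 * 20 * 25 / (vol$V_rg * N_AVOGADRO))
  expect_equal(cm$D_g, 0.2^2 / (4 * 3e-3))
})

test_that("a monomer/trimer mixture reports the amplitude-weighted cpps", {
  # The particle number inferred from the correlation amplitude of a
  # brightness mixture is N_app = (sum c q)^2 / (sum c q^2) x V, so the
  # reported cpps is the brightness-squared-weighted mean brightness:
  # for a 1:1 monomer/trimer mix, (1 + 9)/(1 + 3) = 2.5x the monomer.
  vol <- true_volume()
  man <- list(
    fccs_species("mono", D = 3, concentration = 5e-8, brightness_g = 9000,
                 stoichiometry_g = 1L),
    fccs_species("tri", D = 2.1, concentration = 5e-8, brightness_g = 9000,
                 stoichiometry_g = 3L))
  spec <- fccs_simspec(man, fccs_optics(), duration = 6, seed = 23)
  cm <- analyze_trace(simulate_trace(spec), vol, red = FALSE,
                      strain = "mix")
  expect_equal(cm$cpps_g, 2.5 * cpps_expected(9000), tolerance = 0.15)
})
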