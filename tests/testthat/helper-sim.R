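# Shared fixtures: heavy simulations are built once per session and reused
# by every test block that asserts on them.
.fixture_cache <- new.env(parent = emptyenv())

fixture <- function(key, builder) {
  if (!exists(key, envir = .fixture_cache)) {
    assign(key, builder(), envir = .fixture_cache)
  }
  get(key, envir = .fixture_cache)
}

N_AVOGADRO <- 6.02214076e23

# analytic mean particle number in the effective volume for default optics
n_eff <- function(conc, w = 0.2, kappa = 5) {
  conc * N_AVOGADRO * effective_volume(w, kappa)
}

# exact observation volume of the default simulated optics (bypasses dye
# calibration so stage-level tests are not confounded by calibration noise)
true_volume <- function() observation_volume(0.2, 0.2, 5, 5)

# expected cpps of a species: q * stoich * (1 - theta) / 2^(3/2)
cpps_expected <- function(q, stoich = 1, theta = 0) {
  q * stoich * (1 - theta) / (2 * sqrt(2))
}

default_species <- function(name = "A", D = 3, conc = 1e-7, qg = 9000,
                            qr = 0, ...) {
  fccs_species(name, D = D, concentration = conc, brightness_g = qg,
               brightness_r = qr, ...)
}

# simulate and analyze all cells of one manifest, returning the stacked
# per-cell measurements plus the ground truth
run_screen <- function(manifest, n_cells, duration, root_seed,
                       optics = fccs_optics(), bg_frac = NULL,
                       volume = true_volume(), kind = "anomalous",
                       theta = 0.15, tau_triplet = 5e-5,
                       bleach_rate = 0.005, n_segments = 10L) {
  scen <- make_screen_scenarios(manifest, optics, root_seed = root_seed,
                                n_cells = n_cells,
                                background_fraction = bg_frac,
                                duration = duration, theta = theta,
                                tau_triplet = tau_triplet,
                                bleach_rate = bleach_rate)
  cells <- lapply(scen$specs, function(sp) {
    strain <- sub("#.*$", "", sp$label)
    tr_row <- scen$truth[scen$truth$strain == strain, ]
    corr <- correction_config(
      background_g = sp$optics$background_g,
      background_r = sp$optics$background_r,
      crosstalk_g_to_r = sp$optics$crosstalk_g_to_r,
      overlap_factor = volume$overlap_factor)
    cm <- analyze_trace(simulate_trace(sp), volume, corr, kind = kind,
                        strain = strain, red = tr_row$total_r[1] > 0,
                        n_segments = n_segments)
    cm
  })
  cells <- cells[!vapply(cells, is.null, TRUE)]
  list(cells = do.call(rbind, cells), truth = scen$truth)
}

# independent quadratic-equilibrium oracle via root bracketing
binding_oracle <- function(A, B, KD) {
  if (KD == 0) return(min(A, B))
  f <- function(x) (A - x) * (B - x) / x - KD
  stats::uniroot(f, c(1e-18, min(A, B) * (1 - 1e-12)),
                 tol = 1e-18)$root
}
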