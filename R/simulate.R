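#' Draw the initial particle configuration for a simulation
#'
#' Particle counts per species are Poisson with mean
#' `concentration x box volume x N_Avogadro`; positions are uniform in the
#' periodic box (centered on the detection volumes); all fluorophores start
#' bright. Deterministic given the spec seed, and identical to the initial
#' configuration used by [simulate_trace()] for the same spec.
#'
#' @param spec an [fccs_simspec()].
#' @param max_expected resource guard: error if the expected total particle
#'   count exceeds this (default 1e6).
#' @return A data.frame with columns `x`, `y`, `z` (um) and `species`
#'   (1-based index into `spec$species`).
#' @export
populate_box <- function(spec, max_expected = 1e6) {
  stopifnot(inherits(spec, "fccs_simspec"))
  p <- cpp_populate(.species_matrix(spec$species), spec$box,
                    as.numeric(spec$seed), max_expected)
  data.frame(x = p$x, y = p$y, z = p$z, species = p$species)
}

#' Simulate a two-channel photon-count trace
#'
#' Brownian-dynamics simulation of all species through the two Gaussian
#' detection volumes. Per fine time step each particle takes an isotropic
#' Gaussian displacement with per-axis standard deviation
#' `sqrt(2 D time_step)` (periodic wrap); the expected photon rate of a
#' bright fluorophore at distance (x, y, z) from a volume center is
#' `brightness * exp(-2 (x^2 + y^2) / w_xy^2 - 2 z^2 / w_z^2)`. Triplet
#' blinking is a two-state Markov process with stationary dark fraction
#' `theta` and dark lifetime `tau_triplet`; bleaching is irreversible with
#' rate `bleach_rate` per fluorophore. Per-bin channel counts are Poisson
#' draws of the integrated molecular rate plus background, with the green
#' molecular rate times `crosstalk_g_to_r` added to the red channel.
#'
#' Far away from the detection region (where the truncated Gaussian profile
#' is identically zero) the propagator merges many fine steps into a single
#' statistically equivalent Gaussian jump whose length keeps re-entry within
#' the jump a > 4-sigma event; this changes no observable statistic of the
#' trace but makes dilute boxes cheap.
#'
#' @param spec an [fccs_simspec()].
#' @param particles optional initial configuration as returned by
#'   [populate_box()] (overrides the Poisson draw; useful for pinned-particle
#'   checks).
#' @param max_expected resource guard forwarded to the populate step.
#' @return A [photon_trace()] with metadata recording seed and label.
#' @export
simulate_trace <- function(spec, particles = NULL, max_expected = 1e6) {
  stopifnot(inherits(spec, "fccs_simspec"))
  init <- NULL
  if (!is.null(particles)) {
    stopifnot(all(c("x", "y", "z", "species") %in% names(particles)))
    init <- list(x = as.numeric(particles$x), y = as.numeric(particles$y),
                 z = as.numeric(particles$z),
                 species = as.integer(particles$species))
  }
  res <- cpp_simulate(.species_matrix(spec$species),
                      .optics_vector(spec$optics), spec$box,
                      spec$duration, spec$time_step, spec$bin_width,
                      as.numeric(spec$seed), init, max_expected)
  photon_trace(res$counts_g, res$counts_r, spec$bin_width,
               metadata = list(seed = spec$seed, label = spec$label,
                               duration = spec$duration,
                               n_particles = res$n_particles,
                               mol_rate_g = res$mol_rate_g,
                               mol_rate_r = res$mol_rate_r))
}

#' Derive the seed of one cell from the root seed
#'
#' Documented counter scheme: `cell_seed = root_seed * 1e5 + cell_counter`,
#' where the counter enumerates cells across the whole scenario set. Any
#' single cell can therefore be re-simulated in isolation.
#'
#' @param root_seed integer root seed of the scenario set.
#' @param counter 1-based cell counter.
#' @return Numeric scalar seed.
#' @export
cell_seed <- function(root_seed, counter) root_seed * 1e5 + counter

#' Build per-cell simulation specs for a screening manifest
#'
#' One row of the manifest defines one strain: a green-labeled protein, an
#' optional red-labeled protein, and (optionally) their binding equilibrium.
#' For an interacting pair the complex concentration comes from
#' [solve_binding_equilibrium()]; free and complexed species are simulated
#' as distinct static species (FCCS amplitudes depend only on equilibrium
#' fractions). `n_cells` specs per strain are generated with seeds from
#' [cell_seed()], and the ground truth of every strain is recorded.
#'
#' Recognized manifest columns (units: mol/L, um^2/s, counts/s):
#' `strain`, `protein_g`, `protein_r`, `total_g`, `total_r`, `K_D`
#' (`NA`/`Inf` = non-interacting), `D_g`, `D_r`, `brightness_g`,
#' `brightness_r`, `stoich_g`, `stoich_r`, `n_cells`. Missing optional
#' columns fall back to defaults.
#'
#' @param manifest data.frame of strain definitions (see Details).
#' @param optics an [fccs_optics()]; per-strain background can be overridden
#'   by `background_fraction`.
#' @param root_seed integer root seed.
#' @param n_cells default number of cells per strain (the screen's per-strain
#'   sample size).
#' @param background_fraction if not `NULL`, set each channel's background to
#'   this fraction of the strain's analytic molecular signal rate.
#' @param duration,time_step,bin_width,box acquisition/simulation defaults
#'   forwarded to [fccs_simspec()].
#' @param theta,tau_triplet,bleach_rate photophysics defaults applied to all
#'   species of the scenario.
#' @return A list with elements `specs` (list of `fccs_simspec`, one per
#'   cell, labelled `strain#cell`) and `truth` (data.frame of per-strain
#'   ground truth: concentrations, complex concentration, diffusion
#'   coefficients, expected cpps).
#' @export
make_screen_scenarios <- function(manifest, optics = fccs_optics(),
                                  root_seed = 1L, n_cells = 12L,
                                  background_fraction = NULL,
                                  duration = 20, time_step = 1e-5,
                                  bin_width = 1e-5, box = c(3, 3, 6),
                                  theta = 0.15, tau_triplet = 5e-5,
                                  bleach_rate = 0.005) {
  manifest <- as.data.frame(manifest, stringsAsFactors = FALSE)
  if (!nrow(manifest)) stop("empty manifest")
  need <- c("strain", "total_g")
  miss <- setdiff(need, names(manifest))
  if (length(miss))
    stop("manifest is missing required column(s): ",
         paste(miss, collapse = ", "))

  col <- function(row, name, default) {
    v <- if (name %in% names(manifest)) manifest[row, name] else NA
    if (is.null(v) || length(v) != 1 || is.na(v)) default else v
  }

  specs <- list()
  truth <- list()
  counter <- 0L
  for (i in seq_len(nrow(manifest))) {
    strain <- manifest$strain[i]
    if (is.na(strain) || !nzchar(strain))
      stop("manifest row ", i, ": missing strain label")
    total_g <- manifest$total_g[i]
    total_r <- col(i, "total_r", 0)
    if (is.na(total_g) || total_g < 0 || total_r < 0)
      stop("manifest row ", i, " (", strain, "): invalid concentrations")
    K_D <- col(i, "K_D", Inf)
    D_g <- col(i, "D_g", 3)
    D_r <- col(i, "D_r", 3)
    q_g <- col(i, "brightness_g", 9000)
    q_r <- col(i, "brightness_r", 5000)
    s_g <- col(i, "stoich_g", 1L)
    s_r <- col(i, "stoich_r", 1L)
    nc <- as.integer(col(i, "n_cells", n_cells))
    if (nc < 1) stop("manifest row ", i, " (", strain, "): n_cells < 1")

    c_ab <- if (total_r > 0 && is.finite(K_D))
      solve_binding_equilibrium(total_g, total_r, K_D) else 0
    sp <- list()
    mk <- function(name, D, conc, qg, qr, sg, sr)
      fccs_species(name, D = D, concentration = conc, brightness_g = qg,
                   brightness_r = qr, stoichiometry_g = sg,
                   stoichiometry_r = sr, theta = theta,
                   tau_triplet = tau_triplet, bleach_rate = bleach_rate)
    if (total_g - c_ab > 0)
      sp <- c(sp, list(mk(col(i, "protein_g", "A_green"), D_g,
                          total_g - c_ab, q_g, 0, s_g, 0L)))
    if (total_r - c_ab > 0)
      sp <- c(sp, list(mk(col(i, "protein_r", "B_red"), D_r,
                          total_r - c_ab, 0, q_r, 0L, s_r)))
    if (c_ab > 0)
      sp <- c(sp, list(mk("complex_AB", complex_diffusion(D_g, D_r), c_ab,
                          q_g, q_r, s_g, s_r)))
    if (!length(sp))
      stop("manifest row ", i, " (", strain, "): no species to simulate")

    opt <- optics
    if (!is.null(background_fraction)) {
      probe <- fccs_simspec(sp, optics, box = box, duration = duration,
                            time_step = time_step, bin_width = bin_width,
                            seed = 0)
      opt$background_g <- background_fraction *
        expected_molecular_rate(probe, "g")
      opt$background_r <- background_fraction *
        (expected_molecular_rate(probe, "r") +
           optics$crosstalk_g_to_r * expected_molecular_rate(probe, "g"))
    }
    for (j in seq_len(nc)) {
      counter <- counter + 1L
      specs[[counter]] <- fccs_simspec(
        sp, opt, box = box, duration = duration, time_step = time_step,
        bin_width = bin_width, seed = cell_seed(root_seed, counter),
        label = sprintf("%s#%02d", strain, j))
    }
    truth[[i]] <- data.frame(
      strain = strain, total_g = total_g, total_r = total_r, K_D = K_D,
      C_AB = c_ab, D_g = D_g, D_r = D_r, D_AB = complex_diffusion(D_g, D_r),
      cpps_g = q_g * s_g * (1 - theta) / (2 * sqrt(2)),
      cpps_r = q_r * s_r * (1 - theta) / (2 * sqrt(2)),
      background_g = opt$background_g, background_r = opt$background_r,
      n_cells = nc, stringsAsFactors = FALSE)
  }
  list(specs = specs, truth = do.call(rbind, truth))
}
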