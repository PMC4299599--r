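#' Define a diffusing fluorescent species
#'
#' A species is a population of identical diffusing particles, each carrying
#' an integer number of green and/or red fluorophore units. Brightness is the
#' mean detected photon rate per fluorophore unit at the center of the
#' detection volume; the total molecular rate scales linearly with the copy
#' number. Triplet-like blinking is a reversible dark state with stationary
#' fraction `theta` and lifetime `tau_triplet`; photobleaching is an
#' irreversible first-order loss per fluorophore unit.
#'
#' @param name label for the species.
#' @param D diffusion coefficient, um^2/s. Must be positive.
#' @param concentration molar concentration, mol/L.
#' @param brightness_g,brightness_r detected photon rate per fluorophore unit
#'   at beam center, counts/s.
#' @param stoichiometry_g,stoichiometry_r integer fluorophore copy numbers.
#' @param theta triplet (dark-state) fraction, in `[0, 1)`.
#' @param tau_triplet triplet lifetime, s.
#' @param bleach_rate irreversible bleaching rate per fluorophore, 1/s.
#' @return An object of class `fccs_species`.
#' @examples
#' fccs_species("Ede1-3myeGFP", D = 1.2, concentration = 250e-9,
#'              brightness_g = 9000)
#' @export
fccs_species <- function(name, D, concentration,
                         brightness_g = 0, brightness_r = 0,
                         stoichiometry_g = if (brightness_g > 0) 1L else 0L,
                         stoichiometry_r = if (brightness_r > 0) 1L else 0L,
                         theta = 0, tau_triplet = 5e-5, bleach_rate = 0) {
  stopifnot(is.character(name), length(name) == 1L)
  if (!is.finite(D) || D <= 0) stop("D must be positive")
  if (concentration < 0) stop("concentration must be >= 0")
  if (brightness_g < 0 || brightness_r < 0) stop("brightness must be >= 0")
  if (stoichiometry_g < 0 || stoichiometry_r < 0 ||
      stoichiometry_g != round(stoichiometry_g) ||
      stoichiometry_r != round(stoichiometry_r))
    stop("stoichiometry must be a nonnegative integer")
  if (theta < 0 || theta >= 1) stop("theta must be in [0, 1)")
  if (tau_triplet <= 0) stop("tau_triplet must be positive")
  if (bleach_rate < 0) stop("bleach_rate must be >= 0")
  structure(list(name = name, D = D, concentration = concentration,
                 brightness_g = brightness_g, brightness_r = brightness_r,
                 stoichiometry_g = as.integer(stoichiometry_g),
                 stoichiometry_r = as.integer(stoichiometry_r),
                 theta = theta, tau_triplet = tau_triplet,
                 bleach_rate = bleach_rate),
            class = "fccs_species")
}

#' Define the two-channel confocal detection geometry
#'
#' Both detection volumes are 3D Gaussians with lateral 1/e^2 radius `w_xy`
#' and axial radius `w_z = kappa * w_xy`. `channel_offset` displaces the red
#' volume center relative to the green one. Background is an uncorrelated
#' count rate added to each channel; `crosstalk_g_to_r` is the fraction of
#' the green molecular signal that bleeds into the red detector.
#'
#' @param w_xy_g,w_xy_r lateral 1/e^2 radii, um.
#' @param kappa_g,kappa_r structure parameters `w_z / w_xy` (>= 1).
#' @param channel_offset numeric length-3 displacement (x, y, z) of the red
#'   volume relative to the green, um.
#' @param background_g,background_r background count rates, counts/s.
#' @param crosstalk_g_to_r green-to-red bleed-through fraction, in `[0, 1)`.
#' @return An object of class `fccs_optics`.
#' @export
fccs_optics <- function(w_xy_g = 0.2, w_xy_r = 0.2, kappa_g = 5, kappa_r = 5,
                        channel_offset = c(0, 0, 0),
                        background_g = 0, background_r = 0,
                        crosstalk_g_to_r = 0) {
  if (w_xy_g <= 0 || w_xy_r <= 0) stop("detection radii must be positive")
  if (kappa_g < 1 || kappa_r < 1) stop("kappa must be >= 1")
  if (length(channel_offset) != 3 || any(!is.finite(channel_offset)))
    stop("channel_offset must be a finite length-3 vector")
  if (background_g < 0 || background_r < 0) stop("background must be >= 0")
  if (crosstalk_g_to_r < 0 || crosstalk_g_to_r >= 1)
    stop("crosstalk_g_to_r must be in [0, 1)")
  structure(list(w_xy_g = w_xy_g, w_xy_r = w_xy_r,
                 kappa_g = kappa_g, kappa_r = kappa_r,
                 channel_offset = as.numeric(channel_offset),
                 background_g = background_g, background_r = background_r,
                 crosstalk_g_to_r = crosstalk_g_to_r),
            class = "fccs_optics")
}

#' Assemble a full trace-simulation specification
#'
#' @param species a single `fccs_species` or a list of them.
#' @param optics an `fccs_optics` object.
#' @param box periodic box dimensions (x, y, z), um. Each axis must be at
#'   least 10 lateral radii so periodic images do not overlap the focus.
#' @param duration acquisition length, s; must be an integer number of bins.
#' @param time_step propagation time step near the focus, s
#'   (`time_step <= bin_width`, with `bin_width / time_step` integer).
#' @param bin_width photon-count binning interval, s.
#' @param seed integer seed; the trace is fully reproducible from it.
#' @param label optional cell/strain label stored in trace metadata.
#' @return An object of class `fccs_simspec`.
#' @export
fccs_simspec <- function(species, optics = fccs_optics(), box = c(3, 3, 6),
                         duration = 20, time_step = 1e-5, bin_width = 1e-5,
                         seed = 1L, label = "") {
  if (inherits(species, "fccs_species")) species <- list(species)
  if (!length(species) || !all(vapply(species, inherits, TRUE, "fccs_species")))
    stop("species must be fccs_species objects")
  if (!inherits(optics, "fccs_optics")) stop("optics must be an fccs_optics")
  if (length(box) != 3 || any(box <= 0)) stop("box must be 3 positive lengths")
  wmax <- max(optics$w_xy_g, optics$w_xy_r)
  if (any(box < 10 * wmax))
    stop("box dimensions must be >= 10 x w_xy in each axis")
  if (time_step <= 0 || bin_width <= 0) stop("time steps must be positive")
  if (time_step > bin_width * (1 + 1e-9)) stop("time_step must be <= bin_width")
  spb <- bin_width / time_step
  if (abs(spb - round(spb)) > 1e-6)
    stop("bin_width must be an integer multiple of time_step")
  nbins <- duration / bin_width
  if (abs(nbins - round(nbins)) > 1e-6)
    stop("duration must be an integer number of bins")
  structure(list(species = species, optics = optics, box = as.numeric(box),
                 duration = duration, time_step = time_step,
                 bin_width = bin_width, seed = seed, label = label),
            class = "fccs_simspec")
}

## species list -> parameter matrix consumed by the C++ simulator
.species_matrix <- function(species) {
  m <- t(vapply(species, function(s)
    c(s$D, s$brightness_g, s$brightness_r, s$stoichiometry_g,
      s$stoichiometry_r, s$theta, s$tau_triplet, s$bleach_rate,
      s$concentration), numeric(9)))
  dimnames(m) <- NULL
  m
}

.optics_vector <- function(o) {
  c(o$w_xy_g, o$w_xy_r, o$kappa_g, o$kappa_r, o$channel_offset,
    o$background_g, o$background_r, o$crosstalk_g_to_r)
}

#' Effective detection volume of a 3D-Gaussian observation profile
#'
#' `V_eff = pi^(3/2) w_xy^2 w_z`, returned in litres (`w` in um).
#'
#' @param w_xy lateral 1/e^2 radius, um.
#' @param kappa structure parameter `w_z / w_xy`.
#' @return Effective volume in litres.
#' @examples
#' effective_volume(0.2, 5)  # ~2.23e-16 L
#' @export
effective_volume <- function(w_xy, kappa) {
  pi^1.5 * w_xy^3 * kappa * 1e-15
}

#' Analytic mean molecular photon rate of a simulation spec
#'
#' For a uniform particle density c and a 3D-Gaussian profile, the expected
#' molecular count rate per channel is
#' `sum_i q_i s_i (1 - theta_i) c_i (pi/2)^(3/2) w_xy^2 w_z`,
#' i.e. the brightness-weighted particle density integrated over the
#' detection profile. Used as an independent oracle for the long-trace mean
#' of simulated signals and to set relative background levels.
#'
#' @param spec an `fccs_simspec`.
#' @param channel `"g"` or `"r"`.
#' @param include_triplet scale by the stationary bright fraction
#'   `1 - theta` (default `TRUE`).
#' @return Expected molecular count rate, counts/s (excludes background and
#'   crosstalk).
#' @export
expected_molecular_rate <- function(spec, channel = c("g", "r"),
                                    include_triplet = TRUE) {
  channel <- match.arg(channel)
  o <- spec$optics
  w <- if (channel == "g") o$w_xy_g else o$w_xy_r
  wz <- w * (if (channel == "g") o$kappa_g else o$kappa_r)
  vol_int <- (pi / 2)^1.5 * w^2 * wz  # um^3
  sum(vapply(spec$species, function(s) {
    q <- if (channel == "g") s$brightness_g * s$stoichiometry_g
         else s$brightness_r * s$stoichiometry_r
    dens <- s$concentration * .NA_CONST * 1e-15  # particles per um^3
    f <- if (include_triplet) 1 - s$theta else 1
    q * dens * vol_int * f
  }, numeric(1)))
}

#' @export
print.fccs_simspec <- function(x, ...) {
  cat("FCS/FCCS trace simulation spec\n")
  cat(sprintf("  %d species, box %s um, duration %g s, bin %g us, seed %s\n",
              length(x$species), paste(x$box, collapse = "x"), x$duration,
              x$bin_width * 1e6, format(x$seed)))
  for (s in x$species)
    cat(sprintf("  - %s: D=%g um2/s, C=%g nM, q=(%g,%g) x (%d,%d)\n",
                s$name, s$D, s$concentration * 1e9, s$brightness_g,
                s$brightness_r, s$stoichiometry_g, s$stoichiometry_r))
  invisible(x)
}
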