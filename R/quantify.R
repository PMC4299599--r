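#' Correction parameters for per-cell quantification
#'
#' Background rates come from wild-type (unlabeled) cell measurements;
#' crosstalk is the green-to-red bleed-through fraction; maturation factors
#' are the fluorescent fractions of each fluorophore (complexes carrying a
#' dark partner are invisible to cross-correlation); the overlap factor
#' comes from volume calibration. All corrections are identity operations
#' at their neutral values (B = 0, beta = 0, maturation = 1, overlap = 1).
#'
#' @param background_g,background_r background count rates, counts/s.
#' @param crosstalk_g_to_r bleed-through fraction in `[0, 1)`.
#' @param maturation_g,maturation_r fluorescent fractions in (0, 1].
#' @param overlap_factor detection-volume overlap in (0, 1].
#' @return A `correction_config` list.
#' @export
correction_config <- function(background_g = 0, background_r = 0,
                              crosstalk_g_to_r = 0,
                              maturation_g = 1, maturation_r = 1,
                              overlap_factor = 1) {
  if (background_g < 0 || background_r < 0) stop("background must be >= 0")
  if (crosstalk_g_to_r < 0 || crosstalk_g_to_r >= 1)
    stop("crosstalk must be in [0, 1)")
  if (maturation_g <= 0 || maturation_g > 1 ||
      maturation_r <= 0 || maturation_r > 1)
    stop("maturation must be in (0, 1]")
  if (overlap_factor <= 0 || overlap_factor > 1)
    stop("overlap_factor must be in (0, 1]")
  structure(list(background_g = background_g, background_r = background_r,
                 crosstalk_g_to_r = crosstalk_g_to_r,
                 maturation_g = maturation_g, maturation_r = maturation_r,
                 overlap_factor = overlap_factor),
            class = "correction_config")
}

#' Background correction of an apparent particle number
#'
#' Uncorrelated background inflates the apparent particle number because it
#' dilutes the relative fluctuation amplitude:
#' `N_corr = N_apparent ((F - B) / F)^2`.
#'
#' @param N_apparent fitted particle number.
#' @param F_mean measured mean count rate, counts/s.
#' @param B background count rate, counts/s (must be < `F_mean`).
#' @return Corrected particle number (`<= N_apparent`; equal iff B = 0).
#' @export
correct_background <- function(N_apparent, F_mean, B) {
  if (B < 0 || B >= F_mean)
    stop("background must satisfy 0 <= B < F_mean")
  N_apparent * ((F_mean - B) / F_mean)^2
}

#' Particle number to molar concentration
#'
#' `C = N / (V_eff N_Avogadro)`.
#'
#' @param N_corrected background-corrected particle number.
#' @param V_eff effective detection volume, litres.
#' @return Concentration, mol/L.
#' @export
compute_concentration <- function(N_corrected, V_eff) {
  if (V_eff <= 0) stop("V_eff must be positive")
  N_corrected / (V_eff * .NA_CONST)
}

#' Molecular brightness: counts per particle per second
#'
#' `cpps = (F_mean - B) / N_corrected`. This is the average brightness of
#' all detected diffusing particles; for a mixture of oligomeric states it
#' is the particle-number-weighted mean of the state brightnesses.
#'
#' @param F_mean mean count rate, counts/s.
#' @param B background rate, counts/s.
#' @param N_corrected background-corrected particle number (> 0).
#' @return Brightness, counts/particle/s.
#' @export
compute_cpps <- function(F_mean, B, N_corrected) {
  if (N_corrected <= 0) stop("N_corrected must be positive")
  (F_mean - B) / N_corrected
}

#' Diffusion coefficient from diffusion time
#'
#' `D = w_xy^2 / (4 tau_diff)`, with the diffusion time taken from the
#' half-width of the autocorrelation curve (the fitted `tau_diff`).
#'
#' @param tau_diff diffusion time, s.
#' @param w_xy lateral 1/e^2 radius of the detection volume, um.
#' @return Diffusion coefficient, um^2/s.
#' @export
compute_D <- function(tau_diff, w_xy) {
  if (tau_diff <= 0 || w_xy <= 0) stop("inputs must be positive")
  w_xy^2 / (4 * tau_diff)
}

#' Remove green-to-red spectral bleed-through from amplitudes and rates
#'
#' With bleed-through fraction `beta`, the measured red signal is
#' `F_r^meas = F_r + beta F_g` and the measured (unnormalized) covariance
#' amplitudes gain green contributions:
#' `c_gr^meas = c_gr + beta c_gg`,
#' `c_rr^meas = c_rr + 2 beta c_gr^meas - beta^2 c_gg` (in measured form
#' `c_rr^meas = c_rr + 2 beta c_gr + beta^2 c_gg`). The correction inverts
#' this algebra exactly on the covariances `c_ij = G_ij F_i F_j` and
#' re-normalizes with the corrected red rate. `beta = 0` is the identity.
#'
#' Inputs must already be background-corrected (see [correct_background()]
#' and [quantify_cell()] for the full ordering).
#'
#' @param G_gg0,G_rr0,G_gr0 measured amplitudes (background-corrected).
#' @param F_g,F_r mean molecular rates, counts/s (`F_r` still containing the
#'   bleed-through contribution).
#' @param beta crosstalk fraction in `[0, 1)`.
#' @return list with corrected `G_gg0`, `G_rr0`, `G_gr0`, `F_g`, `F_r`.
#' @export
correct_crosstalk <- function(G_gg0, G_rr0, G_gr0, F_g, F_r, beta) {
  if (beta < 0 || beta >= 1) stop("beta must be in [0, 1)")
  c_gg <- G_gg0 * F_g^2
  c_gr_m <- G_gr0 * F_g * F_r
  c_rr_m <- G_rr0 * F_r^2
  F_r_c <- F_r - beta * F_g
  if (F_r_c <= 0)
    stop("corrected red rate is non-positive: crosstalk fraction too large")
  c_gr <- c_gr_m - beta * c_gg
  c_rr <- c_rr_m - 2 * beta * c_gr_m + beta^2 * c_gg
  list(G_gg0 = G_gg0,
       G_rr0 = c_rr / F_r_c^2,
       G_gr0 = c_gr / (F_g * F_r_c),
       F_g = F_g, F_r = F_r_c)
}

#' Complex concentration from FCCS amplitudes
#'
#' The cross-correlation amplitude is proportional to the concentration of
#' double-labeled complexes:
#' `C_AB = G_gr0 / (G_gg0 G_rr0 V_rg N_Avogadro)`, divided by the
#' maturation factors (complexes with a non-fluorescent partner escape
#' cross-correlation) and by `overlap_factor^2` (imperfect volume overlap
#' attenuates the cross amplitude). A negative cross amplitude is clipped
#' to `C_AB = 0` with a flag.
#'
#' @param G_gg0,G_rr0 background- and crosstalk-corrected autocorrelation
#'   amplitudes (> 0).
#' @param G_gr0 corrected cross-correlation amplitude.
#' @param volume an `observation_volume` (uses `V_rg`).
#' @param corrections a [correction_config()].
#' @param G_gr0_se optional standard error of `G_gr0`, propagated to
#'   `C_AB_se`.
#' @return list with `C_AB` (mol/L), `C_AB_se`, and `clipped` flag.
#' @export
complex_concentration <- function(G_gg0, G_rr0, G_gr0, volume,
                                  corrections = correction_config(),
                                  G_gr0_se = NA_real_) {
  if (G_gg0 <= 0 || G_rr0 <= 0)
    stop("autocorrelation amplitudes must be positive")
  scale <- 1 / (G_gg0 * G_rr0 * volume$V_rg * .NA_CONST) /
    (corrections$maturation_g * corrections$maturation_r) /
    corrections$overlap_factor^2
  c_ab <- G_gr0 * scale
  clipped <- FALSE
  if (c_ab < 0) {
    c_ab <- 0
    clipped <- TRUE
  }
  list(C_AB = c_ab, C_AB_se = abs(G_gr0_se) * scale, clipped = clipped)
}

#' Apparent dissociation constant from FCS/FCCS concentrations
#'
#' `K_D^app = ([A]_FCS - C_AB)([B]_FCS - C_AB) / C_AB`, where the FCS
#' concentrations contain both free and complexed protein. If the complex
#' concentration is zero or smaller than its uncertainty, the interaction
#' is outside the dynamic range and the above-range sentinel `Inf` is
#' returned (reported as "> 1 uM", the reliable FCCS detection bound). The
#' value is an upper bound for self-interactions, where same-label
#' complexes are invisible to cross-correlation.
#'
#' @param C_A,C_B total concentrations from FCS, mol/L.
#' @param C_AB complex concentration from FCCS, mol/L.
#' @param C_AB_se uncertainty of `C_AB`; used for the above-range decision.
#' @return `K_D^app` in mol/L, or `Inf` (above-range sentinel).
#' @export
apparent_KD <- function(C_A, C_B, C_AB, C_AB_se = 0) {
  if (is.na(C_AB) || C_AB <= 0) return(Inf)
  if (is.finite(C_AB_se) && C_AB <= C_AB_se) return(Inf)
  c_ab <- min(C_AB, C_A, C_B)  # clip to the stoichiometric bound
  if (c_ab <= 0) return(Inf)
  (C_A - c_ab) * (C_B - c_ab) / c_ab
}

#' Above-range test for apparent K_D values
#' @param K_D_app value from [apparent_KD()].
#' @return `TRUE` if the value is the above-range sentinel.
#' @export
is_above_range <- function(K_D_app) !is.finite(K_D_app)

#' Cytoplasmic molecules per cell
#'
#' `count = round(C x cell volume x cytoplasmic fraction x N_Avogadro)`,
#' with the volume in litres (1 um^3 = 1e-15 L).
#'
#' @param C concentration, mol/L.
#' @param cell_volume total cell volume, um^3 (default 70, haploid budding
#'   yeast).
#' @param cytoplasmic_fraction fraction of the cell volume that is
#'   cytoplasm (default 0.29).
#' @return Integer molecule count.
#' @examples
#' molecules_per_cell(16e-9)   # ~196
#' molecules_per_cell(10e-9)   # 122
#' @export
molecules_per_cell <- function(C, cell_volume = 70,
                               cytoplasmic_fraction = 0.29) {
  if (C < 0 || cell_volume <= 0 || cytoplasmic_fraction <= 0 ||
      cytoplasmic_fraction > 1)
    stop("invalid inputs")
  round(C * cell_volume * cytoplasmic_fraction * 1e-15 * .NA_CONST)
}

#' Full per-cell quantification from fitted curves
#'
#' Applies the correction chain in its physical order and converts fitted
#' amplitudes into the per-cell quantities: (1) amplitudes and rates are
#' taken from the three fits and the measured mean rates; (2) background is
#' removed from rates, and amplitudes are rescaled by `(F/(F-B))` per
#' channel (the amplitude form of `N_corr = N ((F-B)/F)^2`); (3) spectral
#' crosstalk is inverted on the covariance amplitudes; (4) particle
#' numbers, concentrations, diffusion coefficients, brightness, complex
#' concentration and apparent K_D are computed.
#'
#' @param fit_gg,fit_rr `fit_result`s of the two autocorrelations.
#' @param amp_gr list with `amplitude` and `se` of the cross-correlation
#'   (from a fit amplitude `1/N` or [plateau_amplitude()]).
#' @param rates named list/vector with mean measured rates `F_g`, `F_r`
#'   (counts/s, from the retained pre-detrend trace).
#' @param volume an `observation_volume`.
#' @param corrections a [correction_config()].
#' @param strain optional strain label.
#' @return A `cell_measurement`: one-row data.frame with concentrations
#'   (mol/L), diffusion coefficients (um^2/s), cpps (counts/particle/s),
#'   `C_AB`, `K_D_app` (`Inf` = above range) and quality flags.
#' @export
quantify_cell <- function(fit_gg, fit_rr, amp_gr, rates, volume,
                          corrections = correction_config(), strain = "") {
  stopifnot(fit_gg$converged)
  F_g <- rates[["F_g"]]
  F_r <- rates[["F_r"]]
  B_g <- corrections$background_g
  B_r <- corrections$background_r

  G_gg0 <- 1 / fit_gg$model$N
  # background: rescale amplitudes, subtract rates
  fg_fac <- F_g / (F_g - B_g)
  if (!is.finite(fg_fac) || fg_fac <= 0)
    stop("background exceeds measured rate in the green channel")
  G_gg0 <- G_gg0 * fg_fac^2
  F_g_c <- F_g - B_g

  have_red <- !is.null(fit_rr) && isTRUE(fit_rr$converged)
  if (have_red) {
    fr_fac <- F_r / (F_r - B_r)
    if (!is.finite(fr_fac) || fr_fac <= 0)
      stop("background exceeds measured rate in the red channel")
    F_r_c <- F_r - B_r
    G_rr0 <- (1 / fit_rr$model$N) * fr_fac^2
    G_gr0 <- amp_gr$amplitude * fg_fac * fr_fac
    G_gr0_se <- amp_gr$se * fg_fac * fr_fac
    ct <- correct_crosstalk(G_gg0, G_rr0, G_gr0, F_g_c, F_r_c,
                            corrections$crosstalk_g_to_r)
  } else {
    ct <- list(G_gg0 = G_gg0, G_rr0 = NA_real_, G_gr0 = NA_real_,
               F_g = F_g_c, F_r = NA_real_)
    G_gr0_se <- NA_real_
  }

  N_g <- 1 / ct$G_gg0
  C_g <- compute_concentration(N_g, volume$V_eff_g) / corrections$maturation_g
  D_g <- compute_D(fit_gg$model$tau_diff, volume$w_xy_g)
  cpps_g <- compute_cpps(ct$F_g, 0, N_g)

  if (have_red && ct$G_rr0 > 0) {
    N_r <- 1 / ct$G_rr0
    C_r <- compute_concentration(N_r, volume$V_eff_r) /
      corrections$maturation_r
    D_r <- compute_D(fit_rr$model$tau_diff, volume$w_xy_r)
    cpps_r <- compute_cpps(ct$F_r, 0, N_r)
    cc <- complex_concentration(ct$G_gg0, ct$G_rr0, ct$G_gr0, volume,
                                corrections, G_gr0_se)
    kd <- apparent_KD(C_g, C_r, cc$C_AB, cc$C_AB_se)
    c_ab <- cc$C_AB
    c_ab_se <- cc$C_AB_se
    clipped <- cc$clipped
  } else {
    N_r <- C_r <- D_r <- cpps_r <- NA_real_
    c_ab <- c_ab_se <- NA_real_
    kd <- Inf
    clipped <- FALSE
  }

  structure(data.frame(
    strain = strain, C_g = C_g, C_r = C_r, D_g = D_g, D_r = D_r,
    cpps_g = cpps_g, cpps_r = cpps_r, N_g = N_g, N_r = N_r,
    F_g = F_g, F_r = F_r, C_AB = c_ab, C_AB_se = c_ab_se,
    K_D_app = kd, kd_above_range = is_above_range(kd),
    cross_clipped = clipped, red_converged = have_red,
    alpha_g = fit_gg$model$alpha,
    alpha_r = if (have_red) fit_rr$model$alpha else NA_real_,
    stringsAsFactors = FALSE), class = c("cell_measurement", "data.frame"))
}

#' Analyze one photon trace end to end
#'
#' Convenience wrapper running the full single-cell chain: artifact
#' rejection, bleach detrending, multi-tau correlation of both
#' autocorrelations and the cross-correlation, model fitting, and
#' [quantify_cell()].
#'
#' @param trace a [photon_trace()].
#' @param volume an `observation_volume`.
#' @param corrections a [correction_config()].
#' @param kind diffusion model for the autocorrelation fits
#'   (`"anomalous"` for in vivo data, `"free"` for dyes).
#' @param detrend_window local-average window, s.
#' @param artifact_window,z_threshold artifact-scan parameters
#'   (see [reject_artifacts()]).
#' @param n_segments correlator segments.
#' @param strain strain label for the output row.
#' @param red treat the red channel as labeled (`FALSE` for green-only
#'   measurements).
#' @return A `cell_measurement`, or `NULL` (with a warning) if the trace is
#'   flagged for discarding or the green fit fails.
#' @export
analyze_trace <- function(trace, volume,
                          corrections = correction_config(),
                          kind = "anomalous", detrend_window = 2,
                          artifact_window = 0.2, z_threshold = 5,
                          n_segments = 10L, strain = "", red = TRUE) {
  mask <- reject_artifacts(trace, window = artifact_window,
                           z_threshold = z_threshold)
  if (mask$discard) {
    warning("trace flagged for discarding (", strain, ")")
    return(NULL)
  }
  det <- detrend_local_average(trace, window = detrend_window)
  cv_gg <- correlate(det, mask, "gg", n_segments = n_segments)
  fit_gg <- fit_curve(cv_gg, kind = kind, volume = volume)
  if (!fit_gg$converged) {
    warning("green autocorrelation fit failed (", strain, "): ",
            fit_gg$message)
    return(NULL)
  }
  fit_rr <- NULL
  amp_gr <- list(amplitude = NA_real_, se = NA_real_)
  cv_rr <- correlate(det, mask, "rr", n_segments = n_segments)
  if (red) {
    fit_rr <- tryCatch(fit_curve(cv_rr, kind = kind, volume = volume),
                       error = function(e) NULL)
    cv_gr <- correlate(det, mask, "gr", n_segments = n_segments)
    fit_gr <- tryCatch(fit_curve(cv_gr, kind = kind, volume = volume,
                                 fit_triplet = FALSE),
                       error = function(e) NULL)
    amp_gr <- if (!is.null(fit_gr) && fit_gr$converged) {
      se_N <- tryCatch(fit_gr$se[["N"]], error = function(e) NA_real_)
      se_amp <- if (is.finite(se_N)) se_N / fit_gr$model$N^2
                else plateau_amplitude(cv_gr)$se
      list(amplitude = 1 / fit_gr$model$N, se = se_amp)
    } else plateau_amplitude(cv_gr)
    if (!is.null(fit_rr) && !fit_rr$converged) fit_rr <- NULL
  }
  rates <- list(F_g = cv_gg$mean_rate_i, F_r = cv_rr$mean_rate_i)
  quantify_cell(fit_gg, fit_rr, amp_gr, rates, volume, corrections,
                strain = strain)
}
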