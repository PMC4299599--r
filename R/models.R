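#' Triplet-corrected (anomalous) diffusion correlation model
#'
#' Closed form for one diffusing component in a 3D-Gaussian volume with a
#' fast reversible dark state:
#' \deqn{G(\tau) = G_\infty + \frac{1}{N}
#'   \left[1 + \frac{\Theta}{1-\Theta} e^{-\tau/\tau_T}\right]
#'   \left(1 + (\tau/\tau_D)^\alpha\right)^{-1}
#'   \left(1 + \kappa^{-2} (\tau/\tau_D)^\alpha\right)^{-1/2}}
#' Free diffusion is the restriction `alpha = 1`; `alpha < 1` describes
#' subdiffusion in the crowded cytoplasm. At `tau -> 0` the diffusive
#' amplitude is `1/N` (times `1/(1-Theta)` when blinking is present).
#'
#' @param lag lag time(s), s (vectorized).
#' @param N mean particle number in the effective volume (> 0).
#' @param tau_diff diffusion time, s.
#' @param alpha anomaly exponent in (0, 1]; 1 = free diffusion.
#' @param theta triplet fraction in `[0, 1)`.
#' @param tau_triplet triplet lifetime, s.
#' @param kappa structure parameter `w_z / w_xy`.
#' @param G_inf baseline offset.
#' @return Model correlation value(s).
#' @examples
#' model_G(0, N = 10, tau_diff = 1e-3)            # 1/N
#' model_G(1e-3, N = 10, tau_diff = 1e-3, kappa = 1e9)  # ~1/(2N)
#' @export
model_G <- function(lag, N, tau_diff, alpha = 1, theta = 0,
                    tau_triplet = 1e-5, kappa = 5, G_inf = 0) {
  x <- (lag / tau_diff)^alpha
  trip <- if (theta > 0)
    1 + theta / (1 - theta) * exp(-lag / tau_triplet) else 1
  G_inf + (1 / N) * trip / ((1 + x) * sqrt(1 + x / kappa^2))
}

## running geometric mean of per-lag SEMs (window 2*half+1, edge-shrunk)
.smooth_sem <- function(sem, half = 4L) {
  n <- length(sem)
  if (n < 3) return(sem)
  lg <- log(pmax(sem, .Machine$double.xmin))
  exp(.movmean(lg, half))
}

#' Average correlation curves measured under identical conditions
#'
#' Lag-wise mean of curves sharing one lag grid (e.g. repeated calibration
#' measurements); the SEM is recomputed from the between-curve scatter.
#'
#' @param curves list of `correlation_curve`s with identical lag grids.
#' @return A `correlation_curve`.
#' @export
average_curves <- function(curves) {
  stopifnot(length(curves) >= 1)
  lags <- curves[[1]]$lags
  for (cv in curves)
    if (length(cv$lags) != length(lags) || any(abs(cv$lags - lags) > 1e-12))
      stop("curves must share one lag grid")
  Gm <- vapply(curves, function(cv) cv$G, numeric(length(lags)))
  if (length(lags) == 1L) Gm <- matrix(Gm, nrow = 1)
  out <- curves[[1]]
  out$G <- rowMeans(Gm)
  sems <- vapply(curves, function(cv) cv$G_sem, numeric(length(lags)))
  if (length(lags) == 1L) sems <- matrix(sems, nrow = 1)
  out$G_sem <- if (all(is.finite(sems)))
    sqrt(rowMeans(sems^2)) / sqrt(length(curves))  # pooled chunk SEMs
  else if (length(curves) >= 2) apply(Gm, 1, sd) / sqrt(length(curves))
  else curves[[1]]$G_sem
  out$mean_rate_i <- mean(vapply(curves, `[[`, 0, "mean_rate_i"))
  out$mean_rate_j <- mean(vapply(curves, `[[`, 0, "mean_rate_j"))
  out$effective_duration <-
    sum(vapply(curves, `[[`, 0, "effective_duration"))
  out$n_segments <- sum(vapply(curves, `[[`, 0L, "n_segments"))
  out
}

#' Fit a diffusion model to a correlation curve
#'
#' Weighted least squares (weights `1/G_sem^2`; unit weights if the SEM is
#' unavailable) of [model_G()] via Levenberg-Marquardt. Initialization
#' follows standard practice: `N0 = 1/G` at the first fitted lag, `tau0`
#' from the half-width of the curve (the lag where G first falls below half
#' its initial value), `Theta0 = 0.1`, `tau_triplet0 = 10` us. Bounds keep
#' all parameters in their physical ranges; non-convergence is reported in
#' the result, never silently replaced by defaults.
#'
#' @param curve a `correlation_curve` (needs >= 20 lags spanning >= 3
#'   decades for a meaningful fit; fewer lags give a warning).
#' @param kind `"anomalous"` (alpha free in (0, 1]) or `"free"` (alpha = 1).
#' @param volume optional `observation_volume`; fixes `kappa` per channel
#'   from the calibration (green for pair `"gg"`, red for `"rr"`, their
#'   geometric mean for cross curves).
#' @param fit_triplet fit `theta`/`tau_triplet` (`TRUE`), or fix them
#'   (`FALSE` fixes `theta = theta_fixed`).
#' @param theta_fixed triplet fraction used when `fit_triplet = FALSE`.
#' @param fit_kappa float `kappa` (used for reference-dye calibration fits);
#'   otherwise it is fixed.
#' @param kappa fixed structure parameter when no `volume` is given.
#' @param lag_range numeric length-2 fit window, s. Default starts at the
#'   second bin (the first bin is most exposed to residual afterpulsing-like
#'   artifacts) and extends to the end of the curve.
#' @param min_lags minimum number of lags required.
#' @return A `fit_result`: list with `model` (named parameters incl.
#'   `kappa` and `kind`), `se` (standard errors), `chisq_red`, `converged`,
#'   `lag_range`, `n_lags`, and `message` on failure.
#' @export
fit_curve <- function(curve, kind = c("anomalous", "free"), volume = NULL,
                      fit_triplet = TRUE, theta_fixed = 0,
                      fit_kappa = FALSE, kappa = 5, lag_range = NULL,
                      min_lags = 20L) {
  stopifnot(inherits(curve, "correlation_curve"))
  kind <- match.arg(kind)
  if (!is.null(volume)) {
    kappa <- switch(curve$pair,
                    gg = volume$kappa_g, rr = volume$kappa_r,
                    sqrt(volume$kappa_g * volume$kappa_r))
  }
  if (is.null(lag_range)) lag_range <- c(2 * curve$bin_width, Inf)
  sel <- curve$lags >= lag_range[1] & curve$lags <= lag_range[2] &
    is.finite(curve$G)
  lag <- curve$lags[sel]
  G <- curve$G[sel]
  sem <- curve$G_sem[sel]
  if (length(lag) < min_lags)
    warning("only ", length(lag), " lags in fit range")
  if (length(lag) < 5) stop("fit-infeasible: too few lags")
  if (max(head(G, 5)) <= 0)
    stop("fit-infeasible: non-positive correlation amplitude")

  # Weights from the between-segment SEM, smoothed across neighboring lags:
  # raw per-lag SEMs are themselves noisy (few segments) and correlated with
  # the point noise, which biases a weighted fit; a running geometric mean
  # keeps the orders-of-magnitude lag dependence while decorrelating the
  # weights from the fluctuations they weight.
  w <- if (all(is.finite(sem)) && all(sem > 0))
    1 / .smooth_sem(sem)^2 else rep(1, length(lag))

  G1 <- G[1]
  N0 <- 1 / G1
  half_idx <- which(G < G1 / 2)
  tau0 <- if (length(half_idx)) lag[half_idx[1]] else lag[length(lag)] / 4
  tau_t_hi <- max(min(tau0 / 2, 1e-3), 2e-5)

  start <- list(N = N0, tau_diff = tau0, G_inf = 0)
  lower <- c(N = 1e-8, tau_diff = lag[1] / 10, G_inf = -abs(G1))
  upper <- c(N = Inf, tau_diff = 100, G_inf = abs(G1))
  if (kind == "anomalous") {
    start$alpha <- 0.95
    lower["alpha"] <- 0.2
    upper["alpha"] <- 1
  }
  if (fit_triplet) {
    start$theta <- 0.1
    start$tau_triplet <- 1e-5
    lower["theta"] <- 0
    upper["theta"] <- 0.8
    lower["tau_triplet"] <- 1e-7
    upper["tau_triplet"] <- tau_t_hi
  }
  if (fit_kappa) {
    start$kappa <- kappa
    lower["kappa"] <- 1
    upper["kappa"] <- 50
  }

  fixed <- list(alpha = 1, theta = theta_fixed, tau_triplet = 1e-5,
                kappa = kappa)
  fn <- function(p) {
    pp <- modifyList(fixed, as.list(p))
    model_G(lag, N = pp$N, tau_diff = pp$tau_diff, alpha = pp$alpha,
            theta = pp$theta, tau_triplet = pp$tau_triplet,
            kappa = pp$kappa, G_inf = pp$G_inf)
  }

  fit <- tryCatch(
    minpack.lm::nls.lm(
      par = start,
      lower = lower[names(start)], upper = upper[names(start)],
      fn = function(p) sqrt(w) * (G - fn(p)),
      control = minpack.lm::nls.lm.control(maxiter = 300, ftol = 1e-13,
                                           ptol = 1e-13)),
    error = function(e) e)

  if (inherits(fit, "error") || !(fit$info %in% 1:4)) {
    msg <- if (inherits(fit, "error")) conditionMessage(fit) else fit$message
    return(structure(list(model = NULL, se = NULL, chisq_red = NA_real_,
                          converged = FALSE, lag_range = range(lag),
                          n_lags = length(lag), pair = curve$pair,
                          message = msg),
                     class = "fit_result"))
  }

  par <- modifyList(fixed, fit$par)
  se <- tryCatch(summary(fit)$coefficients[, "Std. Error"],
                 error = function(e)
                   setNames(rep(NA_real_, length(fit$par)),
                            names(fit$par)))
  dof <- max(length(lag) - length(fit$par), 1)
  chisq_red <- sum(fit$fvec^2) / dof
  structure(list(
    model = list(kind = kind, N = par$N, tau_diff = par$tau_diff,
                 alpha = par$alpha, theta = par$theta,
                 tau_triplet = par$tau_triplet, kappa = par$kappa,
                 G_inf = par$G_inf),
    se = se, chisq_red = chisq_red, converged = TRUE,
    lag_range = range(lag), n_lags = length(lag), pair = curve$pair,
    message = ""), class = "fit_result")
}

#' @export
print.fit_result <- function(x, ...) {
  if (!x$converged) {
    cat("fit_result: NOT CONVERGED (", x$message, ")\n")
    return(invisible(x))
  }
  m <- x$model
  cat(sprintf(
    "fit_result [%s, %s]: N=%.4g tau_diff=%.4g s alpha=%.3g theta=%.3g\n",
    x$pair, m$kind, m$N, m$tau_diff, m$alpha, m$theta))
  cat(sprintf("  kappa=%.3g G_inf=%.3g red.chisq=%.3g (%d lags)\n",
              m$kappa, m$G_inf, x$chisq_red, x$n_lags))
  invisible(x)
}

#' Write a delimited fit report
#'
#' One row per fitted curve with all model parameters, standard errors,
#' reduced chi-square and the convergence flag.
#'
#' @param fits list of `fit_result`s (optionally named).
#' @param path output path (tab-separated).
#' @return `path`, invisibly.
#' @export
write_fit_report <- function(fits, path) {
  if (inherits(fits, "fit_result")) fits <- list(fits)
  rows <- lapply(seq_along(fits), function(i) {
    f <- fits[[i]]
    label <- if (!is.null(names(fits)) && nzchar(names(fits)[i]))
      names(fits)[i] else sprintf("curve_%02d", i)
    se <- function(p) {
      v <- tryCatch(f$se[[p]], error = function(e) NA_real_)
      if (is.null(v)) NA_real_ else v
    }
    m <- f$model
    data.frame(
      curve = label, pair = f$pair, converged = f$converged,
      kind = if (f$converged) m$kind else NA_character_,
      N = if (f$converged) m$N else NA_real_, N_se = se("N"),
      tau_diff_s = if (f$converged) m$tau_diff else NA_real_,
      tau_diff_se = se("tau_diff"),
      alpha = if (f$converged) m$alpha else NA_real_,
      alpha_se = se("alpha"),
      theta = if (f$converged) m$theta else NA_real_,
      theta_se = se("theta"),
      tau_triplet_s = if (f$converged) m$tau_triplet else NA_real_,
      kappa = if (f$converged) m$kappa else NA_real_,
      G_inf = if (f$converged) m$G_inf else NA_real_,
      red_chisq = f$chisq_red, n_lags = f$n_lags,
      message = f$message, stringsAsFactors = FALSE)
  })
  data.table::fwrite(do.call(rbind, rows), path, sep = "\t")
  invisible(path)
}

#' Small-lag amplitude of a curve from its initial plateau
#'
#' Robust fallback when a model fit is infeasible (e.g. a cross-correlation
#' curve fluctuating around zero): the mean of the first `n` correlation
#' values and its standard error.
#'
#' @param curve a `correlation_curve`.
#' @param n number of initial lags to average.
#' @return list with `amplitude` and `se`.
#' @export
plateau_amplitude <- function(curve, n = 8L) {
  n <- min(n, length(curve$G))
  g <- curve$G[seq_len(n)]
  sems <- curve$G_sem[seq_len(n)]
  se1 <- if (all(is.finite(sems))) mean(sems) / sqrt(n / 2) else NA_real_
  se2 <- if (n >= 3) sd(g) / sqrt(n / 2) else NA_real_
  list(amplitude = mean(g), se = max(se1, se2, na.rm = TRUE))
}

#' Calibrate the observation volumes from reference-dye measurements
#'
#' Free-diffusion fits of dye correlation curves with known diffusion
#' coefficients determine the detection geometry at the start of a
#' measurement session: `w_xy = sqrt(4 D_known tau_diff)` per channel with
#' `kappa` floated in the dye fit, `V_eff = pi^(3/2) w_xy^2 w_z`, the
#' effective cross-correlation volume `V_rg` from a dual-labeled dye
#' measured in the cross channel, and
#' `overlap_factor = sqrt(V_eff_g V_eff_r) / V_rg`.
#'
#' @param dye_curves named list of `correlation_curve`s: `g` (green
#'   autocorrelation of the green-channel dye), `r` (red), `x`
#'   (cross-correlation of the dual-channel dye).
#' @param D_known named numeric vector (`g`, `r`, `x`) of dye diffusion
#'   coefficients, um^2/s.
#' @param fit_triplet fit a triplet component in the dye fits (default
#'   `FALSE`: dye photophysics is negligible at the powers used).
#' @param joint_kappa fit a single structure parameter shared by the three
#'   dye curves (default `TRUE`). The pinhole geometry is common to all
#'   channels, and kappa is weakly identified from a single dilute-dye
#'   curve because it trades off against the diffusion time; the three
#'   different dye diffusion times break that degeneracy.
#' @param lag_max largest lag used in the dye fits, s. The far tail of a
#'   dilute-dye curve carries no shape information (the dye has left the
#'   volume) but is the part most exposed to residual estimator bias, so it
#'   is excluded by default.
#' @return An `observation_volume`: `w_xy_g`, `w_xy_r`, `w_xy_rg` (um),
#'   `kappa_g`, `kappa_r`, `kappa_rg`, `V_eff_g`, `V_eff_r`, `V_rg` (L),
#'   `overlap_factor`.
#' @export
calibrate_volume <- function(dye_curves, D_known, fit_triplet = FALSE,
                             joint_kappa = TRUE, lag_max = 2e-3) {
  stopifnot(all(c("g", "r", "x") %in% names(dye_curves)),
            all(c("g", "r", "x") %in% names(D_known)))
  fits <- lapply(c(g = "g", r = "r", x = "x"), function(ch) {
    f <- tryCatch(
      fit_curve(dye_curves[[ch]], kind = "free",
                fit_triplet = fit_triplet, fit_kappa = TRUE,
                lag_range = c(0, lag_max)),
      error = function(e) stop("calibration error: dye fit for channel '",
                               ch, "' failed (", conditionMessage(e), ")"))
    if (!f$converged)
      stop("calibration error: dye fit for channel '", ch,
           "' did not converge (", f$message, ")")
    f
  })
  if (joint_kappa) {
    jf <- .fit_dyes_joint_kappa(dye_curves, fits, lag_max)
    for (ch in c("g", "r", "x")) {
      fits[[ch]]$model$tau_diff <- jf$tau[[ch]]
      fits[[ch]]$model$N <- jf$N[[ch]]
      fits[[ch]]$model$kappa <- jf$kappa
    }
  }
  w <- vapply(c("g", "r", "x"), function(ch)
    sqrt(4 * D_known[[ch]] * fits[[ch]]$model$tau_diff), numeric(1))
  k <- vapply(c("g", "r", "x"), function(ch) fits[[ch]]$model$kappa,
              numeric(1))
  V_g <- effective_volume(w[["g"]], k[["g"]])
  V_r <- effective_volume(w[["r"]], k[["r"]])
  V_rg <- effective_volume(w[["x"]], k[["x"]])
  overlap <- min(sqrt(V_g * V_r) / V_rg, 1)
  structure(list(w_xy_g = w[["g"]], w_xy_r = w[["r"]], w_xy_rg = w[["x"]],
                 kappa_g = k[["g"]], kappa_r = k[["r"]], kappa_rg = k[["x"]],
                 V_eff_g = V_g, V_eff_r = V_r, V_rg = V_rg,
                 overlap_factor = overlap, fits = fits),
            class = "observation_volume")
}

## joint weighted fit of the three dye curves with one shared kappa;
## per-curve N, tau_diff, G_inf; initialized from the individual fits
.fit_dyes_joint_kappa <- function(dye_curves, fits, lag_max) {
  chs <- c("g", "r", "x")
  dat <- lapply(chs, function(ch) {
    cv <- dye_curves[[ch]]
    sel <- cv$lags >= 2 * cv$bin_width & cv$lags <= lag_max &
      is.finite(cv$G)
    sem <- cv$G_sem[sel]
    w <- if (all(is.finite(sem)) && all(sem > 0))
      1 / .smooth_sem(sem)^2 else rep(1, sum(sel))
    list(lag = cv$lags[sel], G = cv$G[sel], w = w)
  })
  names(dat) <- chs
  start <- list()
  for (ch in chs) {
    start[[paste0("N_", ch)]] <- fits[[ch]]$model$N
    start[[paste0("tau_", ch)]] <- fits[[ch]]$model$tau_diff
    start[[paste0("Ginf_", ch)]] <- fits[[ch]]$model$G_inf
  }
  start$kappa <- median(vapply(fits, function(f) f$model$kappa, numeric(1)))
  lower <- setNames(rep(1e-8, length(start)), names(start))
  upper <- setNames(rep(Inf, length(start)), names(start))
  for (ch in chs) {
    lower[[paste0("Ginf_", ch)]] <- -1
    upper[[paste0("Ginf_", ch)]] <- 1
  }
  lower[["kappa"]] <- 1
  upper[["kappa"]] <- 50
  resid <- function(p) {
    p <- as.list(p)
    unlist(lapply(chs, function(ch) {
      m <- model_G(dat[[ch]]$lag, N = p[[paste0("N_", ch)]],
                   tau_diff = p[[paste0("tau_", ch)]], alpha = 1,
                   theta = 0, kappa = p$kappa,
                   G_inf = p[[paste0("Ginf_", ch)]])
      sqrt(dat[[ch]]$w) * (dat[[ch]]$G - m)
    }))
  }
  fit <- minpack.lm::nls.lm(
    par = start, lower = lower[names(start)], upper = upper[names(start)],
    fn = resid,
    control = minpack.lm::nls.lm.control(maxiter = 300, ftol = 1e-13,
                                         ptol = 1e-13))
  if (!(fit$info %in% 1:4))
    stop("calibration error: joint dye fit did not converge (",
         fit$message, ")")
  p <- fit$par
  list(kappa = p$kappa,
       N = list(g = p$N_g, r = p$N_r, x = p$N_x),
       tau = list(g = p$tau_g, r = p$tau_r, x = p$tau_x))
}

#' Construct an observation volume directly from known geometry
#'
#' Bypass dye calibration when the geometry is known (e.g. for simulated
#' data where the optics are specified exactly).
#'
#' @param w_xy_g,w_xy_r lateral radii, um.
#' @param kappa_g,kappa_r structure parameters.
#' @param w_xy_rg,kappa_rg cross-volume geometry; defaults assume centered
#'   volumes (`w_rg^2 = (w_g^2 + w_r^2)/2`, kappa the geometric mean).
#' @return An `observation_volume`.
#' @export
observation_volume <- function(w_xy_g, w_xy_r = w_xy_g, kappa_g = 5,
                               kappa_r = kappa_g,
                               w_xy_rg = sqrt((w_xy_g^2 + w_xy_r^2) / 2),
                               kappa_rg = sqrt(kappa_g * kappa_r)) {
  V_g <- effective_volume(w_xy_g, kappa_g)
  V_r <- effective_volume(w_xy_r, kappa_r)
  V_rg <- effective_volume(w_xy_rg, kappa_rg)
  structure(list(w_xy_g = w_xy_g, w_xy_r = w_xy_r, w_xy_rg = w_xy_rg,
                 kappa_g = kappa_g, kappa_r = kappa_r, kappa_rg = kappa_rg,
                 V_eff_g = V_g, V_eff_r = V_r, V_rg = V_rg,
                 overlap_factor = min(sqrt(V_g * V_r) / V_rg, 1)),
            class = "observation_volume")
}

#' @export
print.observation_volume <- function(x, ...) {
  cat(sprintf(
    "observation_volume: w_xy %0.3g/%0.3g um, kappa %0.3g/%0.3g\n",
    x$w_xy_g, x$w_xy_r, x$kappa_g, x$kappa_r))
  cat(sprintf("  V_eff %0.3g / %0.3g L, V_rg %0.3g L, overlap %0.3g\n",
              x$V_eff_g, x$V_eff_r, x$V_rg, x$overlap_factor))
  invisible(x)
}
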