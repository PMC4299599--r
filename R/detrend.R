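## moving average with edge-shrunk centered windows, O(n)
.movmean <- function(v, half) {
  n <- length(v)
  cs <- cumsum(c(0, v))
  i <- seq_len(n)
  lo <- pmax(1L, i - half)
  hi <- pmin(n, i + half)
  (cs[hi + 1L] - cs[lo]) / (hi - lo + 1L)
}

#' Local-average bleaching correction of a photon trace
#'
#' Computes a moving local mean `Fbar(t)` per channel and rescales the
#' signal as
#' `F_c(t) = F(t) / sqrt(Fbar(t)/F0) + F0 (1 - sqrt(Fbar(t)/F0))`,
#' where `F0` is the global trace mean. The square-root scaling restores
#' the local variance of shot noise while the additive term restores the
#' mean, so a photobleaching-induced decay is removed without distorting
#' the fluctuation amplitude; a noise-free decay maps onto a constant at
#' the trace mean. Anchoring at the global mean (rather than at the
#' initial local mean) makes the correction an exact no-op on stationary
#' traces; an initial-intensity anchor would inject the first window's
#' sampling noise (a few percent) into every correlation amplitude. Under
#' bleaching, amplitudes consequently reflect the time-averaged particle
#' number during the acquisition. The uncorrected counts are kept
#' alongside so that photon rates for brightness analysis still reflect
#' the real flux.
#'
#' @param trace a [photon_trace()].
#' @param window local-average window, s (must be at least 100 bins and at
#'   most the trace duration).
#' @return A `photon_trace` with numeric corrected counts, the original
#'   counts preserved in `$counts_g_raw` / `$counts_r_raw`, and
#'   `metadata$detrended = TRUE`.
#' @export
detrend_local_average <- function(trace, window = 2) {
  stopifnot(inherits(trace, "photon_trace"))
  dur <- trace_duration(trace)
  if (window > dur) stop("detrend window longer than trace")
  if (window < 100 * trace$bin_width)
    stop("detrend window must span at least 100 bins")
  half <- max(1L, round(window / trace$bin_width / 2))
  out <- trace
  for (ch in c("counts_g", "counts_r")) {
    f <- as.numeric(trace[[ch]])
    fbar <- .movmean(f, half)
    f0 <- mean(f)
    if (f0 > 0 && all(fbar > 0)) {
      s <- sqrt(fbar / f0)
      out[[ch]] <- f / s + f0 * (1 - s)
    }
    out[[paste0(ch, "_raw")]] <- trace[[ch]]
  }
  out$metadata$detrended <- TRUE
  out$metadata$detrend_window <- window
  out
}

#' Automatic rejection of artifact segments
#'
#' Emulates the manual removal of trace segments in which cell movement or a
#' bright vesicle crossing the observation volume dominates the signal:
#' window means that exceed the robust trace level (median) by
#' `z_threshold` robust standard deviations in either channel are excluded,
#' together with one window of padding on each side. If less than half of
#' the trace survives, the whole trace is flagged for discarding.
#'
#' @param trace a [photon_trace()] (raw counts are used if present).
#' @param window test-window length, s.
#' @param z_threshold robust z-score threshold (> 0).
#' @return A `segment_mask`: list with `intervals` (data.frame of retained
#'   `[start, end)` times, s), `discard` flag, `rejected` intervals with
#'   reasons, and `retained_fraction`.
#' @export
reject_artifacts <- function(trace, window = 0.2, z_threshold = 5) {
  stopifnot(inherits(trace, "photon_trace"))
  if (z_threshold <= 0) stop("z_threshold must be > 0")
  bw <- trace$bin_width
  g <- if (!is.null(trace$counts_g_raw)) trace$counts_g_raw else trace$counts_g
  r <- if (!is.null(trace$counts_r_raw)) trace$counts_r_raw else trace$counts_r
  npb <- max(1L, round(window / bw))
  nwin <- floor(length(g) / npb)
  if (nwin < 3) stop("trace too short for artifact scan at this window")
  wmean <- function(v) {
    m <- matrix(v[seq_len(nwin * npb)], nrow = npb)
    colMeans(m)
  }
  bad <- rep(FALSE, nwin)
  for (v in list(wmean(g), wmean(r))) {
    med <- median(v)
    # robust scale, floored at the Poisson shot-noise level of a window mean
    scl <- max(mad(v), sqrt(max(med, 1e-12) / npb))
    bad <- bad | (v > med + z_threshold * scl)
  }
  # one window of padding on each side of every rejected window
  padded <- bad
  idx <- which(bad)
  padded[pmax(1L, idx - 1L)] <- TRUE
  padded[pmin(nwin, idx + 1L)] <- TRUE

  keep <- !padded
  runs <- rle(keep)
  ends <- cumsum(runs$lengths)
  starts <- ends - runs$lengths + 1L
  iv <- data.frame(start = numeric(0), end = numeric(0))
  rej <- data.frame(start = numeric(0), end = numeric(0),
                    reason = character(0), stringsAsFactors = FALSE)
  for (k in seq_along(runs$values)) {
    a <- (starts[k] - 1L) * npb * bw
    b <- ends[k] * npb * bw
    if (runs$values[k]) iv <- rbind(iv, data.frame(start = a, end = b))
    else rej <- rbind(rej, data.frame(
      start = a, end = b,
      reason = sprintf("window mean > median + %g robust SD", z_threshold),
      stringsAsFactors = FALSE))
  }
  # tail bins beyond the last full window follow the last window's fate
  tail_bins <- length(g) - nwin * npb
  if (tail_bins > 0 && nrow(iv) && abs(iv$end[nrow(iv)] - nwin * npb * bw) <
      bw / 2)
    iv$end[nrow(iv)] <- length(g) * bw
  retained <- if (nrow(iv)) sum(iv$end - iv$start) else 0
  frac <- retained / (length(g) * bw)
  structure(list(intervals = iv, rejected = rej, discard = frac < 0.5,
                 retained_fraction = frac, bin_width = bw,
                 duration = length(g) * bw),
            class = "segment_mask")
}

#' Full-span segment mask for a trace
#' @param trace a `photon_trace`.
#' @return A `segment_mask` retaining the whole trace.
#' @export
full_mask <- function(trace) {
  dur <- trace_duration(trace)
  structure(list(intervals = data.frame(start = 0, end = dur),
                 rejected = data.frame(start = numeric(0), end = numeric(0),
                                       reason = character(0)),
                 discard = FALSE, retained_fraction = 1,
                 bin_width = trace$bin_width, duration = dur),
            class = "segment_mask")
}

#' @export
print.segment_mask <- function(x, ...) {
  cat(sprintf("segment_mask: %.1f%% retained in %d interval(s)%s\n",
              100 * x$retained_fraction, nrow(x$intervals),
              if (x$discard) " [DISCARD]" else ""))
  invisible(x)
}
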