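## map a segment_mask to integer bin intervals [a, b] (1-based, inclusive)
.mask_bins <- function(mask, n) {
  iv <- mask$intervals
  if (!nrow(iv)) return(matrix(numeric(0), ncol = 2))
  a <- pmax(1L, floor(iv$start / mask$bin_width) + 1L)
  b <- pmin(n, round(iv$end / mask$bin_width))
  keep <- b >= a
  cbind(a[keep], b[keep])
}

#' Multi-tau correlation of a two-channel trace
#'
#' Computes `G_ij(tau) = <dF_i(t) dF_j(t + tau)> / (<F_i> <F_j>)` for a
#' channel pair on a quasi-logarithmic multi-tau lag grid (`m` linear lags
#' per octave with bin doubling; the shot-noise-dominated zero-lag bin is
#' excluded, so the first lag is one bin width). The retained part of the
#' trace is divided into `n_segments` equal contiguous chunks (each chunk
#' lying inside one retained interval); the correlation is computed per
#' chunk and averaged, and the per-lag standard error is taken from the
#' between-chunk scatter.
#'
#' Mean photon rates are computed from the uncorrected counts of the
#' retained bins (if the trace was detrended), so brightness estimates
#' reflect the real photon flux.
#'
#' @param trace a [photon_trace()], normally detrended with
#'   [detrend_local_average()].
#' @param mask a `segment_mask` from [reject_artifacts()]; `NULL` retains
#'   the whole trace. Must retain at least 50% of the trace.
#' @param pair one of `"gg"`, `"rr"`, `"gr"`, `"rg"`.
#' @param m multi-tau lags per octave (default 16).
#' @param n_segments number of chunks for the between-segment error.
#' @param max_lag largest lag, s. Defaults to
#'   `min(retained duration / 10, chunk length / 5)`.
#' @return A `correlation_curve`: list with `lags`, `G`, `G_sem`,
#'   `pair`, `mean_rate_i`, `mean_rate_j` (counts/s), `effective_duration`
#'   (s), `n_segments`, `bin_width`.
#' @export
correlate <- function(trace, mask = NULL, pair = c("gg", "rr", "gr", "rg"),
                      m = 16L, n_segments = 10L, max_lag = NULL) {
  stopifnot(inherits(trace, "photon_trace"))
  pair <- match.arg(pair)
  if (is.null(mask)) mask <- full_mask(trace)
  if (mask$discard || mask$retained_fraction < 0.5)
    stop("mask retains less than 50% of the trace; discard the measurement")
  bw <- trace$bin_width
  n <- length(trace$counts_g)
  chan <- function(ch, raw = FALSE) {
    key <- if (ch == "g") "counts_g" else "counts_r"
    if (raw && !is.null(trace[[paste0(key, "_raw")]]))
      trace[[paste0(key, "_raw")]] else trace[[key]]
  }
  ci <- substr(pair, 1, 1)
  cj <- substr(pair, 2, 2)
  x <- as.numeric(chan(ci))
  y <- as.numeric(chan(cj))

  bins <- .mask_bins(mask, n)
  total_bins <- sum(bins[, 2] - bins[, 1] + 1)
  eff_dur <- total_bins * bw
  chunk_bins <- floor(total_bins / n_segments)
  if (chunk_bins < 4 * m)
    stop("trace too short for ", n_segments, " segments at m = ", m)
  if (is.null(max_lag))
    max_lag <- min(eff_dur / 10, chunk_bins * bw / 5)

  # carve contiguous chunks out of the retained intervals
  chunks <- list()
  for (k in seq_len(nrow(bins))) {
    a <- bins[k, 1]
    while (a + chunk_bins - 1 <= bins[k, 2]) {
      chunks[[length(chunks) + 1L]] <- c(a, a + chunk_bins - 1)
      a <- a + chunk_bins
    }
  }
  if (!length(chunks)) stop("no usable segments in mask")

  curves <- lapply(chunks, function(ab) {
    cpp_multitau(x[ab[1]:ab[2]], y[ab[1]:ab[2]], bw, as.integer(m), max_lag)
  })
  lags <- curves[[1]]$lags
  Gm <- vapply(curves, function(cv) cv$G, numeric(length(lags)))
  if (length(lags) == 1L) Gm <- matrix(Gm, nrow = 1)
  G <- rowMeans(Gm)
  nseg <- length(curves)
  if (nseg >= 2) {
    G_sem <- apply(Gm, 1, sd) / sqrt(nseg)
  } else {
    warning("fewer than 2 segments: G_sem unavailable")
    G_sem <- rep(NA_real_, length(lags))
  }

  ret <- unlist(lapply(seq_len(nrow(bins)), function(k) bins[k, 1]:bins[k, 2]))
  rate_i <- mean(chan(ci, raw = TRUE)[ret]) / bw
  rate_j <- mean(chan(cj, raw = TRUE)[ret]) / bw

  structure(list(pair = pair, lags = lags, G = G, G_sem = G_sem,
                 mean_rate_i = rate_i, mean_rate_j = rate_j,
                 effective_duration = eff_dur, n_segments = nseg,
                 bin_width = bw),
            class = "correlation_curve")
}

#' Brute-force correlation estimator (reference implementation)
#'
#' Direct evaluation of the defining formula
#' `G(k) = <dF_i(t) dF_j(t + k)> / (<F_i> <F_j>)` at integer bin lags with
#' the same symmetric normalization as the multi-tau estimator, by explicit
#' summation. Quadratic cost; intended as an independent oracle for the
#' multi-tau path on short traces.
#'
#' @param x,y numeric count vectors of equal length.
#' @param lag_bins integer lags, in bins (>= 1).
#' @return Numeric vector of correlation values.
#' @export
correlate_direct <- function(x, y, lag_bins) {
  stopifnot(length(x) == length(y))
  n <- length(x)
  vapply(lag_bins, function(k) {
    stopifnot(k >= 1, k < n)
    xs <- x[1:(n - k)]
    ys <- y[(k + 1):n]
    mx <- mean(xs)
    my <- mean(ys)
    if (mx == 0 || my == 0) return(0)
    mean(xs * ys) / (mx * my) - 1
  }, numeric(1))
}

#' @export
print.correlation_curve <- function(x, ...) {
  cat(sprintf(
    "correlation_curve [%s]: %d lags (%.2g .. %.2g s), G(first) = %.4g\n",
    x$pair, length(x$lags), min(x$lags), max(x$lags), x$G[1]))
  cat(sprintf("  rates %.3g / %.3g kHz, %.3g s effective, %d segments\n",
              x$mean_rate_i / 1e3, x$mean_rate_j / 1e3,
              x$effective_duration, x$n_segments))
  invisible(x)
}

#' Write a correlation curve to delimited text
#'
#' Columns `lag_s, G, G_sem` with `#key=value` metadata headers.
#'
#' @param curve a `correlation_curve`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_curve <- function(curve, path) {
  hdr <- c(sprintf("#pair=%s", curve$pair),
           sprintf("#mean_rate_i=%.10g", curve$mean_rate_i),
           sprintf("#mean_rate_j=%.10g", curve$mean_rate_j),
           sprintf("#effective_duration=%.10g", curve$effective_duration),
           sprintf("#n_segments=%d", curve$n_segments),
           sprintf("#bin_width=%.10g", curve$bin_width))
  writeLines(hdr, path)
  data.table::fwrite(data.table::data.table(
    lag_s = curve$lags, G = curve$G, G_sem = curve$G_sem),
    path, append = TRUE, col.names = TRUE)
  invisible(path)
}

#' Read a correlation curve written by [write_curve()]
#' @param path input path.
#' @return A `correlation_curve`.
#' @export
read_curve <- function(path) {
  lines <- readLines(path, warn = FALSE)
  is_meta <- startsWith(lines, "#")
  n_meta <- match(FALSE, is_meta, nomatch = length(lines) + 1L) - 1L
  kv <- sub("^#", "", lines[seq_len(n_meta)])
  eq <- regexpr("=", kv, fixed = TRUE)
  meta <- setNames(as.list(substr(kv, eq + 1, nchar(kv))),
                   substr(kv, 1, eq - 1))
  dt <- data.table::fread(text = lines[(n_meta + 1L):length(lines)],
                          header = TRUE)
  structure(list(pair = meta$pair, lags = dt$lag_s, G = dt$G,
                 G_sem = dt$G_sem,
                 mean_rate_i = as.numeric(meta$mean_rate_i),
                 mean_rate_j = as.numeric(meta$mean_rate_j),
                 effective_duration = as.numeric(meta$effective_duration),
                 n_segments = as.integer(meta$n_segments),
                 bin_width = as.numeric(meta$bin_width)),
            class = "correlation_curve")
}
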