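#' Construct a two-channel photon-count trace
#'
#' @param counts_g,counts_r nonnegative integer (or, for detrended traces,
#'   numeric) count sequences of equal length.
#' @param bin_width bin width, s.
#' @param metadata named list of metadata (seed, labels, spec digest, ...).
#' @return An object of class `photon_trace`.
#' @export
photon_trace <- function(counts_g, counts_r, bin_width, metadata = list()) {
  if (length(counts_g) != length(counts_r))
    stop("channel count vectors must have equal length")
  if (bin_width <= 0) stop("bin_width must be positive")
  if (any(counts_g < 0) || any(counts_r < 0)) stop("counts must be >= 0")
  structure(list(counts_g = counts_g, counts_r = counts_r,
                 bin_width = bin_width, metadata = metadata),
            class = "photon_trace")
}

#' @export
print.photon_trace <- function(x, ...) {
  n <- length(x$counts_g)
  cat(sprintf(
    "photon_trace: %d bins x %g us (%.3g s), mean rates %.3g / %.3g kHz\n",
    n, x$bin_width * 1e6, n * x$bin_width,
    mean(x$counts_g) / x$bin_width / 1e3,
    mean(x$counts_r) / x$bin_width / 1e3))
  invisible(x)
}

#' Trace duration in seconds
#' @param trace a `photon_trace`.
#' @return Duration, s.
#' @export
trace_duration <- function(trace) length(trace$counts_g) * trace$bin_width

#' Write a photon trace to delimited text
#'
#' Format: `#key=value` metadata comment lines, a header
#' `time_s,counts_g,counts_r`, then one row per bin.
#'
#' @param trace a `photon_trace`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_trace <- function(trace, path) {
  meta <- trace$metadata
  meta$bin_width <- trace$bin_width
  hdr <- sprintf("#%s=%s", names(meta),
                 vapply(meta, function(v) paste(format(v, digits = 15),
                                                collapse = ";"),
                        character(1)))
  writeLines(hdr, path)
  n <- length(trace$counts_g)
  dt <- data.table::data.table(
    time_s = (seq_len(n) - 1) * trace$bin_width,
    counts_g = trace$counts_g, counts_r = trace$counts_r)
  data.table::fwrite(dt, path, append = TRUE, col.names = TRUE)
  invisible(path)
}

#' Read a photon trace from delimited text
#'
#' Validates that the time column is uniformly spaced (tolerance 1e-9 s) and
#' that counts are nonnegative; parse failures report the offending line.
#'
#' @param path file written by [write_trace()] (or of the same schema).
#' @return A `photon_trace`.
#' @export
read_trace <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  if (!length(lines)) stop("parse error: empty trace file ", path)
  is_meta <- startsWith(lines, "#")
  n_meta <- match(FALSE, is_meta, nomatch = length(lines) + 1L) - 1L
  meta <- list()
  if (n_meta > 0) {
    kv <- sub("^#", "", lines[seq_len(n_meta)])
    eq <- regexpr("=", kv, fixed = TRUE)
    keys <- substr(kv, 1, eq - 1)
    vals <- substr(kv, eq + 1, nchar(kv))
    meta <- as.list(vals)
    names(meta) <- keys
  }
  if (n_meta >= length(lines))
    stop("parse error: no data rows in ", path)
  dt <- data.table::fread(text = lines[(n_meta + 1L):length(lines)],
                          header = TRUE)
  req <- c("time_s", "counts_g", "counts_r")
  miss <- setdiff(req, names(dt))
  if (length(miss))
    stop("parse error at line ", n_meta + 1L, ": missing column(s) ",
         paste(miss, collapse = ", "))
  if (!nrow(dt)) stop("parse error: no data rows in ", path)
  tm <- dt$time_s
  if (nrow(dt) >= 2) {
    steps <- diff(tm)
    bw <- steps[1]
    bad <- which(abs(steps - bw) > 1e-9)
    if (length(bad))
      stop("parse error at line ", n_meta + 2L + bad[1],
           ": non-uniform time bins")
  } else {
    bw <- suppressWarnings(as.numeric(meta$bin_width))
    if (!length(bw) || is.na(bw))
      stop("parse error: single-row trace without #bin_width metadata")
  }
  neg <- which(dt$counts_g < 0 | dt$counts_r < 0)
  if (length(neg))
    stop("parse error at line ", n_meta + 1L + neg[1], ": negative counts")
  meta$bin_width <- NULL
  photon_trace(dt$counts_g, dt$counts_r, bw, metadata = meta)
}
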