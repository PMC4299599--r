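#' Aggregate per-cell measurements of one strain
#'
#' Unweighted mean and sample standard deviation (n - 1 denominator) per
#' quantity across single-cell measurements, mirroring per-strain error
#' bars derived from single-cell scatter. Above-range `K_D_app` sentinels
#' are excluded from the mean and counted separately; the across-cell
#' median (sentinels entering as `Inf`) is also reported because it is
#' robust against that censoring.
#'
#' @param cells list of `cell_measurement`s (or a data.frame of stacked
#'   rows).
#' @param strain optional label; defaults to the cells' label.
#' @return A `strain_summary`: list with `strain`, `n`, `stats` (data.frame
#'   quantity/mean/sd/n), `kd_median`, `n_sentinel`.
#' @export
aggregate_strain <- function(cells, strain = NULL) {
  df <- if (is.data.frame(cells)) cells
        else do.call(rbind, cells[!vapply(cells, is.null, TRUE)])
  if (is.null(df) || !nrow(df)) stop("no cell measurements to aggregate")
  if (is.null(strain))
    strain <- if ("strain" %in% names(df) && nzchar(df$strain[1]))
      df$strain[1] else ""
  quantities <- c("C_g", "C_r", "D_g", "D_r", "cpps_g", "cpps_r",
                  "C_AB", "K_D_app")
  quantities <- intersect(quantities, names(df))
  stats <- do.call(rbind, lapply(quantities, function(q) {
    v <- df[[q]]
    v <- v[is.finite(v)]  # drops NA and above-range sentinels
    data.frame(quantity = q,
               mean = if (length(v)) mean(v) else NA_real_,
               sd = if (length(v) >= 2) sd(v) else NA_real_,
               n = length(v), stringsAsFactors = FALSE)
  }))
  kd <- df$K_D_app
  structure(list(strain = strain, n = nrow(df), stats = stats,
                 kd_median = if (length(kd)) median(kd) else NA_real_,
                 n_sentinel = sum(!is.finite(kd)),
                 cells = df),
            class = "strain_summary")
}

#' @export
print.strain_summary <- function(x, ...) {
  cat(sprintf("strain_summary '%s' (n = %d cells, %d above-range K_D)\n",
              x$strain, x$n, x$n_sentinel))
  print(x$stats, row.names = FALSE)
  invisible(x)
}

#' Classify an interaction as detected or not
#'
#' An interaction is called detected when the across-cell median apparent
#' K_D lies below the reliable FCCS detection bound (~1 uM) and a majority
#' of the cells yielded an in-range value; weaker interactions are outside
#' the dynamic range of the method.
#'
#' @param summary a `strain_summary` (or a numeric median K_D, mol/L).
#' @param threshold detection bound, mol/L (default 1 uM).
#' @param n_sentinel,n used when `summary` is a bare numeric.
#' @return Logical: interaction detected.
#' @export
classify_interaction <- function(summary, threshold = 1e-6,
                                 n_sentinel = 0, n = 1) {
  if (inherits(summary, "strain_summary")) {
    kd <- summary$kd_median
    n_sentinel <- summary$n_sentinel
    n <- summary$n
  } else kd <- summary
  is.finite(kd) && kd < threshold && n_sentinel < n / 2
}

#' Welch comparison of one quantity between two strains
#'
#' Two-sided Welch unequal-variance t comparison computed from the
#' per-strain summary statistics, with the usual significance star code
#' (`***` p <= 0.001, `**` p <= 0.01, `*` p <= 0.05, `ns` otherwise).
#'
#' @param summary_A,summary_B `strain_summary`s (each needs n >= 2 for the
#'   chosen quantity).
#' @param quantity name of the quantity column (e.g. `"cpps_g"`).
#' @return list with `difference` (mean_A - mean_B), `t`, `df`, `p_value`,
#'   `stars`.
#' @export
compare_strains <- function(summary_A, summary_B, quantity) {
  pick <- function(s) {
    row <- s$stats[s$stats$quantity == quantity, ]
    if (!nrow(row)) stop("unknown quantity: ", quantity)
    if (row$n < 2 || !is.finite(row$sd))
      stop("need n >= 2 cells per strain for comparison")
    row
  }
  a <- pick(summary_A)
  b <- pick(summary_B)
  se2a <- a$sd^2 / a$n
  se2b <- b$sd^2 / b$n
  se <- sqrt(se2a + se2b)
  if (se == 0) {
    p <- 1
    tstat <- 0
    df <- a$n + b$n - 2
  } else {
    tstat <- (a$mean - b$mean) / se
    df <- (se2a + se2b)^2 /
      (se2a^2 / (a$n - 1) + se2b^2 / (b$n - 1))
    p <- 2 * pt(-abs(tstat), df)
  }
  stars <- if (p <= 0.001) "***" else if (p <= 0.01) "**"
           else if (p <= 0.05) "*" else "ns"
  list(difference = a$mean - b$mean, t = tstat, df = df, p_value = p,
       stars = stars)
}

#' Build an interaction record for one measured protein pair
#'
#' @param protein_A,protein_B node labels (equal for self-interactions).
#' @param summary the pair strain's `strain_summary`.
#' @param threshold detection bound, mol/L.
#' @return An `interaction_record`: list with labels, `K_D_app` (median,
#'   mol/L; `Inf` if above range), `detected`, `is_self`, and `n` cells.
#' @export
interaction_record <- function(protein_A, protein_B, summary,
                               threshold = 1e-6) {
  structure(list(protein_A = protein_A, protein_B = protein_B,
                 K_D_app = summary$kd_median,
                 detected = classify_interaction(summary, threshold),
                 is_self = identical(protein_A, protein_B),
                 n = summary$n, n_sentinel = summary$n_sentinel),
            class = "interaction_record")
}

#' Export the quantitative interaction network
#'
#' Writes the screen result as a graph: nodes are proteins with their
#' cytoplasmic concentration as attribute (node size in the usual network
#' rendering); edges are the measured pairs, with `detected` marking solid
#' versus dotted edges, `kd_app_nM` the median apparent K_D, and `weight`
#' the interaction strength `1/K_D` normalized to the strongest detected
#' edge (0 for undetected pairs). Self-interactions appear as loops.
#' Output is a GraphML file plus flat `*_nodes.tsv` / `*_edges.tsv` tables,
#' with deterministic ordering.
#'
#' @param records list of [interaction_record()]s.
#' @param summaries named list of per-protein `strain_summary`s (singly
#'   labeled strains) supplying node concentrations; names are protein
#'   labels.
#' @param path output GraphML path (`.graphml`); the TSV pair derives from
#'   it.
#' @return Invisibly, the `igraph` graph object.
#' @export
export_network <- function(records, summaries, path) {
  rec_nodes <- unique(unlist(lapply(records, function(r)
    c(r$protein_A, r$protein_B))))
  known <- names(summaries)
  unknown <- setdiff(rec_nodes, known)
  if (length(unknown))
    stop("unknown node label(s): ", paste(unknown, collapse = ", "))
  nodes <- sort(known)
  conc <- vapply(nodes, function(p) {
    s <- summaries[[p]]$stats
    row <- s[s$quantity == "C_g", ]
    if (nrow(row) && is.finite(row$mean)) row$mean else NA_real_
  }, numeric(1))

  kd_det <- vapply(records, function(r)
    if (r$detected && is.finite(r$K_D_app)) r$K_D_app else NA_real_,
    numeric(1))
  kd_min <- if (any(is.finite(kd_det))) min(kd_det, na.rm = TRUE) else NA

  ord <- order(vapply(records, function(r)
    paste(sort(c(r$protein_A, r$protein_B)), collapse = "|"), character(1)))
  records <- records[ord]
  edges <- do.call(rbind, lapply(records, function(r) {
    w <- if (r$detected && is.finite(r$K_D_app) && is.finite(kd_min))
      kd_min / r$K_D_app else 0
    data.frame(from = r$protein_A, to = r$protein_B,
               detected = r$detected, is_self = r$is_self,
               kd_app_nM = if (is.finite(r$K_D_app)) r$K_D_app * 1e9
                           else NA_real_,
               weight = w, n_cells = r$n, stringsAsFactors = FALSE)
  }))

  g <- igraph::make_empty_graph(n = 0, directed = FALSE)
  g <- igraph::add_vertices(g, length(nodes), name = nodes,
                            concentration_nM = conc * 1e9)
  if (!is.null(edges) && nrow(edges)) {
    for (i in seq_len(nrow(edges))) {
      g <- igraph::add_edges(
        g, c(edges$from[i], edges$to[i]),
        detected = edges$detected[i], is_self = edges$is_self[i],
        kd_app_nM = edges$kd_app_nM[i], weight = edges$weight[i],
        n_cells = edges$n_cells[i])
    }
  }
  igraph::write_graph(g, path, format = "graphml")
  base <- sub("\\.graphml$", "", path)
  data.table::fwrite(data.frame(protein = nodes,
                                concentration_nM = conc * 1e9),
                     paste0(base, "_nodes.tsv"), sep = "\t")
  if (!is.null(edges) && nrow(edges))
    data.table::fwrite(edges, paste0(base, "_edges.tsv"), sep = "\t")
  else
    data.table::fwrite(data.frame(from = character(0), to = character(0)),
                       paste0(base, "_edges.tsv"), sep = "\t")
  invisible(g)
}
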