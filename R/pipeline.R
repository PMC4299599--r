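## allowed configuration schema: block -> known keys
.config_schema <- list(
  seed = NULL, output_dir = NULL, verbosity = NULL,
  optics = c("w_xy_g", "w_xy_r", "kappa_g", "kappa_r", "channel_offset",
             "background_g", "background_r", "crosstalk_g_to_r"),
  calibration = c("D_g", "D_r", "D_x", "concentration", "duration",
                  "time_step", "bin_width", "brightness", "n_repeats"),
  simulation = c("duration", "time_step", "bin_width", "box", "n_cells",
                 "theta", "tau_triplet", "bleach_rate",
                 "background_fraction"),
  correlator = c("detrend_window", "artifact_window", "z_threshold", "m",
                 "n_segments"),
  fit = c("kind"),
  corrections = c("maturation_g", "maturation_r", "overlap_factor"),
  thresholds = c("kd_detect"),
  manifest = NULL)

#' Read and validate a pipeline configuration
#'
#' The configuration is a YAML file (or an equivalent nested list) with
#' blocks `optics`, `calibration`, `simulation`, `correlator`, `fit`,
#' `corrections`, `thresholds`, a `manifest` (list of strain rows or a path
#' to a delimited file), and a root `seed`. Unknown blocks or keys are
#' rejected before any stage runs; `seed`, `manifest` and `calibration` are
#' required.
#'
#' @param config path to a YAML file, or a named list.
#' @return The validated configuration list (class `pipeline_config`).
#' @export
read_pipeline_config <- function(config) {
  if (is.character(config)) {
    if (!file.exists(config)) stop("config file not found: ", config)
    config <- yaml::read_yaml(config)
  }
  if (!is.list(config)) stop("config must be a list or a YAML path")
  unknown <- setdiff(names(config), names(.config_schema))
  if (length(unknown))
    stop("unknown config block(s): ", paste(unknown, collapse = ", "))
  for (blk in names(config)) {
    keys <- .config_schema[[blk]]
    if (is.null(keys)) next
    bad <- setdiff(names(config[[blk]]), keys)
    if (length(bad))
      stop("unknown key(s) in config block '", blk, "': ",
           paste(bad, collapse = ", "))
  }
  for (req in c("seed", "manifest", "calibration"))
    if (is.null(config[[req]]))
      stop("config validation error: missing required block '", req, "'")
  if (is.character(config$manifest) && length(config$manifest) == 1) {
    if (!file.exists(config$manifest))
      stop("manifest file not found: ", config$manifest)
    config$manifest <- as.data.frame(data.table::fread(config$manifest))
  } else if (!is.data.frame(config$manifest)) {
    rows <- lapply(config$manifest, as.list)
    cols <- unique(unlist(lapply(rows, names)))
    config$manifest <- do.call(rbind, lapply(rows, function(r) {
      missing <- setdiff(cols, names(r))
      r[missing] <- NA
      as.data.frame(r[cols], stringsAsFactors = FALSE)
    }))
  }
  class(config) <- c("pipeline_config", "list")
  config
}

.cfg <- function(config, block, key, default) {
  v <- config[[block]][[key]]
  if (is.null(v)) default else v
}

.build_optics <- function(config) {
  o <- config$optics
  if (is.null(o)) o <- list()
  fccs_optics(
    w_xy_g = if (is.null(o$w_xy_g)) 0.2 else o$w_xy_g,
    w_xy_r = if (is.null(o$w_xy_r)) 0.2 else o$w_xy_r,
    kappa_g = if (is.null(o$kappa_g)) 5 else o$kappa_g,
    kappa_r = if (is.null(o$kappa_r)) 5 else o$kappa_r,
    channel_offset = if (is.null(o$channel_offset)) c(0, 0, 0)
                     else o$channel_offset,
    background_g = if (is.null(o$background_g)) 0 else o$background_g,
    background_r = if (is.null(o$background_r)) 0 else o$background_r,
    crosstalk_g_to_r = if (is.null(o$crosstalk_g_to_r)) 0
                       else o$crosstalk_g_to_r)
}

#' Simulate the reference-dye calibration session
#'
#' Generates the three dye measurements that open a measurement session
#' (green-channel dye, red-channel dye, and a dual-channel dye for the
#' cross-correlation volume) at 2 nM, correlates them, and calibrates the
#' observation volumes via [calibrate_volume()]. Dye traces use a finer
#' time base than in vivo acquisitions because free dyes diffuse ~100x
#' faster than cytoplasmic proteins.
#'
#' @param optics an [fccs_optics()] (background and crosstalk are switched
#'   off for the calibration cell).
#' @param D_known named vector (`g`, `r`, `x`) of dye diffusion
#'   coefficients, um^2/s.
#' @param concentration dye concentration, mol/L.
#' @param duration,time_step,bin_width acquisition parameters, s. The time
#'   step must resolve the beam waist for fast-diffusing dyes
#'   (`sqrt(2 D dt) << w_xy`).
#' @param brightness dye brightness, counts/s per molecule.
#' @param n_repeats repeated acquisitions per dye; the repeats' correlation
#'   curves are averaged before fitting (the structure parameter kappa is
#'   weakly identified from a single 2 nM acquisition).
#' @param seed integer seed.
#' @return An `observation_volume`.
#' @export
simulate_dye_calibration <- function(optics = fccs_optics(),
                                     D_known = c(g = 435, r = 341, x = 420),
                                     concentration = 2e-9, duration = 20,
                                     time_step = 2.5e-7, bin_width = 2e-6,
                                     brightness = 2e4, n_repeats = 3L,
                                     seed = 1L) {
  cal_opt <- optics
  cal_opt$background_g <- cal_opt$background_r <- 0
  cal_opt$crosstalk_g_to_r <- 0
  dyes <- list(
    g = fccs_species("dye_green", D = D_known[["g"]],
                     concentration = concentration,
                     brightness_g = brightness),
    r = fccs_species("dye_red", D = D_known[["r"]],
                     concentration = concentration,
                     brightness_r = brightness),
    x = fccs_species("dye_dual", D = D_known[["x"]],
                     concentration = concentration,
                     brightness_g = 0.75 * brightness,
                     brightness_r = 0.75 * brightness))
  curves <- lapply(seq_along(dyes), function(i) {
    ch <- names(dyes)[i]
    reps <- lapply(seq_len(n_repeats), function(j) {
      spec <- fccs_simspec(dyes[[ch]], cal_opt, duration = duration,
                           time_step = time_step, bin_width = bin_width,
                           seed = seed * 100 + i * 10 + j,
                           label = paste0("calibration_", ch, j))
      tr <- simulate_trace(spec)
      correlate(tr, pair = switch(ch, g = "gg", r = "rr", x = "gr"))
    })
    average_curves(reps)
  })
  names(curves) <- names(dyes)
  calibrate_volume(curves, D_known)
}

#' Run the full screening pipeline
#'
#' Executes the reproducible chain simulate -> correlate -> fit ->
#' quantify -> screen from one validated configuration: dye calibration of
#' the observation volumes, per-cell trace simulation for every manifest
#' strain, per-cell analysis ([analyze_trace()]), per-strain aggregation,
#' interaction classification, and export of the per-cell table, strain
#' summaries, interaction network (GraphML + TSV) and a run log. Identical
#' configuration and seed give identical result tables.
#'
#' @param config a `pipeline_config`, YAML path, or equivalent list
#'   (see [read_pipeline_config()]).
#' @return Invisibly, a list with `cells` (per-cell data.frame),
#'   `summaries`, `records`, `volume`, `truth`, and output `paths`.
#' @export
run_pipeline <- function(config) {
  config <- read_pipeline_config(config)
  seed <- as.integer(config$seed)
  out_dir <- if (is.null(config$output_dir)) tempfile("fccs_run_")
             else config$output_dir
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  cfg_path <- file.path(out_dir, "config.yaml")
  yaml::write_yaml(unclass(config), cfg_path)
  log_lines <- c(
    sprintf("fccstools %s", as.character(utils::packageVersion("fccstools"))),
    sprintf("seed=%d", seed),
    sprintf("config_md5=%s", unname(tools::md5sum(cfg_path))))
  optics <- .build_optics(config)

  # stage 1: calibration
  cal <- config$calibration
  D_known <- c(g = .cfg(config, "calibration", "D_g", 435),
               r = .cfg(config, "calibration", "D_r", 341),
               x = .cfg(config, "calibration", "D_x", 420))
  volume <- tryCatch(
    simulate_dye_calibration(
      optics, D_known,
      concentration = .cfg(config, "calibration", "concentration", 2e-9),
      duration = .cfg(config, "calibration", "duration", 10),
      time_step = .cfg(config, "calibration", "time_step", 1e-6),
      bin_width = .cfg(config, "calibration", "bin_width", 2e-6),
      brightness = .cfg(config, "calibration", "brightness", 2e4),
      n_repeats = .cfg(config, "calibration", "n_repeats", 3L),
      seed = seed),
    error = function(e) stop("stage calibration: ", conditionMessage(e)))
  log_lines <- c(log_lines, sprintf(
    "calibration: w_xy_g=%.4g w_xy_r=%.4g V_rg=%.4g overlap=%.4g",
    volume$w_xy_g, volume$w_xy_r, volume$V_rg, volume$overlap_factor))

  # stage 2: scenarios
  scen <- tryCatch(
    make_screen_scenarios(
      config$manifest, optics, root_seed = seed,
      n_cells = .cfg(config, "simulation", "n_cells", 12L),
      background_fraction = .cfg(config, "simulation",
                                 "background_fraction", NULL),
      duration = .cfg(config, "simulation", "duration", 20),
      time_step = .cfg(config, "simulation", "time_step", 1e-5),
      bin_width = .cfg(config, "simulation", "bin_width", 1e-5),
      box = .cfg(config, "simulation", "box", c(3, 3, 6)),
      theta = .cfg(config, "simulation", "theta", 0.15),
      tau_triplet = .cfg(config, "simulation", "tau_triplet", 5e-5),
      bleach_rate = .cfg(config, "simulation", "bleach_rate", 0.005)),
    error = function(e) stop("stage scenarios: ", conditionMessage(e)))

  # stages 3-4: per-cell simulation and analysis
  kind <- .cfg(config, "fit", "kind", "anomalous")
  kd_detect <- .cfg(config, "thresholds", "kd_detect", 1e-6)
  cells <- list()
  for (spec in scen$specs) {
    strain <- sub("#.*$", "", spec$label)
    tr_row <- scen$truth[scen$truth$strain == strain, ]
    corr <- correction_config(
      background_g = spec$optics$background_g,
      background_r = spec$optics$background_r,
      crosstalk_g_to_r = spec$optics$crosstalk_g_to_r,
      maturation_g = .cfg(config, "corrections", "maturation_g", 1),
      maturation_r = .cfg(config, "corrections", "maturation_r", 1),
      # the calibration's overlap estimate is reported, but the correction
      # factor applied to C_AB is configured manually (its calibration
      # estimate is too noisy to divide by; see methods vignette)
      overlap_factor = .cfg(config, "corrections", "overlap_factor", 1))
    cm <- tryCatch({
      tr <- simulate_trace(spec)
      analyze_trace(
        tr, volume, corr, kind = kind,
        detrend_window = .cfg(config, "correlator", "detrend_window", 2),
        artifact_window = .cfg(config, "correlator", "artifact_window", 0.2),
        z_threshold = .cfg(config, "correlator", "z_threshold", 5),
        n_segments = .cfg(config, "correlator", "n_segments", 10L),
        strain = strain, red = tr_row$total_r[1] > 0)
    }, error = function(e)
      stop("stage analyze, cell ", spec$label, ": ", conditionMessage(e)))
    if (!is.null(cm)) {
      cm$cell <- spec$label
      cm$seed <- spec$seed
      # correction parameters used, for full provenance
      cm$bg_g_cps <- corr$background_g
      cm$bg_r_cps <- corr$background_r
      cm$crosstalk <- corr$crosstalk_g_to_r
      cm$maturation_g <- corr$maturation_g
      cm$maturation_r <- corr$maturation_r
      cm$overlap_factor <- corr$overlap_factor
      cells[[length(cells) + 1L]] <- cm
    } else {
      log_lines <- c(log_lines, sprintf("cell %s discarded", spec$label))
    }
  }
  cell_df <- do.call(rbind, cells)

  # stage 5: aggregation, classification, network
  strains <- unique(cell_df$strain)
  summaries <- lapply(strains, function(s)
    aggregate_strain(cell_df[cell_df$strain == s, ], strain = s))
  names(summaries) <- strains

  records <- list()
  node_summaries <- list()
  for (i in seq_len(nrow(scen$truth))) {
    s <- scen$truth$strain[i]
    if (!s %in% names(summaries)) next
    m <- config$manifest[config$manifest$strain == s, ]
    pg <- if ("protein_g" %in% names(m) && !is.na(m$protein_g[1]))
      m$protein_g[1] else s
    node_summaries[[pg]] <- summaries[[s]]
    if (scen$truth$total_r[i] > 0) {
      pr <- if ("protein_r" %in% names(m) && !is.na(m$protein_r[1]))
        m$protein_r[1] else paste0(s, "_red")
      if (is.null(node_summaries[[pr]])) {
        ns <- summaries[[s]]
        ns$stats$mean[ns$stats$quantity == "C_g"] <-
          ns$stats$mean[ns$stats$quantity == "C_r"]
        node_summaries[[pr]] <- ns
      }
      records[[length(records) + 1L]] <-
        interaction_record(pg, pr, summaries[[s]], threshold = kd_detect)
    }
  }

  # outputs (unit-suffixed columns for provenance)
  paths <- list(
    cells = file.path(out_dir, "cells.tsv"),
    strains = file.path(out_dir, "strains.tsv"),
    network = file.path(out_dir, "network.graphml"),
    truth = file.path(out_dir, "ground_truth.tsv"),
    log = file.path(out_dir, "run_log.txt"))
  out_cells <- data.frame(
    strain = cell_df$strain, cell = cell_df$cell, seed = cell_df$seed,
    C_g_nM = cell_df$C_g * 1e9, C_r_nM = cell_df$C_r * 1e9,
    D_g_um2_per_s = cell_df$D_g, D_r_um2_per_s = cell_df$D_r,
    cpps_g = cell_df$cpps_g, cpps_r = cell_df$cpps_r,
    C_AB_nM = cell_df$C_AB * 1e9, K_D_app_nM = cell_df$K_D_app * 1e9,
    kd_above_range = cell_df$kd_above_range,
    alpha_g = cell_df$alpha_g,
    bg_g_cps = cell_df$bg_g_cps, bg_r_cps = cell_df$bg_r_cps,
    crosstalk = cell_df$crosstalk,
    maturation_g = cell_df$maturation_g,
    maturation_r = cell_df$maturation_r,
    overlap_factor = cell_df$overlap_factor, stringsAsFactors = FALSE)
  data.table::fwrite(out_cells, paths$cells, sep = "\t")
  strain_rows <- do.call(rbind, lapply(summaries, function(s) {
    st <- s$stats
    data.frame(strain = s$strain, quantity = st$quantity, mean = st$mean,
               sd = st$sd, n = st$n, stringsAsFactors = FALSE)
  }))
  data.table::fwrite(strain_rows, paths$strains, sep = "\t")
  data.table::fwrite(scen$truth, paths$truth, sep = "\t")
  if (length(records))
    export_network(records, node_summaries, paths$network)
  log_lines <- c(log_lines,
                 sprintf("%d cells analyzed, %d strains, %d pair records",
                         nrow(cell_df), length(summaries), length(records)))
  writeLines(log_lines, paths$log)

  invisible(list(cells = cell_df, summaries = summaries, records = records,
                 volume = volume, truth = scen$truth, paths = paths))
}
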