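#' Analyze one well from a tile scan
#'
#' The full per-well chain: locate clones on a quick unaligned mosaic,
#' refine tile offsets from overlap-strip signal on the clone-bearing
#' tiles, correct the per-tile illumination/background gradient, stitch,
#' segment nuclei, (optionally) classify barcode colors, call clones and
#' summarize.
#'
#' @param scan a [tile_scan()].
#' @param seeded_cells cells seeded into the well (for plating efficiency).
#' @param color_model optional [train_color_model()] model; `"rules"` uses
#'   the rule-based classifier; `NULL` leaves colors `UNSET` (classical
#'   arm).
#' @param eps,min_samples DBSCAN parameters (`eps = NULL` auto-estimates).
#' @param cfg a [threshold_config()].
#' @param max_shift stitching shift search radius, px.
#' @param n_background_points background sample locations per tile.
#' @param well_id identifier for the outputs.
#' @param correct_background set `FALSE` when tiles are already corrected.
#' @return list with `nuclei`, `clones`, `summary`, `offsets`, `eps`.
#' @export
analyze_well <- function(scan, seeded_cells, color_model = NULL,
                         eps = NULL, min_samples = 3L,
                         cfg = threshold_config(), max_shift = 20L,
                         n_background_points = 20L, well_id = "well",
                         correct_background = TRUE) {
  stopifnot(inherits(scan, "tile_scan"))
  mosaic <- rough_mosaic(scan)
  clone_tiles <- locate_clone_tiles(mosaic, scan)
  offsets <- refine_offsets(scan, clone_tiles, max_shift = max_shift)
  if (correct_background)
    scan <- correct_scan_background(scan, n_points = n_background_points)
  well <- stitch(scan, offsets)
  nuclei <- segment_well(well)
  if (nrow(nuclei) == 0)
    return(list(nuclei = nuclei, clones = clone_metrics(nuclei),
                summary = NULL, offsets = offsets, eps = NA_real_))
  if (identical(color_model, "rules")) {
    nuclei <- classify_nuclei_rules(nuclei)
  } else if (inherits(color_model, "color_model")) {
    nuclei <- classify_nuclei(nuclei, color_model)
  }
  called <- call_clones(nuclei, eps = eps, min_samples = min_samples)
  summary <- summarize_well(called$nuclei, called$clones, seeded_cells,
                            cfg = cfg, well_id = well_id,
                            dna_histogram = length(scan$channel_names) == 1)
  list(nuclei = called$nuclei, clones = called$clones, summary = summary,
       offsets = offsets, eps = called$eps)
}

#' Pipeline configuration
#'
#' Single validated container for a reproducible run. Unknown keys are
#' rejected (typo safety) and the object round-trips through YAML without
#' loss.
#'
#' @param out output directory.
#' @param wells number of synthetic wells to simulate and analyze.
#' @param sim list of [sim_params()] overrides for the simulated wells.
#' @param tiles_dir read tiles from this directory instead of simulating
#'   (one well).
#' @param seeded_cells cells seeded per well (defaults to the simulated
#'   count).
#' @param classify `"none"`, `"rules"`, or a path to a JSON color model.
#' @param eps DBSCAN radius (`NULL` = auto), `min_samples` its companion.
#' @param min_samples DBSCAN minimum samples.
#' @param max_shift stitch search radius, px.
#' @param n_background_points background samples per tile.
#' @param thresholds list of [threshold_config()] overrides.
#' @param seed global RNG seed; well `i` derives seed `seed + i - 1`.
#' @return an object of class `pipeline_config`.
#' @export
pipeline_config <- function(out = "clonoscope_out", wells = 1L, sim = list(),
                            tiles_dir = NULL, seeded_cells = NULL,
                            classify = "none", eps = NULL, min_samples = 3L,
                            max_shift = 20L, n_background_points = 20L,
                            thresholds = list(), seed = 1L) {
  cfg <- list(out = out, wells = as.integer(wells), sim = sim,
              tiles_dir = tiles_dir, seeded_cells = seeded_cells,
              classify = classify, eps = eps,
              min_samples = as.integer(min_samples),
              max_shift = as.integer(max_shift),
              n_background_points = as.integer(n_background_points),
              thresholds = thresholds, seed = as.integer(seed),
              version = as.character(utils::packageVersion("clonoscope")))
  known_sim <- names(formals(sim_params))
  bad <- setdiff(names(sim), known_sim)
  if (length(bad)) stopf("unknown sim parameter(s): %s", paste(bad, collapse = ", "))
  known_thr <- names(formals(threshold_config))
  bad <- setdiff(names(thresholds), known_thr)
  if (length(bad)) stopf("unknown threshold(s): %s", paste(bad, collapse = ", "))
  class(cfg) <- "pipeline_config"
  cfg
}

#' Read / write a pipeline configuration as YAML
#'
#' @param path YAML file.
#' @param config a [pipeline_config()].
#' @return `read_pipeline_config()` returns the validated config;
#'   `write_pipeline_config()` the path, invisibly.
#' @export
read_pipeline_config <- function(path) {
  raw <- yaml::read_yaml(path)
  raw$version <- NULL
  known <- setdiff(names(formals(pipeline_config)), "...")
  bad <- setdiff(names(raw), known)
  if (length(bad)) stopf("unknown config key(s): %s", paste(bad, collapse = ", "))
  do.call(pipeline_config, raw)
}

#' @rdname read_pipeline_config
#' @export
write_pipeline_config <- function(config, path) {
  stopifnot(inherits(config, "pipeline_config"))
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' Run the full pipeline
#'
#' Simulates (or reads) the wells, runs [analyze_well()] on each, writes
#' `nuclei.csv`, `clones.csv` and `well_summary.csv` to the output
#' directory, and a `run_manifest.json` with the config, stage timings and
#' QC tallies. Re-running with an identical config reproduces identical
#' CSVs; on failure the manifest records the failing stage and well.
#'
#' @param config a [pipeline_config()].
#' @return the output directory, invisibly; results attached as attribute
#'   `results`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$out, recursive = TRUE, showWarnings = FALSE)
  manifest <- list(config = unclass(config), started = TRUE, stages = list())
  done <- function() {
    jsonlite::write_json(manifest, file.path(config$out, "run_manifest.json"),
                         auto_unbox = TRUE, digits = NA, null = "null")
  }
  on.exit(done())
  if (!is.null(config$tiles_dir) && !dir.exists(config$tiles_dir))
    stopf("input manifest/tiles directory not found: %s", config$tiles_dir)

  model <- switch(config$classify,
                  none = NULL, rules = "rules",
                  read_color_model(config$classify))
  cfg_thr <- do.call(threshold_config, config$thresholds)
  all_nuc <- list(); all_clo <- list(); all_sum <- list()
  for (w in seq_len(if (is.null(config$tiles_dir)) config$wells else 1L)) {
    wid <- sprintf("well_%02d", w)
    stage <- "simulate"
    t0 <- proc.time()[["elapsed"]]
    res <- tryCatch({
      if (is.null(config$tiles_dir)) {
        sp <- do.call(sim_params, modifyList(config$sim,
                                             list(seed = config$seed + w - 1L)))
        gw <- generate_well(sp)
        scan <- gw$scan
        seeded <- config$seeded_cells %||% sp$seeded_cells_per_well
      } else {
        scan <- read_tiles(config$tiles_dir)
        seeded <- config$seeded_cells %||%
          stopf("seeded_cells is required when reading tiles")
      }
      stage <- "analyze"
      analyze_well(scan, seeded_cells = seeded, color_model = model,
                   eps = config$eps, min_samples = config$min_samples,
                   cfg = cfg_thr, max_shift = config$max_shift,
                   n_background_points = config$n_background_points,
                   well_id = wid)
    }, error = function(e) {
      manifest$failure <<- list(stage = stage, well = wid,
                                message = conditionMessage(e))
      done()
      stopf("pipeline failed at stage '%s' on %s: %s", stage, wid,
            conditionMessage(e))
    })
    manifest$stages[[wid]] <- list(
      elapsed_s = round(proc.time()[["elapsed"]] - t0, 3),
      n_nuclei = nrow(res$nuclei), n_clones = nrow(res$clones),
      eps = res$eps)
    if (nrow(res$nuclei)) res$nuclei$well_id <- wid
    if (nrow(res$clones)) res$clones$well_id <- wid
    all_nuc[[wid]] <- res$nuclei
    all_clo[[wid]] <- res$clones
    all_sum[[wid]] <- res$summary
  }
  nuclei <- do.call(rbind, all_nuc)
  clones <- do.call(rbind, all_clo)
  summaries <- do.call(rbind, all_sum)
  write.csv(nuclei, file.path(config$out, "nuclei.csv"), row.names = FALSE)
  write.csv(clones, file.path(config$out, "clones.csv"), row.names = FALSE)
  write.csv(summaries, file.path(config$out, "well_summary.csv"),
            row.names = FALSE)
  manifest$config_md5 <- unname(tools::md5sum(
    write_pipeline_config(config, file.path(config$out, "config.yaml"))))
  out <- config$out
  attr(out, "results") <- list(nuclei = nuclei, clones = clones,
                               summaries = summaries)
  invisible(out)
}

#' Simulate and analyze a mock drug screen
#'
#' Generates a multi-treatment plate — cell lines x drugs x concentrations
#' x replicates plus matched untreated controls — as small synthetic
#' barcoded wells, runs every well through the full image pipeline, and
#' assembles the screen table. Drug effects are expressed as a survival
#' multiplier and a clone-size multiplier per concentration step.
#'
#' @param drugs data frame with `drug`, `survival_mult`, `size_mult` (per
#'   unit concentration); defaults to a 20-drug mock panel with strong-kill,
#'   intermediate and no-effect groups.
#' @param cell_lines character vector (default two lines).
#' @param concentrations numeric vector (default `c(1, 2)`).
#' @param replicates wells per treatment (default 3).
#' @param sim list of [sim_params()] overrides for the per-well generator
#'   (defaults to a compact single-tile well so a full screen stays fast).
#' @param control_survival plating probability of untreated cells.
#' @param min_cells_per_clone clone-counting threshold for these small
#'   early-time-point clones (default 3).
#' @param seed base RNG seed; each well derives its own.
#' @return list with `table` (a `screen_table`), `summaries`,
#'   `treatment_map` and the per-well `truth` survival probabilities.
#' @export
simulate_screen <- function(drugs = NULL,
                            cell_lines = c("LINE1", "LINE2"),
                            concentrations = c(1, 2), replicates = 3L,
                            sim = list(), control_survival = 0.8,
                            min_cells_per_clone = 3L, seed = 1L) {
  if (is.null(drugs)) drugs <- mock_drug_panel()
  sim_base <- modifyList(list(
    seeded_cells_per_well = 20L,
    cells_per_clone_law = list(median = 8, sigma = 0.4),
    clone_dispersion_px = 8, nucleus_axes_px = c(10, 7),
    fragment_rate = 0.02, tile_grid = c(1, 1), tile_size_px = c(400, 400),
    illumination = 0.2, noise = list(gaussian_sd = 2, poisson_gain = 0.05)),
    sim)
  cfg <- threshold_config(min_cells_per_clone = min_cells_per_clone)
  map <- expand.grid(cell_line = cell_lines, drug = drugs$drug,
                     concentration = concentrations,
                     replicate = seq_len(replicates),
                     stringsAsFactors = FALSE)
  map$is_control <- FALSE
  ctrl <- expand.grid(cell_line = cell_lines, drug = "none",
                      concentration = 0, replicate = seq_len(replicates),
                      stringsAsFactors = FALSE)
  ctrl$is_control <- TRUE
  map <- rbind(ctrl, map)
  map$well_id <- sprintf("w%03d", seq_len(nrow(map)))
  summaries <- vector("list", nrow(map))
  for (i in seq_len(nrow(map))) {
    m <- map[i, ]
    eff <- if (m$is_control) list(survival_mult = 1, size_mult = 1)
           else drugs[drugs$drug == m$drug, ]
    surv <- control_survival * eff$survival_mult ^ m$concentration
    law <- sim_base$cells_per_clone_law
    law$median <- max(2, law$median * eff$size_mult ^ m$concentration)
    sp <- do.call(sim_params, modifyList(
      sim_base, list(survival_prob = surv, cells_per_clone_law = law,
                     seed = seed + i)))
    gw <- generate_well(sp)
    res <- analyze_well(gw$scan, seeded_cells = sp$seeded_cells_per_well,
                        color_model = "rules", cfg = cfg,
                        well_id = m$well_id)
    summaries[[i]] <- res$summary
  }
  summaries <- do.call(rbind, summaries)
  tab <- build_screen_table(summaries, map)
  list(table = tab, summaries = summaries, treatment_map = map)
}

#' @rdname simulate_screen
#' @export
mock_drug_panel <- function() {
  data.frame(
    drug = sprintf("drug%02d", 1:20),
    survival_mult = c(rep(0.35, 7), rep(0.75, 6), rep(1.0, 7)),
    size_mult = c(rep(0.7, 7), rep(0.9, 6), rep(1.0, 7)),
    group = c(rep("strong", 7), rep("intermediate", 6), rep("none", 7)),
    stringsAsFactors = FALSE)
}
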