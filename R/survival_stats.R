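#' Anomaly and clone-counting thresholds
#'
#' Central container for the fixed thresholds of the assay: a cluster of 50
#' or more cells counts as a clone; small nuclei fall below 0.5 of the
#' median normalized total intensity (resp. area), large nuclei inside 3-10
#' (intensity) or 2-4 (area) times the median; misshapen nuclei have
#' roundness below 0.5; a-circular nuclei circularity below 0.9.
#'
#' @param min_cells_per_clone clone-counting threshold (cells).
#' @param small_intensity_max upper bound of "small" normalized intensity.
#' @param large_intensity_range c(lo, hi) of "large" normalized intensity.
#' @param small_area_max upper bound of "small" normalized area.
#' @param large_area_range c(lo, hi) of "large" normalized area.
#' @param low_roundness_max roundness below which a nucleus is misshapen.
#' @param low_circularity_max circularity below which a nucleus is
#'   a-circular.
#' @return an object of class `threshold_config`.
#' @export
threshold_config <- function(min_cells_per_clone = 50L,
                             small_intensity_max = 0.5,
                             large_intensity_range = c(3, 10),
                             small_area_max = 0.5,
                             large_area_range = c(2, 4),
                             low_roundness_max = 0.5,
                             low_circularity_max = 0.9) {
  cfg <- list(min_cells_per_clone = as.integer(min_cells_per_clone),
              small_intensity_max = small_intensity_max,
              large_intensity_range = large_intensity_range,
              small_area_max = small_area_max,
              large_area_range = large_area_range,
              low_roundness_max = low_roundness_max,
              low_circularity_max = low_circularity_max)
  for (rng in list(cfg$large_intensity_range, cfg$large_area_range))
    if (length(rng) != 2 || rng[1] >= rng[2])
      stopf("range bounds must satisfy lo < hi")
  if (any(unlist(cfg) <= 0)) stopf("all thresholds must be positive")
  class(cfg) <- "threshold_config"
  cfg
}

#' Count clones at a cell-number threshold
#'
#' @param clones clone table with `n_cells`.
#' @param min_cells minimum cells for a cluster to count as a clone
#'   (default 50; 1 counts every cluster).
#' @return the clone count.
#' @export
count_clones <- function(clones, min_cells = 50L) {
  if (is.data.frame(clones)) clones <- clones$n_cells
  sum(clones >= min_cells)
}

#' Surviving fraction from plating efficiencies
#'
#' @param pe_treated plating efficiency of the treated condition.
#' @param pe_control plating efficiency of its control (> 0).
#' @return `pe_treated / pe_control`.
#' @export
survival_fraction <- function(pe_treated, pe_control) {
  if (any(pe_control <= 0)) stopf("surviving fraction undefined: control plating efficiency is 0")
  pe_treated / pe_control
}

#' DNA-content histogram of normalized nuclear intensities
#'
#' Density-normalized histogram of `norm_intensity` (total DNA-stain
#' intensity over the well median): the DNA-content profile whose G1/G2
#' structure reflects cell-cycle position, since stain intensity is
#' proportional to total DNA.
#'
#' @param records nucleus table with `norm_intensity` (see
#'   [normalize_features()]).
#' @param bins number of bins (default 80).
#' @param range histogram range (default c(0, 4); values beyond are
#'   clipped into the end bins).
#' @return data frame with `mid` (bin centers) and `density` (sums to 1).
#' @export
dna_content_histogram <- function(records, bins = 80L, range = c(0, 4)) {
  if (nrow(records) == 0) stopf("no records for DNA-content histogram")
  v <- pmin(pmax(records$norm_intensity, range[1]), range[2])
  br <- seq(range[1], range[2], length.out = bins + 1L)
  h <- tabulate(findInterval(v, br, rightmost.closed = TRUE), bins)
  data.frame(mid = (br[-1] + br[-length(br)]) / 2, density = h / sum(h))
}

#' Fractions of anomalous nuclei
#'
#' Six fractions over the same denominator (all non-TRASH records): small /
#' large normalized intensity, small / large normalized area, low
#' roundness, low circularity.
#'
#' @param records normalized nucleus table.
#' @param cfg a [threshold_config()].
#' @return named numeric vector of the six fractions.
#' @export
anomaly_fractions <- function(records, cfg = threshold_config()) {
  recs <- records[!(records$color_class %in% "TRASH"), , drop = FALSE]
  if (nrow(recs) == 0) stopf("no records for anomaly fractions")
  n <- nrow(recs)
  c(frac_small_intensity = sum(recs$norm_intensity < cfg$small_intensity_max) / n,
    frac_large_intensity = sum(recs$norm_intensity >= cfg$large_intensity_range[1] &
                               recs$norm_intensity <= cfg$large_intensity_range[2]) / n,
    frac_small_area = sum(recs$norm_area < cfg$small_area_max) / n,
    frac_large_area = sum(recs$norm_area >= cfg$large_area_range[1] &
                          recs$norm_area <= cfg$large_area_range[2]) / n,
    frac_low_roundness = sum(recs$roundness < cfg$low_roundness_max) / n,
    frac_low_circularity = sum(recs$circularity < cfg$low_circularity_max) / n)
}

#' Per-well summary
#'
#' Aggregates a segmented, clone-called well into the survival-level
#' readouts: clone counts (thresholded and total), plating efficiency,
#' anomaly fractions and the DNA-content histogram.
#'
#' @param nuclei normalized nucleus table.
#' @param clones clone table from [clone_metrics()].
#' @param seeded_cells cells seeded into the well.
#' @param cfg a [threshold_config()].
#' @param well_id identifier carried into the output.
#' @param dna_histogram compute the DNA-content histogram (set `FALSE` for
#'   the barcoded arm, whose marker intensity is not DNA content).
#' @return an object of class `well_summary` (a one-row data frame plus a
#'   `dna_histogram` attribute).
#' @export
summarize_well <- function(nuclei, clones, seeded_cells,
                           cfg = threshold_config(), well_id = "well",
                           dna_histogram = TRUE) {
  fr <- anomaly_fractions(nuclei, cfg)
  cc_thr <- count_clones(clones, cfg$min_cells_per_clone)
  cc_all <- count_clones(clones, 1L)
  pe <- cc_thr / seeded_cells
  if (pe > 1) warnf("plating efficiency > 1 in %s", well_id)
  out <- data.frame(well_id = well_id, seeded_cells = seeded_cells,
                    clone_count_at_threshold = cc_thr,
                    clone_count_all = cc_all,
                    plating_efficiency = pe,
                    median_n_cells = if (nrow(clones)) median(clones$n_cells) else NA_real_,
                    iqr_n_cells = if (nrow(clones))
                      clone_heterogeneity_iqr(clones$n_cells) else NA_real_,
                    median_nucleus_area = median(nuclei$area),
                    median_circularity = median(nuclei$circularity),
                    t(fr), stringsAsFactors = FALSE)
  if (dna_histogram)
    attr(out, "dna_histogram") <- dna_content_histogram(nuclei)
  class(out) <- c("well_summary", class(out))
  out
}

#' Select the optimal seeding density
#'
#' Given clone counts by seeding density and imaging day, returns the
#' highest density whose clone count is stable across days — relative
#' day-to-day deviation from the per-density mean within `tol`. (Too-dense
#' wells lose countable clones over time as clones merge.) If no density
#' qualifies, the lowest density is returned with a warning.
#'
#' @param counts data frame with columns `density`, `day`, `clone_count`
#'   (replicates allowed: counts are averaged per density x day).
#' @param tol maximum relative deviation counted as stable (default 0.15).
#' @return the selected density; per-density stability attached as
#'   attribute `stability`.
#' @export
select_seeding_density <- function(counts, tol = 0.15) {
  stopifnot(nrow(counts) > 0)
  agg <- aggregate(clone_count ~ density + day, counts, mean)
  densities <- sort(unique(agg$density))
  stab <- vapply(densities, function(d) {
    v <- agg$clone_count[agg$density == d]
    if (length(v) < 2) stopf("need counts on >= 2 days per density")
    m <- mean(v)
    if (m == 0) return(Inf)
    max(abs(v - m) / m)
  }, numeric(1))
  ok <- densities[stab <= tol]
  if (length(ok)) sel <- max(ok)
  else {
    warnf("no seeding density is stable within %.0f%%; returning the lowest", 100 * tol)
    sel <- min(densities)
  }
  attr(sel, "stability") <- stats::setNames(stab, densities)
  sel
}
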