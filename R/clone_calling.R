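#' DBSCAN clustering of nucleus centroids into clones
#'
#' Groups nuclei into clones by density-based clustering of their stitched
#' centroids (standard DBSCAN core/border/noise semantics, Euclidean
#' distance, neighborhoods are closed balls including the point itself).
#' In the barcoded (LeGO) arm, clustering is run independently per color
#' class so that overlapping clones of different colors stay separate —
#' the reason the barcode exists. Noise points are kept as singleton clones
#' (flagged), so small clones below any counting threshold remain visible.
#' TRASH records are never clustered.
#'
#' @param records nucleus table with `x`, `y` (and `color_class` when
#'   `color_constrained`).
#' @param eps neighborhood radius, px.
#' @param min_samples minimum neighbors (self included) for a core point.
#' @param color_constrained cluster within color classes only.
#' @return the records with `clone_id` assigned (disjoint across classes)
#'   and a logical `unclustered` column marking DBSCAN noise singletons.
#' @export
cluster_clones_dbscan <- function(records, eps, min_samples = 3L,
                                  color_constrained = FALSE) {
  if (eps <= 0) stopf("eps must be positive")
  if (min_samples < 1) stopf("min_samples must be >= 1")
  records$clone_id <- NA_integer_
  records$unclustered <- FALSE
  if (nrow(records) == 0) return(records)
  is_trash <- records$color_class %in% "TRASH"
  next_id <- 0L
  groups <- if (color_constrained) {
    split(which(!is_trash), records$color_class[!is_trash])
  } else list(all = which(!is_trash))
  for (g in groups) {
    if (!length(g)) next
    cl <- cpp_dbscan(records$x[g], records$y[g], eps, as.integer(min_samples))
    noise <- cl == 0L
    if (any(noise)) {
      cl[noise] <- max(cl) + seq_len(sum(noise))  # singleton clones
      records$unclustered[g[noise]] <- TRUE
    }
    records$clone_id[g] <- next_id + cl
    next_id <- next_id + max(cl)
  }
  records
}

#' Estimate the DBSCAN radius from the k-distance curve
#'
#' Sorts the distance to the `min_samples`-th nearest neighbor of every
#' point and takes the knee of the curve (maximum distance to the chord
#' joining its endpoints) — the classic heuristic for choosing `eps`. The
#' estimate is floored at `floor_px` (defaults to twice the median nucleus
#' major axis when available) so duplicated or stacked points cannot
#' collapse it to zero.
#'
#' @param records nucleus table with `x`, `y`.
#' @param min_samples the DBSCAN `min_samples` (k of the k-distance curve).
#' @param floor_px lower bound on the returned eps.
#' @return the estimated eps, with the sorted k-distance curve attached as
#'   attribute `k_distance_curve` for audit.
#' @export
estimate_eps <- function(records, min_samples = 3L, floor_px = NULL) {
  n <- nrow(records)
  if (n < min_samples) stopf("need at least min_samples = %d records", min_samples)
  if (is.null(floor_px))
    floor_px <- if ("major_axis" %in% names(records))
      2 * median(records$major_axis) else 0
  k <- max(1L, as.integer(min_samples) - 1L)  # self excluded by get.knn
  kd <- FNN::get.knn(cbind(records$x, records$y), k = k)$nn.dist[, k]
  curve <- sort(kd)
  i <- knee_by_chord(curve)
  eps <- if (is.na(i)) max(curve) else curve[i]
  eps <- max(eps, floor_px)
  attr(eps, "k_distance_curve") <- curve
  eps
}

#' Clone-level metrics
#'
#' Aggregates member nuclei of each clone: cell count, clone area (convex
#' hull of member centroids for three or more non-collinear members, sum of
#' member nucleus areas otherwise), normalized area (clone area over the
#' well's median nucleus area), compactness (cells per normalized clone
#' area) and the dominant color class.
#'
#' @param records nucleus table with `clone_id` assigned (TRASH rows are
#'   ignored).
#' @param median_nucleus_area well-level median nucleus area; computed from
#'   the records when `NULL`.
#' @return a `data.frame` with one row per clone: `clone_id`, `n_cells`,
#'   `area_px2`, `norm_area`, `compactness`, `color_class`, `x`, `y`,
#'   `unclustered`.
#' @export
clone_metrics <- function(records, median_nucleus_area = NULL) {
  recs <- records[!is.na(records$clone_id) &
                    !(records$color_class %in% "TRASH"), , drop = FALSE]
  if (nrow(recs) == 0)
    return(data.frame(clone_id = integer(), n_cells = integer(),
                      area_px2 = numeric(), norm_area = numeric(),
                      compactness = numeric(), color_class = character(),
                      x = numeric(), y = numeric(), unclustered = logical()))
  if (is.null(median_nucleus_area)) median_nucleus_area <- median(recs$area)
  ids <- sort(unique(recs$clone_id))
  rows <- lapply(ids, function(id) {
    m <- recs[recs$clone_id == id, , drop = FALSE]
    hull_a <- hull_area(m$x, m$y)
    area <- if (is.na(hull_a)) sum(m$area) else hull_a
    norm_area <- area / median_nucleus_area
    cls <- if ("color_class" %in% names(m))
      names(sort(table(m$color_class), decreasing = TRUE))[1] else "UNSET"
    data.frame(clone_id = id, n_cells = nrow(m), area_px2 = area,
               norm_area = norm_area,
               compactness = nrow(m) / norm_area,
               color_class = cls, x = mean(m$x), y = mean(m$y),
               unclustered = all(m$unclustered %||% FALSE),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

# convex hull area of points (shoelace on chull); NA when degenerate
# (fewer than 3 points or collinear)
hull_area <- function(x, y) {
  if (length(x) < 3) return(NA_real_)
  h <- grDevices::chull(x, y)
  if (length(h) < 3) return(NA_real_)
  hx <- x[h]; hy <- y[h]
  a <- abs(sum(hx * c(hy[-1], hy[1]) - c(hx[-1], hx[1]) * hy)) / 2
  if (a <= 0) NA_real_ else a
}

#' Call clones in a segmented well
#'
#' Convenience wrapper: estimate eps (unless given), run DBSCAN (color
#' constrained when the records carry color classes), compute clone
#' metrics.
#'
#' @param records nucleus table from [segment_well()] /
#'   [classify_nuclei()].
#' @param eps DBSCAN radius; `"auto"` or `NULL` estimates it with
#'   [estimate_eps()].
#' @param min_samples DBSCAN minimum samples (default 3).
#' @param color_constrained `NULL` = auto (constrained when any color class
#'   is set).
#' @return list with `nuclei` (records with `clone_id`) and `clones`
#'   (clone metrics table).
#' @export
call_clones <- function(records, eps = NULL, min_samples = 3L,
                        color_constrained = NULL) {
  if (is.null(color_constrained))
    color_constrained <- any(!records$color_class %in% c("UNSET", "TRASH"))
  if (nrow(records) < min_samples) {
    # too few nuclei for any density estimate: every nucleus is its own
    # (unclustered) clone — the honest reading of a near-empty well
    records$clone_id <- seq_len(nrow(records))
    records$unclustered <- rep(TRUE, nrow(records))
    return(list(nuclei = records, clones = clone_metrics(records),
                eps = NA_real_, min_samples = min_samples))
  }
  if (is.null(eps) || identical(eps, "auto"))
    eps <- estimate_eps(records, min_samples = min_samples)
  records <- cluster_clones_dbscan(records, eps = as.numeric(eps),
                                   min_samples = min_samples,
                                   color_constrained = color_constrained)
  list(nuclei = records, clones = clone_metrics(records),
       eps = as.numeric(eps), min_samples = min_samples)
}

#' Longitudinal clone-count and clone-size summaries
#'
#' The same well imaged on successive days yields per-day clone counts and
#' cells-per-clone distributions (no cross-day identity tracking: barcoded
#' wells are imaged live, but clones are summarized per day).
#'
#' @param clone_sets named list (one element per day, in order) of clone
#'   tables from [clone_metrics()].
#' @return list with `summary` (per-day clone count and median/IQR of cells
#'   per clone) and `sizes` (long table of per-day clone sizes).
#' @export
longitudinal_link <- function(clone_sets) {
  stopifnot(is.list(clone_sets), length(clone_sets) >= 2)
  days <- names(clone_sets) %||% as.character(seq_along(clone_sets))
  if (is.null(names(clone_sets))) names(clone_sets) <- days
  summary <- do.call(rbind, lapply(days, function(d) {
    cl <- clone_sets[[d]]
    data.frame(day = d, clone_count = nrow(cl),
               median_n_cells = median(cl$n_cells),
               iqr_n_cells = clone_heterogeneity_iqr(cl$n_cells),
               stringsAsFactors = FALSE)
  }))
  sizes <- do.call(rbind, lapply(days, function(d)
    data.frame(day = d, n_cells = clone_sets[[d]]$n_cells,
               stringsAsFactors = FALSE)))
  list(summary = summary, sizes = sizes)
}
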