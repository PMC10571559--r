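#' Threshold nuclei in a background-corrected image
#'
#' The threshold is read off the intensity derivative of the image: sort
#' the (lightly smoothed) pixel intensities in descending order and take
#' the knee of the resulting curve — the point of maximum curvature where
#' the bright object pixels give way to the background plateau. If the knee
#' is undefined (flat or degenerate curve) the Otsu threshold is used
#' instead. Components smaller than `min_object_px` and border-touching
#' high-gradient artifacts (well edges) are removed.
#'
#' @param image background-corrected numeric matrix.
#' @param min_object_px minimum component area kept, px^2 (default 9).
#' @param smooth half-width of the box smoothing applied before thresholding
#'   (0 disables).
#' @return logical mask; attribute `threshold` carries the chosen level,
#'   `n_debris` the number of sub-minimum components removed.
#' @export
threshold_nuclei <- function(image, min_object_px = 9L, smooth = 1L) {
  stopifnot(is.matrix(image))
  if (all(image == 0)) {
    m <- matrix(FALSE, nrow(image), ncol(image))
    attr(m, "threshold") <- 0
    attr(m, "n_debris") <- 0L
    return(m)
  }
  sm <- if (smooth > 0) box_smooth(image, smooth) else image
  thr <- derivative_knee_threshold(sm)
  if (!is.finite(thr) || thr <= min(sm) || thr >= max(sm))
    thr <- otsu_threshold(sm)
  mask <- sm > thr
  mask <- drop_border_artifacts(mask, image)
  lab <- cpp_label(mask, 8L)
  n <- attr(lab, "n_labels")
  n_debris <- 0L
  if (n > 0) {
    sizes <- tabulate(lab[lab > 0], n)
    small <- which(sizes < min_object_px)
    n_debris <- length(small)
    if (n_debris) mask[lab %in% small] <- FALSE
  }
  attr(mask, "threshold") <- thr
  attr(mask, "n_debris") <- n_debris
  mask
}

# Knee of the descending sorted-intensity curve: the corner where the
# steeply falling object-pixel segment gives way to the background
# plateau, found as the point of maximum distance to the chord joining the
# curve's endpoints (a robust curvature-maximum estimate). Evaluated on a
# fixed-length resampled curve for scale independence.
derivative_knee_threshold <- function(img, n_curve = 512L) {
  v <- sort(as.numeric(img), decreasing = TRUE)
  if (length(v) > n_curve)
    v <- v[round(seq(1, length(v), length.out = n_curve))]
  if (diff(range(v)) == 0) return(NA_real_)
  i <- knee_by_chord(v)
  if (is.na(i) || i < 2L || i > length(v) - 1L) return(NA_real_)
  as.numeric(v[i])
}

# 2-D box smoothing with half-width w (window 2w+1), edge-replicated
box_smooth <- function(img, w) {
  k <- 2L * w + 1L
  nr <- nrow(img); nc <- ncol(img)
  pad <- img[c(rep(1L, w), seq_len(nr), rep(nr, w)),
             c(rep(1L, w), seq_len(nc), rep(nc, w))]
  cs <- apply(pad, 2L, function(col) {
    s <- cumsum(col)
    (s[k:length(s)] - c(0, s[seq_len(length(s) - k)])) / k
  })
  cs <- t(apply(cs, 1L, function(row) {
    s <- cumsum(row)
    (s[k:length(s)] - c(0, s[seq_len(length(s) - k)])) / k
  }))
  cs
}

# remove border-touching components that look like well-edge artifacts:
# high boundary gradient but hollow (low interior fill relative to their
# bounding box) — nuclei clipped by the border are kept
drop_border_artifacts <- function(mask, image, fill_min = 0.35) {
  lab <- cpp_label(mask, 8L)
  n <- attr(lab, "n_labels")
  if (n == 0) return(mask)
  nr <- nrow(mask); nc <- ncol(mask)
  border_labels <- unique(c(lab[1, ], lab[nr, ], lab[, 1], lab[, nc]))
  border_labels <- border_labels[border_labels > 0]
  for (l in border_labels) {
    idx <- which(lab == l)
    ys <- (idx - 1) %% nr + 1; xs <- (idx - 1) %/% nr + 1
    fill <- length(idx) / ((diff(range(ys)) + 1) * (diff(range(xs)) + 1))
    # long, thin, hollow structures hugging the border are edge artifacts
    span <- max(diff(range(ys)), diff(range(xs)))
    if (fill < fill_min && span > 0.5 * min(nr, nc)) mask[idx] <- FALSE
  }
  mask
}

#' Split touching nuclei with a marker-controlled watershed
#'
#' Markers are local maxima — of the smoothed intensity image when one is
#' supplied (each nucleus carries its own brightness peak even when
#' footprints merge deeply), of the Euclidean distance transform of the
#' mask otherwise — suppressed to a minimum separation `h_min`. The
#' watershed floods the corresponding relief (negated intensity or negated
#' distance transform) so valleys and necks between touching nuclei become
#' the split boundaries. Every mask pixel is assigned exactly one label.
#'
#' @param mask logical mask from [threshold_nuclei()].
#' @param image intensity image used for marker detection and flooding;
#'   `NULL` falls back to the distance transform.
#' @param h_min minimum marker separation for the distance-transform
#'   route, px; default half the typical minor axis, estimated from the
#'   mask's distance transform.
#' @param prominence_frac minimum peak prominence for the intensity route,
#'   as a fraction of the bright-pixel (90th percentile) level.
#' @return integer label matrix with attribute `n_labels`.
#' @export
split_touching <- function(mask, image = NULL, h_min = NULL,
                           prominence_frac = 0.015) {
  stopifnot(is.logical(mask))
  if (!any(mask)) {
    lab <- matrix(0L, nrow(mask), ncol(mask))
    attr(lab, "n_labels") <- 0L
    return(lab)
  }
  edt <- cpp_edt(mask)
  if (is.null(h_min)) {
    # minor-axis estimate / 2: the EDT peak of a mask component is its
    # half-thickness, which for both single nuclei and monolayer clumps is
    # the semi-minor axis scale — a geometric estimate that is robust to
    # where exactly the intensity threshold lands
    comp <- cpp_label(mask, 8L)
    idx <- which(mask)
    h_min <- max(2, median(tapply(edt[idx], comp[idx], max)))
  }
  if (is.null(image)) {
    markers <- cpp_peak_markers(edt, mask, h_min)
    cpp_watershed(-edt, markers, mask)
  } else {
    # extended-maxima markers: regional maxima with a minimum prominence,
    # so quantization/noise ripples on a nucleus' flat top never split it,
    # while the dimmer boundary between abutting nuclei (a deeper valley)
    # still separates their peaks
    sm <- box_smooth(image, 2L)
    # prominence floor: above quantization ripple (2) and above the
    # smoothed background noise, scaled to the bright-pixel level
    noise_sm <- if (all(mask)) 0 else stats::mad(sm[!mask])
    h_prom <- max(2, 4 * noise_sm, prominence_frac * quantile(sm[mask], 0.9))
    hmax <- cpp_reconstruct(sm - h_prom, sm)
    rmax <- (hmax - cpp_reconstruct(hmax - 0.5, hmax)) > 1e-9
    markers <- cpp_label(rmax & mask, 8L)
    cpp_watershed(-sm, markers, mask)
  }
}

#' Measure per-nucleus features
#'
#' For every label: intensity-weighted centroid on the reference channel
#' (0-based stitched coordinates), area (pixel count), per-channel total
#' intensity, perimeter (corrected chain-code contour length), major axis
#' (Feret/maximum-caliper diameter), roundness `4 A / (pi L^2)` and
#' circularity `4 pi A / P^2`.
#'
#' @param labels integer label matrix from [split_touching()].
#' @param images named list of channel images (same shape as `labels`).
#' @param reference_channel channel used for centroid weighting (default
#'   the first).
#' @param min_object_px labels smaller than this are dropped and tallied in
#'   attribute `n_dropped`.
#' @return a `data.frame` with one row per nucleus: `nucleus_id`, `x`, `y`,
#'   `area`, `perimeter`, `major_axis`, `total_<channel>` columns,
#'   `roundness`, `circularity`, `color_class` (`"UNSET"`), `clone_id`
#'   (`NA`).
#' @export
measure_nuclei <- function(labels, images, reference_channel = NULL,
                           min_object_px = 9L) {
  stopifnot(is.list(images), length(images) >= 1)
  if (is.null(names(images)) || any(!nzchar(names(images))))
    stopf("`images` must be a named list of channel matrices")
  if (is.null(reference_channel)) reference_channel <- names(images)[1]
  n <- attr(labels, "n_labels") %||% max(labels)
  empty <- data.frame(nucleus_id = integer(), x = numeric(), y = numeric(),
                      area = numeric(), perimeter = numeric(),
                      major_axis = numeric(), roundness = numeric(),
                      circularity = numeric(), color_class = character(),
                      clone_id = integer())
  for (ch in names(images)) empty[[paste0("total_", ch)]] <- numeric()
  if (n == 0) return(empty)
  idx <- which(labels > 0)
  l <- labels[idx]
  nr <- nrow(labels)
  ys0 <- (idx - 1) %% nr        # 0-based
  xs0 <- (idx - 1) %/% nr
  area <- tabulate(l, n)
  ref <- images[[reference_channel]][idx]
  wsum <- rowsum_vec(ref, l, n)
  # fall back to unweighted centroid where the reference signal is zero
  w <- ifelse(wsum[l] > 0, ref, 1)
  wtot <- rowsum_vec(w, l, n)
  cx <- rowsum_vec(w * xs0, l, n) / wtot
  cy <- rowsum_vec(w * ys0, l, n) / wtot
  totals <- lapply(images, function(img) rowsum_vec(img[idx], l, n))
  bm <- cpp_boundary_metrics(labels, as.integer(n))
  # The chain code follows boundary-pixel centers, which sit ~half a pixel
  # inside the true outline: add a fixed outer-offset term (calibrated on
  # rasterized disks and ellipses over the nucleus size range), then floor
  # at the equivalent-area circle perimeter — the isoperimetric lower
  # bound, which also guarantees circularity <= 1 for tiny blobs whose
  # digitization is too crude for the chain estimate.
  per <- pmax(bm[, 1] + 2.5, 2 * sqrt(pi * area))
  feret <- bm[, 2]
  roundness <- 4 * area / (pi * feret^2)
  circularity <- 4 * pi * area / per^2
  out <- data.frame(nucleus_id = seq_len(n), x = cx, y = cy, area = area,
                    perimeter = per, major_axis = feret,
                    roundness = roundness, circularity = circularity,
                    color_class = "UNSET", clone_id = NA_integer_,
                    stringsAsFactors = FALSE)
  for (ch in names(images)) out[[paste0("total_", ch)]] <- totals[[ch]]
  keep <- out$area >= min_object_px
  n_dropped <- sum(!keep)
  out <- out[keep, , drop = FALSE]
  out$nucleus_id <- seq_len(nrow(out))
  rownames(out) <- NULL
  attr(out, "n_dropped") <- n_dropped
  out
}

# per-group sums of a vector (groups 1..n), dense result
rowsum_vec <- function(v, g, n) {
  out <- numeric(n)
  s <- rowsum(v, g)
  out[as.integer(rownames(s))] <- s[, 1]
  out
}

#' Normalize nucleus features to the well median
#'
#' Adds `norm_intensity` (reference-channel total intensity over the well
#' median) and `norm_area` (area over the well median area). Medians are
#' computed excluding TRASH-classified objects when a classification is
#' present, over all records otherwise.
#'
#' @param records nucleus table from [measure_nuclei()].
#' @param reference_channel channel whose total intensity is normalized;
#'   `"dominant"` uses each nucleus's brightest channel (LeGO arm, where
#'   marker intensity is not DNA content).
#' @return the records with `norm_intensity` and `norm_area` columns.
#' @export
normalize_features <- function(records, reference_channel = NULL) {
  if (nrow(records) == 0) stopf("no nucleus records to normalize")
  chans <- sub("^total_", "", grep("^total_", names(records), value = TRUE))
  if (is.null(reference_channel)) reference_channel <- chans[1]
  base <- if (identical(reference_channel, "dominant")) {
    do.call(pmax, records[paste0("total_", chans)])
  } else {
    if (!paste0("total_", reference_channel) %in% names(records))
      stopf("no channel '%s' in records", reference_channel)
    records[[paste0("total_", reference_channel)]]
  }
  ok <- if ("color_class" %in% names(records) &&
            any(records$color_class != "UNSET"))
    records$color_class != "TRASH" else rep(TRUE, nrow(records))
  records$norm_intensity <- base / median(base[ok])
  records$norm_area <- records$area / median(records$area[ok])
  records
}

#' Segment a stitched well end to end
#'
#' Convenience wrapper: threshold, watershed split, measure, normalize.
#'
#' @param well a `stitched_well` (or a named list of channel images).
#' @inheritParams threshold_nuclei
#' @inheritParams split_touching
#' @inheritParams normalize_features
#' @return nucleus records (see [measure_nuclei()]).
#' @export
segment_well <- function(well, min_object_px = 9L, h_min = NULL,
                         reference_channel = NULL) {
  images <- if (inherits(well, "stitched_well")) well$images else well
  signal <- Reduce(`+`, images)
  mask <- threshold_nuclei(signal, min_object_px = min_object_px)
  labels <- split_touching(mask, signal, h_min = h_min)
  recs <- measure_nuclei(labels, images, reference_channel = reference_channel,
                         min_object_px = min_object_px)
  if (nrow(recs) == 0) return(recs)
  normalize_features(recs, reference_channel =
                       if (length(images) > 1) "dominant" else names(images)[1])
}
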