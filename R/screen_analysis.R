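#' Clone-size heterogeneity (IQR)
#'
#' Interquartile range of the cells-per-clone distribution (quartiles by
#' linear interpolation): a high IQR means a heterogeneous mix of small and
#' large clones under the same treatment.
#'
#' @param clone_sizes vector of cells per clone (>= 1 clone).
#' @return the IQR.
#' @export
clone_heterogeneity_iqr <- function(clone_sizes) {
  if (!length(clone_sizes)) stopf("no clone sizes for IQR heterogeneity")
  unname(quantile(clone_sizes, 0.75, type = 7) -
           quantile(clone_sizes, 0.25, type = 7))
}

#' Normalize treatment metrics to the matched control
#'
#' Divides each metric by the same-plate, same-cell-line untreated control
#' value, so the control row becomes exactly 1.
#'
#' @param treated named numeric vector (or one-row data frame) of metrics.
#' @param control matching control metrics.
#' @return normalized metrics (same names).
#' @export
normalize_to_control <- function(treated, control) {
  treated <- unlist(treated); control <- unlist(control)
  nm <- intersect(names(treated), names(control))
  if (!length(nm)) stopf("treated and control metrics share no names")
  bad <- nm[control[nm] == 0]
  if (length(bad))
    stopf("zero control value for metric(s): %s", paste(bad, collapse = ", "))
  treated[nm] / control[nm]
}

#' Assemble the screen table from per-well summaries
#'
#' Joins per-well summaries with a treatment map (well, drug, concentration,
#' cell line, is_control), aggregates replicates by the mean of
#' per-replicate values, computes survival fractions against the matched
#' control and normalizes the clone/nucleus metrics to that control.
#'
#' @param well_summaries data frame rbind of [summarize_well()] rows.
#' @param treatment_map data frame with columns `well_id`, `drug`,
#'   `concentration`, `cell_line`, `is_control`.
#' @return an object of class `screen_table`: one row per treatment
#'   (drug x concentration x cell line) with `survival_fraction`,
#'   `norm_median_nuclei_per_clone`, `norm_iqr_heterogeneity`,
#'   `norm_median_nucleus_size`, `norm_median_circularity`, `replicate_n`;
#'   the per-replicate table is attached as attribute `replicates`.
#' @export
build_screen_table <- function(well_summaries, treatment_map) {
  need <- c("well_id", "drug", "concentration", "cell_line", "is_control")
  miss <- setdiff(need, names(treatment_map))
  if (length(miss)) stopf("treatment map lacks columns: %s", paste(miss, collapse = ", "))
  d <- merge(well_summaries, treatment_map, by = "well_id")
  if (!nrow(d)) stopf("no wells shared between summaries and treatment map")
  d$treatment <- ifelse(d$is_control, paste(d$cell_line, "control"),
                        paste(d$cell_line, d$drug, d$concentration))
  # mean of per-replicate values per treatment
  metr <- c("plating_efficiency", "median_n_cells", "iqr_n_cells",
            "median_nucleus_area", "median_circularity")
  agg <- aggregate(d[metr], by = d[c("treatment", "cell_line", "drug",
                                     "concentration", "is_control")], mean)
  nrep <- aggregate(list(replicate_n = d$well_id),
                    by = d["treatment"], function(x) length(unique(x)))
  agg <- merge(agg, nrep, by = "treatment")
  rows <- lapply(seq_len(nrow(agg)), function(i) {
    ctrl <- agg[agg$cell_line == agg$cell_line[i] & agg$is_control, ]
    if (nrow(ctrl) != 1)
      stopf("expected exactly one control for cell line %s", agg$cell_line[i])
    nm <- normalize_to_control(
      c(norm_median_nuclei_per_clone = agg$median_n_cells[i],
        norm_iqr_heterogeneity = agg$iqr_n_cells[i],
        norm_median_nucleus_size = agg$median_nucleus_area[i],
        norm_median_circularity = agg$median_circularity[i]),
      c(norm_median_nuclei_per_clone = ctrl$median_n_cells,
        norm_iqr_heterogeneity = ctrl$iqr_n_cells,
        norm_median_nucleus_size = ctrl$median_nucleus_area,
        norm_median_circularity = ctrl$median_circularity))
    data.frame(treatment = agg$treatment[i], cell_line = agg$cell_line[i],
               drug = agg$drug[i], concentration = agg$concentration[i],
               is_control = agg$is_control[i],
               survival_fraction = survival_fraction(
                 agg$plating_efficiency[i], ctrl$plating_efficiency),
               t(nm), replicate_n = agg$replicate_n[i],
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "replicates") <- d
  class(out) <- c("screen_table", class(out))
  out
}

screen_metric_cols <- function() {
  c("survival_fraction", "norm_median_nuclei_per_clone",
    "norm_iqr_heterogeneity", "norm_median_nucleus_size",
    "norm_median_circularity")
}

#' Hierarchically cluster treatments
#'
#' Standardizes each metric column to zero mean / unit variance across
#' treatments (constant columns are dropped with a warning), clusters with
#' Euclidean distance and Ward linkage, and cuts the tree at `k` classes.
#' Deterministic for a given row order.
#'
#' @param table a `screen_table` (or data frame with the metric columns).
#' @param k number of treatment classes (default 3).
#' @param columns metric columns to use.
#' @return list with `labels` (1..k per row), `order` (dendrogram leaf
#'   order for heatmap rendering), `hclust`, and the `standardized` matrix.
#' @export
cluster_treatments <- function(table, k = 3L,
                               columns = screen_metric_cols()) {
  if (nrow(table) < k) stopf("need at least k = %d treatments", k)
  X <- as.matrix(table[, columns, drop = FALSE])
  if (any(!is.finite(X))) stopf("missing cells in the screen table")
  sds <- apply(X, 2, sd)
  if (any(sds == 0)) {
    warnf("dropping constant column(s): %s",
          paste(columns[sds == 0], collapse = ", "))
    X <- X[, sds > 0, drop = FALSE]
  }
  Z <- scale(X)
  hc <- hclust(dist(Z), method = "ward.D2")
  labels <- cutree(hc, k = k)
  # relabel so cluster ids appear in first-occurrence order (deterministic)
  first <- sapply(unique(labels), function(l) which(labels == l)[1])
  remap <- order(order(first))
  labels <- remap[match(labels, unique(labels))]
  list(labels = as.integer(labels), order = hc$order, hclust = hc,
       standardized = Z)
}

#' Correlate screen metrics with the survival fraction
#'
#' Pearson and Spearman coefficients of each normalized metric against the
#' survival fraction across treatments. Zero-variance metrics are reported
#' as `NA` (undefined), not 0.
#'
#' @param table a `screen_table`.
#' @param columns metric columns (survival fraction excluded
#'   automatically).
#' @return data frame with `metric`, `pearson`, `spearman`, `n`.
#' @export
correlate_metrics_with_survival <- function(table,
                                            columns = screen_metric_cols()) {
  if (nrow(table) < 3) stopf("need >= 3 treatments for correlation")
  columns <- setdiff(columns, "survival_fraction")
  sf <- table$survival_fraction
  rows <- lapply(columns, function(cl) {
    v <- table[[cl]]
    if (sd(v) == 0 || sd(sf) == 0) {
      data.frame(metric = cl, pearson = NA_real_, spearman = NA_real_,
                 n = length(v))
    } else {
      data.frame(metric = cl, pearson = cor(v, sf, method = "pearson"),
                 spearman = cor(v, sf, method = "spearman"), n = length(v))
    }
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Heatmap of the clustered screen table
#'
#' Optional visual: standardized metrics in dendrogram leaf order
#' (requires the `pheatmap` package).
#'
#' @param table a `screen_table`.
#' @param k treatment classes.
#' @param file optional PNG path.
#' @return the pheatmap object, invisibly.
#' @export
plot_screen_heatmap <- function(table, k = 3L, file = NULL) {
  if (!requireNamespace("pheatmap", quietly = TRUE))
    stopf("plot_screen_heatmap needs the 'pheatmap' package")
  cl <- cluster_treatments(table, k = k)
  Z <- cl$standardized
  rownames(Z) <- table$treatment
  ann <- data.frame(class = factor(cl$labels))
  rownames(ann) <- table$treatment
  args <- list(mat = Z, annotation_row = ann, clustering_method = "ward.D2")
  if (!is.null(file)) { args$filename <- file }
  p <- do.call(pheatmap::pheatmap, args)
  invisible(p)
}
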