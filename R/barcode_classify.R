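#' Color features for barcode classification
#'
#' Builds the fixed feature vector used by the color classifier from a
#' nucleus record: per-channel mean intensity (total/area), per-channel
#' intensity fractions (scale-invariant — the signature of the additive RGB
#' barcode), log10 total intensity, area and circularity. Records with zero
#' intensity in every channel get fractions 1/3 and are flagged.
#'
#' @param records nucleus table with `total_r`, `total_g`, `total_b`,
#'   `area`, `circularity` columns.
#' @return numeric feature matrix; the canonical column order is recorded
#'   in attribute `feature_spec`, rows flagged degenerate in attribute
#'   `zero_intensity`.
#' @export
extract_color_features <- function(records) {
  need <- c("total_r", "total_g", "total_b", "area", "circularity")
  miss <- setdiff(need, names(records))
  if (length(miss)) stopf("records lack columns: %s", paste(miss, collapse = ", "))
  tr <- records$total_r; tg <- records$total_g; tb <- records$total_b
  tot <- tr + tg + tb
  zero <- tot <= 0
  tots <- ifelse(zero, 1, tot)
  f <- cbind(mean_r = tr / records$area,
             mean_g = tg / records$area,
             mean_b = tb / records$area,
             frac_r = ifelse(zero, 1 / 3, tr / tots),
             frac_g = ifelse(zero, 1 / 3, tg / tots),
             frac_b = ifelse(zero, 1 / 3, tb / tots),
             log_total = log10(pmax(tot, 1)),
             area = records$area,
             circularity = records$circularity)
  attr(f, "feature_spec") <- colnames(f)
  attr(f, "zero_intensity") <- which(zero)
  f
}

# Gini impurity of class counts
gini <- function(counts) {
  n <- sum(counts)
  if (n == 0) return(0)
  1 - sum((counts / n)^2)
}

# best (feature, threshold) split of a node by Gini gain; deterministic
# tie-breaks: lower feature index, then lower threshold
best_split <- function(X, yi, k) {
  n <- length(yi)
  parent <- gini(tabulate(yi, k))
  best <- NULL
  for (j in seq_len(ncol(X))) {
    o <- order(X[, j], yi)
    xv <- X[o, j]; yv <- yi[o]
    cum <- matrix(0L, n, k)
    cnt <- integer(k)
    for (i in seq_len(n)) { cnt[yv[i]] <- cnt[yv[i]] + 1L; cum[i, ] <- cnt }
    tot <- cum[n, ]
    # candidate cuts between distinct consecutive values
    cut_at <- which(diff(xv) > 0)
    for (i in cut_at) {
      nl <- i; nr <- n - i
      gl <- gini(cum[i, ]); gr <- gini(tot - cum[i, ])
      imp <- (nl * gl + nr * gr) / n
      gain <- parent - imp
      thr <- (xv[i] + xv[i + 1]) / 2
      if (gain > 1e-12 &&
          (is.null(best) || gain > best$gain + 1e-12 ||
           (abs(gain - best$gain) <= 1e-12 &&
            (j < best$feature ||
             (j == best$feature && thr < best$threshold))))) {
        best <- list(feature = j, threshold = thr, gain = gain)
      }
    }
  }
  best
}

grow_tree <- function(X, yi, k, nodes, depth = 0L) {
  counts <- tabulate(yi, k)
  node <- list(feature = NA_integer_, threshold = NA_real_,
               left = NA_integer_, right = NA_integer_,
               class = which.max(counts), n = length(yi))
  id <- length(nodes) + 1L
  nodes[[id]] <- node
  if (gini(counts) <= 1e-12 || length(yi) < 2L) return(list(id = id, nodes = nodes))
  sp <- best_split(X, yi, k)
  if (is.null(sp)) return(list(id = id, nodes = nodes))
  go_l <- X[, sp$feature] <= sp$threshold
  L <- grow_tree(X[go_l, , drop = FALSE], yi[go_l], k, nodes, depth + 1L)
  R <- grow_tree(X[!go_l, , drop = FALSE], yi[!go_l], k, L$nodes, depth + 1L)
  nodes <- R$nodes
  nodes[[id]]$feature <- sp$feature
  nodes[[id]]$threshold <- sp$threshold
  nodes[[id]]$left <- L$id
  nodes[[id]]$right <- R$id
  list(id = id, nodes = nodes)
}

#' Train the color-class decision tree
#'
#' CART decision tree (Gini impurity, unlimited depth, no pruning) over the
#' color feature vector — the "default settings" tree of the barcode
#' workflow. Training is deterministic: exhaustive split search with fixed
#' tie-breaking, so a fixed input yields an identical tree.
#'
#' @param features feature matrix from [extract_color_features()] (or with
#'   matching columns).
#' @param class class label per row (six colors and optionally `TRASH`).
#' @param min_per_class warn below this many examples per class (default 10).
#' @return an object of class `color_model` with the fitted `nodes` table,
#'   `classes`, `feature_spec` and `training_accuracy`.
#' @export
train_color_model <- function(features, class, min_per_class = 10L) {
  features <- as.matrix(features)
  class <- as.character(class)
  stopifnot(nrow(features) == length(class))
  classes <- sort(unique(class))
  if (length(classes) < 2L) stopf("need at least 2 classes to train")
  tab <- table(class)
  if (any(tab < min_per_class))
    warnf("classes with fewer than %d examples: %s", min_per_class,
          paste(names(tab)[tab < min_per_class], collapse = ", "))
  yi <- match(class, classes)
  res <- grow_tree(features, yi, length(classes), list())
  nodes <- do.call(rbind, lapply(res$nodes, function(nd)
    data.frame(feature = nd$feature, threshold = nd$threshold,
               left = nd$left, right = nd$right, class = nd$class,
               n = nd$n)))
  model <- structure(list(nodes = nodes, classes = classes,
                          feature_spec = colnames(features),
                          version = "1"),
                     class = "color_model")
  model$training_accuracy <-
    mean(predict_color_model(model, features) == class)
  model
}

predict_color_model <- function(model, features) {
  nodes <- model$nodes
  n <- nrow(features)
  out <- integer(n)
  for (i in seq_len(n)) {
    id <- 1L
    while (!is.na(nodes$feature[id])) {
      id <- if (features[i, nodes$feature[id]] <= nodes$threshold[id])
        nodes$left[id] else nodes$right[id]
    }
    out[i] <- nodes$class[id]
  }
  model$classes[out]
}

#' @export
print.color_model <- function(x, ...) {
  cat(sprintf("<color_model> %d classes (%s), %d nodes, training accuracy %.3f\n",
              length(x$classes), paste(x$classes, collapse = ", "),
              nrow(x$nodes), x$training_accuracy))
  invisible(x)
}

#' Classify nuclei into barcode color classes
#'
#' Sets `color_class` on every record using a trained [train_color_model()]
#' tree (features are re-derived from the records in the model's feature
#' order). TRASH records are excluded downstream from clone calling and
#' from normalization medians.
#'
#' @param records nucleus table.
#' @param model a `color_model`.
#' @return the records with `color_class` filled in.
#' @export
classify_nuclei <- function(records, model) {
  stopifnot(inherits(model, "color_model"))
  if (nrow(records) == 0) return(records)
  features <- extract_color_features(records)
  if (!identical(colnames(features)[seq_along(model$feature_spec)],
                 model$feature_spec)) {
    # accept any column order that covers the spec
    if (!all(model$feature_spec %in% colnames(features)))
      stopf("feature spec mismatch: model expects %s",
            paste(model$feature_spec, collapse = ", "))
    features <- features[, model$feature_spec, drop = FALSE]
  }
  records$color_class <- predict_color_model(model, features)
  records
}

#' Rule-based fallback color classifier
#'
#' Label-free alternative to the trained tree: a channel is "on" when its
#' intensity fraction exceeds `on_frac`; the on-set maps to the six color
#' classes, anything else (no channel on, all three on) is TRASH.
#'
#' @param records nucleus table.
#' @param on_frac fraction above which a channel counts as expressed
#'   (default 0.25).
#' @return the records with `color_class` filled in.
#' @export
classify_nuclei_rules <- function(records, on_frac = 0.25) {
  if (nrow(records) == 0) return(records)
  f <- extract_color_features(records)
  on <- cbind(f[, "frac_r"] > on_frac, f[, "frac_g"] > on_frac,
              f[, "frac_b"] > on_frac)
  key <- on[, 1] * 4 + on[, 2] * 2 + on[, 3]
  map <- c("4" = "R", "2" = "G", "1" = "B", "6" = "RG", "5" = "RB",
           "3" = "GB")
  cls <- map[as.character(key)]
  cls[is.na(cls)] <- "TRASH"
  records$color_class <- unname(cls)
  records
}

#' Save / load a color model as versioned JSON
#'
#' @param model a `color_model`.
#' @param path JSON file path.
#' @return `write_color_model()` returns `path` invisibly;
#'   `read_color_model()` the model.
#' @export
write_color_model <- function(model, path) {
  stopifnot(inherits(model, "color_model"))
  jsonlite::write_json(list(version = model$version, classes = model$classes,
                            feature_spec = model$feature_spec,
                            training_accuracy = model$training_accuracy,
                            nodes = model$nodes),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_color_model
#' @export
read_color_model <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  structure(list(nodes = as.data.frame(x$nodes), classes = x$classes,
                 feature_spec = x$feature_spec,
                 training_accuracy = x$training_accuracy,
                 version = x$version),
            class = "color_model")
}
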