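pts_record <- function(x, y, cls = "UNSET") {
  data.frame(x = x, y = y, color_class = cls, area = 50,
             stringsAsFactors = FALSE)
}

test_that("DBSCAN matches hand-checkable configurations", {
  # three collinear points at spacing eps/2: one cluster of three
  r <- pts_record(c(0, 5, 10), c(0, 0, 0))
  out <- cluster_clones_dbscan(r, eps = 10, min_samples = 2)
  expect_equal(length(unique(out$clone_id)), 1)
  expect_false(any(out$unclustered))

  # two groups separated by 10 eps: two clusters
  r2 <- pts_record(c(0, 1, 2, 100, 101, 102), rep(0, 6))
  out2 <- cluster_clones_dbscan(r2, eps = 10, min_samples = 2)
  expect_equal(length(unique(out2$clone_id)), 2)

  expect_error(cluster_clones_dbscan(r, eps = 0, min_samples = 2), "eps")
  expect_error(cluster_clones_dbscan(r, eps = 1, min_samples = 0),
               "min_samples")
})

test_that("color constraint separates overlapping clones of unlike color", {
  set.seed(5)
  n <- 30
  mixed <- pts_record(c(rnorm(n, 0, 4), rnorm(n, 2, 4)),
                      c(rnorm(n, 0, 4), rnorm(n, 2, 4)),
                      cls = rep(c("R", "GB"), each = n))
  con <- cluster_clones_dbscan(mixed, eps = 6, min_samples = 3,
                               color_constrained = TRUE)
  expect_equal(length(unique(con$clone_id[!con$unclustered])), 2)
  for (cl in unique(con$clone_id))
    expect_equal(length(unique(mixed$color_class[con$clone_id == cl])), 1)
  un <- cluster_clones_dbscan(mixed, eps = 6, min_samples = 3,
                              color_constrained = FALSE)
  expect_equal(length(unique(un$clone_id[!un$unclustered])), 1)
})

test_that("DBSCAN agrees with the brute-force reachability oracle", {
  set.seed(11)
  for (trial in 1:60) {
    n <- sample(5:100, 1)
    k <- sample(1:5, 1)
    cx <- runif(k, 0, 100)
    cy <- runif(k, 0, 100)
    g <- sample(k, n, replace = TRUE)
    x <- cx[g] + rnorm(n, 0, 4)
    y <- cy[g] + rnorm(n, 0, 4)
    eps <- runif(1, 2, 12)
    ms <- sample(2:6, 1)
    mine <- clonoscope:::cpp_dbscan(x, y, eps, ms)
    oracle <- brute_dbscan(x, y, eps, ms)
    expect_true(same_partition(as.integer(mine), oracle),
                label = sprintf("trial %d (n=%d eps=%.2f ms=%d)",
                                trial, n, eps, ms))
  }
})

test_that("eps estimation reads the k-distance curve", {
  # regular grid of spacing d: eps lands in [d, 2d]
  g <- expand.grid(x = seq(0, 90, 10), y = seq(0, 90, 10))
  e <- estimate_eps(g, min_samples = 3, floor_px = 0)
  expect_gte(as.numeric(e), 10)
  expect_lte(as.numeric(e), 20)
  expect_equal(length(attr(e, "k_distance_curve")), nrow(g))

  # duplicated points collapse the curve; the floor guards eps
  dup <- data.frame(x = rep(c(0, 50), each = 10), y = 0, major_axis = 12)
  ed <- estimate_eps(dup, min_samples = 3)
  expect_gte(as.numeric(ed), 2 * 12)

  # scaling coordinates by c scales eps by c
  e3 <- estimate_eps(transform(g, x = 3 * x, y = 3 * y),
                     min_samples = 3, floor_px = 0)
  expect_equal(as.numeric(e3), 3 * as.numeric(e))

  expect_error(estimate_eps(g[1:2, ], min_samples = 3), "min_samples")
})

test_that("clone metrics follow their definitions", {
  # singleton: clone area falls back to the nucleus area
  one <- pts_record(5, 5)
  one$clone_id <- 1L
  one$unclustered <- FALSE
  m1 <- clone_metrics(one, median_nucleus_area = 25)
  expect_equal(m1$area_px2, 50)
  expect_equal(m1$compactness, 1 / (50 / 25))

  # four members on a unit square, median nucleus area 0.5:
  # hull 1, norm_area 2, compactness 2
  sq <- pts_record(c(0, 1, 1, 0), c(0, 0, 1, 1))
  sq$clone_id <- 1L
  sq$unclustered <- FALSE
  m2 <- clone_metrics(sq, median_nucleus_area = 0.5)
  expect_equal(m2$area_px2, 1)
  expect_equal(m2$norm_area, 2)
  expect_equal(m2$compactness, 2)
  expect_equal(m2$n_cells, 4)

  # translation leaves every metric unchanged
  sq2 <- transform(sq, x = x + 37, y = y - 12)
  m3 <- clone_metrics(sq2, median_nucleus_area = 0.5)
  expect_equal(m3[c("n_cells", "area_px2", "norm_area", "compactness")],
               m2[c("n_cells", "area_px2", "norm_area", "compactness")])
})

test_that("clone assignment partitions the non-trash records", {
  gw <- generate_well(small_well_params(51))
  res <- suppressWarnings(analyze_well(gw$scan, seeded_cells = 60,
                                       color_model = "rules"))
  nu <- res$nuclei
  non_trash <- nu[nu$color_class != "TRASH", ]
  expect_true(all(!is.na(non_trash$clone_id)))
  expect_equal(sum(res$clones$n_cells), nrow(non_trash))
  # members of one clone share its color class (LeGO arm)
  for (cl in res$clones$clone_id[res$clones$n_cells > 1][1:5])
    expect_equal(length(unique(nu$color_class[which(nu$clone_id == cl)])), 1)
})

test_that("clone recovery on paper-density wells exceeds 95%", {
  hits <- 0
  total <- 0
  for (sd in 61:62) {
    gw <- generate_well(small_well_params(sd, seeded = 200,
                                          tile_size_px = c(700, 700)))
    res <- suppressWarnings(analyze_well(gw$scan, seeded_cells = 200,
                                         color_model = "rules"))
    tc <- gw$truth$clones
    nn <- FNN::get.knnx(cbind(res$clones$x, res$clones$y),
                        cbind(tc$x, tc$y), k = 1)
    # a truth clone is recovered if exactly one cluster sits at its center
    owner <- FNN::get.knnx(cbind(tc$x, tc$y),
                           cbind(res$clones$x, res$clones$y), k = 1)$nn.index
    per_truth <- tabulate(owner, nrow(tc))
    hits <- hits + sum(per_truth == 1 & nn$nn.dist[, 1] < 40)
    total <- total + nrow(tc)
  }
  expect_gte(hits / total, 0.95)
})

test_that("longitudinal summaries track per-day clone sets", {
  mk <- function(sizes) data.frame(clone_id = seq_along(sizes),
                                   n_cells = sizes)
  same <- longitudinal_link(list(d2 = mk(c(4, 6, 8)), d4 = mk(c(4, 6, 8))))
  expect_equal(same$summary$clone_count, c(3, 3))
  expect_equal(same$summary$median_n_cells, c(6, 6))

  growth <- longitudinal_link(list(d2 = mk(c(4, 6, 8)),
                                   d4 = mk(2 * c(4, 6, 8))))
  expect_equal(growth$summary$median_n_cells[2],
               2 * growth$summary$median_n_cells[1])

  # two clones merging on the later day: the count drops by one
  merged <- longitudinal_link(list(d4 = mk(c(10, 12, 20)),
                                   d6 = mk(c(34, 22))))
  expect_equal(diff(merged$summary$clone_count), -1)
})
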