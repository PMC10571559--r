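make_uniform_scan <- function(v = 5, n = 64, grid = c(1, 2)) {
  tiles <- list()
  for (r in seq_len(grid[1])) {
    tiles[[r]] <- list()
    for (c in seq_len(grid[2]))
      tiles[[r]][[c]] <- list(ch = matrix(v, n, n))
  }
  tile_scan(tiles, overlap_frac = 0.10, channel_names = "ch")
}

test_that("tile_scan rejects ragged or incomplete grids", {
  tiles <- list(list(list(ch = matrix(0, 8, 8)), list(ch = matrix(0, 8, 8))),
                list(list(ch = matrix(0, 8, 8))))
  expect_error(tile_scan(tiles), "rectangular")
  tiles2 <- list(list(list(ch = matrix(0, 8, 8)), list(ch = matrix(0, 9, 8))))
  expect_error(tile_scan(tiles2), "wrong size")
})

test_that("rough_mosaic reduces to a downsampled copy for one tile", {
  set.seed(1)
  img <- matrix(runif(64 * 64), 64, 64)
  sc <- tile_scan(list(list(list(ch = img))), channel_names = "ch")
  mos <- rough_mosaic(sc, downsample = 4L)
  expect_equal(dim(mos), c(16, 16))
  expect_equal(mos[1, 1], mean(img[1:4, 1:4]))
})

test_that("rough_mosaic takes the maximum in overlaps", {
  sc <- make_uniform_scan(v = 7)
  mos <- rough_mosaic(sc, downsample = 1L)
  expect_true(all(mos == 7))
})

test_that("mosaic preserves the clone centroid to downsample accuracy", {
  # one clone: the intensity-weighted centroid of the mosaic foreground
  # lands within 2 x downsample px of the true mean nucleus position
  gw <- generate_well(small_well_params(11, seeded = 1, noise_free = TRUE))
  mos <- rough_mosaic(gw$scan, downsample = 4L)
  thr <- clonoscope:::otsu_threshold(mos)
  idx <- which(mos > thr)
  w <- mos[idx]
  cy <- sum(((idx - 1) %% nrow(mos)) * w) / sum(w) * 4
  cx <- sum(((idx - 1) %/% nrow(mos)) * w) / sum(w) * 4
  tn <- gw$truth$nuclei
  expect_lt(sqrt((mean(tn$x) - cx)^2 + (mean(tn$y) - cy)^2), 2 * 4)
})

test_that("locate_clone_tiles finds exactly the tiles holding signal", {
  blank <- generate_well(small_well_params(12, seeded = 0))
  hits <- locate_clone_tiles(rough_mosaic(blank$scan), blank$scan)
  expect_equal(nrow(hits), 0)

  gw <- generate_well(small_well_params(13, seeded = 1, noise_free = TRUE))
  cl <- gw$truth$clones
  hits <- locate_clone_tiles(rough_mosaic(gw$scan), gw$scan)
  # the clone's tile(s) must be hit; a strictly interior clone gives one
  sc <- gw$scan
  in_tile <- function(r, c)
    cl$y >= sc$origin_y[r] & cl$y < sc$origin_y[r] + sc$tile_size[1] &
    cl$x >= sc$origin_x[c] & cl$x < sc$origin_x[c] + sc$tile_size[2]
  for (i in seq_len(nrow(hits)))
    expect_true(in_tile(hits[i, 1], hits[i, 2]))
  expect_gte(nrow(hits), 1)
})

test_that("a clone straddling a tile border reports both tiles", {
  # clone forced near the vertical seam of a 1x2 scan
  found <- FALSE
  for (sd in 1:20) {
    gw <- generate_well(small_well_params(100 + sd, seeded = 2,
                                          noise_free = TRUE,
                                          tile_grid = c(1, 2)))
    sc <- gw$scan
    seam <- sc$origin_x[2]
    near <- abs(gw$truth$clones$x - seam) < 15
    if (!any(near)) next
    found <- TRUE
    hits <- locate_clone_tiles(rough_mosaic(sc), sc)
    expect_true(all(c(1, 2) %in% hits[, "col"]))
    break
  }
  expect_true(found)
})

test_that("refine_offsets returns nominal offsets for aligned scans", {
  gw <- generate_well(small_well_params(14, noise_free = TRUE))
  off <- refine_offsets(gw$scan, locate_clone_tiles(rough_mosaic(gw$scan),
                                                    gw$scan))
  sc <- gw$scan
  expect_equal(off$oy, sc$origin_y[off$row])
  expect_equal(off$ox, sc$origin_x[off$col])
})

test_that("an injected known shift is recovered exactly", {
  gw <- generate_well(small_well_params(15, seeded = 80, clone_spacing_px = 45,
                                        noise_free = TRUE, tile_jitter_px = 5))
  sh <- gw$truth$tile_shifts
  expect_true(any(sh$dy != 0 | sh$dx != 0))
  off <- refine_offsets(gw$scan, locate_clone_tiles(rough_mosaic(gw$scan),
                                                    gw$scan))
  sc <- gw$scan
  for (i in seq_len(nrow(off))) {
    s <- sh[sh$row == off$row[i] & sh$col == off$col[i], ]
    expect_equal(off$oy[i], sc$origin_y[off$row[i]] + s$dy)
    expect_equal(off$ox[i], sc$origin_x[off$col[i]] + s$dx)
  }
})

test_that("blank overlap strips keep nominal offsets and are all reported", {
  sc <- make_uniform_scan(v = 3, grid = c(2, 2))
  expect_warning(off <- refine_offsets(sc, NULL), "4 overlap")
  expect_equal(attr(off, "n_skipped"), 4L)
  expect_equal(off$oy, sc$origin_y[off$row])
  expect_false(any(off$refined))
})

test_that("stitching a single tile is the identity", {
  set.seed(2)
  img <- matrix(runif(50 * 50), 50, 50)
  sc <- tile_scan(list(list(list(ch = img))), channel_names = "ch")
  well <- stitch(sc)
  expect_equal(well$images$ch, img)
  expect_true(all(well$provenance == 1L))
})

test_that("stitch rejects offsets that leave gaps", {
  sc <- make_uniform_scan(grid = c(1, 2))
  off <- data.frame(row = c(1, 1), col = c(1, 2), oy = c(0, 0),
                    ox = c(0, 70))
  expect_error(stitch(sc, off), "gap")
})

test_that("cross-border clones are counted once after stitching", {
  for (sd in c(31, 32)) {
    gw <- generate_well(sparse_well_params(sd))
    res <- suppressWarnings(analyze_well(gw$scan, seeded_cells = 40))
    # conservation: no object lost or duplicated at the seams
    expect_rel_error(nrow(res$nuclei), nrow(gw$truth$nuclei), 0.02)
    # duplicates would appear as near-coincident centroid pairs
    nn <- FNN::get.knn(cbind(res$nuclei$x, res$nuclei$y), k = 1)
    expect_gt(min(nn$nn.dist), 3)
  }
})

test_that("stitched foreground never exceeds the tile total", {
  gw <- generate_well(small_well_params(16, noise_free = TRUE))
  well <- stitch(gw$scan)
  thr <- 10
  fg_stitched <- sum(well$images$r > thr)
  fg_tiles <- sum(vapply(1:2, function(r) sum(vapply(1:2, function(c)
    sum(gw$scan$tiles[[r]][[c]]$r > thr), numeric(1))), numeric(1)))
  expect_lte(fg_stitched, fg_tiles)
})

test_that("background estimation honors its contracts", {
  # uniform image, no objects -> surface == value everywhere
  img <- matrix(9, 70, 70)
  expect_equal(estimate_background(img), matrix(9, 70, 70))

  # known radial gradient, object-free -> surface within 2% of amplitude
  p <- sim_params(seeded_cells_per_well = 0, tile_grid = c(1, 1),
                  tile_size_px = c(500, 500), illumination = 0.25, seed = 21)
  gw <- generate_well(p)
  tile <- gw$scan$tiles[[1]][[1]][[1]]
  truth <- 200 * clonoscope:::illumination_field(500, 500, 0.25)
  surf <- estimate_background(tile)
  amplitude <- 0.25 * 200
  expect_lt(max(abs(surf - truth)), 0.02 * amplitude)

  # residual after subtraction stays below the noise sigma
  resid <- subtract_background(tile, surf)
  sigma <- sqrt(2^2 + 0.05 * 200)
  expect_lt(mean(abs(resid)), sigma)

  # image fully covered by an object -> global-median fallback with warning
  obj <- matrix(c(0, 1000), 60, 60)
  obj[, ] <- 1000
  obj[1, 1] <- 0
  expect_warning(fb <- estimate_background(obj), "global median")
  expect_equal(fb, matrix(median(obj), 60, 60))
})

test_that("subtract_background clips at zero and checks shapes", {
  img <- matrix(1:9, 3, 3)
  expect_equal(subtract_background(img, matrix(0, 3, 3)), img)
  expect_equal(subtract_background(img, img), matrix(0, 3, 3))
  expect_true(all(subtract_background(img, matrix(100, 3, 3)) == 0))
  expect_error(subtract_background(img, matrix(0, 2, 2)), "shape")
})
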