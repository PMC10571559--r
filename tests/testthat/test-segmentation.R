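test_that("thresholding handles empty and populated images", {
  z <- matrix(0, 40, 40)
  m <- threshold_nuclei(z)
  expect_false(any(m))
  expect_equal(attr(m, "n_debris"), 0L)

  # noise-free well: one foreground component per (isolated) nucleus
  gw <- generate_well(sparse_well_params(1))
  well <- stitch(gw$scan)
  mask <- threshold_nuclei(Reduce(`+`, well$images))
  lab <- clonoscope:::cpp_label(mask)
  n <- attr(lab, "n_labels")
  expect_rel_error(n, nrow(gw$truth$nuclei), 0.03)
})

test_that("tiny components are dropped and tallied as debris", {
  img <- matrix(0, 60, 60)
  img[20:30, 20:30] <- 100   # real object, 121 px
  img[5, 5] <- 100           # speck
  img[50, 52] <- 100         # speck
  m <- threshold_nuclei(img, min_object_px = 9L, smooth = 0L)
  expect_equal(attr(m, "n_debris"), 2L)
  expect_equal(sum(m), 121)
})

test_that("watershed splits the canonical fixtures", {
  # one disk stays whole
  one <- disk_mask(80, cbind(40, 40), 15)
  expect_equal(attr(split_touching(one), "n_labels"), 1L)

  # two disks overlapping by 20% of the radius split into exactly two,
  # with the cut near the true chord
  r <- 15
  d <- 1.8 * r
  two <- disk_mask(120, rbind(c(60 - d / 2, 60), c(60 + d / 2, 60)), r)
  lab <- split_touching(two)
  expect_equal(attr(lab, "n_labels"), 2L)
  # the dividing boundary is the vertical chord at x = 60
  for (l in 1:2) {
    idx <- which(lab == l)
    xs <- (idx - 1) %/% 120 + 1
    side <- if (mean(xs) < 60) max(xs) else min(xs)
    expect_lt(abs(side - 60), 2 + 1)
  }

  # the labels partition the mask
  expect_identical(lab > 0, two)
})

test_that("measured shape factors match analytic fixtures", {
  disk <- disk_mask(51, cbind(26, 26), 20)
  lab <- clonoscope:::cpp_label(disk)
  rec <- measure_nuclei(lab, list(ch = disk * 50))
  expect_gt(rec$roundness, 0.9)
  expect_lt(rec$roundness, 1.05)
  expect_gt(rec$circularity, 0.9)
  expect_lt(rec$circularity, 1.05)

  rect <- matrix(FALSE, 30, 60)
  rect[11:20, 11:50] <- TRUE  # 10 x 40 px
  labr <- clonoscope:::cpp_label(rect)
  recr <- measure_nuclei(labr, list(ch = rect * 1))
  expect_equal(recr$area, 400)
  # roundness 4A / (pi L^2) with the caliper major axis ~ the diagonal
  expect_lt(abs(recr$roundness - 0.30), 0.05)
})

test_that("intensity scaling moves totals but not shapes", {
  gw <- generate_well(small_well_params(21, noise_free = TRUE))
  well <- stitch(gw$scan)
  sig <- Reduce(`+`, well$images)
  mask <- threshold_nuclei(sig)
  lab <- split_touching(mask, sig)
  a <- measure_nuclei(lab, list(s = sig))
  b <- measure_nuclei(lab, list(s = sig * 2))
  expect_equal(b$total_s, 2 * a$total_s)
  expect_equal(b$roundness, a$roundness)
  expect_equal(b$circularity, a$circularity)
})

test_that("total intensity is conserved over the mask", {
  gw <- generate_well(small_well_params(22))
  well <- stitch(gw$scan)
  sig <- Reduce(`+`, well$images)
  mask <- threshold_nuclei(sig)
  lab <- split_touching(mask, sig)
  rec <- measure_nuclei(lab, list(s = sig), min_object_px = 0L)
  expect_equal(sum(rec$total_s), sum(sig[lab > 0]), tolerance = 1e-6)
})

test_that("nucleus counts recover ground truth in both density regimes", {
  # seldom-touching nuclei: within 2%
  for (sd in 2:3) {
    gw <- generate_well(sparse_well_params(sd))
    res <- suppressWarnings(analyze_well(gw$scan, seeded_cells = 40))
    expect_rel_error(nrow(res$nuclei), nrow(gw$truth$nuclei), 0.02)
  }
  # touching regime (dispersion = nucleus major axis): within 5%
  for (sd in 2:3) {
    gw <- generate_well(sparse_well_params(sd, clone_dispersion_px = 12,
                                           nucleus_min_sep_px = 9))
    res <- suppressWarnings(analyze_well(gw$scan, seeded_cells = 40))
    expect_rel_error(nrow(res$nuclei), nrow(gw$truth$nuclei), 0.05)
  }
})

test_that("shape sanity holds across a rendered well", {
  gw <- generate_well(small_well_params(23))
  res <- suppressWarnings(analyze_well(gw$scan, seeded_cells = 60))
  expect_true(all(res$nuclei$roundness <= 1.05))
  expect_true(all(res$nuclei$circularity <= 1.05))
  expect_true(all(res$nuclei$area > 0))
})

test_that("normalization is anchored at the well median", {
  one <- data.frame(area = 50, total_ch = 123, color_class = "UNSET")
  n1 <- normalize_features(one, "ch")
  expect_equal(n1$norm_intensity, 1)
  expect_equal(n1$norm_area, 1)

  recs <- data.frame(area = c(10, 20, 40), total_ch = c(50, 100, 300),
                     color_class = "UNSET")
  nr <- normalize_features(recs, "ch")
  expect_equal(nr$norm_intensity, c(0.5, 1, 3))
  expect_equal(median(nr$norm_area), 1)

  expect_error(normalize_features(recs[0, ], "ch"), "no nucleus records")

  # TRASH records are excluded from the medians once classified
  recs2 <- data.frame(area = c(10, 50, 50, 50), total_ch = c(5, 100, 100, 100),
                      color_class = c("TRASH", "R", "G", "B"))
  n2 <- normalize_features(recs2, "ch")
  expect_equal(n2$norm_intensity[2], 1)
  expect_equal(n2$norm_area[1], 10 / 50)
})
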