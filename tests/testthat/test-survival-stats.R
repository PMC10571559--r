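test_that("clone counting applies the 50-cell rule", {
  clones <- data.frame(n_cells = c(49, 50, 120))
  expect_equal(count_clones(clones, 50), 2)
  expect_equal(count_clones(data.frame(n_cells = rep(3, 7)), 1), 7)
  expect_equal(count_clones(data.frame(n_cells = integer()), 50), 0)
  # non-increasing in the threshold
  sizes <- data.frame(n_cells = c(1, 5, 20, 49, 50, 80, 200))
  counts <- vapply(c(1, 10, 50, 100), function(m) count_clones(sizes, m),
                   numeric(1))
  expect_true(all(diff(counts) <= 0))
})

test_that("surviving fraction is the plating-efficiency ratio", {
  expect_equal(survival_fraction(0.3, 0.3), 1)
  expect_equal(survival_fraction(0.1, 0.5), 0.2)
  expect_equal(survival_fraction(0, 0.5), 0)
  expect_error(survival_fraction(0.1, 0), "undefined")
})

test_that("plating efficiency recovers the survival probability", {
  # 60 replicate wells at the truth level: the generator's surviving count
  # over seeded cells is Binom(n, p)/n
  p <- 0.4
  n <- 200
  pe <- vapply(1:60, function(i) {
    gw <- generate_well(sim_params(
      seeded_cells_per_well = n, survival_prob = p,
      cells_per_clone_law = list(median = 1, sigma = 0.01),
      clone_dispersion_px = 2, nucleus_axes_px = c(8, 6),
      clone_spacing_px = 11, tile_grid = c(1, 1),
      tile_size_px = c(360, 360), fragment_rate = 0, illumination = 0,
      noise = list(gaussian_sd = 0, poisson_gain = 0), seed = 900 + i))
    gw$truth$surviving_clones / n
  }, numeric(1))
  se <- sqrt(p * (1 - p) / n) / sqrt(60)
  expect_lt(abs(mean(pe) - p), 3 * se)
})

test_that("DNA-content histogram is density-normalized with honest modes", {
  # pure G1 log-normal population: single mode at 1 (truth-level records)
  gw <- generate_well(small_well_params(71, arm = "classical",
                                        intensity_sigma = 0.1,
                                        fragment_rate = 0))
  tn <- gw$truth$nuclei
  recs <- data.frame(area = tn$area, color_class = "UNSET",
                     total_dna = tn$total_dna)
  recs <- normalize_features(recs, "dna")
  h <- dna_content_histogram(recs)
  expect_equal(sum(h$density), 1)
  d <- density(recs$norm_intensity, bw = 0.05)
  expect_lt(abs(d$x[which.max(d$y)] - 1), 0.05)
  expect_error(dna_content_histogram(recs[0, ]), "no records")
})

test_that("anomaly fractions count what the thresholds say", {
  base <- data.frame(norm_intensity = 1, norm_area = 1, roundness = 0.9,
                     circularity = 0.95, color_class = "UNSET")
  f0 <- anomaly_fractions(base[rep(1, 5), ])
  expect_true(all(f0 == 0))

  tri <- data.frame(norm_intensity = c(0.2, 1.0, 3.5),
                    norm_area = c(1, 1, 1), roundness = 0.9,
                    circularity = 0.95, color_class = "UNSET")
  ft <- anomaly_fractions(tri)
  expect_equal(unname(ft["frac_small_intensity"]), 1 / 3)
  expect_equal(unname(ft["frac_large_intensity"]), 1 / 3)
  expect_error(anomaly_fractions(tri[0, ]), "no records")
})

test_that("fragment planting shows up in the small-area fraction", {
  sp <- sparse_well_params(81, seeded_cells_per_well = 60,
                           clone_dispersion_px = 25, clone_spacing_px = 130,
                           tile_size_px = c(900, 900),
                           fragment_rate = 0.2, arm = "classical")
  gw <- generate_well(sp)
  res <- suppressWarnings(analyze_well(gw$scan, seeded_cells = 60))
  tn <- gw$truth$nuclei
  tt <- normalize_features(
    data.frame(area = tn$area, roundness = tn$roundness,
               circularity = tn$circularity, color_class = "UNSET",
               total_dna = tn$total_dna), "dna")
  truth_fr <- anomaly_fractions(tt)
  seg_fr <- anomaly_fractions(res$nuclei)
  # segmented fractions match the ground-truth table within 0.02
  expect_true(all(abs(seg_fr - truth_fr) < 0.02))
  # and the small-area fraction tracks the realized fragment fraction
  realized <- mean(tn$is_fragment)
  se <- sqrt(realized * (1 - realized) / nrow(tn))
  expect_lt(abs(seg_fr["frac_small_area"] - realized), 3 * se + 0.02)
})

test_that("summaries assemble plating efficiency and fractions", {
  gw <- generate_well(small_well_params(82, arm = "classical"))
  res <- suppressWarnings(analyze_well(gw$scan, seeded_cells = 60,
                                       cfg = threshold_config(min_cells_per_clone = 3)))
  s <- res$summary
  expect_equal(s$plating_efficiency, s$clone_count_at_threshold / 60)
  expect_true(all(unlist(s[grep("^frac_", names(s))]) >= 0))
  expect_true(all(unlist(s[grep("^frac_", names(s))]) <= 1))
  h <- attr(s, "dna_histogram")
  expect_equal(sum(h$density), 1)
})

test_that("seeding-density selection prefers the densest stable condition", {
  flat <- expand.grid(density = c(100, 200, 300), day = c(2, 4, 6))
  flat$clone_count <- flat$density * 0.4
  expect_equal(as.numeric(select_seeding_density(flat)), 300)

  # densest condition loses 40% of its clones by day 6: pick 200
  drop <- flat
  drop$clone_count[drop$density == 300] <- c(120, 110, 72)
  expect_equal(as.numeric(select_seeding_density(drop)), 200)

  one <- data.frame(density = 150, day = c(2, 4), clone_count = c(60, 61))
  expect_equal(as.numeric(select_seeding_density(one)), 150)
  expect_error(select_seeding_density(one[1, ]), "2 days")

  unstable <- data.frame(density = c(100, 100), day = c(2, 6),
                         clone_count = c(100, 10))
  expect_warning(sel <- select_seeding_density(unstable), "stable")
  expect_equal(as.numeric(sel), 100)
})
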