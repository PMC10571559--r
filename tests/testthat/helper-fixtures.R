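# Shared fixture builders. All wells here are deliberately small so the
# full suite stays fast; the geometry (10% overlap, hard-core packed
# elliptical nuclei, radial vignette, Poisson-Gaussian noise) matches the
# generator defaults.

# compact early-time-point well: 10%-overlap 2x2 scan, small clones
small_well_params <- function(seed, survival = 1, seeded = 60,
                              noise_free = FALSE, ...) {
  args <- list(
    seeded_cells_per_well = seeded, survival_prob = survival,
    cells_per_clone_law = list(median = 8, sigma = 0.3),
    clone_dispersion_px = 8, nucleus_axes_px = c(10, 7),
    clone_spacing_px = 55, tile_grid = c(2, 2), tile_size_px = c(450, 450),
    seed = seed)
  if (noise_free)
    args <- c(args, list(illumination = 0,
                         noise = list(gaussian_sd = 0, poisson_gain = 0)))
  do.call(sim_params, utils::modifyList(args, list(...)))
}

# sparse well where nuclei seldom touch (for count-recovery properties)
sparse_well_params <- function(seed, ...) {
  do.call(sim_params, utils::modifyList(list(
    seeded_cells_per_well = 40, survival_prob = 1,
    cells_per_clone_law = list(median = 8, sigma = 0.3),
    clone_dispersion_px = 30, nucleus_axes_px = c(12, 9),
    nucleus_min_sep_px = 14, fragment_rate = 0, clone_spacing_px = 125,
    tile_grid = c(2, 2), tile_size_px = c(700, 700),
    noise = list(gaussian_sd = 0, poisson_gain = 0), seed = seed),
    list(...)))
}

# binary mask of one or two rasterized disks
disk_mask <- function(n, centers, r) {
  yy <- matrix(seq_len(n), n, n)
  xx <- t(yy)
  m <- matrix(FALSE, n, n)
  for (i in seq_len(nrow(centers)))
    m <- m | (sqrt((yy - centers[i, 2])^2 + (xx - centers[i, 1])^2) <= r)
  m
}

# truth-labeled color training data straight from rendered wells: objects
# flagged as fragments become TRASH, everything else keeps its color class
truth_labeled_training <- function(seeds, fragment_rate = 0.15) {
  recs <- list()
  for (sd in seeds) {
    gw <- generate_well(small_well_params(sd, fragment_rate = fragment_rate))
    tn <- gw$truth$nuclei
    d <- data.frame(area = tn$area, circularity = tn$circularity,
                    total_r = tn$total_r, total_g = tn$total_g,
                    total_b = tn$total_b,
                    class = ifelse(tn$is_fragment, "TRASH", tn$color_class),
                    stringsAsFactors = FALSE)
    recs[[length(recs) + 1L]] <- d
  }
  do.call(rbind, recs)
}

expect_rel_error <- function(est, truth, tol) {
  expect_lt(abs(est - truth) / truth, tol)
}
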