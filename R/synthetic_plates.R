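#' Simulation parameters for a synthetic well
#'
#' Builds and validates the parameter set for the synthetic plate-image
#' generator. The generator emulates a clonogenic survival assay imaged as a
#' fluorescence tile scan: single seeded cells either die or grow into
#' compact clones of elliptical nuclei; nuclei carry one of six additive RGB
#' barcode color classes (R, G, B, RG, RB, GB) in the LeGO arm, or a single
#' DNA-stain channel in the classical arm; tiles overlap by a fixed
#' fraction, are vignetted by a radial illumination gradient and corrupted
#' by Poisson-Gaussian camera noise.
#'
#' Defaults describe the regime the assay is designed for: 200 seeded
#' cells/well (the optimal seeding density for stable clone counts), day-4
#' clones of a few dozen cells (log-normal cells-per-clone, median 30),
#' 10 percent tile overlap. Noise and illumination amplitudes are not dictated by
#' any published value and are deliberately exposed here.
#'
#' @param seeded_cells_per_well cells seeded into the well.
#' @param survival_prob probability that a seeded cell forms a clone.
#' @param cells_per_clone_law list(median, sigma) of the log-normal clone
#'   size law (cells per surviving clone, at imaging time).
#' @param clone_dispersion_px isotropic Gaussian scatter (sd, px) of member
#'   nuclei around the clone center.
#' @param nucleus_axes_px c(major, minor) full axes of the elliptical
#'   nucleus footprint, px.
#' @param color_mix six fractions over c(R, G, B, RG, RB, GB), summing to 1.
#' @param fragment_rate fraction of nuclei replaced by 2-4 small fragments
#'   (micronucleus / debris emulation).
#' @param tile_grid c(rows, cols) of the tile scan.
#' @param tile_size_px c(height, width) of one tile, px.
#' @param overlap_frac fractional overlap between neighboring tiles
#'   (default 0.10).
#' @param illumination radial vignette amplitude per tile: the field is 1 at
#'   the tile center and `1 - illumination` at the corners.
#' @param noise list(gaussian_sd, poisson_gain): additive Gaussian read
#'   noise (intensity units) and Poisson gain (intensity units per photon
#'   count; 0 disables shot noise).
#' @param background_level flat background intensity before vignetting.
#' @param arm `"lego"` (three channels r, g, b) or `"classical"` (single
#'   `dna` channel).
#' @param intensity_mode `"g1"` (one log-normal intensity population) or
#'   `"g1g2"` (adds a G2 population at twice the G1 total intensity).
#' @param g2_frac fraction of nuclei in G2 when `intensity_mode = "g1g2"`.
#' @param intensity_per_area mean total intensity contributed per px^2 of
#'   nucleus area.
#' @param intensity_sigma log-normal sd of cell-to-cell intensity variation.
#' @param tile_jitter_px maximum absolute integer stage misalignment
#'   injected per tile (0 = perfectly placed tiles).
#' @param clone_spacing_px minimum distance between clone centers; default
#'   `5 * clone_dispersion_px + 2 * nucleus_axes_px[1]`.
#' @param nucleus_min_sep_px hard-core minimum distance between member
#'   nucleus centers (cells in a monolayer exclude each other; nuclei may
#'   touch but not stack). Defaults to the minor axis. The Gaussian scatter
#'   sd expands beyond `clone_dispersion_px` when a large clone cannot
#'   pack at the nominal spread.
#' @param seed integer RNG seed; the same parameter set (including seed)
#'   reproduces bit-identical tiles and ground truth.
#' @return an object of class `sim_params`.
#' @export
sim_params <- function(seeded_cells_per_well = 200,
                       survival_prob = 1,
                       cells_per_clone_law = list(median = 30, sigma = 0.45),
                       clone_dispersion_px = 15,
                       nucleus_axes_px = c(12, 9),
                       color_mix = rep(1 / 6, 6),
                       fragment_rate = 0.02,
                       tile_grid = c(2, 2),
                       tile_size_px = c(1200, 1200),
                       overlap_frac = 0.10,
                       illumination = 0.25,
                       noise = list(gaussian_sd = 2, poisson_gain = 0.05),
                       background_level = 200,
                       arm = c("lego", "classical"),
                       intensity_mode = c("g1", "g1g2"),
                       g2_frac = 1 / 3,
                       intensity_per_area = 120,
                       intensity_sigma = 0.15,
                       tile_jitter_px = 0,
                       clone_spacing_px = NULL,
                       nucleus_min_sep_px = NULL,
                       seed = 1) {
  arm <- match.arg(arm)
  intensity_mode <- match.arg(intensity_mode)
  color_mix <- as.numeric(color_mix)
  if (length(color_mix) != 6 || any(color_mix < 0) || any(color_mix > 1) ||
      abs(sum(color_mix) - 1) > 1e-9)
    stopf("color_mix must be 6 fractions in [0,1] summing to 1")
  if (survival_prob < 0 || survival_prob > 1)
    stopf("survival_prob must be in [0,1]")
  if (fragment_rate < 0 || fragment_rate > 1)
    stopf("fragment_rate must be in [0,1]")
  if (overlap_frac <= 0 || overlap_frac >= 0.5)
    stopf("overlap_frac must be in (0, 0.5)")
  if (any(tile_size_px <= 0) || any(tile_grid < 1))
    stopf("tile dimensions and grid must be positive")
  if (illumination < 0 || illumination >= 1)
    stopf("illumination amplitude must be in [0, 1)")
  if (is.null(clone_spacing_px))
    clone_spacing_px <- 5 * clone_dispersion_px + 2 * nucleus_axes_px[1]
  if (is.null(nucleus_min_sep_px)) nucleus_min_sep_px <- nucleus_axes_px[2]
  p <- list(seeded_cells_per_well = as.integer(seeded_cells_per_well),
            survival_prob = survival_prob,
            cells_per_clone_law = cells_per_clone_law,
            clone_dispersion_px = clone_dispersion_px,
            nucleus_axes_px = nucleus_axes_px,
            color_mix = stats::setNames(color_mix, lego_classes()),
            fragment_rate = fragment_rate,
            tile_grid = as.integer(tile_grid),
            tile_size_px = as.integer(tile_size_px),
            overlap_frac = overlap_frac,
            illumination = illumination,
            noise = noise,
            background_level = background_level,
            arm = arm,
            intensity_mode = intensity_mode,
            g2_frac = g2_frac,
            intensity_per_area = intensity_per_area,
            intensity_sigma = intensity_sigma,
            tile_jitter_px = as.integer(tile_jitter_px),
            clone_spacing_px = clone_spacing_px,
            nucleus_min_sep_px = nucleus_min_sep_px,
            seed = as.integer(seed))
  # impossible geometry: a clone or nucleus must fit inside one tile
  if (6 * clone_dispersion_px + 2 * nucleus_axes_px[1] > min(tile_size_px))
    stopf("clone dispersion / nucleus size exceed the tile size")
  class(p) <- "sim_params"
  p
}

lego_classes <- function() c("R", "G", "B", "RG", "RB", "GB")

# channels lit by each color class
class_channels <- function(cls) {
  switch(cls,
         R = "r", G = "g", B = "b",
         RG = c("r", "g"), RB = c("r", "b"), GB = c("g", "b"),
         character())
}

# nominal stitched canvas size and 0-based tile origins for a grid
nominal_layout <- function(tile_grid, tile_size_px, overlap_frac) {
  step_y <- round(tile_size_px[1] * (1 - overlap_frac))
  step_x <- round(tile_size_px[2] * (1 - overlap_frac))
  oy <- (seq_len(tile_grid[1]) - 1L) * step_y
  ox <- (seq_len(tile_grid[2]) - 1L) * step_x
  list(origin_y = oy, origin_x = ox,
       height = oy[length(oy)] + tile_size_px[1],
       width = ox[length(ox)] + tile_size_px[2])
}

# random sequential placement with a hard-core minimum spacing
place_clone_centers <- function(n, width, height, margin, min_spacing,
                                max_iter = 200L) {
  if (n == 0) return(cbind(x = numeric(), y = numeric()))
  xs <- numeric(n); ys <- numeric(n); placed <- 0L
  tries <- 0L
  while (placed < n) {
    m <- (n - placed) * 4L
    cx <- runif(m, margin, width - 1 - margin)
    cy <- runif(m, margin, height - 1 - margin)
    for (i in seq_len(m)) {
      if (placed >= n) break
      if (placed == 0L ||
          min((xs[seq_len(placed)] - cx[i])^2 +
              (ys[seq_len(placed)] - cy[i])^2) >= min_spacing^2) {
        placed <- placed + 1L
        xs[placed] <- cx[i]; ys[placed] <- cy[i]
      }
    }
    tries <- tries + 1L
    if (tries > max_iter)
      stopf("could not place %d clone centers at spacing %.0f px: well too dense",
            n, min_spacing)
  }
  cbind(x = xs, y = ys)
}

# Gaussian scatter with a hard-core exclusion between nucleus centers:
# cells in a monolayer cannot stack, so member nuclei may touch but not
# overlap deeply. The radial scatter is truncated at 2.25 sigma — a colony
# is a contiguous patch of adherent cells, not a cloud with detached
# stragglers. If a clone cannot pack n cells at the nominal spread the
# sd expands by 20% per round (clones spread as they grow).
scatter_hardcore <- function(n, cx, cy, sigma, min_sep, trunc = 2.25) {
  xs <- numeric(n); ys <- numeric(n)
  placed <- 0L
  s <- sigma
  while (placed < n) {
    m <- (n - placed) * 6L
    px <- rnorm(m, 0, s)
    py <- rnorm(m, 0, s)
    keep <- px^2 + py^2 <= (trunc * s)^2
    px <- cx + px[keep]; py <- cy + py[keep]
    for (i in seq_along(px)) {
      if (placed >= n) break
      if (placed == 0L ||
          min((xs[seq_len(placed)] - px[i])^2 +
              (ys[seq_len(placed)] - py[i])^2) >= min_sep^2) {
        placed <- placed + 1L
        xs[placed] <- px[i]; ys[placed] <- py[i]
      }
    }
    s <- s * 1.2
  }
  cbind(xs, ys)
}

# analytic shape descriptors of an ellipse with full axes (M, m):
# roundness = 4A / (pi M^2) = m/M; circularity = 4 pi A / P^2 with
# Ramanujan's perimeter approximation
ellipse_descriptors <- function(major, minor) {
  a <- major / 2; b <- minor / 2
  area <- pi * a * b
  h <- ((a - b) / (a + b))^2
  per <- pi * (a + b) * (1 + 3 * h / (10 + sqrt(4 - 3 * h)))
  list(area = area, roundness = minor / major,
       circularity = 4 * pi * area / per^2)
}

#' Replace a fraction of nuclei by small fragments
#'
#' Emulates micronuclei, DNA fragments and debris: each selected nucleus is
#' replaced by 2-4 fragments scattered around the parent position, each with
#' area below half the median nucleus area and total intensity reduced in
#' proportion to the area it takes from the parent.
#'
#' @param nuclei ground-truth nucleus table (as built by [generate_well()]).
#' @param fragment_rate fraction of nuclei to fragment, in \[0,1\].
#' @return the nucleus table with selected rows replaced by fragment rows
#'   (`is_fragment = TRUE`).
#' @export
plant_fragments <- function(nuclei, fragment_rate) {
  stopifnot(fragment_rate >= 0, fragment_rate <= 1)
  n <- nrow(nuclei)
  if (fragment_rate == 0 || n == 0) return(nuclei)
  med_area <- median(nuclei$area)
  n_frag <- round(fragment_rate * n)
  if (n_frag == 0) return(nuclei)
  idx <- sample.int(n, n_frag)
  keep <- nuclei[-idx, , drop = FALSE]
  pieces <- list(keep)
  for (i in idx) {
    parent <- nuclei[i, ]
    k <- sample(2:4, 1)
    # fragment areas: small slivers of the parent, capped below half the
    # median nucleus area as micronuclei are by definition small, but kept
    # above the detectable minimum (real micronuclei are 2-5 um across)
    af <- pmin(parent$area * runif(k, 0.12, 0.30), 0.45 * med_area)
    d <- 2 * sqrt(af / pi)  # circular fragments
    frag <- parent[rep(1L, k), ]
    # scatter around the vanished parent, keeping clear of other nuclei
    # and of sibling fragments so fragments stay individually resolvable
    ox <- keep$x; oy <- keep$y
    fx <- numeric(k); fy <- numeric(k)
    for (j in seq_len(k)) {
      best_d <- -Inf
      for (try in 1:40) {
        cx <- parent$x + rnorm(1, 0, parent$major_px)
        cy <- parent$y + rnorm(1, 0, parent$major_px)
        d_other <- if (length(ox)) sqrt(min((ox - cx)^2 + (oy - cy)^2)) else Inf
        d_sib <- if (j > 1)
          sqrt(min((fx[seq_len(j - 1)] - cx)^2 + (fy[seq_len(j - 1)] - cy)^2))
        else Inf
        dmin <- min(d_other - parent$major_px * 0.75, d_sib - max(d) - 1)
        if (dmin > best_d) { best_d <- dmin; fx[j] <- cx; fy[j] <- cy }
        if (dmin > 0) break
      }
    }
    frag$x <- fx
    frag$y <- fy
    frag$area <- af
    frag$major_px <- d
    frag$minor_px <- d
    frag$theta <- 0
    frag$roundness <- 1
    frag$circularity <- 1
    sc <- af / parent$area
    for (ch in grep("^total_", names(nuclei), value = TRUE))
      frag[[ch]] <- parent[[ch]] * sc
    frag$is_fragment <- TRUE
    pieces[[length(pieces) + 1L]] <- frag
  }
  out <- do.call(rbind, pieces)
  rownames(out) <- NULL
  out$nucleus_id <- seq_len(nrow(out))
  out
}

#' Apply a radial illumination gradient to a tile
#'
#' Multiplies the tile by a smooth vignette equal to 1 at the tile center
#' and `1 - amplitude` at the corners, falling off quadratically with
#' radius — the background gradient one sees in wide-field fluorescence
#' tiles, with values decreasing toward the edges of each image.
#'
#' @param tile numeric matrix.
#' @param amplitude vignette amplitude in \[0, 1).
#' @return the vignetted tile.
#' @export
render_illumination <- function(tile, amplitude) {
  stopifnot(amplitude >= 0, amplitude < 1)
  if (amplitude == 0) return(tile)
  tile * illumination_field(nrow(tile), ncol(tile), amplitude)
}

illumination_field <- function(nr, nc, amplitude) {
  cy <- (nr + 1) / 2; cx <- (nc + 1) / 2
  r2max <- (nr - cy)^2 + (nc - cx)^2
  yy <- (seq_len(nr) - cy)^2
  xx <- (seq_len(nc) - cx)^2
  1 - amplitude * outer(yy, xx, "+") / r2max
}

# render one nucleus into a canvas (in place via returned patch):
# super-Gaussian elliptical profile, half-max at the ellipse boundary, so
# the thresholded footprint closely matches the analytic ellipse area
render_nucleus_patch <- function(x, y, major, minor, theta, total) {
  a <- major / 2; b <- minor / 2
  w <- ceiling(1.8 * a)
  xs <- (round(x) - w):(round(x) + w)
  ys <- (round(y) - w):(round(y) + w)
  dx <- outer(rep(1, length(ys)), xs - x)
  dy <- outer(ys - y, rep(1, length(xs)))
  u <- (dx * cos(theta) + dy * sin(theta)) / a
  v <- (-dx * sin(theta) + dy * cos(theta)) / b
  q2 <- u^2 + v^2
  # steep super-Gaussian: half-max at the ellipse boundary with a sharp
  # skirt, so the thresholded footprint and the measured total intensity
  # are insensitive to the exact threshold (nuclei have sharp edges)
  prof <- exp(-log(2) * q2^4)
  prof[q2 > 1.8] <- 0  # < 0.2% of peak beyond 1.34x the ellipse
  s <- sum(prof)
  list(rows = ys + 1L, cols = xs + 1L, patch = prof * (total / s))
}

#' Generate one synthetic well with exhaustive ground truth
#'
#' Simulates seeding, clonal survival and growth, renders every surviving
#' nucleus into a stitched "clean" canvas, then cuts overlapping tiles,
#' applies the per-tile illumination gradient and Poisson-Gaussian noise,
#' and quantizes to 16-bit. Because tiles are cut from one shared canvas,
#' overlap strips of neighboring tiles are pixel-identical before the
#' per-tile illumination and noise are applied.
#'
#' @param params a [sim_params()] object.
#' @return a list with elements
#'   \describe{
#'     \item{scan}{a [tile_scan()] of the well,}
#'     \item{truth}{ground truth: `nuclei` and `clones` tables,
#'       `seeded_cells`, `surviving_clones`, per-tile injected shifts
#'       `tile_shifts`, and the clean background descriptors.}
#'   }
#' @export
generate_well <- function(params) {
  stopifnot(inherits(params, "sim_params"))
  with_seed(params$seed, generate_well_impl(params))
}

generate_well_impl <- function(p) {
  lay <- nominal_layout(p$tile_grid, p$tile_size_px, p$overlap_frac)
  H <- lay$height; W <- lay$width
  channels <- if (p$arm == "lego") c("r", "g", "b") else "dna"

  n_surv <- rbinom(1, p$seeded_cells_per_well, p$survival_prob)
  margin <- 3 * p$clone_dispersion_px + p$nucleus_axes_px[1] +
    p$tile_jitter_px + 2
  centers <- place_clone_centers(n_surv, W, H, margin, p$clone_spacing_px)
  cls <- if (p$arm == "lego" && n_surv > 0)
    sample(lego_classes(), n_surv, replace = TRUE, prob = p$color_mix)
  else rep("UNSET", n_surv)

  meanlog <- log(p$cells_per_clone_law$median)
  n_cells <- if (n_surv > 0)
    pmax(1L, round(rlnorm(n_surv, meanlog, p$cells_per_clone_law$sigma)))
  else integer()

  nuclei <- NULL
  if (n_surv > 0) {
    ids <- rep(seq_len(n_surv), n_cells)
    total_n <- sum(n_cells)
    x <- numeric(total_n); y <- numeric(total_n)
    pos <- 0L
    for (ci in seq_len(n_surv)) {
      pts <- scatter_hardcore(n_cells[ci], centers[ci, "x"], centers[ci, "y"],
                              p$clone_dispersion_px, p$nucleus_min_sep_px)
      ix <- pos + seq_len(n_cells[ci])
      x[ix] <- pts[, 1]; y[ix] <- pts[, 2]
      pos <- pos + n_cells[ci]
    }
    x <- pmin(pmax(x, margin / 2), W - 1 - margin / 2)
    y <- pmin(pmax(y, margin / 2), H - 1 - margin / 2)
    desc <- ellipse_descriptors(p$nucleus_axes_px[1], p$nucleus_axes_px[2])
    is_g2 <- if (p$intensity_mode == "g1g2")
      runif(total_n) < p$g2_frac else rep(FALSE, total_n)
    total <- p$intensity_per_area * desc$area *
      rlnorm(total_n, 0, p$intensity_sigma) * ifelse(is_g2, 2, 1)
    nuclei <- data.frame(nucleus_id = seq_len(total_n), clone_id = ids,
                         x = x, y = y, area = desc$area,
                         major_px = p$nucleus_axes_px[1],
                         minor_px = p$nucleus_axes_px[2],
                         theta = runif(total_n, 0, pi),
                         roundness = desc$roundness,
                         circularity = desc$circularity,
                         color_class = cls[ids], is_g2 = is_g2,
                         is_fragment = FALSE)
    for (ch in channels) nuclei[[paste0("total_", ch)]] <- 0
    for (i in seq_len(total_n)) {
      on <- if (p$arm == "lego") class_channels(cls[ids[i]]) else "dna"
      for (ch in on) nuclei[[paste0("total_", ch)]][i] <- total[i]
    }
    nuclei <- plant_fragments(nuclei, p$fragment_rate)
  } else {
    nuclei <- data.frame(nucleus_id = integer(), clone_id = integer(),
                         x = numeric(), y = numeric(), area = numeric(),
                         major_px = numeric(), minor_px = numeric(),
                         theta = numeric(), roundness = numeric(),
                         circularity = numeric(),
                         color_class = character(), is_g2 = logical(),
                         is_fragment = logical())
    for (ch in channels) nuclei[[paste0("total_", ch)]] <- numeric()
  }

  # Clean stitched canvas per channel. Nuclei are blended with pmax, not
  # summed: cells in a monolayer exclude each other, so where footprints
  # abut the image shows two distinct tops with a dimmer boundary — never
  # a bright ridge brighter than either nucleus.
  canvas <- lapply(channels, function(ch) {
    m <- matrix(0, H, W)
    tot <- nuclei[[paste0("total_", ch)]]
    for (i in seq_len(nrow(nuclei))) {
      if (tot[i] <= 0) next
      pt <- render_nucleus_patch(nuclei$x[i], nuclei$y[i], nuclei$major_px[i],
                                 nuclei$minor_px[i], nuclei$theta[i], tot[i])
      rr <- pt$rows >= 1L & pt$rows <= H
      cc <- pt$cols >= 1L & pt$cols <= W
      m[pt$rows[rr], pt$cols[cc]] <-
        pmax(m[pt$rows[rr], pt$cols[cc]], pt$patch[rr, cc])
    }
    m + p$background_level
  })
  names(canvas) <- channels

  # cut tiles (with optional stage jitter), vignette, add noise, quantize
  jit <- p$tile_jitter_px
  shifts <- expand.grid(row = seq_len(p$tile_grid[1]),
                        col = seq_len(p$tile_grid[2]))
  shifts$dy <- if (jit > 0) sample(-jit:jit, nrow(shifts), TRUE) else 0L
  shifts$dx <- if (jit > 0) sample(-jit:jit, nrow(shifts), TRUE) else 0L
  shifts$dy[shifts$row == 1 & shifts$col == 1] <- 0L  # reference tile
  shifts$dx[shifts$row == 1 & shifts$col == 1] <- 0L
  th <- p$tile_size_px[1]; tw <- p$tile_size_px[2]
  tiles <- vector("list", p$tile_grid[1])
  for (r in seq_len(p$tile_grid[1])) {
    tiles[[r]] <- vector("list", p$tile_grid[2])
    for (c in seq_len(p$tile_grid[2])) {
      si <- which(shifts$row == r & shifts$col == c)
      y0 <- lay$origin_y[r] + shifts$dy[si]
      x0 <- lay$origin_x[c] + shifts$dx[si]
      # edge tiles cannot be cut outside the canvas; record the effective
      # (possibly clamped) jitter so ground truth matches the pixels
      y0 <- min(max(y0, 0L), H - th); x0 <- min(max(x0, 0L), W - tw)
      shifts$dy[si] <- y0 - lay$origin_y[r]
      shifts$dx[si] <- x0 - lay$origin_x[c]
      tl <- list()
      for (ch in channels) {
        t1 <- canvas[[ch]][y0 + seq_len(th), x0 + seq_len(tw)]
        t1 <- render_illumination(t1, p$illumination)
        t1 <- add_camera_noise(t1, p$noise)
        tl[[ch]] <- t1
      }
      tiles[[r]][[c]] <- tl
    }
  }

  clones <- if (n_surv > 0)
    data.frame(clone_id = seq_len(n_surv), x = centers[, "x"],
               y = centers[, "y"], color_class = cls, n_cells = n_cells)
  else data.frame(clone_id = integer(), x = numeric(), y = numeric(),
                  color_class = character(), n_cells = integer())

  list(scan = tile_scan(tiles, overlap_frac = p$overlap_frac,
                        channel_names = channels),
       truth = list(nuclei = nuclei, clones = clones,
                    seeded_cells = p$seeded_cells_per_well,
                    surviving_clones = n_surv,
                    tile_shifts = shifts,
                    background_level = p$background_level,
                    illumination = p$illumination,
                    noise = p$noise,
                    params = p))
}

# Poisson shot noise (gain = intensity units per count) plus Gaussian read
# noise, quantized to 16-bit unsigned; gain 0 and sd 0 leave the tile
# noise-free but still quantized
add_camera_noise <- function(tile, noise) {
  g <- noise$poisson_gain %||% 0
  s <- noise$gaussian_sd %||% 0
  out <- tile
  if (g > 0) out <- matrix(rpois(length(tile), tile / g) * g,
                           nrow(tile), ncol(tile))
  if (s > 0) out <- out + rnorm(length(out), 0, s)
  matrix(pmin(pmax(round(out), 0), 65535), nrow(tile), ncol(tile))
}

#' Simulate labeled color-classification training data
#'
#' Feature-level generator for the barcode classifier: draws per-channel
#' total intensities for the six LeGO classes with a configurable level of
#' channel crosstalk, and (optionally) small dim TRASH objects, then builds
#' the standard color feature matrix.
#'
#' @param n_per_class objects per class.
#' @param crosstalk fraction of each lit channel's intensity leaking into
#'   each unlit channel (e.g. 0.05 for 5 percent).
#' @param classes classes to generate; default the six LeGO colors.
#' @param trash_n additional TRASH objects (small, dim, irregular).
#' @param seed RNG seed.
#' @return a list with `features` (matrix), `class` (factor) and the raw
#'   `records` table.
#' @export
simulate_color_training <- function(n_per_class = 200, crosstalk = 0.05,
                                    classes = lego_classes(), trash_n = 0,
                                    seed = 1) {
  with_seed(seed, {
    recs <- list()
    for (cl in classes) {
      on <- class_channels(cl)
      tot <- rlnorm(n_per_class, log(2500), 0.3)
      area <- rlnorm(n_per_class, log(85), 0.2)
      d <- data.frame(area = area, circularity = runif(n_per_class, 0.85, 1),
                      total_r = 0, total_g = 0, total_b = 0,
                      class = cl, stringsAsFactors = FALSE)
      for (ch in c("r", "g", "b")) {
        col <- paste0("total_", ch)
        if (ch %in% on) d[[col]] <- tot * (1 + rnorm(n_per_class, 0, 0.05))
        else d[[col]] <- tot * crosstalk * abs(1 + rnorm(n_per_class, 0, 0.3))
      }
      recs[[cl]] <- d
    }
    if (trash_n > 0) {
      d <- data.frame(area = rlnorm(trash_n, log(12), 0.4),
                      circularity = runif(trash_n, 0.3, 0.9),
                      total_r = rlnorm(trash_n, log(150), 0.8),
                      total_g = rlnorm(trash_n, log(150), 0.8),
                      total_b = rlnorm(trash_n, log(150), 0.8),
                      class = "TRASH", stringsAsFactors = FALSE)
      recs$TRASH <- d
    }
    records <- do.call(rbind, recs)
    rownames(records) <- NULL
    feats <- extract_color_features(records)
    list(features = feats, class = factor(records$class),
         records = records)
  })
}
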