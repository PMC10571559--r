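#' Tile scan container
#'
#' A rectangular, complete grid of overlapping image tiles with nominal
#' placement. Tiles are stored as `tiles[[row]][[col]][[channel]]` numeric
#' matrices; nominal origins (0-based stitched-pixel offsets, x right /
#' y down, origin at the top-left of tile (1,1)) are derived from the tile
#' size and overlap fraction.
#'
#' @param tiles nested list `[[row]][[col]][[channel]]` of numeric matrices,
#'   all the same size.
#' @param overlap_frac fractional overlap between neighboring tiles.
#' @param channel_names channel names; defaults to the names found on the
#'   first tile.
#' @return an object of class `tile_scan`.
#' @export
tile_scan <- function(tiles, overlap_frac = 0.10, channel_names = NULL) {
  if (overlap_frac <= 0 || overlap_frac >= 0.5)
    stopf("overlap_frac must be in (0, 0.5)")
  nrows <- length(tiles)
  ncols <- length(tiles[[1]])
  for (r in seq_len(nrows)) {
    if (length(tiles[[r]]) != ncols)
      stopf("tile grid is not rectangular (row %d has %d tiles, expected %d)",
            r, length(tiles[[r]]), ncols)
    for (c in seq_len(ncols))
      if (is.null(tiles[[r]][[c]]) || !length(tiles[[r]][[c]]))
        stopf("missing tile at grid position (%d, %d)", r, c)
  }
  if (is.null(channel_names)) channel_names <- names(tiles[[1]][[1]])
  ts <- dim(tiles[[1]][[1]][[1]])
  for (r in seq_len(nrows)) for (c in seq_len(ncols)) {
    for (ch in channel_names) {
      m <- tiles[[r]][[c]][[ch]]
      if (is.null(m)) stopf("tile (%d, %d) lacks channel '%s'", r, c, ch)
      if (!identical(dim(m), ts))
        stopf("tile (%d, %d) channel '%s' has wrong size", r, c, ch)
    }
  }
  lay <- nominal_layout(c(nrows, ncols), ts, overlap_frac)
  structure(list(tiles = tiles, grid = c(nrows, ncols), tile_size = ts,
                 overlap_frac = overlap_frac, channel_names = channel_names,
                 origin_y = lay$origin_y, origin_x = lay$origin_x,
                 height = lay$height, width = lay$width),
            class = "tile_scan")
}

#' @export
print.tile_scan <- function(x, ...) {
  cat(sprintf("<tile_scan> %d x %d tiles of %d x %d px, %.0f%% overlap, channels: %s\n",
              x$grid[1], x$grid[2], x$tile_size[1], x$tile_size[2],
              100 * x$overlap_frac, paste(x$channel_names, collapse = ", ")))
  invisible(x)
}

# sum of channels of one tile (signal image used for locating/aligning)
tile_signal <- function(scan, r, c) {
  Reduce(`+`, scan$tiles[[r]][[c]][scan$channel_names])
}

#' Low-resolution mosaic of a tile scan
#'
#' Places tiles at their nominal origins without any alignment and
#' downsamples the result. Clones are located on this quick mosaic first;
#' only tiles that contain clone signal are then stitched with proper
#' alignment. Overlap regions take the per-pixel maximum so misaligned
#' copies of an object cannot cancel.
#'
#' @param scan a [tile_scan()].
#' @param downsample integer block size for the downsampling (default 4).
#' @param channel channel to mosaic; default the sum of all channels.
#' @return a numeric matrix of the downsampled mosaic.
#' @export
rough_mosaic <- function(scan, downsample = 4L, channel = NULL) {
  stopifnot(inherits(scan, "tile_scan"))
  canvas <- matrix(-Inf, scan$height, scan$width)
  for (r in seq_len(scan$grid[1])) {
    for (c in seq_len(scan$grid[2])) {
      img <- if (is.null(channel)) tile_signal(scan, r, c)
             else scan$tiles[[r]][[c]][[channel]]
      ys <- scan$origin_y[r] + seq_len(scan$tile_size[1])
      xs <- scan$origin_x[c] + seq_len(scan$tile_size[2])
      canvas[ys, xs] <- pmax(canvas[ys, xs], img)
    }
  }
  downsample_mean(canvas, as.integer(downsample))
}

# block-mean downsampling, truncating partial blocks
downsample_mean <- function(img, f) {
  if (f <= 1L) return(img)
  nr <- (nrow(img) %/% f) * f
  nc <- (ncol(img) %/% f) * f
  img <- img[seq_len(nr), seq_len(nc)]
  a <- array(img, c(f, nr %/% f, nc))
  m <- colMeans(a)                       # (nr/f) x nc
  a2 <- array(t(m), c(f, nc %/% f, nr %/% f))
  t(colMeans(a2))
}

#' Find tiles containing clone signal
#'
#' Thresholds the low-resolution mosaic (Otsu) and returns every tile whose
#' area intersects a connected foreground component. Tiles without signal
#' are skipped by offset refinement and keep their nominal placement.
#'
#' @param mosaic output of [rough_mosaic()].
#' @param scan the [tile_scan()] the mosaic came from.
#' @param downsample the downsample factor used for the mosaic.
#' @param min_px minimum component size (mosaic px) to count as signal.
#' @return a two-column matrix (`row`, `col`) of tile grid positions; zero
#'   rows for a blank well.
#' @export
locate_clone_tiles <- function(mosaic, scan, downsample = 4L, min_px = 4L) {
  stopifnot(inherits(scan, "tile_scan"))
  thr <- otsu_threshold(mosaic)
  mask <- mosaic > thr
  # a blank vignetted well would otherwise split along its own background
  # gradient: require the foreground to stand clear of background noise
  if (any(mask) && !all(mask)) {
    bg_sd <- stats::sd(mosaic[!mask])
    if (!is.finite(bg_sd) || bg_sd == 0) bg_sd <- 1e-9
    if ((mean(mosaic[mask]) - mean(mosaic[!mask])) / bg_sd < 4) mask[] <- FALSE
  }
  lab <- cpp_label(mask, 8L)
  n <- attr(lab, "n_labels")
  hits <- matrix(integer(), 0, 2, dimnames = list(NULL, c("row", "col")))
  if (n == 0) return(hits)
  sizes <- tabulate(lab[lab > 0], n)
  keep <- which(sizes >= min_px)
  if (!length(keep)) return(hits)
  idx <- which(lab %in% keep)
  ys <- ((idx - 1) %% nrow(mosaic)) * downsample      # 0-based stitched y
  xs <- ((idx - 1) %/% nrow(mosaic)) * downsample
  out <- matrix(integer(), 0, 2)
  for (r in seq_len(scan$grid[1])) {
    for (c in seq_len(scan$grid[2])) {
      y0 <- scan$origin_y[r]; x0 <- scan$origin_x[c]
      inside <- ys >= y0 & ys < y0 + scan$tile_size[1] &
                xs >= x0 & xs < x0 + scan$tile_size[2]
      if (any(inside)) out <- rbind(out, c(r, c))
    }
  }
  colnames(out) <- c("row", "col")
  out
}

# Otsu's threshold on a numeric image (256-bin histogram)
otsu_threshold <- function(img, nbins = 256L) {
  v <- as.numeric(img)
  rng <- range(v)
  if (diff(rng) == 0) return(rng[1])
  br <- seq(rng[1], rng[2], length.out = nbins + 1L)
  h <- tabulate(findInterval(v, br, rightmost.closed = TRUE), nbins)
  p <- h / sum(h)
  mids <- (br[-1] + br[-length(br)]) / 2
  w1 <- cumsum(p)
  mu <- cumsum(p * mids)
  mu_t <- mu[nbins]
  w2 <- 1 - w1
  ok <- w1 > 0 & w2 > 0
  sb <- (mu_t * w1 - mu)^2 / (w1 * w2)
  sb[!ok] <- -Inf
  mids[which.max(sb)]
}

#' Refine tile offsets using signal in overlap strips
#'
#' For each adjacent pair of clone-bearing tiles, estimates the integer
#' shift maximizing the normalized cross-correlation of the shared overlap
#' strip (search window `±max_shift` px), then propagates shifts from the
#' reference tile (1,1) through a spanning tree of aligned pairs. Tiles
#' without clone signal, and pairs whose overlap strip has (near) zero
#' variance, keep nominal offsets.
#'
#' @param scan a [tile_scan()].
#' @param clone_tiles matrix from [locate_clone_tiles()]; `NULL` aligns all
#'   tiles.
#' @param max_shift maximum absolute shift searched, px (default 20).
#' @return a data frame with one row per tile: `row`, `col`, `oy`, `ox`
#'   (refined 0-based origins), `refined` flag; the number of skipped
#'   degenerate pairs is attached as attribute `n_skipped`.
#' @export
refine_offsets <- function(scan, clone_tiles = NULL, max_shift = 20L) {
  stopifnot(inherits(scan, "tile_scan"))
  nrows <- scan$grid[1]; ncols <- scan$grid[2]
  if (is.null(clone_tiles))
    clone_tiles <- as.matrix(expand.grid(row = seq_len(nrows),
                                         col = seq_len(ncols)))
  in_set <- matrix(FALSE, nrows, ncols)
  if (nrow(clone_tiles)) in_set[clone_tiles] <- TRUE

  off <- expand.grid(row = seq_len(nrows), col = seq_len(ncols))
  off$oy <- scan$origin_y[off$row]
  off$ox <- scan$origin_x[off$col]
  off$refined <- FALSE
  n_skipped <- 0L

  ov_y <- scan$tile_size[1] - round(scan$tile_size[1] * (1 - scan$overlap_frac))
  ov_x <- scan$tile_size[2] - round(scan$tile_size[2] * (1 - scan$overlap_frac))
  step_y <- scan$tile_size[1] - ov_y
  step_x <- scan$tile_size[2] - ov_x

  # Pairwise shift between adjacent in-set tiles: NCC of the full tiles
  # over the nominal relative offset +/- 2*max_shift (each tile may be off
  # by max_shift, so the pair can be off by twice that). Pairs whose
  # nominal overlap band holds no signal above background are skipped.
  edges <- list()
  pair_shift <- function(ra, ca, rb, cb, horiz) {
    a <- tile_signal(scan, ra, ca); b <- tile_signal(scan, rb, cb)
    m <- 2L * max_shift
    band_a <- if (horiz) a[, (ncol(a) - ov_x + 1):ncol(a), drop = FALSE]
              else a[(nrow(a) - ov_y + 1):nrow(a), , drop = FALSE]
    band_b <- if (horiz) b[, 1:ov_x, drop = FALSE] else b[1:ov_y, , drop = FALSE]
    if (sd(band_a) < 1e-9 || sd(band_b) < 1e-9) return(NULL)
    thr <- median(band_a) + 6 * stats::mad(band_a) + 1e-9
    if (!any(band_a > thr) || !any(band_b > thr)) return(NULL)
    res <- if (horiz)
      pyramid_shift_range(a, b, -m, m, step_x - m, step_x + m)
    else
      pyramid_shift_range(a, b, step_y - m, step_y + m, -m, m)
    if (res[3] < -1) return(NULL)
    if (horiz) c(dy = res[1], dx = res[2] - step_x, ncc = res[3])
    else c(dy = res[1] - step_y, dx = res[2], ncc = res[3])
  }
  for (r in seq_len(nrows)) for (c in seq_len(ncols)) {
    if (!in_set[r, c]) next
    if (c < ncols && in_set[r, c + 1]) {
      s <- pair_shift(r, c, r, c + 1, TRUE)
      if (is.null(s)) n_skipped <- n_skipped + 1L
      else edges[[length(edges) + 1L]] <-
          list(from = c(r, c), to = c(r, c + 1), dy = s["dy"], dx = s["dx"],
               w = s["ncc"])
    }
    if (r < nrows && in_set[r + 1, c]) {
      s <- pair_shift(r, c, r + 1, c, FALSE)
      if (is.null(s)) n_skipped <- n_skipped + 1L
      else edges[[length(edges) + 1L]] <-
          list(from = c(r, c), to = c(r + 1, c), dy = s["dy"], dx = s["dx"],
               w = s["ncc"])
    }
  }

  # propagate through a BFS spanning tree rooted at the first in-set tile
  # (reading order); relative shift of `to` w.r.t. `from` is (dy, dx)
  if (length(edges)) {
    key <- function(rc) paste(rc[1], rc[2])
    adj <- list()
    for (i in seq_along(edges)) {
      e <- edges[[i]]
      adj[[key(e$from)]] <- c(adj[[key(e$from)]], i)
      adj[[key(e$to)]] <- c(adj[[key(e$to)]], i)
    }
    roots <- which(in_set, arr.ind = TRUE)
    roots <- roots[order(roots[, 1], roots[, 2]), , drop = FALSE]
    visited <- character()
    shift <- list()
    for (ri in seq_len(nrow(roots))) {
      root <- roots[ri, ]
      if (key(root) %in% visited) next
      shift[[key(root)]] <- c(0, 0)
      visited <- c(visited, key(root))
      queue <- list(root)
      while (length(queue)) {
        cur <- queue[[1]]; queue <- queue[-1]
        for (i in adj[[key(cur)]] %||% integer()) {
          e <- edges[[i]]
          fwd <- key(e$from) == key(cur)
          other <- if (fwd) e$to else e$from
          if (key(other) %in% visited) next
          sgn <- if (fwd) 1 else -1
          shift[[key(other)]] <- shift[[key(cur)]] + sgn * c(e$dy, e$dx)
          visited <- c(visited, key(other))
          queue[[length(queue) + 1L]] <- other
        }
      }
    }
    for (k in names(shift)) {
      rc <- as.integer(strsplit(k, " ")[[1]])
      i <- which(off$row == rc[1] & off$col == rc[2])
      off$oy[i] <- off$oy[i] + shift[[k]][1]
      off$ox[i] <- off$ox[i] + shift[[k]][2]
      off$refined[i] <- TRUE
    }
  }
  if (n_skipped > 0)
    warnf("%d overlap strip(s) had no usable signal; nominal offsets kept",
          n_skipped)
  attr(off, "n_skipped") <- n_skipped
  off
}

# Coarse-to-fine integer-shift search over an arbitrary (dy, dx) window:
# exhaustive NCC at 4x downsampling, then a full-resolution local
# refinement around the coarse peak. Exact for integer shifts (the fine
# window is wider than the coarse quantization); a fine pass over the full
# window is used when the window is small or the tiles are tiny.
pyramid_shift_range <- function(ref, mov, dy_lo, dy_hi, dx_lo, dx_hi,
                                factor = 4L, min_frac = 0.02) {
  dy_lo <- as.integer(dy_lo); dy_hi <- as.integer(dy_hi)
  dx_lo <- as.integer(dx_lo); dx_hi <- as.integer(dx_hi)
  if (max(dy_hi - dy_lo, dx_hi - dx_lo) <= 12L || min(dim(ref)) < 8L * factor)
    return(cpp_best_shift_range(ref, mov, dy_lo, dy_hi, dx_lo, dx_hi, min_frac))
  cref <- downsample_mean(ref, factor)
  cmov <- downsample_mean(mov, factor)
  coarse <- cpp_best_shift_range(
    cref, cmov,
    as.integer(floor(dy_lo / factor)), as.integer(ceiling(dy_hi / factor)),
    as.integer(floor(dx_lo / factor)), as.integer(ceiling(dx_hi / factor)),
    min_frac)
  if (coarse[3] < -1)
    return(cpp_best_shift_range(ref, mov, dy_lo, dy_hi, dx_lo, dx_hi, min_frac))
  r <- 2L * factor
  dy0 <- as.integer(coarse[1]) * factor
  dx0 <- as.integer(coarse[2]) * factor
  cpp_best_shift_range(ref, mov,
                       max(dy_lo, dy0 - r), min(dy_hi, dy0 + r),
                       max(dx_lo, dx0 - r), min(dx_hi, dx0 + r), min_frac)
}

#' Stitch tiles into a whole-well image
#'
#' Full-resolution composite at the given per-tile offsets. In overlap
#' regions each output pixel is taken from the tile whose center is nearest,
#' so every physical object appears exactly once (no blending: blending
#' would distort total-intensity measurements). A provenance map records the
#' source tile of every pixel.
#'
#' @param scan a [tile_scan()].
#' @param offsets data frame from [refine_offsets()]; `NULL` uses nominal
#'   origins.
#' @return an object of class `stitched_well`: list of per-channel `image`
#'   matrices, `provenance` (tile index matrix), `offsets`, and well
#'   geometry.
#' @export
stitch <- function(scan, offsets = NULL) {
  stopifnot(inherits(scan, "tile_scan"))
  if (is.null(offsets)) {
    offsets <- expand.grid(row = seq_len(scan$grid[1]),
                           col = seq_len(scan$grid[2]))
    offsets$oy <- scan$origin_y[offsets$row]
    offsets$ox <- scan$origin_x[offsets$col]
  }
  th <- scan$tile_size[1]; tw <- scan$tile_size[2]
  H <- max(offsets$oy) + th; W <- max(offsets$ox) + tw
  # gap check: adjacent offsets must still overlap
  for (i in seq_len(nrow(offsets))) {
    r <- offsets$row[i]; c <- offsets$col[i]
    j <- which(offsets$row == r & offsets$col == c + 1)
    if (length(j) && offsets$ox[j] - offsets$ox[i] >= tw)
      stopf("offsets leave a gap between tiles (%d,%d) and (%d,%d)", r, c, r, c + 1)
    j <- which(offsets$row == r + 1 & offsets$col == c)
    if (length(j) && offsets$oy[j] - offsets$oy[i] >= th)
      stopf("offsets leave a gap between tiles (%d,%d) and (%d,%d)", r, c, r + 1, c)
  }
  dist_own <- matrix(Inf, H, W)
  prov <- matrix(0L, H, W)
  images <- lapply(scan$channel_names, function(ch) matrix(0, H, W))
  names(images) <- scan$channel_names
  for (i in seq_len(nrow(offsets))) {
    r <- offsets$row[i]; c <- offsets$col[i]
    ys <- offsets$oy[i] + seq_len(th)
    xs <- offsets$ox[i] + seq_len(tw)
    cy <- offsets$oy[i] + (th + 1) / 2
    cx <- offsets$ox[i] + (tw + 1) / 2
    d <- outer((ys - cy)^2, (xs - cx)^2, "+")
    own <- d < dist_own[ys, xs]
    if (!any(own)) next
    dl <- dist_own[ys, xs]; dl[own] <- d[own]; dist_own[ys, xs] <- dl
    pl <- prov[ys, xs]; pl[own] <- i; prov[ys, xs] <- pl
    for (ch in scan$channel_names) {
      tl <- scan$tiles[[r]][[c]][[ch]]
      il <- images[[ch]][ys, xs]
      il[own] <- tl[own]
      images[[ch]][ys, xs] <- il
    }
  }
  structure(list(images = images, provenance = prov, offsets = offsets,
                 height = H, width = W, channel_names = scan$channel_names,
                 overlap_frac = scan$overlap_frac),
            class = "stitched_well")
}

#' @export
print.stitched_well <- function(x, ...) {
  cat(sprintf("<stitched_well> %d x %d px, channels: %s\n", x$height,
              x$width, paste(x$channel_names, collapse = ", ")))
  invisible(x)
}

#' Estimate the smooth background surface of an image
#'
#' Masks objects by rough Otsu thresholding (dilated), samples the local
#' background (median of a patch) at `n_points` object-free locations chosen
#' to spread across the image (farthest-point sampling on a candidate grid),
#' and interpolates between the sampled values with a thin-plate spline.
#' With fewer than 4 usable sample locations the surface falls back to the
#' global median, with a warning.
#'
#' @param image numeric matrix.
#' @param n_points number of background sample locations (default 20).
#' @param patch odd patch side for the local median (default 15).
#' @return numeric matrix of the interpolated background surface (finite
#'   everywhere; thin-plate extrapolation is mild at borders).
#' @export
estimate_background <- function(image, n_points = 20L, patch = 15L) {
  stopifnot(is.matrix(image), length(image) > 0)
  nr <- nrow(image); nc <- ncol(image)
  thr <- otsu_threshold(image)
  obj <- image > thr
  # an object-free noisy image still splits at Otsu's threshold: treat the
  # "foreground" as objects only if it stands clear of the background
  # fluctuations (genuine objects are many noise-sd above background)
  if (any(obj) && !all(obj)) {
    bg_sd <- stats::sd(image[!obj])
    if (!is.finite(bg_sd) || bg_sd == 0) bg_sd <- 1e-9
    if ((mean(image[obj]) - mean(image[!obj])) / bg_sd < 4) obj[] <- FALSE
  }
  # dilate object mask by the patch radius so patches stay object-free
  pr <- patch %/% 2L
  if (any(obj)) obj <- cpp_edt(!obj) <= pr  # within pr of an object
  # candidate grid
  gs <- max(8L, ceiling(sqrt(4 * n_points)))
  cy <- round(seq(1 + pr, nr - pr, length.out = gs))
  cx <- round(seq(1 + pr, nc - pr, length.out = gs))
  cand <- expand.grid(y = unique(cy), x = unique(cx))
  free <- !obj[cbind(cand$y, cand$x)]
  cand <- cand[free, , drop = FALSE]
  if (nrow(cand) < 4L) {
    warnf("fewer than 4 object-free background locations; using global median")
    return(matrix(median(image), nr, nc))
  }
  # farthest-point (greedy max-min) sampling for spatial spread
  n_pick <- min(n_points, nrow(cand))
  picked <- integer(n_pick)
  picked[1] <- which.min((cand$y - nr / 2)^2 + (cand$x - nc / 2)^2)
  dmin <- (cand$y - cand$y[picked[1]])^2 + (cand$x - cand$x[picked[1]])^2
  for (i in seq_len(n_pick - 1L)) {
    nxt <- which.max(dmin)
    picked[i + 1L] <- nxt
    dmin <- pmin(dmin, (cand$y - cand$y[nxt])^2 + (cand$x - cand$x[nxt])^2)
  }
  py <- cand$y[picked]; px <- cand$x[picked]
  pz <- vapply(seq_along(py), function(i) {
    ys <- max(1, py[i] - pr):min(nr, py[i] + pr)
    xs <- max(1, px[i] - pr):min(nc, px[i] + pr)
    median(image[ys, xs])
  }, numeric(1))
  tps_surface(py, px, pz, nr, nc)
}

# Thin-plate spline interpolation of scattered samples onto the full image
# grid: radial basis r^2 log r plus affine part, exact at the samples.
# Coordinates are scaled to ~[0,1] before the solve (conditioning).
tps_surface <- function(py, px, pz, nr, nc) {
  n <- length(py)
  s <- max(nr, nc)
  uy <- py / s; ux <- px / s
  k <- function(d2) {
    out <- numeric(length(d2))
    pos <- d2 > 0
    out[pos] <- 0.5 * d2[pos] * log(d2[pos])  # r^2 log r = d2 * log(d2)/2
    out
  }
  d2 <- outer(uy, uy, function(a, b) (a - b)^2) +
        outer(ux, ux, function(a, b) (a - b)^2)
  K <- matrix(k(as.numeric(d2)), n, n)
  # polynomial part up to degree 2: vignetting fields are quadratic to
  # leading order, and the radial basis alone cannot represent them
  # smoothing rather than exact interpolation: the samples are noisy patch
  # medians, and the polynomial part (which carries the vignette) is
  # unpenalized, so smooth fields pass through unshrunk
  P <- cbind(1, uy, ux, uy^2, ux^2, uy * ux)
  np <- ncol(P)
  A <- rbind(cbind(K + diag(5e-2, n), P), cbind(t(P), matrix(0, np, np)))
  rhs <- c(pz, rep(0, np))
  coef <- tryCatch(solve(A, rhs), error = function(e) qr.solve(A, rhs))
  w <- coef[seq_len(n)]; a <- coef[n + seq_len(np)]
  # the surface is smooth by construction: evaluate on a coarse grid and
  # bilinearly upsample (errors are negligible at step 8)
  step <- 8L
  yg <- unique(c(seq(1L, nr, by = step), nr))
  xg <- unique(c(seq(1L, nc, by = step), nc))
  ysg <- yg / s; xsg <- xg / s
  coarse <- matrix(a[1], length(yg), length(xg)) +
    outer(a[2] * ysg + a[4] * ysg^2, rep(1, length(xg))) +
    outer(rep(1, length(yg)), a[3] * xsg + a[5] * xsg^2) +
    a[6] * outer(ysg, xsg)
  for (i in seq_len(n)) {
    d2i <- outer((ysg - uy[i])^2, (xsg - ux[i])^2, "+")
    coarse <- coarse + w[i] * matrix(k(as.numeric(d2i)), length(yg), length(xg))
  }
  bilinear_upsample(coarse, yg, xg, nr, nc)
}

# separable linear interpolation of a coarse grid onto 1..nr x 1..nc
bilinear_upsample <- function(z, yg, xg, nr, nc) {
  tmp <- apply(z, 2L, function(col) stats::approx(yg, col, xout = seq_len(nr),
                                                  rule = 2)$y)
  t(apply(tmp, 1L, function(row) stats::approx(xg, row, xout = seq_len(nc),
                                               rule = 2)$y))
}

#' Subtract a background surface from an image
#'
#' Pixelwise difference, clipped at zero.
#'
#' @param image numeric matrix.
#' @param surface background surface of the same shape.
#' @return the corrected image.
#' @export
subtract_background <- function(image, surface) {
  if (!identical(dim(image), dim(surface)))
    stopf("image and background surface shapes differ")
  pmax(image - surface, 0)
}

#' Correct the illumination/background gradient of every tile in a scan
#'
#' Convenience wrapper: estimates and subtracts the per-tile background
#' surface for every tile and channel (the gradient is a per-tile effect of
#' the optics, so correction is applied before stitching).
#'
#' @param scan a [tile_scan()].
#' @inheritParams estimate_background
#' @return a corrected [tile_scan()].
#' @export
correct_scan_background <- function(scan, n_points = 20L, patch = 15L) {
  stopifnot(inherits(scan, "tile_scan"))
  tiles <- scan$tiles
  for (r in seq_len(scan$grid[1])) {
    for (c in seq_len(scan$grid[2])) {
      for (ch in scan$channel_names) {
        img <- tiles[[r]][[c]][[ch]]
        surf <- estimate_background(img, n_points = n_points, patch = patch)
        tiles[[r]][[c]][[ch]] <- subtract_background(img, surf)
      }
    }
  }
  tile_scan(tiles, overlap_frac = scan$overlap_frac,
            channel_names = scan$channel_names)
}
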