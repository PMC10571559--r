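#' Read and write portable graymap (PGM) images
#'
#' Tiles and stitched wells are exchanged on disk as plain-text (ASCII, "P2")
#' portable graymaps with a 16-bit value range, one file per tile per
#' channel. PGM was chosen as the interchange format because it is a plain
#' text format every scientific image stack can read, and needs no image
#' library. Values are clipped to `[0, maxval]` and rounded on write.
#'
#' @param path file path.
#' @param img numeric matrix (rows = y, columns = x).
#' @param maxval maximum gray value written to the header (default 65535,
#'   i.e. 16-bit).
#' @return `read_pgm()` returns a numeric matrix; `write_pgm()` returns
#'   `path` invisibly.
#' @export
write_pgm <- function(img, path, maxval = 65535L) {
  stopifnot(is.matrix(img))
  v <- round(pmin(pmax(img, 0), maxval))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("P2", paste(ncol(img), nrow(img)), as.character(maxval)), con)
  # one image row per line, row-major as PGM requires
  writeLines(apply(v, 1L, paste, collapse = " "), con)
  invisible(path)
}

#' @rdname write_pgm
#' @export
read_pgm <- function(path) {
  toks <- scan(path, what = character(), quiet = TRUE, comment.char = "#")
  if (toks[1] != "P2") stopf("not an ASCII PGM (P2) file: %s", path)
  w <- as.integer(toks[2]); h <- as.integer(toks[3])
  vals <- as.numeric(toks[-(1:4)])
  if (length(vals) != w * h) stopf("corrupt PGM %s: expected %d values, got %d",
                                   path, w * h, length(vals))
  matrix(vals, nrow = h, ncol = w, byrow = TRUE)
}

#' Write a tile scan to a directory
#'
#' One ASCII PGM per tile per channel, named `r{row}_c{col}_{channel}.pgm`
#' (rows and columns 1-based), plus a `manifest.csv` describing the grid.
#'
#' @param scan a [tile_scan()] object.
#' @param dir output directory (created if needed).
#' @return the manifest data frame, invisibly.
#' @export
write_tiles <- function(scan, dir) {
  stopifnot(inherits(scan, "tile_scan"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  rows <- integer(); cols <- integer(); chans <- character(); paths <- character()
  for (r in seq_len(scan$grid[1])) {
    for (c in seq_len(scan$grid[2])) {
      for (ch in scan$channel_names) {
        fn <- sprintf("r%d_c%d_%s.pgm", r, c, ch)
        write_pgm(scan$tiles[[r]][[c]][[ch]], file.path(dir, fn))
        rows <- c(rows, r); cols <- c(cols, c); chans <- c(chans, ch)
        paths <- c(paths, fn)
      }
    }
  }
  manifest <- data.frame(path = paths, row = rows, col = cols,
                         channel = chans, stringsAsFactors = FALSE)
  write.csv(manifest, file.path(dir, "manifest.csv"), row.names = FALSE)
  meta <- list(grid = as.integer(scan$grid),
               tile_size = as.integer(scan$tile_size),
               overlap_frac = scan$overlap_frac,
               channel_names = scan$channel_names)
  jsonlite::write_json(meta, file.path(dir, "scan.json"), auto_unbox = TRUE)
  invisible(manifest)
}

#' Read a tile scan written by [write_tiles()]
#'
#' @param dir directory containing `manifest.csv`, `scan.json` and the PGM
#'   tiles.
#' @return a [tile_scan()] object.
#' @export
read_tiles <- function(dir) {
  meta <- jsonlite::read_json(file.path(dir, "scan.json"), simplifyVector = TRUE)
  manifest <- read.csv(file.path(dir, "manifest.csv"), stringsAsFactors = FALSE)
  tiles <- vector("list", meta$grid[1])
  for (r in seq_len(meta$grid[1])) {
    tiles[[r]] <- vector("list", meta$grid[2])
    for (c in seq_len(meta$grid[2])) tiles[[r]][[c]] <- list()
  }
  for (i in seq_len(nrow(manifest))) {
    m <- manifest[i, ]
    tiles[[m$row]][[m$col]][[m$channel]] <-
      read_pgm(file.path(dir, m$path))
  }
  tile_scan(tiles, overlap_frac = meta$overlap_frac,
            channel_names = meta$channel_names)
}
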