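#' @useDynLib clonoscope, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats median quantile rnorm rpois rlnorm runif rbinom density
#'   cor hclust cutree dist sd setNames aggregate
#' @importFrom utils read.csv write.csv head modifyList
NULL

# Run `expr` under a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  force(expr)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stopf <- function(...) stop(sprintf(...), call. = FALSE)
warnf <- function(...) warning(sprintf(...), call. = FALSE)

# knee of a monotone curve y(i): point of maximum perpendicular distance
# below/above the chord joining the endpoints
knee_by_chord <- function(y) {
  n <- length(y)
  if (n < 3L) return(NA_integer_)
  x <- seq_len(n)
  dx <- n - 1
  dy <- y[n] - y[1]
  len <- sqrt(dx^2 + dy^2)
  if (len == 0) return(NA_integer_)
  d <- abs(dx * (y - y[1]) - dy * (x - 1)) / len
  which.max(d)
}
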