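# Independent brute-force DBSCAN by literal density reachability:
# neighborhoods as closed balls (self included in the core count), core
# points grown by BFS, border points claimed by the first cluster that
# reaches them in expansion order, noise = 0. O(n^2), no shared code with
# the package implementation.
brute_dbscan <- function(x, y, eps, min_samples) {
  n <- length(x)
  if (n == 0) return(integer())
  d2 <- outer(x, x, "-")^2 + outer(y, y, "-")^2
  nb <- lapply(seq_len(n), function(i) which(d2[i, ] <= eps^2))
  core <- vapply(nb, length, 1L) >= min_samples
  cl <- integer(n)
  cur <- 0L
  for (i in seq_len(n)) {
    if (cl[i] != 0L || !core[i]) next
    cur <- cur + 1L
    cl[i] <- cur
    queue <- i
    while (length(queue)) {
      p <- queue[[1]]
      queue <- queue[-1]
      for (q in nb[[p]]) {
        if (cl[q] == 0L) {
          cl[q] <- cur
          if (core[q]) queue <- c(queue, q)
        }
      }
    }
  }
  cl
}

# cluster labelings are equivalent up to label permutation; noise (0) must
# match exactly
same_partition <- function(a, b) {
  if (length(a) != length(b)) return(FALSE)
  if (!identical(a == 0L, b == 0L)) return(FALSE)
  ka <- paste(a, b)[a != 0L]
  length(unique(ka)) == length(unique(a[a != 0L])) &&
    length(unique(ka)) == length(unique(b[b != 0L]))
}
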