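# Density-based clustering of planar points (DBSCAN). No clustering library
# is wrapped here: the demarcation pipeline depends on the exact neighbor
# convention (self counted, boundary-inclusive distances, deterministic
# id-ordered expansion), so the algorithm is implemented directly and checked
# in the test suite against an independent core-graph reference.

#' DBSCAN over planar points
#'
#' Classic DBSCAN with `eps`-neighborhoods that are boundary-inclusive
#' (`distance <= eps`) and a core condition counting the point itself:
#' a point is a core point when at least `min_pts` points (including itself)
#' lie within `eps`. Clusters are grown from core points in ascending index
#' order, so border points reachable from several clusters join the
#' first-discovered one — the run is deterministic with no seed.
#'
#' @param x,y Point coordinates (um).
#' @param eps Neighborhood radius (um).
#' @param min_pts Minimum neighborhood size (counting self) for a core point.
#' @return Integer vector of cluster labels, `0` for noise.
#' @export
#' @examples
#' set.seed(1)
#' x <- c(rnorm(30, 0, 5), rnorm(30, 100, 5))
#' y <- c(rnorm(30, 0, 5), rnorm(30, 0, 5))
#' table(dbscan_points(x, y, eps = 15, min_pts = 10))
dbscan_points <- function(x, y, eps, min_pts) {
  n <- length(x)
  stopifnot(length(y) == n, eps > 0, min_pts >= 1)
  labels <- integer(n)
  if (n == 0L) return(labels)
  eps2 <- eps * eps
  # neighbor lists in blocks to bound memory at large n
  nb <- vector("list", n)
  block <- max(1L, floor(4e6 / n))
  for (s in seq(1L, n, by = block)) {
    idx <- s:min(n, s + block - 1L)
    d2 <- outer(x[idx], x, "-")^2 + outer(y[idx], y, "-")^2
    hit <- d2 <= eps2
    for (k in seq_along(idx)) nb[[idx[k]]] <- which(hit[k, ])
  }
  core <- lengths(nb) >= min_pts
  cl <- 0L
  for (i in seq_len(n)) {
    if (labels[i] != 0L || !core[i]) next
    cl <- cl + 1L
    labels[i] <- cl
    queue <- nb[[i]]
    while (length(queue)) {
      p <- queue[[1]]
      queue <- queue[-1]
      if (labels[p] == 0L) {
        labels[p] <- cl
        if (core[p]) queue <- c(queue, nb[[p]][labels[nb[[p]]] == 0L])
      }
    }
  }
  labels
}
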