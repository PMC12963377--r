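# Independent brute-force oracles used to cross-check the pipeline stages.
# These deliberately re-derive each quantity by exhaustive scan/enumeration
# and share no code with the implementation paths they check.

# O(n^2) scan for chemokine seed cells
oracle_seed_select <- function(cells, pair_radius, positivity_min = 1) {
  ids <- character(0)
  for (i in seq_len(nrow(cells))) {
    if (cells$CCL19[i] < positivity_min) next
    found <- FALSE
    for (j in seq_len(nrow(cells))) {
      if (cells$CXCL13[j] >= positivity_min &&
          (cells$x[i] - cells$x[j])^2 + (cells$y[i] - cells$y[j])^2 <=
            pair_radius^2) {
        found <- TRUE
        break
      }
    }
    if (found) ids <- c(ids, cells$cell_id[i])
  }
  ids
}

# Reference DBSCAN: full distance matrix, core-point graph, connected
# components via igraph, border points to the first-discovered adjacent
# cluster (clusters ordered by their smallest core index).
oracle_dbscan <- function(x, y, eps, min_pts) {
  n <- length(x)
  labels <- integer(n)
  if (n == 0L) return(labels)
  adj <- as.matrix(dist(cbind(x, y))) <= eps
  diag(adj) <- TRUE
  core <- which(rowSums(adj) >= min_pts)
  if (!length(core)) return(labels)
  g <- igraph::graph_from_adjacency_matrix(
    adj[core, core, drop = FALSE], mode = "undirected", diag = FALSE)
  comp <- igraph::components(g)$membership
  first_core <- tapply(core, comp, min)
  relabel <- rank(first_core)
  labels[core] <- as.integer(relabel[comp])
  for (i in setdiff(seq_len(n), core)) {
    near_cores <- core[adj[i, core]]
    if (length(near_cores)) labels[i] <- min(labels[near_cores])
  }
  labels
}

# connected-components oracle for centroid merging
oracle_merge_components <- function(centroids, merge_distance) {
  k <- nrow(centroids)
  if (k == 0L) return(integer(0))
  adj <- as.matrix(dist(centroids)) <= merge_distance
  g <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected",
                                           diag = FALSE)
  igraph::components(g)$membership
}

# partition comparison robust to label numbering
same_partition <- function(a, b) {
  stopifnot(length(a) == length(b))
  key <- function(v) {
    m <- split(seq_along(v), v)
    paste(sort(vapply(m, function(ix) paste(ix, collapse = ","),
                      character(1))), collapse = ";")
  }
  key(a) == key(b)
}

# small random cell map with random chemokine positivity
random_chemokine_cells <- function(n, extent = 500, p_pos = 0.3) {
  data.frame(
    cell_id = sprintf("c%03d", seq_len(n)),
    x = runif(n, 0, extent), y = runif(n, 0, extent),
    cell_type = sample(c("B", "PC", "T_TEX", "T_PEX", "tumor"), n,
                       replace = TRUE),
    CCL19 = rbinom(n, 1, p_pos), CXCL13 = rbinom(n, 1, p_pos),
    stringsAsFactors = FALSE)
}

# Jaccard index between two id sets
jaccard <- function(a, b) length(intersect(a, b)) / length(union(a, b))

# closed-form two-sided p for a regression slope (used in type-I checks)
fast_slope_p <- function(x, y) {
  n <- length(x)
  sxx <- sum((x - mean(x))^2)
  b <- sum((x - mean(x)) * (y - mean(y))) / sxx
  a <- mean(y) - b * mean(x)
  ss <- sum((y - a - b * x)^2) / (n - 2)
  tt <- b / sqrt(ss / sxx)
  2 * pt(-abs(tt), n - 2)
}
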