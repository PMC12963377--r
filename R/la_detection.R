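# B-cell-independent lymphoid-aggregate demarcation: chemokine seed
# selection -> DBSCAN -> centroid merging -> buffered concave-hull polygons
# -> cell assignment. All distance comparisons are boundary-inclusive (<=),
# matching "within"; every stage is deterministic for fixed input.

#' Select chemokine seed cells
#'
#' The seed set is all CCL19-positive cells lying within `pair_radius` of a
#' CXCL13-positive cell (center-to-center, boundary inclusive). Positivity
#' is `count >= positivity_min`. With `self_pairing = TRUE` (default) a
#' CCL19+CXCL13 double-positive cell pairs with itself and is always a seed;
#' otherwise it needs another CXCL13-positive cell within range.
#'
#' @param cellmap A [cell_map()] carrying `CCL19` and `CXCL13` count columns.
#' @param pair_radius Pairing distance (um); default 50.
#' @param positivity_min Transcript threshold for positivity; default 1.
#' @param self_pairing Allow a double-positive cell to seed itself; default
#'   TRUE.
#' @return Character vector of seed cell ids.
#' @export
select_chemokine_seed_cells <- function(cellmap, pair_radius = 50,
                                        positivity_min = 1,
                                        self_pairing = TRUE) {
  stopifnot(inherits(cellmap, "cell_map"))
  cells <- cellmap$cells
  for (g in c("CCL19", "CXCL13")) {
    if (!g %in% names(cells)) {
      stop("select_chemokine_seed_cells: count column '", g, "' absent")
    }
  }
  ccl19 <- which(cells$CCL19 >= positivity_min)
  cxcl13 <- which(cells$CXCL13 >= positivity_min)
  if (!length(ccl19) || !length(cxcl13)) return(character(0))
  r2 <- pair_radius^2
  is_seed <- logical(length(ccl19))
  block <- max(1L, floor(4e6 / length(cxcl13)))
  for (s in seq(1L, length(ccl19), by = block)) {
    idx <- s:min(length(ccl19), s + block - 1L)
    d2 <- outer(cells$x[ccl19[idx]], cells$x[cxcl13], "-")^2 +
          outer(cells$y[ccl19[idx]], cells$y[cxcl13], "-")^2
    if (!self_pairing) {
      self <- outer(ccl19[idx], cxcl13, "==")
      d2[self] <- Inf
    }
    is_seed[idx] <- apply(d2 <= r2, 1L, any)
  }
  cells$cell_id[ccl19[is_seed]]
}

#' Cluster seed cells with DBSCAN
#'
#' Runs [dbscan_points()] on the seed cells with `eps = radius` and core
#' condition "at least `min_cells` seeds within `eps`, counting the cell
#' itself". Noise is discarded; every returned cluster has at least
#' `min_cells` members. Centroids are the arithmetic means of member
#' coordinates.
#'
#' @param cellmap A [cell_map()].
#' @param seeds Seed cell ids from [select_chemokine_seed_cells()].
#' @param radius DBSCAN eps (um); default 75.
#' @param min_cells Core threshold; default 15.
#' @return List of clusters: each `list(cluster_id, cell_ids, coords,
#'   centroid)`.
#' @export
cluster_seed_cells <- function(cellmap, seeds, radius = 75, min_cells = 15) {
  stopifnot(inherits(cellmap, "cell_map"))
  cells <- cellmap$cells
  idx <- match(seeds, cells$cell_id)
  if (anyNA(idx)) stop("cluster_seed_cells: unknown seed cell id")
  if (!length(idx)) return(list())
  lab <- dbscan_points(cells$x[idx], cells$y[idx], eps = radius,
                       min_pts = min_cells)
  out <- list()
  for (cl in sort(unique(lab[lab > 0L]))) {
    m <- idx[lab == cl]
    coords <- cbind(x = cells$x[m], y = cells$y[m])
    out[[length(out) + 1L]] <- list(
      cluster_id = length(out) + 1L,
      cell_ids = cells$cell_id[m],
      coords = coords,
      centroid = colMeans(coords))
  }
  out
}

#' Merge clusters by centroid proximity
#'
#' Single-linkage connected components over the graph "centroid distance
#' <= merge_distance", computed once on the original centroids (no
#' iterative recomputation, so the result is order-independent). Merged
#' members are the union; the centroid is recomputed once after merging.
#'
#' @param clusters List from [cluster_seed_cells()].
#' @param merge_distance Distance threshold (um); default 400.
#' @return List of merged clusters; each carries `source_ids`, the original
#'   cluster ids it absorbed.
#' @export
merge_clusters <- function(clusters, merge_distance = 400) {
  k <- length(clusters)
  if (k <= 1L) {
    return(lapply(clusters, function(cl) { cl$source_ids <- cl$cluster_id; cl }))
  }
  cx <- vapply(clusters, function(cl) cl$centroid[1], numeric(1))
  cy <- vapply(clusters, function(cl) cl$centroid[2], numeric(1))
  parent <- seq_len(k)
  find <- function(i) { while (parent[i] != i) { parent[i] <<- parent[parent[i]]; i <- parent[i] }; i }
  d2max <- merge_distance^2
  for (i in seq_len(k - 1L)) {
    for (j in (i + 1L):k) {
      if ((cx[i] - cx[j])^2 + (cy[i] - cy[j])^2 <= d2max) {
        a <- find(i); b <- find(j)
        if (a != b) parent[a] <- b
      }
    }
  }
  comp <- vapply(seq_len(k), find, integer(1))
  out <- list()
  for (cp in unique(comp)) {
    members <- which(comp == cp)
    coords <- do.call(rbind, lapply(clusters[members], `[[`, "coords"))
    out[[length(out) + 1L]] <- list(
      cluster_id = length(out) + 1L,
      cell_ids = unlist(lapply(clusters[members], `[[`, "cell_ids")),
      coords = coords,
      centroid = colMeans(coords),
      source_ids = vapply(clusters[members], `[[`, integer(1), "cluster_id"))
  }
  out
}

#' Assign cells to LA polygons
#'
#' A cell belongs to an LA iff its point lies inside or on the LA polygon.
#' Cells inside several (overlapping) polygons are assigned to the LA whose
#' source-cluster centroid is nearest (ties to the lower `la_id`); remaining
#' cells are `"outside"`.
#'
#' @param cellmap A [cell_map()].
#' @param polygons List of `region_polygon`s, one per LA, in `la_id` order.
#' @param centroids Optional matrix of source-cluster centroids (one row per
#'   polygon) used for overlap resolution; defaults to polygon centroids.
#' @return Data frame `membership` with columns `cell_id`, `la_id` (integer
#'   or NA for outside).
#' @export
assign_cells_to_las <- function(cellmap, polygons, centroids = NULL) {
  stopifnot(inherits(cellmap, "cell_map"))
  cells <- cellmap$cells
  n <- nrow(cells)
  la_id <- rep(NA_integer_, n)
  if (!length(polygons)) {
    return(data.frame(cell_id = cells$cell_id, la_id = la_id,
                      stringsAsFactors = FALSE))
  }
  if (is.null(centroids)) {
    centroids <- do.call(rbind, lapply(polygons, polygon_centroid))
  }
  best_d2 <- rep(Inf, n)
  for (k in seq_along(polygons)) {
    poly <- polygons[[k]]
    bb <- c(range(poly$x), range(poly$y))
    cand <- which(cells$x >= bb[1] & cells$x <= bb[2] &
                  cells$y >= bb[3] & cells$y <= bb[4])
    if (!length(cand)) next
    inside <- cand[point_in_polygon(cells$x[cand], cells$y[cand], poly)]
    if (!length(inside)) next
    d2 <- (cells$x[inside] - centroids[k, 1])^2 +
          (cells$y[inside] - centroids[k, 2])^2
    take <- d2 < best_d2[inside]   # strict: ties stay with the lower la_id
    la_id[inside[take]] <- k
    best_d2[inside[take]] <- d2[take]
  }
  data.frame(cell_id = cells$cell_id, la_id = la_id, stringsAsFactors = FALSE)
}

#' Detect lymphoid aggregates
#'
#' Full demarcation pipeline: [select_chemokine_seed_cells()] (CCL19+ cells
#' within `pair_radius` of a CXCL13+ cell), [cluster_seed_cells()] (DBSCAN,
#' `min_cluster_cells` in `dbscan_radius`), [merge_clusters()] (centroids
#' within `merge_distance`), [build_la_polygon()] (alpha-shape concave hull
#' dilated by `hull_buffer`), and [assign_cells_to_las()]. Deterministic for
#' fixed input and configuration.
#'
#' @param cellmap A [cell_map()] with CCL19 and CXCL13 counts.
#' @param config An [la_config()].
#' @return An object of class `la_set`: list with `aggregates` (per-LA
#'   records: `la_id`, `polygon`, `area_um2`, `centroid`, `cell_ids`,
#'   `seed_ids`, `n_by_type`, `source_ids`, `hull_fallback`), `membership`
#'   (cell_id / la_id data frame), `seeds`, `sample_id`, `config`.
#' @export
#' @examples
#' tg <- generate_tissue(tissue_sim_params(n_las = 1, n_background = 100,
#'   n_cells_per_la = 120, width = 2000, height = 2000,
#'   min_la_separation = 100, seed = 3))
#' las <- detect_lymphoid_aggregates(tg$cellmap)
#' las
detect_lymphoid_aggregates <- function(cellmap, config = la_config()) {
  stopifnot(inherits(cellmap, "cell_map"), inherits(config, "la_config"))
  seeds <- select_chemokine_seed_cells(
    cellmap, pair_radius = config$pair_radius,
    positivity_min = config$marker_positivity_min)
  clusters <- cluster_seed_cells(cellmap, seeds,
                                 radius = config$dbscan_radius,
                                 min_cells = config$min_cluster_cells)
  merged <- merge_clusters(clusters, merge_distance = config$merge_distance)
  polygons <- lapply(merged, function(cl) {
    build_la_polygon(cl$coords, hull_buffer = config$hull_buffer,
                     hull_alpha = config$hull_alpha)
  })
  centroids <- if (length(merged)) {
    do.call(rbind, lapply(merged, `[[`, "centroid"))
  } else NULL
  membership <- assign_cells_to_las(cellmap, polygons, centroids)
  cells <- cellmap$cells
  vocab <- cellmap$vocabulary
  aggregates <- lapply(seq_along(merged), function(k) {
    member_idx <- which(membership$la_id == k)
    n_by_type <- table(factor(cells$cell_type[member_idx], levels = vocab))
    list(la_id = k,
         polygon = polygons[[k]],
         area_um2 = polygons[[k]]$area,
         centroid = merged[[k]]$centroid,
         cell_ids = cells$cell_id[member_idx],
         seed_ids = merged[[k]]$cell_ids,
         n_by_type = stats::setNames(as.integer(n_by_type), vocab),
         source_ids = merged[[k]]$source_ids,
         hull_fallback = isTRUE(attr(polygons[[k]], "fallback")))
  })
  structure(list(aggregates = aggregates, membership = membership,
                 seeds = seeds, sample_id = cellmap$sample_id,
                 config = config),
            class = "la_set")
}

#' @export
print.la_set <- function(x, ...) {
  n <- length(x$aggregates)
  cat(sprintf("<la_set '%s': %d lymphoid aggregate(s), %d seed cells, %d cells assigned>\n",
              x$sample_id, n, length(x$seeds),
              sum(!is.na(x$membership$la_id))))
  invisible(x)
}

#' @export
summary.la_set <- function(object, ...) {
  las <- object$aggregates
  df <- data.frame(
    la_id = vapply(las, `[[`, integer(1), "la_id"),
    area_um2 = vapply(las, `[[`, numeric(1), "area_um2"),
    n_cells = vapply(las, function(a) length(a$cell_ids), integer(1)),
    n_seeds = vapply(las, function(a) length(a$seed_ids), integer(1)),
    hull_fallback = vapply(las, `[[`, logical(1), "hull_fallback"))
  class(df) <- c("summary.la_set", "data.frame")
  df
}

#' Plot detected lymphoid aggregates
#'
#' Base-graphics map of the tissue: cells as points (grey outside, colored by
#' LA inside) with the LA boundary polygons overlaid.
#'
#' @param x An `la_set`.
#' @param cellmap The [cell_map()] the set was detected on.
#' @param ... Passed to [graphics::plot()].
#' @return `x`, invisibly.
#' @export
plot.la_set <- function(x, cellmap, ...) {
  cells <- cellmap$cells
  graphics::plot(cells$x, cells$y, pch = ".", col = "grey70", asp = 1,
                 xlab = "x (um)", ylab = "y (um)", ...)
  if (length(x$aggregates)) {
    cols <- grDevices::hcl.colors(max(2L, length(x$aggregates)), "Dark 3")
    for (la in x$aggregates) {
      idx <- match(la$cell_ids, cells$cell_id)
      graphics::points(cells$x[idx], cells$y[idx], pch = 16, cex = 0.3,
                       col = cols[la$la_id])
      graphics::polygon(la$polygon$x, la$polygon$y, border = cols[la$la_id])
    }
  }
  invisible(x)
}
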