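# IHC-side lymphoid-aggregate identification and density analyses on
# marker-centroid tables (CD20, CD3, CD4, CD8, CD23, MUM1 boolean calls)
# with a tumor-bed polygon annotation. The published identification was
# operator-driven outlining; this module is an explicit, reproducible
# DBSCAN-based operationalization with every parameter configurable.

.validate_ihc_table <- function(table) {
  req <- c("cell_id", "x", "y", "cd20", "cd3", "cd4", "cd8", "cd23", "mum1")
  for (col in req) {
    if (!col %in% names(table)) stop("IHC table: missing column '", col, "'")
  }
  if (anyDuplicated(table$cell_id)) stop("IHC table: duplicate cell_id")
  lineage <- table$cd20 + table$cd3 + table$mum1
  if (any(lineage > 1)) {
    la_log("IHC table: %d cell(s) co-positive for several lineage markers",
           sum(lineage > 1))
  }
  invisible(table)
}

#' Identify lymphoid aggregates on an IHC slide
#'
#' Operationalizes "compact clusters of more than 50 CD20+ cells associated
#' with proximal compact clusters of CD3+ cells": DBSCAN over CD20+
#' centroids proposes candidate clusters; a candidate is kept when it has
#' strictly more than `ihc_cd20_min` CD20+ members and at least
#' `ihc_cd3_min` CD3+ cells within `ihc_cd3_radius` of the cluster's convex
#' hull. The LA polygon is the buffered concave hull of the CD20+ members
#' (reusing [build_la_polygon()], buffer `ihc_hull_buffer`); marker counts
#' are tallied inside the polygon.
#'
#' @param table IHC centroid data frame (`cell_id`, `x`, `y` in um, boolean
#'   `cd20`, `cd3`, `cd4`, `cd8`, `cd23`, `mum1`).
#' @param config An [la_config()] supplying `ihc_eps`, `ihc_min_pts`,
#'   `ihc_cd20_min`, `ihc_cd3_min`, `ihc_cd3_radius`, `ihc_hull_buffer`,
#'   `hull_alpha`, `cd23_min_cells`.
#' @return Object of class `ihc_la_set`: list of aggregates (`la_id`,
#'   `polygon`, `area_um2`, `centroid`, `cd20_ids`, `n_cd20`, `n_cd3`,
#'   `n_cd4`, `n_cd8`, `n_cd23`, `n_mum1`, `cd23_positive`) plus the config.
#' @export
identify_ihc_las <- function(table, config = la_config()) {
  .validate_ihc_table(table)
  d20 <- which(table$cd20)
  out <- list()
  if (length(d20)) {
    lab <- dbscan_points(table$x[d20], table$y[d20], eps = config$ihc_eps,
                         min_pts = config$ihc_min_pts)
    cd3_idx <- which(table$cd3)
    for (cl in sort(unique(lab[lab > 0L]))) {
      m <- d20[lab == cl]
      if (length(m) <= config$ihc_cd20_min) next # strict: > 50
      # proximal CD3 cluster: CD3+ cells within reach of the convex hull
      h <- grDevices::chull(table$x[m], table$y[m])
      hull <- list(x = table$x[m][h], y = table$y[m][h])
      n_cd3_near <- if (length(cd3_idx)) {
        sum(dist_to_polygon(table$x[cd3_idx], table$y[cd3_idx], hull) <=
              config$ihc_cd3_radius)
      } else 0L
      if (n_cd3_near < config$ihc_cd3_min) next
      poly <- build_la_polygon(cbind(table$x[m], table$y[m]),
                               hull_buffer = config$ihc_hull_buffer,
                               hull_alpha = config$hull_alpha)
      inside <- point_in_polygon(table$x, table$y, poly)
      la <- list(la_id = length(out) + 1L,
                 polygon = poly, area_um2 = poly$area,
                 centroid = polygon_centroid(poly),
                 cd20_ids = table$cell_id[m],
                 n_cd20 = sum(inside & table$cd20),
                 n_cd3 = sum(inside & table$cd3),
                 n_cd4 = sum(inside & table$cd4),
                 n_cd8 = sum(inside & table$cd8),
                 n_cd23 = sum(inside & table$cd23),
                 n_mum1 = sum(inside & table$mum1))
      la$cd23_positive <- la$n_cd23 >= config$cd23_min_cells
      out[[length(out) + 1L]] <- la
    }
  }
  structure(list(aggregates = out, config = config), class = "ihc_la_set")
}

#' @export
print.ihc_la_set <- function(x, ...) {
  cat(sprintf("<ihc_la_set: %d lymphoid aggregate(s)>\n", length(x$aggregates)))
  invisible(x)
}

#' Classify an LA as intra- or extra-tumoral
#'
#' Intra-tumoral iff the LA polygon's centroid lies inside or on the
#' tumor-bed polygon (centroid rule, for determinism).
#'
#' @param la An aggregate record with a `polygon` (or a `region_polygon`).
#' @param tumor_bed The tumor-bed `region_polygon`; if missing (NULL) the
#'   call is skipped with a log entry and NA returned.
#' @return `"intra_tumoral"`, `"extra_tumoral"`, or NA.
#' @export
classify_la_location <- function(la, tumor_bed) {
  if (is.null(tumor_bed)) {
    la_log("classify_la_location: no tumor bed; classification skipped")
    return(NA_character_)
  }
  poly <- if (inherits(la, "region_polygon")) la else la$polygon
  ctr <- polygon_centroid(poly)
  if (point_in_polygon(ctr[1], ctr[2], tumor_bed)) "intra_tumoral"
  else "extra_tumoral"
}

#' Intra-tumoral plasma-cell density
#'
#' Number of MUM1-positive cells inside the tumor-bed polygon divided by the
#' tumor-bed area, in cells/mm^2.
#'
#' @param table IHC centroid data frame.
#' @param tumor_bed Tumor-bed `region_polygon`.
#' @return Density (cells/mm^2).
#' @export
intratumoral_pc_density <- function(table, tumor_bed) {
  .validate_ihc_table(table)
  if (!inherits(tumor_bed, "region_polygon") || tumor_bed$area <= 0) {
    stop("intratumoral_pc_density: degenerate tumor-bed polygon")
  }
  m <- which(table$mum1)
  n_in <- if (length(m)) {
    sum(point_in_polygon(table$x[m], table$y[m], tumor_bed))
  } else 0L
  n_in / (tumor_bed$area / 1e6)
}

#' Per-LA marker density summaries
#'
#' Densities (cells/mm^2) of each marker within each LA polygon, the CD23
#' positivity call, and the intra/extra-tumoral location when a tumor bed is
#' given.
#'
#' @param ihc_las An `ihc_la_set` from [identify_ihc_las()].
#' @param tumor_bed Optional tumor-bed `region_polygon`.
#' @return Data frame: `la_id`, `area_um2`, `n_*` counts, `density_*`
#'   (cells/mm^2), `cd23_positive`, `location`.
#' @export
la_density_summaries <- function(ihc_las, tumor_bed = NULL) {
  las <- ihc_las$aggregates
  if (!length(las)) {
    return(data.frame(la_id = integer(0)))
  }
  df <- data.frame(
    la_id = vapply(las, `[[`, integer(1), "la_id"),
    area_um2 = vapply(las, `[[`, numeric(1), "area_um2"))
  for (mk in c("cd20", "cd3", "cd4", "cd8", "cd23", "mum1")) {
    n <- vapply(las, `[[`, numeric(1), paste0("n_", mk))
    df[[paste0("n_", mk)]] <- n
    df[[paste0("density_", mk)]] <- n / (df$area_um2 / 1e6)
  }
  df$cd23_positive <- vapply(las, `[[`, logical(1), "cd23_positive")
  df$location <- vapply(las, function(la) {
    classify_la_location(la, tumor_bed)
  }, character(1))
  df
}

#' Compare marker densities between LA groups
#'
#' Two-sided Mann-Whitney (Wilcoxon rank-sum) test of a density column
#' between two groups of LAs (e.g. intra- vs extra-tumoral, or CD23+ vs
#' CD23-).
#'
#' @param summaries Data frame from [la_density_summaries()].
#' @param value Column to compare (e.g. `"density_cd20"`).
#' @param group Logical or two-level column/vector defining the groups.
#' @return List with `statistic` (U), `p`, and group sizes.
#' @export
compare_la_densities <- function(summaries, value, group) {
  v <- summaries[[value]]
  g <- if (is.character(group) && length(group) == 1L) summaries[[group]] else group
  g <- as.factor(g)
  if (nlevels(g) != 2L) stop("compare_la_densities: need exactly 2 groups")
  wt <- stats::wilcox.test(v ~ g, exact = TRUE)
  list(statistic = unname(wt$statistic), p = wt$p.value,
       n = as.vector(table(g)))
}

#' Correlate intra-tumoral plasma cells with LA burden
#'
#' Simple linear regression of the per-tumor intra-tumoral plasma-cell count
#' (or density) on the intra-tumoral and, separately, the extra-tumoral LA
#' count (or density), with the two-sided p-value of each slope.
#'
#' @param records Data frame with one row per tumor: columns `pc` (plasma
#'   cells), `la_intra`, `la_extra`.
#' @return List of two `la_association`-like results, `intra` and `extra`,
#'   each with `slope`, `intercept`, `p`, `n`.
#' @export
correlate_pc_with_la_burden <- function(records) {
  if (nrow(records) < 3L) {
    stop("correlate_pc_with_la_burden: need at least 3 tumors")
  }
  fit1 <- function(xcol) {
    fit <- stats::lm(records$pc ~ records[[xcol]])
    sm <- suppressWarnings(summary(fit)$coefficients) # exact fits are legal
    list(slope = unname(coef(fit)[2]), intercept = unname(coef(fit)[1]),
         p = if (nrow(sm) > 1L) sm[2, 4] else NA_real_, n = nrow(records))
  }
  list(intra = fit1("la_intra"), extra = fit1("la_extra"))
}
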