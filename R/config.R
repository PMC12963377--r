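#' Pipeline configuration
#'
#' Collects every tunable of the lymphoid-aggregate (LA) pipeline with its
#' default. Distances are planar micrometres (center-to-center), counts are
#' cells or transcripts, clinical thresholds carry their clinical units.
#'
#' @param pair_radius Maximum distance (um) from a CCL19-positive cell to a
#'   CXCL13-positive cell for the former to qualify as an LA seed. Default 50.
#' @param dbscan_radius DBSCAN eps (um) for clustering seed cells. Default 75.
#' @param min_cluster_cells DBSCAN core threshold: a seed is a core point when
#'   at least this many seeds (counting itself) lie within `dbscan_radius`.
#'   Clusters below this size are discarded. Default 15.
#' @param merge_distance Clusters whose centroids lie within this distance (um)
#'   are merged (single-linkage, transitive). Default 400.
#' @param hull_buffer Buffer (um) dilating the concave hull into the LA
#'   boundary polygon. Default 100.
#' @param hull_alpha Alpha-shape disc radius (um) for the concave hull.
#'   Default 150 (2x `dbscan_radius`).
#' @param marker_positivity_min Transcript count at or above which a cell is
#'   called positive for a marker gene. Default 1.
#' @param qc_min_genes,qc_min_transcripts Cell QC: minimum detected genes and
#'   minimum total transcripts. Defaults 10 and 20.
#' @param rep_cells_max Maximum representative cells retained per cluster per
#'   sample. Default 500.
#' @param score_threshold Label-transfer prediction score below which a cell is
#'   set to "unassigned". Default 0.6.
#' @param ihc_eps,ihc_min_pts DBSCAN parameters (um, cells) for CD20+ centroid
#'   clustering on IHC slides. Defaults 40 and 5.
#' @param ihc_cd20_min An IHC LA requires strictly more than this many CD20+
#'   cells. Default 50.
#' @param ihc_cd3_min,ihc_cd3_radius Required number of CD3+ cells within
#'   `ihc_cd3_radius` (um) of the CD20 cluster hull. Defaults 20 and 50.
#' @param ihc_hull_buffer Buffer (um) for IHC LA polygons. Default 50.
#' @param cd23_min_cells An LA is called CD23-positive when it contains at
#'   least this many CD23+ cells. Default 3.
#' @param ca199_upper_normal Upper limit of normal for CA19-9 (U/mL).
#'   Default 37.
#' @param bilirubin_max CA19-9 draws are evaluable only when total bilirubin is
#'   strictly below this (mg/dL). Default 3.
#' @param recist_pr,recist_pd RECIST 1.1 thresholds (percent change in target
#'   lesion longest diameter): partial response at or below `recist_pr`,
#'   progression at or above `recist_pd` from nadir (with the +5 mm absolute
#'   rule). Defaults -30 and +20.
#' @param seed Optional integer seed recorded for provenance.
#'
#' @return An object of class `la_config` (a named list).
#' @export
#' @examples
#' cfg <- la_config()
#' cfg$pair_radius
la_config <- function(pair_radius = 50,
                      dbscan_radius = 75,
                      min_cluster_cells = 15,
                      merge_distance = 400,
                      hull_buffer = 100,
                      hull_alpha = 150,
                      marker_positivity_min = 1,
                      qc_min_genes = 10,
                      qc_min_transcripts = 20,
                      rep_cells_max = 500,
                      score_threshold = 0.6,
                      ihc_eps = 40,
                      ihc_min_pts = 5,
                      ihc_cd20_min = 50,
                      ihc_cd3_min = 20,
                      ihc_cd3_radius = 50,
                      ihc_hull_buffer = 50,
                      cd23_min_cells = 3,
                      ca199_upper_normal = 37,
                      bilirubin_max = 3,
                      recist_pr = -30,
                      recist_pd = 20,
                      seed = NULL) {
  cfg <- list(pair_radius = pair_radius, dbscan_radius = dbscan_radius,
              min_cluster_cells = min_cluster_cells,
              merge_distance = merge_distance, hull_buffer = hull_buffer,
              hull_alpha = hull_alpha,
              marker_positivity_min = marker_positivity_min,
              qc_min_genes = qc_min_genes,
              qc_min_transcripts = qc_min_transcripts,
              rep_cells_max = rep_cells_max,
              score_threshold = score_threshold,
              ihc_eps = ihc_eps, ihc_min_pts = ihc_min_pts,
              ihc_cd20_min = ihc_cd20_min, ihc_cd3_min = ihc_cd3_min,
              ihc_cd3_radius = ihc_cd3_radius,
              ihc_hull_buffer = ihc_hull_buffer,
              cd23_min_cells = cd23_min_cells,
              ca199_upper_normal = ca199_upper_normal,
              bilirubin_max = bilirubin_max,
              recist_pr = recist_pr, recist_pd = recist_pd,
              seed = seed)
  strict_pos <- c("pair_radius", "dbscan_radius", "min_cluster_cells",
                  "merge_distance", "hull_buffer", "hull_alpha",
                  "marker_positivity_min", "ihc_eps", "ihc_min_pts",
                  "ihc_cd20_min", "ihc_cd3_min", "ihc_cd3_radius",
                  "ihc_hull_buffer", "cd23_min_cells", "ca199_upper_normal",
                  "bilirubin_max")
  for (nm in strict_pos) {
    v <- cfg[[nm]]
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v) || v <= 0) {
      stop("la_config: '", nm, "' must be a single strictly positive number")
    }
  }
  for (nm in c("qc_min_genes", "qc_min_transcripts", "rep_cells_max")) {
    v <- cfg[[nm]]
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v) || v < 0) {
      stop("la_config: '", nm, "' must be a single non-negative number")
    }
  }
  if (cfg$score_threshold < 0 || cfg$score_threshold > 1) {
    stop("la_config: 'score_threshold' must lie in [0, 1]")
  }
  if (cfg$recist_pr >= 0) stop("la_config: 'recist_pr' is a negative percent change")
  if (cfg$recist_pd <= 0) stop("la_config: 'recist_pd' is a positive percent change")
  class(cfg) <- "la_config"
  cfg
}

#' @export
print.la_config <- function(x, ...) {
  cat("laggr pipeline configuration\n")
  for (nm in names(x)) {
    if (is.null(x[[nm]])) next
    cat(sprintf("  %-22s %s\n", nm, format(x[[nm]])))
  }
  invisible(x)
}

#' Read / write a configuration file
#'
#' Plain-text `key = value` format, one tunable per line; `#` starts a
#' comment. Unknown keys are rejected so typos cannot silently fall back to
#' defaults. The same serialization is echoed into JSON outputs for
#' provenance.
#'
#' @param path File path.
#' @return `read_la_config()` returns an `la_config`;
#'   `write_la_config()` returns `path` invisibly.
#' @export
read_la_config <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  defaults <- la_config()
  vals <- list()
  for (ln in lines) {
    kv <- strsplit(ln, "=", fixed = TRUE)[[1]]
    if (length(kv) != 2L) stop("config: cannot parse line: ", ln)
    key <- trimws(kv[1]); val <- trimws(kv[2])
    if (!key %in% names(defaults)) stop("config: unknown key '", key, "'")
    vals[[key]] <- as.numeric(val)
  }
  do.call(la_config, vals)
}

#' @rdname read_la_config
#' @param config An `la_config` object.
#' @export
write_la_config <- function(config, path) {
  stopifnot(inherits(config, "la_config"))
  keep <- !vapply(config, is.null, logical(1))
  lines <- sprintf("%s = %s", names(config)[keep],
                   vapply(config[keep], format, character(1)))
  writeLines(lines, path)
  invisible(path)
}

# config as a flat named list for embedding in JSON outputs
config_as_list <- function(config) {
  keep <- !vapply(config, is.null, logical(1))
  unclass(config)[keep]
}
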