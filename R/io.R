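# Readers and writers for the external representations the pipeline touches:
# delimited cell tables, MatrixMarket sparse expression matrices with
# feature/cell lists, and GeoJSON polygons (LA boundaries, tumor bed).
# Coordinates are planar micrometres, y increasing upward; no axis flipping
# is ever applied implicitly -- image-convention inputs must be pre-flipped
# by the caller.

#' Default cell-type vocabulary
#'
#' The controlled vocabulary of cell-type labels used throughout the package:
#' tumor, stromal and myeloid compartments, B cells, plasma cells (PC), and
#' the T-cell subsets (progenitor/terminally exhausted T_PEX / T_TEX, central
#' and resident memory, regulatory, follicular helper, organization-related,
#' proliferating). Readers reject labels outside the declared vocabulary.
#'
#' @return Character vector of labels.
#' @export
default_cell_vocabulary <- function() {
  c("tumor", "fibroblast", "myeloid", "endothelial",
    "B", "PC",
    "T_TEX", "T_PEX", "T_CM", "T_RM", "T_REG", "T_FH", "T_ORG", "T_PRO",
    "other")
}

#' Cell map: spatial table of cells
#'
#' Validates and wraps a cell-level spatial table: one row per cell with
#' planar coordinates (um), a cell-type label from a controlled vocabulary,
#' and zero or more per-gene transcript-count columns.
#'
#' @param cells Data frame with columns `cell_id`, `x`, `y`, `cell_type` and
#'   optional numeric gene-count columns.
#' @param sample_id Sample identifier.
#' @param vocabulary Allowed cell-type labels.
#' @return An object of class `cell_map`: a list with `sample_id`, `cells`
#'   (the validated data frame), `genes` (count column names) and
#'   `vocabulary`.
#' @export
cell_map <- function(cells, sample_id = "sample",
                     vocabulary = default_cell_vocabulary()) {
  req <- c("cell_id", "x", "y", "cell_type")
  for (col in req) {
    if (!col %in% names(cells)) {
      stop("cell_map: missing required column '", col, "'")
    }
  }
  cells$cell_id <- as.character(cells$cell_id)
  cells$cell_type <- as.character(cells$cell_type)
  if (anyDuplicated(cells$cell_id)) {
    dup <- cells$cell_id[duplicated(cells$cell_id)][1]
    stop("cell_map: duplicate cell_id '", dup, "'")
  }
  if (any(!is.finite(cells$x)) || any(!is.finite(cells$y))) {
    stop("cell_map: non-finite coordinates")
  }
  bad <- setdiff(unique(cells$cell_type), vocabulary)
  if (length(bad)) {
    stop("cell_map: cell_type label(s) outside vocabulary: ",
         paste(bad, collapse = ", "))
  }
  genes <- setdiff(names(cells), req)
  for (g in genes) {
    v <- cells[[g]]
    if (!is.numeric(v)) stop("cell_map: count column '", g, "' is not numeric")
    if (any(!is.finite(v)) || any(v < 0)) {
      stop("cell_map: negative or non-finite count in '", g, "'")
    }
    if (any(v != round(v))) stop("cell_map: non-integer count in '", g, "'")
  }
  structure(list(sample_id = sample_id,
                 cells = cells[, c(req, genes), drop = FALSE],
                 genes = genes, vocabulary = vocabulary),
            class = "cell_map")
}

#' @export
print.cell_map <- function(x, ...) {
  cat(sprintf("<cell_map '%s': %d cells, %d gene(s): %s>\n",
              x$sample_id, nrow(x$cells), length(x$genes),
              paste(utils::head(x$genes, 5), collapse = ", ")))
  invisible(x)
}

#' Read / write a cell table
#'
#' `read_cell_table()` loads a delimited cell table (columns `cell_id`, `x`,
#' `y`, `cell_type`, plus gene-count columns) into a validated [cell_map()].
#' Loading is lossless for counts and coordinates and never silently drops
#' rows: with `unknown_labels = "drop"` the rejected rows are attached as
#' attribute `rejected` and logged; the default is to fail.
#'
#' @param path File path (comma- or tab-delimited, inferred from the header).
#' @param vocabulary Allowed cell-type labels.
#' @param sample_id Sample identifier; default the file name without
#'   extension.
#' @param unknown_labels `"error"` (default) rejects the file on a label
#'   outside the vocabulary; `"drop"` removes those rows with a logged
#'   reason.
#' @return A `cell_map`.
#' @export
read_cell_table <- function(path, vocabulary = default_cell_vocabulary(),
                            sample_id = NULL,
                            unknown_labels = c("error", "drop")) {
  unknown_labels <- match.arg(unknown_labels)
  if (is.null(sample_id)) sample_id <- sub("\\.[^.]*$", "", basename(path))
  hdr <- readLines(path, n = 1L)
  sep <- if (grepl("\t", hdr)) "\t" else ","
  df <- utils::read.csv(path, sep = sep, stringsAsFactors = FALSE,
                        check.names = FALSE)
  for (col in c("cell_id", "x", "y", "cell_type")) {
    if (!col %in% names(df)) {
      stop("read_cell_table: missing required column '", col, "' in ", path)
    }
  }
  rejected <- df[0, ]
  if (unknown_labels == "drop") {
    bad <- !(df$cell_type %in% vocabulary)
    if (any(bad)) {
      rejected <- df[bad, , drop = FALSE]
      la_log("read_cell_table: dropped %d row(s) with labels outside vocabulary (%s)",
             sum(bad), paste(unique(df$cell_type[bad]), collapse = ", "))
      df <- df[!bad, , drop = FALSE]
    }
  }
  cm <- cell_map(df, sample_id = sample_id, vocabulary = vocabulary)
  attr(cm, "rejected") <- rejected
  cm
}

#' @rdname read_cell_table
#' @param cellmap A `cell_map`.
#' @param digits Decimal places written for coordinates (default 6).
#' @export
write_cell_table <- function(cellmap, path, digits = 6) {
  stopifnot(inherits(cellmap, "cell_map"))
  df <- cellmap$cells
  df$x <- formatC(df$x, format = "f", digits = digits)
  df$y <- formatC(df$y, format = "f", digits = digits)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read / write a sparse expression matrix
#'
#' MatrixMarket triplet matrix (genes x cells) with companion one-per-line
#' feature and cell-id text files, mirroring cell-feature-matrix exports.
#'
#' @param matrix_path Path to the `.mtx` triplet file.
#' @param features_path,cells_path One feature / cell id per line.
#' @return A list with `counts` (a `dgCMatrix`, genes x cells with
#'   dimnames), `features`, and `cells`.
#' @export
read_expression_matrix <- function(matrix_path, features_path, cells_path) {
  m <- Matrix::readMM(matrix_path)
  if (methods::is(m, "nMatrix")) { # pattern file (e.g. written with no entries)
    m <- methods::as(m, "dMatrix")
  }
  features <- readLines(features_path)
  cells <- readLines(cells_path)
  if (nrow(m) != length(features) || ncol(m) != length(cells)) {
    stop(sprintf(
      "read_expression_matrix: dimension mismatch: matrix %d x %d vs %d features, %d cells",
      nrow(m), ncol(m), length(features), length(cells)))
  }
  v <- m@x
  if (length(v) && (any(v < 0) || any(v != round(v)))) {
    stop("read_expression_matrix: counts must be non-negative integers")
  }
  m <- methods::as(m, "CsparseMatrix")
  dimnames(m) <- list(features, cells)
  list(counts = m, features = features, cells = cells)
}

#' @rdname read_expression_matrix
#' @param counts Sparse or dense genes x cells count matrix with dimnames.
#' @export
write_expression_matrix <- function(counts, matrix_path, features_path,
                                    cells_path) {
  m <- methods::as(methods::as(counts, "CsparseMatrix"), "generalMatrix")
  Matrix::writeMM(m, matrix_path)
  writeLines(rownames(counts), features_path)
  writeLines(colnames(counts), cells_path)
  invisible(matrix_path)
}

# close a ring for GeoJSON (first position repeated last)
.closed_coords <- function(polygon) {
  x <- c(polygon$x, polygon$x[1])
  y <- c(polygon$y, polygon$y[1])
  lapply(seq_along(x), function(i) c(x[i], y[i]))
}

#' Write detected LAs as GeoJSON
#'
#' Serializes LA boundary polygons as a GeoJSON FeatureCollection.
#' Coordinates stay in micrometres in the source frame (GeoJSON is used here
#' for its explicit ring-closure rules and tool support, not for geographic
#' positioning). Feature properties carry `la_id`, `area_um2`, per-type
#' counts and the PBR; the pipeline configuration is echoed under the
#' top-level `config` member for provenance.
#'
#' @param aggregates An `la_set` from [detect_lymphoid_aggregates()] or a
#'   list of LA records with `la_id`, `polygon`, `area_um2`, `n_by_type`.
#' @param path Output path.
#' @param config Optional `la_config` echoed into the file.
#' @return `path`, invisibly.
#' @export
write_la_geojson <- function(aggregates, path, config = NULL) {
  las <- if (inherits(aggregates, "la_set")) aggregates$aggregates else aggregates
  features <- lapply(las, function(la) {
    poly <- la$polygon
    if (is.null(poly) || length(poly$x) < 3L) {
      stop("write_la_geojson: invalid polygon for la_id ", la$la_id)
    }
    props <- list(la_id = la$la_id, area_um2 = la$area_um2)
    if (!is.null(la$n_by_type)) props <- c(props, as.list(la$n_by_type))
    if (!is.null(la$pbr)) props$pbr <- la$pbr
    list(type = "Feature",
         geometry = list(type = "Polygon",
                         coordinates = list(.closed_coords(poly))),
         properties = props)
  })
  obj <- list(type = "FeatureCollection", features = features)
  if (!is.null(config)) obj$config <- config_as_list(config)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Write a single polygon as GeoJSON
#'
#' @param polygon A `region_polygon`.
#' @param path Output path.
#' @param properties Named list of feature properties.
#' @return `path`, invisibly.
#' @export
write_region_geojson <- function(polygon, path, properties = list()) {
  stopifnot(inherits(polygon, "region_polygon"))
  if (!is.null(polygon$label) && is.null(properties$label)) {
    properties$label <- polygon$label
  }
  obj <- list(type = "FeatureCollection", features = list(list(
    type = "Feature",
    geometry = list(type = "Polygon",
                    coordinates = list(.closed_coords(polygon))),
    properties = properties)))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read polygons from GeoJSON
#'
#' Reads the outer ring of every Polygon feature in a FeatureCollection (or a
#' bare Feature / Polygon geometry) into [region_polygon()] objects.
#'
#' @param path GeoJSON file.
#' @return List of `region_polygon`s; feature properties are attached as
#'   attribute `properties`.
#' @export
read_geojson_polygons <- function(path) {
  obj <- jsonlite::read_json(path)
  feats <- switch(obj$type,
                  FeatureCollection = obj$features,
                  Feature = list(obj),
                  Polygon = list(list(geometry = obj, properties = list())),
                  stop("read_geojson_polygons: unsupported GeoJSON type '",
                       obj$type, "'"))
  lapply(feats, function(f) {
    g <- f$geometry
    if (g$type != "Polygon") {
      stop("read_geojson_polygons: unsupported geometry '", g$type, "'")
    }
    ring <- g$coordinates[[1]]
    x <- vapply(ring, function(p) as.numeric(p[[1]]), numeric(1))
    y <- vapply(ring, function(p) as.numeric(p[[2]]), numeric(1))
    label <- if (!is.null(f$properties$label)) f$properties$label else NULL
    p <- region_polygon(x, y, label = label)
    attr(p, "properties") <- f$properties
    p
  })
}
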