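# Cell-level preprocessing ahead of niche analysis: QC filtering,
# representative-cell subsampling, and low-confidence label filtering.

#' QC-filter cells on detected genes and total transcripts
#'
#' A cell is kept iff it has at least `min_genes` genes with count > 0 AND at
#' least `min_transcripts` total transcripts (both boundaries inclusive).
#'
#' @param counts Sparse or dense genes x cells count matrix with column
#'   names.
#' @param min_genes Minimum detected genes; default 10.
#' @param min_transcripts Minimum total transcripts; default 20.
#' @return List with `kept` and `rejected` cell-id character vectors (an
#'   exhaustive partition of the columns).
#' @export
#' @examples
#' m <- Matrix::Matrix(matrix(rpois(200, 2), 10, 20,
#'   dimnames = list(paste0("g", 1:10), paste0("c", 1:20))), sparse = TRUE)
#' qc_filter_cells(m, min_genes = 5, min_transcripts = 15)
qc_filter_cells <- function(counts, min_genes = 10, min_transcripts = 20) {
  stopifnot(min_genes >= 0, min_transcripts >= 0)
  if (is.null(colnames(counts))) stop("qc_filter_cells: counts need colnames")
  detected <- Matrix::colSums(counts > 0)
  total <- Matrix::colSums(counts)
  keep <- detected >= min_genes & total >= min_transcripts
  la_log("qc_filter_cells: kept %d of %d cells", sum(keep), length(keep))
  list(kept = colnames(counts)[keep], rejected = colnames(counts)[!keep])
}

# per-cell depth normalization to `scale_factor` counts, then log1p
normalize_log1p <- function(counts, scale_factor = 1e4) {
  total <- Matrix::colSums(counts)
  total[total == 0] <- 1
  sf <- scale_factor / total
  log1p(Matrix::t(Matrix::t(counts) * sf))
}

#' Select representative cells per cluster
#'
#' For each cluster, retains up to `n_max` cells whose expression profiles
#' are most similar to the cluster's mean profile. Similarity is Euclidean
#' distance on per-cell depth-normalized, log1p-transformed counts (the mean
#' is computed in the same transformed space); Pearson correlation distance
#' is available as an alternative. Ties are broken by cell id ascending, so
#' the selection is deterministic.
#'
#' @param counts Genes x cells count matrix with column names.
#' @param labels Cluster label per cell (same order as columns).
#' @param n_max Maximum cells retained per cluster; default 500.
#' @param method `"euclidean"` (default) or `"pearson"` (1 - correlation).
#' @param scale_factor Depth-normalization target; default 1e4.
#' @return Named list, one sorted character vector of selected cell ids per
#'   cluster.
#' @export
select_representative_cells <- function(counts, labels, n_max = 500,
                                        method = c("euclidean", "pearson"),
                                        scale_factor = 1e4) {
  method <- match.arg(method)
  stopifnot(length(labels) == ncol(counts), n_max >= 1)
  ids <- colnames(counts)
  if (is.null(ids)) stop("select_representative_cells: counts need colnames")
  norm <- normalize_log1p(counts, scale_factor)
  out <- list()
  for (cl in sort(unique(as.character(labels)))) {
    idx <- which(as.character(labels) == cl)
    if (!length(idx)) {
      la_log("select_representative_cells: empty cluster '%s' skipped", cl)
      next
    }
    sub <- as.matrix(norm[, idx, drop = FALSE])
    mu <- rowMeans(sub)
    d <- if (method == "euclidean") {
      sqrt(colSums((sub - mu)^2))
    } else {
      1 - suppressWarnings(as.numeric(cor(sub, mu)))
    }
    d[is.na(d)] <- Inf
    ord <- order(d, ids[idx])
    take <- ord[seq_len(min(n_max, length(ord)))]
    out[[cl]] <- sort(ids[idx][take])
  }
  out
}

#' Filter low-confidence cell labels
#'
#' Cells with a label-transfer prediction score strictly below `threshold`
#' are set to `"unassigned"`; cells at or above the threshold keep their
#' label. Unassigned cells are excluded from all downstream composition and
#' density denominators.
#'
#' @param labels Character vector of cell labels.
#' @param scores Numeric prediction scores in `[0, 1]`, same length; a
#'   missing (NA) score is an error.
#' @param threshold Default 0.6.
#' @return Character vector of labels with `"unassigned"` substituted.
#' @export
filter_low_confidence <- function(labels, scores, threshold = 0.6) {
  if (length(scores) != length(labels)) {
    stop("filter_low_confidence: labels and scores differ in length")
  }
  if (anyNA(scores)) {
    stop("filter_low_confidence: missing prediction score for ",
         sum(is.na(scores)), " cell(s)")
  }
  if (any(scores < 0 | scores > 1)) {
    stop("filter_low_confidence: scores must lie in [0, 1]")
  }
  out <- as.character(labels)
  out[scores < threshold] <- "unassigned"
  la_log("filter_low_confidence: %d of %d cells unassigned at threshold %g",
         sum(scores < threshold), length(scores), threshold)
  out
}
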