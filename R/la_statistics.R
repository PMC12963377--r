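# Statistics over detected lymphoid aggregates: the plasma-cell-to-B-cell
# ratio (PBR), compartment fractions and enrichment, per-LA subset densities
# and exhaustion log-ratios, and their association analyses (Spearman
# correlation + simple linear regression).

#' Plasma-cell-to-B-cell ratio (PBR)
#'
#' `log2(n_pc + 1) - log2(n_b + 1)`. Positive when an aggregate contains
#' more plasma cells than B cells ("high PBR"); antisymmetric under swapping
#' the arguments.
#'
#' @param n_pc,n_b Non-negative plasma-cell and B-cell counts (vectorized).
#' @return Numeric.
#' @export
#' @examples
#' pbr(3, 1)  # 1
#' pbr(0, 0)  # 0
pbr <- function(n_pc, n_b) {
  if (any(n_pc < 0) || any(n_b < 0)) stop("pbr: counts must be non-negative")
  log2(n_pc + 1) - log2(n_b + 1)
}

#' Compartment cell-type fractions inside vs outside LAs
#'
#' Relative fractions of each cell type among cells inside any LA (pooled
#' over all aggregates) and among cells outside all LAs. Cells labelled
#' `"unassigned"` are excluded from both denominators. Types can be combined
#' into super-groups (e.g. collapsing tumor subclusters) via `group_map`.
#' `mode = "per_la"` instead averages each type's within-LA fraction over
#' aggregates.
#'
#' @param cellmap A [cell_map()].
#' @param membership Membership data frame from [detect_lymphoid_aggregates()]
#'   (columns `cell_id`, `la_id`, NA = outside).
#' @param group_map Optional named character vector mapping cell types to
#'   group labels.
#' @param mode `"pooled"` (default) or `"per_la"`.
#' @return Object of class `compartment_fractions`: list with `inside`,
#'   `outside` (named fractions summing to 1), `n_inside`, `n_outside`.
#' @export
compartment_fractions <- function(cellmap, membership, group_map = NULL,
                                  mode = c("pooled", "per_la")) {
  mode <- match.arg(mode)
  stopifnot(inherits(cellmap, "cell_map"))
  cells <- cellmap$cells
  idx <- match(membership$cell_id, cells$cell_id)
  if (anyNA(idx)) stop("compartment_fractions: membership ids not in cellmap")
  type <- cells$cell_type[idx]
  if (!is.null(group_map)) {
    mapped <- !is.na(group_map[type])
    type[mapped] <- group_map[type[mapped]]
  }
  keep <- type != "unassigned"
  type <- type[keep]
  la <- membership$la_id[keep]
  lvls <- sort(unique(type))
  inside_n <- sum(!is.na(la)); outside_n <- sum(is.na(la))
  if (inside_n == 0L || outside_n == 0L) {
    stop("compartment_fractions: a compartment has zero cells; ",
         "fractions are undefined -- report as missing")
  }
  if (mode == "pooled") {
    fin <- table(factor(type[!is.na(la)], levels = lvls)) / inside_n
    fout <- table(factor(type[is.na(la)], levels = lvls)) / outside_n
    inside <- stats::setNames(as.numeric(fin), lvls)
    outside <- stats::setNames(as.numeric(fout), lvls)
  } else {
    per <- vapply(sort(unique(la[!is.na(la)])), function(k) {
      tt <- table(factor(type[!is.na(la) & la == k], levels = lvls))
      as.numeric(tt) / sum(tt)
    }, numeric(length(lvls)))
    inside <- stats::setNames(rowMeans(per), lvls)
    fout <- table(factor(type[is.na(la)], levels = lvls)) / outside_n
    outside <- stats::setNames(as.numeric(fout), lvls)
  }
  structure(list(inside = inside, outside = outside,
                 n_inside = inside_n, n_outside = outside_n, mode = mode),
            class = "compartment_fractions")
}

#' Cell-type enrichment score
#'
#' log2 ratio of the relative fractions of a cell type between two
#' compartments. With `pseudo = NULL` (default) the pseudocount is 0 when
#' both fractions are positive; when either fraction is 0 and compartment
#' totals are supplied, half of one cell over the smaller compartment total
#' is used (declared in the `pseudo` attribute of the result); without
#' totals the score is NA.
#'
#' @param frac_in,frac_out Relative fractions in `[0, 1]` (vectorized).
#' @param pseudo Pseudocount added to both fractions; `NULL` for the
#'   automatic rule.
#' @param n_in,n_out Compartment totals, used only by the automatic rule.
#' @return Numeric score(s) with attribute `pseudo`.
#' @export
#' @examples
#' enrichment_score(0.2, 0.05) # 2
enrichment_score <- function(frac_in, frac_out, pseudo = NULL,
                             n_in = NULL, n_out = NULL) {
  stopifnot(all(frac_in >= 0 & frac_in <= 1), all(frac_out >= 0 & frac_out <= 1))
  if (is.null(pseudo)) {
    zero <- frac_in == 0 | frac_out == 0
    pseudo <- if (any(zero)) {
      if (is.null(n_in) || is.null(n_out)) NA_real_
      else 0.5 / min(n_in, n_out)
    } else 0
  }
  out <- if (is.na(pseudo)) {
    ifelse(frac_in > 0 & frac_out > 0, log2(frac_in / frac_out), NA_real_)
  } else {
    log2((frac_in + pseudo) / (frac_out + pseudo))
  }
  attr(out, "pseudo") <- pseudo
  out
}

#' Per-aggregate immune profiles
#'
#' One row per LA: area, per-type counts, PBR, per-type densities
#' (cells/mm^2 = count / area_um2 * 1e6), the exhaustion log-ratio
#' `log2((n_TEX + 1) / (n_PEX + 1))` (pseudocounts mirroring the PBR), and
#' the high-PBR flag (`pbr > 0`, i.e. more plasma cells than B cells).
#' Densities use raw counts; pseudocounts appear only inside log-ratios.
#'
#' @param la_set An `la_set` from [detect_lymphoid_aggregates()], or a list
#'   of aggregate records with `la_id`, `area_um2`, `n_by_type`.
#' @param pc_type,b_type,tex_type,pex_type Vocabulary labels for plasma
#'   cells, B cells, and the terminally / progenitor exhausted T subsets.
#' @return Data frame of class `la_profiles` with columns `la_id`,
#'   `area_um2`, `n_<type>`, `pbr`, `density_<type>`, `log2_tex_pex`,
#'   `high_pbr`.
#' @export
la_profiles <- function(la_set, pc_type = "PC", b_type = "B",
                        tex_type = "T_TEX", pex_type = "T_PEX") {
  las <- if (inherits(la_set, "la_set")) la_set$aggregates else la_set
  if (!length(las)) {
    return(structure(data.frame(la_id = integer(0)),
                     class = c("la_profiles", "data.frame")))
  }
  areas <- vapply(las, `[[`, numeric(1), "area_um2")
  if (any(areas <= 0)) stop("la_profiles: zero or negative LA area")
  types <- names(las[[1]]$n_by_type)
  cnt <- vapply(las, function(a) as.numeric(a$n_by_type[types]),
                numeric(length(types)))
  cnt <- matrix(cnt, nrow = length(types),
                dimnames = list(types, NULL))
  dens <- sweep(cnt, 2, areas, "/") * 1e6
  df <- data.frame(la_id = vapply(las, `[[`, integer(1), "la_id"),
                   area_um2 = areas)
  for (tp in types) df[[paste0("n_", tp)]] <- cnt[tp, ]
  df$pbr <- pbr(cnt[pc_type, ], cnt[b_type, ])
  for (tp in types) df[[paste0("density_", tp)]] <- dens[tp, ]
  df$log2_tex_pex <- log2(cnt[tex_type, ] + 1) - log2(cnt[pex_type, ] + 1)
  df$high_pbr <- df$pbr > 0
  class(df) <- c("la_profiles", "data.frame")
  df
}

# Spearman correlation: average ranks for ties; two-sided p from the
# t-approximation, exact permutation enumeration for n <= exact_n_max.
spearman_assoc <- function(x, y, exact_n_max = 9L) {
  n <- length(x)
  stopifnot(length(y) == n)
  if (n < 3L) stop("spearman_assoc: need at least 3 observations")
  rx <- rank(x); ry <- rank(y)
  if (sd(rx) == 0 || sd(ry) == 0) {
    return(list(rho = NA_real_, p = NA_real_, n = n, method = "undefined"))
  }
  rho <- cor(rx, ry)
  if (n <= exact_n_max) {
    perms <- .all_permutations(n)
    # correlation of rx with every permutation of ry, via the cross-product
    ryp <- matrix(ry[t(perms)], nrow = n) # column k = ry[perms[k, ]]
    S <- as.vector(rx %*% ryp)
    rho_null <- (S - n * mean(rx) * mean(ry)) / ((n - 1) * sd(rx) * sd(ry))
    p <- mean(abs(rho_null) >= abs(rho) - 1e-12)
    method <- "exact permutation"
  } else {
    tt <- rho * sqrt((n - 2) / (1 - rho^2))
    p <- 2 * stats::pt(-abs(tt), df = n - 2)
    p <- min(1, max(p, .Machine$double.xmin))
    method <- "t approximation"
  }
  list(rho = rho, p = p, n = n, method = method)
}

# all permutations of 1..n as a matrix (n! rows); n <= 9
.all_permutations <- function(n) {
  if (n == 1L) return(matrix(1L, 1, 1))
  sub <- .all_permutations(n - 1L)
  out <- matrix(0L, nrow(sub) * n, n)
  r <- 0L
  for (pos in seq_len(n)) {
    blk <- cbind(sub[, seq_len(pos - 1L), drop = FALSE], n,
                 sub[, seq(pos, n - 1L)[seq_len(n - pos)], drop = FALSE])
    out[r + seq_len(nrow(sub)), ] <- blk
    r <- r + nrow(sub)
  }
  out
}

#' Associate the PBR with a per-aggregate response
#'
#' Spearman non-parametric correlation (average ranks for ties; two-sided p
#' from the t-approximation, exact permutation for n <= 9) plus a simple
#' least-squares regression of the response on the PBR for the trend line.
#'
#' @param profiles An [la_profiles()] data frame (or any data frame with a
#'   `pbr` column).
#' @param response Name of the response column (e.g. `"density_T_TEX"`,
#'   `"log2_tex_pex"`), or a numeric vector of the same length.
#' @return Object of class `la_association`: `spearman_rho`, `spearman_p`,
#'   `ls_slope`, `ls_intercept`, `slope_p`, `n`, `method`.
#' @export
#' @examples
#' prof <- data.frame(pbr = 1:10, d = (1:10) * 2 + rnorm(10, 0, 0.1))
#' associate_pbr(prof, "d")
associate_pbr <- function(profiles, response) {
  y <- if (is.character(response)) {
    if (!response %in% names(profiles)) {
      stop("associate_pbr: no column '", response, "'")
    }
    profiles[[response]]
  } else response
  x <- profiles$pbr
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  if (length(x) < 3L) stop("associate_pbr: need at least 3 aggregates")
  sp <- spearman_assoc(x, y)
  fit <- stats::lm(y ~ x)
  cf <- stats::coef(fit)
  sm <- suppressWarnings(summary(fit)$coefficients) # exact fits are legal input
  slope_p <- if (nrow(sm) > 1L) sm[2, 4] else NA_real_
  structure(list(spearman_rho = sp$rho, spearman_p = sp$p,
                 ls_slope = unname(cf[2]), ls_intercept = unname(cf[1]),
                 slope_p = slope_p, n = length(x), method = sp$method),
            class = "la_association")
}

#' @export
print.la_association <- function(x, ...) {
  cat(sprintf("Spearman rho = %.3f (p = %.4g, %s), LS slope = %.3f, intercept = %.3f, n = %d\n",
              x$spearman_rho, x$spearman_p, x$method, x$ls_slope,
              x$ls_intercept, x$n))
  invisible(x)
}

#' Inside-vs-outside exhaustion ratios per patient
#'
#' For each patient, pools T_TEX and T_PEX counts over all that patient's LA
#' member cells (inside) and over all non-LA cells (outside), and computes
#' the +1-pseudocount log2 T_TEX:T_PEX ratio in each compartment (counts
#' within one compartment share its area, so the count ratio equals the
#' density ratio). Patients without any LA are excluded with a log entry;
#' association across patients uses the same Spearman + least-squares
#' machinery as [associate_pbr()].
#'
#' @param samples Named list, one entry per patient:
#'   `list(cellmap =, membership =)` (membership as from
#'   [detect_lymphoid_aggregates()]).
#' @param tex_type,pex_type Subset labels.
#' @return List with `pairs` (data frame patient, inside, outside) and
#'   `association` (an `la_association` of inside on outside).
#' @export
inside_outside_patient_ratio <- function(samples, tex_type = "T_TEX",
                                         pex_type = "T_PEX") {
  rows <- list()
  for (nm in names(samples)) {
    s <- samples[[nm]]
    cells <- s$cellmap$cells
    memb <- if (inherits(s$membership, "la_set")) s$membership$membership
            else s$membership
    idx <- match(memb$cell_id, cells$cell_id)
    type <- cells$cell_type[idx]
    ins <- !is.na(memb$la_id)
    if (!any(ins)) {
      la_log("inside_outside_patient_ratio: patient '%s' has no LAs; excluded", nm)
      next
    }
    n_tex_in <- sum(type[ins] == tex_type); n_pex_in <- sum(type[ins] == pex_type)
    n_tex_out <- sum(type[!ins] == tex_type); n_pex_out <- sum(type[!ins] == pex_type)
    rows[[length(rows) + 1L]] <- data.frame(
      patient = nm,
      inside = log2(n_tex_in + 1) - log2(n_pex_in + 1),
      outside = log2(n_tex_out + 1) - log2(n_pex_out + 1),
      stringsAsFactors = FALSE)
  }
  if (length(rows) < 3L) {
    stop("inside_outside_patient_ratio: need at least 3 patients with LAs")
  }
  pairs <- do.call(rbind, rows)
  assoc <- associate_pbr(data.frame(pbr = pairs$outside), pairs$inside)
  list(pairs = pairs, association = assoc)
}
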