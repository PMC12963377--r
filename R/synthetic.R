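# Synthetic-data generators with planted ground truth: spatial tissues with
# lymphoid aggregates, IHC marker-centroid slides, sparse expression
# matrices, and a clinical cohort. Every generator is deterministic under its
# seed.

#' Parameters for the spatial tissue simulator
#'
#' Defaults describe a resected-tumor section the analysis assumes: a
#' rectangular tissue with uniformly scattered background cells, a handful of
#' planted lymphoid aggregates (discs) whose cellular composition is drawn
#' from a Dirichlet prior over the cell-type vocabulary, chemokine organizer
#' cells (CCL19+/CXCL13+) concentrated inside each aggregate, Poisson stray
#' chemokine-positive singletons, and a planted linear coupling between each
#' aggregate's PBR and its log2 T_TEX:T_PEX count ratio.
#'
#' @param width,height Tissue extent (um).
#' @param n_background Number of background (outside-LA) cells.
#' @param background_type_probs Named probabilities over the vocabulary for
#'   background cell types (must sum to 1 within 1e-9).
#' @param n_las Number of planted aggregates.
#' @param la_radius_mean,la_radius_sd Disc radius distribution (um).
#' @param min_la_separation Minimum center-to-center distance (um).
#' @param la_composition_dirichlet Named Dirichlet concentrations for the
#'   per-aggregate type composition.
#' @param n_cells_per_la Mean member-cell count per aggregate (Poisson).
#' @param n_ccl19_per_la,n_cxcl13_per_la Organizer cells per aggregate given
#'   CCL19 (resp. CXCL13) counts >= 1, all inside the disc.
#' @param chemokine_noise_rate Expected stray chemokine-positive singleton
#'   cells per mm^2.
#' @param pbr_effect_beta0,pbr_effect_beta1,pbr_effect_sigma Planted
#'   exhaustion coupling: per LA the target log2 T_TEX:T_PEX ratio is
#'   `beta0 + beta1 * PBR + Normal(0, sigma)`.
#' @param outside_log2_tex_pex Target log2 T_TEX:T_PEX probability ratio in
#'   the background compartment (the TEX+PEX probability mass in
#'   `background_type_probs` is re-split to match); used to give patients a
#'   shared exhaustion tone inside and outside aggregates.
#' @param strict_recovery Logical; when TRUE, requires
#'   `min_la_separation > 2 * (la_radius_mean + hull_buffer)` so that planted
#'   discs plus their buffers cannot overlap.
#' @param hull_buffer Buffer (um) used only for the strict-recovery
#'   feasibility check.
#' @param seed Integer seed.
#' @return An object of class `tissue_sim_params`.
#' @export
tissue_sim_params <- function(width = 9000, height = 7000,
                              n_background = 4000,
                              background_type_probs = c(
                                tumor = 0.40, fibroblast = 0.20,
                                myeloid = 0.12, endothelial = 0.05,
                                B = 0.03, PC = 0.03,
                                T_TEX = 0.04, T_PEX = 0.04, T_CM = 0.04,
                                T_RM = 0.02, T_REG = 0.02, other = 0.01),
                              n_las = 10,
                              la_radius_mean = 100, la_radius_sd = 10,
                              min_la_separation = 800,
                              la_composition_dirichlet = c(
                                B = 8, PC = 6,
                                T_TEX = 2, T_PEX = 2, T_CM = 2, T_RM = 1,
                                T_REG = 1, T_FH = 1, T_ORG = 1, T_PRO = 0.5,
                                myeloid = 2, fibroblast = 2, tumor = 1,
                                endothelial = 0.5),
                              n_cells_per_la = 400,
                              n_ccl19_per_la = 60, n_cxcl13_per_la = 60,
                              chemokine_noise_rate = 0.5,
                              pbr_effect_beta0 = 0, pbr_effect_beta1 = 1,
                              pbr_effect_sigma = 0.25,
                              outside_log2_tex_pex = 0,
                              strict_recovery = FALSE,
                              hull_buffer = 100,
                              seed = 1) {
  p <- as.list(environment())
  if (abs(sum(p$background_type_probs) - 1) > 1e-9) {
    stop("tissue_sim_params: background_type_probs must sum to 1")
  }
  if (any(p$background_type_probs < 0)) {
    stop("tissue_sim_params: negative type probability")
  }
  if (p$n_las < 0) stop("tissue_sim_params: n_las must be >= 0")
  if (any(p$la_composition_dirichlet <= 0)) {
    stop("tissue_sim_params: Dirichlet concentrations must be positive")
  }
  if (p$strict_recovery &&
      p$min_la_separation <= 2 * (p$la_radius_mean + p$hull_buffer)) {
    stop("tissue_sim_params: strict recovery requires min_la_separation > ",
         "2 * (la_radius_mean + hull_buffer)")
  }
  class(p) <- "tissue_sim_params"
  p
}

# split a TEX+PEX probability mass to a target log2 ratio
.split_tex_pex <- function(probs, target_log2) {
  s <- sum(probs[c("T_TEX", "T_PEX")])
  if (s <= 0) return(probs)
  rho <- 2^target_log2
  probs["T_TEX"] <- s * rho / (1 + rho)
  probs["T_PEX"] <- s / (1 + rho)
  probs
}

# sequential random placement of n centers with minimum separation
.place_centers <- function(n, width, height, margin, min_sep,
                           max_tries = 5000L * max(1L, n)) {
  cx <- numeric(0); cy <- numeric(0)
  tries <- 0L
  while (length(cx) < n && tries < max_tries) {
    tries <- tries + 1L
    x <- runif(1, margin, width - margin)
    y <- runif(1, margin, height - margin)
    if (!length(cx) || all((cx - x)^2 + (cy - y)^2 >= min_sep^2)) {
      cx <- c(cx, x); cy <- c(cy, y)
    }
  }
  if (length(cx) < n) {
    stop("generate_tissue: could not place ", n, " centers with separation ",
         min_sep, " um in ", width, " x ", height, " um after ", max_tries,
         " tries")
  }
  cbind(x = cx, y = cy)
}

# draw one LA's per-type counts with the planted PBR -> log2(TEX:PEX)
# coupling applied on counts: T_PEX is drawn, then T_TEX is set to match the
# targeted log2 ratio with +1 pseudocounts, rounded to the nearest integer.
.draw_la_counts <- function(types, conc, n_mean, beta0, beta1, sigma) {
  n <- rpois(1, n_mean)
  g <- rgamma(length(conc), shape = conc)
  p <- g / sum(g)
  cnt <- stats::setNames(as.integer(rmultinom(1, n, p)), names(conc))
  full <- stats::setNames(integer(length(types)), types)
  full[names(cnt)] <- cnt
  pbr_true <- log2(full["PC"] + 1) - log2(full["B"] + 1)
  target <- beta0 + beta1 * pbr_true + rnorm(1, 0, sigma)
  full["T_TEX"] <- max(0L, as.integer(round((full["T_PEX"] + 1) * 2^target - 1)))
  full
}

#' Generate a synthetic spatial tissue with planted lymphoid aggregates
#'
#' Background cells are uniform on the rectangle with types drawn from
#' `background_type_probs`; each aggregate places its members uniformly in a
#' disc around its center with types from a Dirichlet-sampled composition;
#' organizer cells inside the disc receive CCL19 (resp. CXCL13) counts >= 1;
#' stray chemokine-positive singletons are scattered as a Poisson process.
#' For each aggregate the log2 T_TEX:T_PEX count ratio is targeted to
#' `beta0 + beta1 * PBR + Normal(0, sigma)` (see [tissue_sim_params()]).
#' Identical seeds give identical output.
#'
#' @param params A [tissue_sim_params()] object.
#' @return A list with `cellmap` (a [cell_map()] carrying CCL19/CXCL13
#'   counts) and `truth` (class `synthetic_truth`: `la_centers` data frame
#'   with radii, `la_members` id sets, `la_counts` type x LA count matrix,
#'   the coupling coefficients, and the parameters).
#' @export
#' @examples
#' tg <- generate_tissue(tissue_sim_params(n_las = 2, n_background = 200,
#'                                         n_cells_per_la = 80, seed = 7))
#' tg$cellmap
generate_tissue <- function(params) {
  stopifnot(inherits(params, "tissue_sim_params"))
  p <- params
  set.seed(p$seed)
  vocab <- default_cell_vocabulary()
  stopifnot(all(names(p$background_type_probs) %in% vocab),
            all(names(p$la_composition_dirichlet) %in% vocab))

  margin <- p$la_radius_mean + 3 * p$la_radius_sd
  centers <- if (p$n_las > 0) {
    .place_centers(p$n_las, p$width, p$height, margin, p$min_la_separation)
  } else {
    matrix(numeric(0), 0, 2, dimnames = list(NULL, c("x", "y")))
  }
  radii <- if (p$n_las > 0) {
    pmax(20, rnorm(p$n_las, p$la_radius_mean, p$la_radius_sd))
  } else numeric(0)

  all_rows <- list()
  la_members <- vector("list", p$n_las)
  la_counts <- matrix(0L, length(vocab), p$n_las,
                      dimnames = list(vocab, NULL))
  for (i in seq_len(p$n_las)) {
    cnt <- .draw_la_counts(vocab, p$la_composition_dirichlet,
                           p$n_cells_per_la,
                           p$pbr_effect_beta0, p$pbr_effect_beta1,
                           p$pbr_effect_sigma)
    la_counts[, i] <- cnt
    n <- sum(cnt)
    types <- sample(rep(names(cnt), times = cnt))
    r <- radii[i] * sqrt(runif(n))
    th <- runif(n, 0, 2 * pi)
    ids <- sprintf("la%02d_c%04d", i, seq_len(n))
    ccl19 <- integer(n); cxcl13 <- integer(n)
    k1 <- min(p$n_ccl19_per_la, n); k2 <- min(p$n_cxcl13_per_la, n)
    if (k1 > 0) ccl19[sample.int(n, k1)] <- 1L + rpois(k1, 2)
    if (k2 > 0) cxcl13[sample.int(n, k2)] <- 1L + rpois(k2, 2)
    all_rows[[length(all_rows) + 1L]] <- data.frame(
      cell_id = ids,
      x = centers[i, 1] + r * cos(th), y = centers[i, 2] + r * sin(th),
      cell_type = types, CCL19 = ccl19, CXCL13 = cxcl13,
      stringsAsFactors = FALSE)
    la_members[[i]] <- ids
  }

  bg_probs <- .split_tex_pex(p$background_type_probs, p$outside_log2_tex_pex)
  if (p$n_background > 0) {
    nb <- p$n_background
    all_rows[[length(all_rows) + 1L]] <- data.frame(
      cell_id = sprintf("bg_%05d", seq_len(nb)),
      x = runif(nb, 0, p$width), y = runif(nb, 0, p$height),
      cell_type = sample(names(bg_probs), nb, replace = TRUE,
                         prob = bg_probs),
      CCL19 = integer(nb), CXCL13 = integer(nb), stringsAsFactors = FALSE)
  }

  area_mm2 <- p$width * p$height / 1e6
  n_noise <- if (p$chemokine_noise_rate > 0) {
    rpois(1, p$chemokine_noise_rate * area_mm2)
  } else 0L
  if (n_noise > 0) {
    which_gene <- runif(n_noise) < 0.5
    all_rows[[length(all_rows) + 1L]] <- data.frame(
      cell_id = sprintf("nx_%04d", seq_len(n_noise)),
      x = runif(n_noise, 0, p$width), y = runif(n_noise, 0, p$height),
      cell_type = sample(names(bg_probs), n_noise, replace = TRUE,
                         prob = bg_probs),
      CCL19 = ifelse(which_gene, 1L + rpois(n_noise, 1), 0L),
      CXCL13 = ifelse(which_gene, 0L, 1L + rpois(n_noise, 1)),
      stringsAsFactors = FALSE)
  }

  cells <- if (length(all_rows)) do.call(rbind, all_rows) else data.frame(
    cell_id = character(0), x = numeric(0), y = numeric(0),
    cell_type = character(0), CCL19 = integer(0), CXCL13 = integer(0))
  cm <- cell_map(cells, sample_id = sprintf("sim_seed%d", p$seed))
  truth <- structure(list(
    la_centers = data.frame(x = centers[, 1], y = centers[, 2],
                            radius = radii),
    la_members = la_members,
    la_counts = la_counts,
    beta0 = p$pbr_effect_beta0, beta1 = p$pbr_effect_beta1,
    sigma = p$pbr_effect_sigma,
    params = p), class = "synthetic_truth")
  list(cellmap = cm, truth = truth)
}

#' Simulate per-aggregate counts with the planted exhaustion coupling
#'
#' Count-level companion to [generate_tissue()]: draws per-aggregate type
#' counts (Dirichlet-multinomial) and applies the PBR to log2 T_TEX:T_PEX
#' coupling, without placing cells in space. Used for parameter-recovery
#' simulations where only the counts matter.
#'
#' @param n_las Number of aggregates.
#' @param params A [tissue_sim_params()] providing composition and coupling
#'   parameters (its `n_las` field is ignored).
#' @param seed Optional seed (defaults to `params$seed`).
#' @return Integer matrix, type x aggregate.
#' @export
simulate_la_counts <- function(n_las, params = tissue_sim_params(),
                               seed = params$seed) {
  if (!is.null(seed)) set.seed(seed)
  vocab <- default_cell_vocabulary()
  out <- matrix(0L, length(vocab), n_las, dimnames = list(vocab, NULL))
  for (i in seq_len(n_las)) {
    out[, i] <- .draw_la_counts(vocab, params$la_composition_dirichlet,
                                params$n_cells_per_la,
                                params$pbr_effect_beta0,
                                params$pbr_effect_beta1,
                                params$pbr_effect_sigma)
  }
  out
}

#' Generate a synthetic IHC slide
#'
#' Emits a boolean marker-centroid table (CD20, CD3, CD4, CD8, CD23, MUM1),
#' a tumor-bed polygon, and ground truth. Each planted IHC aggregate places
#' its configured CD20+ members in a disc and a CD3+ cluster immediately
#' around it; MUM1+ plasma cells are scattered inside the tumor bed as a
#' Poisson process at `mum1_density`.
#'
#' @param las Data frame with one row per planted aggregate: columns
#'   `n_cd20`, `n_cd3`, `n_cd23`, `n_mum1`, `intra` (logical: place inside
#'   the tumor bed).
#' @param width,height Slide extent (um).
#' @param tumor_bed A `region_polygon`; default a centered rectangle covering
#'   a quarter of the slide.
#' @param la_radius Disc radius (um) for planted CD20 clusters; default 100.
#' @param mum1_density Scattered MUM1+ density inside the tumor bed
#'   (cells/mm^2); default 50.
#' @param min_separation Minimum distance between planted centers (um).
#' @param seed Integer seed.
#' @return List with `table` (the centroid data frame), `tumor_bed`, and
#'   `truth` (centers, per-LA CD20 member ids, intra flags).
#' @export
generate_ihc_slide <- function(las = data.frame(n_cd20 = c(80, 70),
                                                n_cd3 = c(40, 30),
                                                n_cd23 = c(5, 0),
                                                n_mum1 = c(10, 5),
                                                intra = c(TRUE, FALSE)),
                               width = 6000, height = 4000,
                               tumor_bed = NULL,
                               la_radius = 100,
                               mum1_density = 50,
                               min_separation = 800,
                               seed = 1) {
  set.seed(seed)
  if (is.null(tumor_bed)) {
    tumor_bed <- region_polygon(
      c(width * 0.25, width * 0.75, width * 0.75, width * 0.25),
      c(height * 0.25, height * 0.25, height * 0.75, height * 0.75),
      label = "tumor_bed")
  }
  n_la <- nrow(las)
  centers <- matrix(NA_real_, n_la, 2)
  for (i in seq_len(n_la)) {
    ok <- FALSE
    for (try in seq_len(20000L)) {
      x <- runif(1, la_radius, width - la_radius)
      y <- runif(1, la_radius, height - la_radius)
      inside <- point_in_polygon(x, y, tumor_bed)
      clear_margin <- dist_to_polygon(x, y, tumor_bed) > la_radius + 50 ||
        (inside && .depth_in_polygon(x, y, tumor_bed) > la_radius + 50)
      sep_ok <- i == 1L ||
        all((centers[seq_len(i - 1L), 1] - x)^2 +
            (centers[seq_len(i - 1L), 2] - y)^2 >= min_separation^2,
            na.rm = TRUE)
      if (inside == las$intra[i] && clear_margin && sep_ok) {
        centers[i, ] <- c(x, y); ok <- TRUE; break
      }
    }
    if (!ok) stop("generate_ihc_slide: could not place aggregate ", i)
  }

  rows <- list()
  truth_members <- vector("list", n_la)
  emit <- function(n, cx, cy, rad, marker) {
    if (n <= 0) return(NULL)
    r <- rad * sqrt(runif(n)); th <- runif(n, 0, 2 * pi)
    df <- data.frame(x = cx + r * cos(th), y = cy + r * sin(th),
                     cd20 = FALSE, cd3 = FALSE, cd4 = FALSE, cd8 = FALSE,
                     cd23 = FALSE, mum1 = FALSE)
    df[[marker]] <- TRUE
    df
  }
  for (i in seq_len(n_la)) {
    cx <- centers[i, 1]; cy <- centers[i, 2]
    d20 <- emit(las$n_cd20[i], cx, cy, la_radius, "cd20")
    d3 <- emit(las$n_cd3[i], cx, cy, la_radius * 1.2, "cd3")
    if (!is.null(d3) && nrow(d3)) { # CD4/CD8 sublineages of the CD3 cluster
      half <- runif(nrow(d3)) < 0.5
      d3$cd4 <- half; d3$cd8 <- !half
    }
    d23 <- emit(las$n_cd23[i], cx, cy, la_radius, "cd23")
    m1 <- emit(las$n_mum1[i], cx, cy, la_radius, "mum1")
    blk <- rbind(d20, d3, d23, m1)
    blk$planted_la <- i
    rows[[length(rows) + 1L]] <- blk
  }
  bed_bb <- c(range(tumor_bed$x), range(tumor_bed$y))
  bed_area_mm2 <- tumor_bed$area / 1e6
  n_m <- rpois(1, mum1_density * bed_area_mm2)
  got <- 0L
  while (got < n_m) {
    need <- (n_m - got) * 3L + 10L
    xx <- runif(need, bed_bb[1], bed_bb[2])
    yy <- runif(need, bed_bb[3], bed_bb[4])
    keep <- point_in_polygon(xx, yy, tumor_bed)
    xx <- xx[keep][seq_len(min(sum(keep), n_m - got))]
    yy <- yy[keep][seq_len(length(xx))]
    if (length(xx)) {
      rows[[length(rows) + 1L]] <- data.frame(
        x = xx, y = yy, cd20 = FALSE, cd3 = FALSE, cd4 = FALSE,
        cd8 = FALSE, cd23 = FALSE, mum1 = TRUE, planted_la = NA_integer_)
      got <- got + length(xx)
    }
  }
  tab <- do.call(rbind, rows)
  tab <- cbind(cell_id = sprintf("ihc_%05d", seq_len(nrow(tab))), tab)
  for (i in seq_len(n_la)) {
    truth_members[[i]] <- tab$cell_id[!is.na(tab$planted_la) &
                                      tab$planted_la == i & tab$cd20]
  }
  tab$planted_la <- NULL
  rownames(tab) <- NULL
  list(table = tab, tumor_bed = tumor_bed,
       truth = list(centers = data.frame(x = centers[, 1], y = centers[, 2]),
                    radius = la_radius,
                    cd20_members = truth_members,
                    intra = las$intra,
                    mum1_density = mum1_density))
}

# depth of an interior point: distance to the polygon boundary
.depth_in_polygon <- function(px, py, polygon) {
  x <- polygon$x; y <- polygon$y
  m <- length(x); d2 <- Inf; j <- m
  for (i in seq_len(m)) {
    dx <- x[j] - x[i]; dy <- y[j] - y[i]
    L2 <- dx * dx + dy * dy
    tt <- if (L2 > 0) min(1, max(0, ((px - x[i]) * dx + (py - y[i]) * dy) / L2)) else 0
    d2 <- min(d2, (px - (x[i] + tt * dx))^2 + (py - (y[i] + tt * dy))^2)
    j <- i
  }
  sqrt(d2)
}

#' Generate a synthetic expression matrix with planted clusters
#'
#' Counts are Poisson with per-cluster gene means; returns the sparse matrix
#' and the true cluster labels. Fixture generator for the QC /
#' representative-cell stages.
#'
#' @param n_genes Number of genes.
#' @param cluster_spec List of clusters, each `list(size =, means =)` with
#'   `means` of length `n_genes` (recycled if scalar).
#' @param seed Integer seed.
#' @return List with `counts` (dgCMatrix, genes x cells), `labels` (integer
#'   per cell).
#' @export
generate_expression_matrix <- function(n_genes, cluster_spec, seed = 1) {
  set.seed(seed)
  sizes <- vapply(cluster_spec, function(cs) as.integer(cs$size), integer(1))
  n_cells <- sum(sizes)
  blocks <- lapply(cluster_spec, function(cs) {
    mu <- rep_len(cs$means, n_genes)
    matrix(rpois(n_genes * cs$size, mu), nrow = n_genes)
  })
  dense <- if (n_cells > 0) do.call(cbind, blocks) else
    matrix(0L, n_genes, 0)
  counts <- methods::as(Matrix::Matrix(dense, sparse = TRUE), "CsparseMatrix")
  dimnames(counts) <- list(sprintf("g%04d", seq_len(n_genes)),
                           if (n_cells > 0) sprintf("cell_%05d", seq_len(n_cells))
                           else character(0))
  labels <- rep(seq_along(sizes), times = sizes)
  list(counts = counts, labels = labels)
}
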