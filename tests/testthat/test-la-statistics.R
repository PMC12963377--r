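test_that("PBR identities and antisymmetry", {
  expect_equal(pbr(0, 0), 0)
  expect_equal(pbr(3, 1), 1)
  expect_equal(pbr(15, 3), 2)
  expect_equal(pbr(3, 15), -2)
  for (a in c(0, 2, 7, 100)) for (b in c(0, 1, 9)) {
    expect_equal(pbr(a, b), -pbr(b, a))
  }
  expect_error(pbr(-1, 0), "non-negative")
})

test_that("compartment fractions pool counts and match a recount", {
  df <- data.frame(cell_id = sprintf("c%02d", 1:10),
                   x = 1:10, y = 1:10,
                   cell_type = c(rep("B", 3), rep("T_TEX", 7)))
  memb <- data.frame(cell_id = df$cell_id,
                     la_id = c(rep(1L, 5), rep(NA, 5)))
  fr <- compartment_fractions(cell_map(df), memb)
  expect_equal(unname(fr$inside["B"]), 0.6)   # 3 of 5 inside
  expect_equal(unname(fr$inside["T_TEX"]), 0.4)
  expect_equal(sum(fr$inside), 1)
  expect_equal(sum(fr$outside), 1)
  expect_equal(unname(fr$outside["T_TEX"]), 1)

  # all one type: fraction 1 in both compartments
  df1 <- df; df1$cell_type <- "B"
  fr1 <- compartment_fractions(cell_map(df1), memb)
  expect_equal(unname(fr1$inside["B"]), 1)
  expect_equal(unname(fr1$outside["B"]), 1)

  # zero cells in a compartment is an explicit error
  memb_all <- data.frame(cell_id = df$cell_id, la_id = 1L)
  expect_error(compartment_fractions(cell_map(df), memb_all), "undefined")

  # synthetic tissue: fractions equal an exhaustive recount
  tg <- generate_tissue(tissue_sim_params(n_las = 2, n_background = 500,
                                          width = 4000, height = 4000,
                                          n_cells_per_la = 150, seed = 51))
  las <- detect_lymphoid_aggregates(tg$cellmap)
  fr2 <- compartment_fractions(tg$cellmap, las$membership)
  cells <- tg$cellmap$cells
  ins <- cells$cell_id %in% unlist(lapply(las$aggregates, `[[`, "cell_ids"))
  for (tp in names(fr2$inside)) {
    expect_equal(unname(fr2$inside[tp]),
                 sum(cells$cell_type[ins] == tp) / sum(ins))
    expect_equal(unname(fr2$outside[tp]),
                 sum(cells$cell_type[!ins] == tp) / sum(!ins))
  }

  # super-groups: T subsets collapse into one bucket
  gm <- c(T_TEX = "T", T_PEX = "T", T_CM = "T", T_RM = "T", T_REG = "T",
          T_FH = "T", T_ORG = "T", T_PRO = "T")
  fr3 <- compartment_fractions(tg$cellmap, las$membership, group_map = gm)
  expect_false(any(grepl("T_", names(fr3$inside))))
  expect_equal(sum(fr3$inside), 1)

  # fractions are invariant to cell-row order
  perm <- sample(nrow(cells))
  cm_p <- cell_map(cells[perm, ])
  fr4 <- compartment_fractions(cm_p, las$membership[perm, ])
  expect_equal(fr4$inside, fr2$inside)
})

test_that("enrichment scores follow the log2 fraction ratio", {
  expect_equal(as.numeric(enrichment_score(0.3, 0.3)), 0)
  expect_equal(as.numeric(enrichment_score(0.2, 0.05)), 2)
  expect_equal(as.numeric(enrichment_score(0.05, 0.2)), -2)
  # antisymmetry whenever pseudo = 0
  set.seed(52)
  for (rep in 1:20) {
    a <- runif(1, 0.01, 1); b <- runif(1, 0.01, 1)
    expect_equal(as.numeric(enrichment_score(a, b)),
                 -as.numeric(enrichment_score(b, a)))
  }
  # zero fraction without totals is missing; with totals uses half a cell
  expect_true(is.na(enrichment_score(0, 0.2)))
  sc <- enrichment_score(0, 0.2, n_in = 100, n_out = 400)
  expect_equal(attr(sc, "pseudo"), 0.5 / 100)
  expect_equal(as.numeric(sc), log2(0.005 / 0.205))
})

test_that("LA profiles compute densities, ratios and flags", {
  mk_la <- function(id, area, counts) {
    list(la_id = id, area_um2 = area, n_by_type = counts)
  }
  vocab_counts <- function(...) {
    out <- setNames(integer(length(default_cell_vocabulary())),
                    default_cell_vocabulary())
    v <- c(...)
    out[names(v)] <- v
    out
  }
  las <- list(
    mk_la(1L, 1e5, vocab_counts(PC = 3L, B = 1L, T_TEX = 25L, T_PEX = 25L)),
    mk_la(2L, 2e5, vocab_counts(PC = 0L, B = 7L, T_TEX = 15L, T_PEX = 3L)))
  prof <- la_profiles(las)
  expect_equal(prof$density_T_TEX[1], 250)      # 25 cells / 0.1 mm^2
  expect_equal(prof$log2_tex_pex[1], 0)         # n_TEX == n_PEX
  expect_equal(prof$pbr, c(1, -3))
  expect_equal(prof$high_pbr, c(TRUE, FALSE))
  expect_equal(prof$log2_tex_pex[2], log2(16 / 4))
  expect_error(la_profiles(list(mk_la(1L, 0, vocab_counts(B = 1L)))),
               "area")
})

test_that("Spearman association matches the exact permutation oracle", {
  # strictly increasing response: rho = 1
  prof <- data.frame(pbr = 1:10, resp = (1:10)^2)
  a <- associate_pbr(prof, "resp")
  expect_equal(a$spearman_rho, 1)
  expect_equal(a$n, 10L)

  # n = 4 with ranks (1,2,3,4) -> (1,2,4,3): rho = 0.8, p from all 24 orders
  x <- c(10, 20, 30, 40); y <- c(1, 2, 4, 3)
  sp <- laggr:::spearman_assoc(x, y)
  expect_equal(sp$rho, 0.8)
  perms <- laggr:::.all_permutations(4)
  rho_all <- apply(perms, 1, function(pm) cor(rank(x), rank(y)[pm]))
  expect_equal(sp$p, mean(abs(rho_all) >= 0.8 - 1e-12))

  # exact line: least squares recovers it
  lin <- data.frame(pbr = 1:5, resp = 2 * (1:5))
  al <- associate_pbr(lin, "resp")
  expect_equal(al$ls_slope, 2)
  expect_equal(al$ls_intercept, 0, tolerance = 1e-12)

  # zero variance: rho undefined, reported missing
  flat <- data.frame(pbr = rep(1, 5), resp = 1:5)
  af <- associate_pbr(flat, "resp")
  expect_true(is.na(af$spearman_rho))

  expect_error(associate_pbr(data.frame(pbr = 1:2), 1:2), "at least 3")
})

test_that("high-PBR fraction of detected LAs matches the planted truth", {
  par <- tissue_sim_params(n_las = 12, n_background = 1500,
                           chemokine_noise_rate = 0, width = 9000,
                           height = 7000, min_la_separation = 1200,
                           n_cells_per_la = 250, seed = 53)
  tg <- generate_tissue(par)
  las <- detect_lymphoid_aggregates(tg$cellmap)
  prof <- la_profiles(las)
  planted <- mean(tg$truth$la_counts["PC", ] > tg$truth$la_counts["B", ])
  observed <- mean(prof$high_pbr)
  n <- nrow(prof)
  expect_lte(abs(observed - planted), 1.96 * sqrt(0.25 / n) + 1e-9)
})

test_that("per-patient inside/outside exhaustion ratios correlate under coupling", {
  # identical compositions inside and outside sit on the identity line
  df <- data.frame(cell_id = sprintf("c%02d", 1:20), x = 1:20, y = 1:20,
                   cell_type = rep(c("T_TEX", "T_PEX"), 10))
  memb <- data.frame(cell_id = df$cell_id,
                     la_id = rep(c(1L, NA), each = 10))
  samples <- list(p1 = list(cellmap = cell_map(df), membership = memb),
                  p2 = list(cellmap = cell_map(df), membership = memb),
                  p3 = list(cellmap = cell_map(df), membership = memb))
  res <- inside_outside_patient_ratio(samples)
  expect_equal(res$pairs$inside, res$pairs$outside)

  expect_error(inside_outside_patient_ratio(samples[1]), "at least 3")

  # coupled cohort: 6 patients sharing an exhaustion tone inside and
  # outside; positive rho in >= 80% of simulations
  positive <- 0L
  n_sims <- 100L
  for (s in seq_len(n_sims)) {
    set.seed(2000 + s)
    tones <- rnorm(6, 0, 0.75)
    samples <- lapply(seq_len(6), function(i) {
      par <- tissue_sim_params(n_las = 4, n_background = 600,
                               chemokine_noise_rate = 0,
                               width = 5000, height = 4000,
                               min_la_separation = 900,
                               n_cells_per_la = 150,
                               pbr_effect_beta0 = tones[i],
                               pbr_effect_beta1 = 1,
                               pbr_effect_sigma = 0.2,
                               outside_log2_tex_pex = tones[i],
                               seed = 3000 + 10 * s + i)
      tg <- generate_tissue(par)
      memb <- data.frame(
        cell_id = tg$cellmap$cells$cell_id,
        la_id = NA_integer_)
      for (k in seq_along(tg$truth$la_members)) {
        memb$la_id[memb$cell_id %in% tg$truth$la_members[[k]]] <- k
      }
      list(cellmap = tg$cellmap, membership = memb)
    })
    names(samples) <- sprintf("pt%d", 1:6)
    res <- inside_outside_patient_ratio(samples)
    if (!is.na(res$association$spearman_rho) &&
        res$association$spearman_rho > 0) {
      positive <- positive + 1L
    }
  }
  expect_gte(positive / n_sims, 0.8)
})
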