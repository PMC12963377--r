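ihc_cluster <- function(n, cx, cy, r, marker, id0 = 0) {
  rr <- r * sqrt(runif(n)); th <- runif(n, 0, 2 * pi)
  df <- data.frame(cell_id = sprintf("m%05d", id0 + seq_len(n)),
                   x = cx + rr * cos(th), y = cy + rr * sin(th),
                   cd20 = FALSE, cd3 = FALSE, cd4 = FALSE, cd8 = FALSE,
                   cd23 = FALSE, mum1 = FALSE)
  df[[marker]] <- TRUE
  df
}

test_that("IHC LA identification enforces the strict CD20 and CD3 rules", {
  set.seed(61)
  # 60 CD20+ with 30 adjacent CD3+: one LA
  tab <- rbind(ihc_cluster(60, 500, 500, 80, "cd20"),
               ihc_cluster(30, 500, 500, 110, "cd3", id0 = 100))
  las <- identify_ihc_las(tab)
  expect_length(las$aggregates, 1)
  expect_gt(las$aggregates[[1]]$n_cd20, 50)

  # exactly 50 CD20+ fails the strict > 50 rule
  tab50 <- rbind(ihc_cluster(50, 500, 500, 80, "cd20"),
                 ihc_cluster(30, 500, 500, 110, "cd3", id0 = 100))
  expect_length(identify_ihc_las(tab50)$aggregates, 0)

  # no proximal CD3 cluster: candidate rejected
  tab_no3 <- rbind(ihc_cluster(60, 500, 500, 80, "cd20"),
                   ihc_cluster(30, 3000, 3000, 80, "cd3", id0 = 100))
  expect_length(identify_ihc_las(tab_no3)$aggregates, 0)

  # invariance to row order and translation
  las_a <- identify_ihc_las(tab[sample(nrow(tab)), ])
  tab_tr <- tab; tab_tr$x <- tab_tr$x + 5000; tab_tr$y <- tab_tr$y + 100
  las_b <- identify_ihc_las(tab_tr)
  expect_length(las_a$aggregates, 1)
  expect_length(las_b$aggregates, 1)
  expect_setequal(las_a$aggregates[[1]]$cd20_ids, las$aggregates[[1]]$cd20_ids)
  expect_equal(las_b$aggregates[[1]]$area_um2, las$aggregates[[1]]$area_um2,
               tolerance = 1e-9)
})

test_that("planted IHC slides are recovered exactly without noise", {
  for (s in 1:20) {
    sl <- generate_ihc_slide(
      las = data.frame(n_cd20 = c(80, 65, 90), n_cd3 = c(40, 30, 35),
                       n_cd23 = c(4, 0, 2), n_mum1 = c(5, 0, 3),
                       intra = c(TRUE, FALSE, TRUE)),
      seed = 500 + s)
    las <- identify_ihc_las(sl$table)
    expect_length(las$aggregates, 3)
    for (la in las$aggregates) {
      best <- max(vapply(sl$truth$cd20_members, jaccard, numeric(1),
                         b = la$cd20_ids))
      expect_gte(best, 0.9)
    }
  }
})

test_that("location classification uses the inclusive centroid rule", {
  bed <- region_polygon(c(0, 1000, 1000, 0), c(0, 0, 1000, 1000),
                        label = "tumor_bed")
  sq_in <- region_polygon(c(400, 600, 600, 400), c(400, 400, 600, 600))
  sq_out <- region_polygon(c(2000, 2200, 2200, 2000), c(0, 0, 200, 200))
  expect_equal(classify_la_location(sq_in, bed), "intra_tumoral")
  expect_equal(classify_la_location(sq_out, bed), "extra_tumoral")
  # centroid exactly on the bed boundary counts as intra
  sq_edge <- region_polygon(c(900, 1100, 1100, 900), c(400, 400, 600, 600))
  expect_equal(classify_la_location(sq_edge, bed), "intra_tumoral")
  expect_true(is.na(classify_la_location(sq_in, NULL)))
})

test_that("intra-tumoral plasma-cell density is count over bed area", {
  bed <- region_polygon(c(0, 2000, 2000, 0), c(0, 0, 1000, 1000)) # 2 mm^2
  empty <- data.frame(cell_id = "a", x = 100, y = 100, cd20 = FALSE,
                      cd3 = FALSE, cd4 = FALSE, cd8 = FALSE, cd23 = FALSE,
                      mum1 = FALSE)
  expect_equal(intratumoral_pc_density(empty, bed), 0)

  set.seed(62)
  pcs <- ihc_cluster(200, 1000, 500, 450, "mum1")
  expect_equal(intratumoral_pc_density(pcs, bed), 100) # 200 cells / 2 mm^2

  # MUM1+ cells outside the bed are not counted
  pcs2 <- rbind(pcs, transform(ihc_cluster(50, 5000, 5000, 100, "mum1",
                                           id0 = 1000)))
  expect_equal(intratumoral_pc_density(pcs2, bed), 100)

  # planted-density recovery within 3-sigma Poisson
  sl <- generate_ihc_slide(las = data.frame(n_cd20 = 0, n_cd3 = 0,
                                            n_cd23 = 0, n_mum1 = 0,
                                            intra = FALSE)[0, ],
                           mum1_density = 80, seed = 63)
  d <- intratumoral_pc_density(sl$table, sl$tumor_bed)
  lam <- 80 * sl$tumor_bed$area / 1e6
  expect_lt(abs(d - 80), 3 * sqrt(lam) / (sl$tumor_bed$area / 1e6))
})

test_that("density summaries and the Mann-Whitney comparison", {
  set.seed(64)
  sl <- generate_ihc_slide(
    las = data.frame(n_cd20 = c(80, 100), n_cd3 = c(40, 30),
                     n_cd23 = c(5, 0), n_mum1 = c(0, 0),
                     intra = c(TRUE, FALSE)),
    mum1_density = 20, seed = 64)
  las <- identify_ihc_las(sl$table)
  summ <- la_density_summaries(las, sl$tumor_bed)
  expect_equal(nrow(summ), 2)
  expect_equal(summ$density_cd20, summ$n_cd20 / (summ$area_um2 / 1e6))
  expect_setequal(summ$location, c("intra_tumoral", "extra_tumoral"))
  # CD23 call: >= 3 CD23+ cells
  expect_equal(sort(summ$cd23_positive), c(FALSE, TRUE))

  # marker density never exceeds the total cell density within an LA
  tot <- rowSums(summ[, c("n_cd20", "n_cd3", "n_cd23", "n_mum1")])
  for (mk in c("cd20", "cd3", "cd23", "mum1")) {
    expect_true(all(summ[[paste0("density_", mk)]] <=
                      tot / (summ$area_um2 / 1e6) + 1e-9))
  }

  # Mann-Whitney on two samples of 8 equals exhaustive enumeration
  a <- c(1.1, 2.3, 3.1, 4.7, 5.2, 6.9, 7.4, 8.8)
  b <- c(2.8, 4.1, 5.9, 7.7, 9.3, 10.2, 11.5, 12.1)
  df <- data.frame(v = c(a, b), g = rep(c("x", "y"), each = 8))
  res <- compare_la_densities(df, "v", "g")
  pool <- c(a, b)
  combos <- combn(16, 8)
  u_all <- apply(combos, 2, function(ix) {
    xs <- pool[ix]; ys <- pool[-ix]
    sum(outer(xs, ys, ">")) + 0.5 * sum(outer(xs, ys, "=="))
  })
  u_obs <- sum(outer(a, b, ">")) + 0.5 * sum(outer(a, b, "=="))
  expect_equal(unname(res$statistic), u_obs)
  p_oracle <- min(1, 2 * min(mean(u_all <= u_obs), mean(u_all >= u_obs)))
  expect_equal(res$p, p_oracle, tolerance = 1e-12)
})

test_that("plasma-cell vs LA-burden regression matches closed forms", {
  # exact line y = 2x
  rec <- data.frame(pc = 2 * (1:5), la_intra = 1:5, la_extra = c(2, 1, 4, 3, 5))
  res <- correlate_pc_with_la_burden(rec)
  expect_equal(res$intra$slope, 2)
  expect_equal(res$intra$intercept, 0, tolerance = 1e-12)

  # hand-computable n = 3 instance via the normal equations
  rec3 <- data.frame(pc = c(1, 3, 4), la_intra = c(0, 1, 2), la_extra = c(1, 1, 2))
  r3 <- correlate_pc_with_la_burden(rec3)
  x <- rec3$la_intra; y <- rec3$pc
  b1 <- sum((x - mean(x)) * (y - mean(y))) / sum((x - mean(x))^2)
  expect_equal(r3$intra$slope, b1)
  expect_equal(r3$intra$intercept, mean(y) - b1 * mean(x))

  expect_error(correlate_pc_with_la_burden(rec3[1:2, ]), "at least 3")

  # type-I error of the slope p-value under a permuted null
  set.seed(65)
  n_rej <- 0L
  x <- rnorm(20)
  for (r in 1:1000) {
    y <- sample(rnorm(20))
    if (fast_slope_p(x, y) < 0.05) n_rej <- n_rej + 1L
  }
  expect_lt(abs(n_rej / 1000 - 0.05), 0.02)
})
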