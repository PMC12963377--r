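cm_from_df <- function(df, ...) cell_map(df, ...)

test_that("seed selection matches the exhaustive distance scan", {
  # boundary: CXCL13+ cell exactly at the pairing radius qualifies
  df <- data.frame(cell_id = c("a", "b"), x = c(0, 50), y = c(0, 0),
                   cell_type = c("B", "B"), CCL19 = c(1L, 0L),
                   CXCL13 = c(0L, 1L))
  expect_equal(select_chemokine_seed_cells(cm_from_df(df), 50), "a")
  df$x[2] <- 50.001
  expect_equal(select_chemokine_seed_cells(cm_from_df(df), 50), character(0))

  # no CXCL13-positive cells anywhere -> empty seed set
  df2 <- data.frame(cell_id = c("a", "b"), x = c(0, 10), y = c(0, 0),
                    cell_type = "B", CCL19 = c(2L, 1L), CXCL13 = 0L)
  expect_equal(select_chemokine_seed_cells(cm_from_df(df2), 50), character(0))

  # a double-positive cell seeds itself by default, not when disabled
  dp <- data.frame(cell_id = "a", x = 0, y = 0, cell_type = "B",
                   CCL19 = 1L, CXCL13 = 1L)
  expect_equal(select_chemokine_seed_cells(cm_from_df(dp), 50), "a")
  expect_equal(select_chemokine_seed_cells(cm_from_df(dp), 50,
                                           self_pairing = FALSE),
               character(0))

  expect_error(select_chemokine_seed_cells(
    cm_from_df(data.frame(cell_id = "a", x = 0, y = 0, cell_type = "B",
                          CCL19 = 1L)), 50), "CXCL13")

  # 200 random cells with random positivity vs the O(n^2) oracle
  set.seed(41)
  for (rep in 1:5) {
    cells <- random_chemokine_cells(200)
    got <- select_chemokine_seed_cells(cm_from_df(cells), pair_radius = 50)
    expect_setequal(got, oracle_seed_select(cells, 50))
  }
})

test_that("DBSCAN stage agrees with the core-graph reference", {
  # 14 seeds in a tight disc: below min_cells, all noise
  set.seed(42)
  th <- runif(14, 0, 2 * pi); r <- 5 * sqrt(runif(14))
  expect_equal(dbscan_points(r * cos(th), r * sin(th), 75, 15),
               rep(0L, 14))

  # 15 coincident seeds: one cluster, centroid at the point
  lab <- dbscan_points(rep(3, 15), rep(-2, 15), 75, 15)
  expect_equal(lab, rep(1L, 15))

  # random instances vs the independent reference (blobs + scatter)
  set.seed(43)
  for (rep in 1:12) {
    n <- sample(20:300, 1)
    k <- sample(1:4, 1)
    ctrs <- matrix(runif(2 * k, 0, 600), ncol = 2)
    g <- sample(k, n, replace = TRUE)
    x <- ctrs[g, 1] + rnorm(n, 0, 30)
    y <- ctrs[g, 2] + rnorm(n, 0, 30)
    eps <- runif(1, 20, 80); mp <- sample(3:15, 1)
    expect_identical(dbscan_points(x, y, eps, mp),
                     oracle_dbscan(x, y, eps, mp))
  }
})

test_that("cluster merging is transitive single linkage on original centroids", {
  mk <- function(cx, cy) {
    coords <- cbind(x = cx + c(-1, 0, 1), y = cy + c(0, 0, 0))
    list(cluster_id = NA, cell_ids = paste0(cx, "_", 1:3), coords = coords,
         centroid = colMeans(coords))
  }
  one <- merge_clusters(list(mk(0, 0)), 400)
  expect_length(one, 1)
  expect_equal(length(one[[1]]$cell_ids), 3)

  # A-B 390, B-C 390, A-C 780: one merged cluster by transitivity
  chain <- merge_clusters(list(mk(0, 0), mk(390, 0), mk(780, 0)), 400)
  expect_length(chain, 1)
  expect_equal(length(chain[[1]]$cell_ids), 9)
  expect_equal(chain[[1]]$centroid, c(x = 390, y = 0))

  # boundary: exactly 400 merges, 401 does not
  expect_length(merge_clusters(list(mk(0, 0), mk(400, 0)), 400), 1)
  expect_length(merge_clusters(list(mk(0, 0), mk(401, 0)), 400), 2)

  # random centroid sets vs the connected-components oracle
  set.seed(44)
  for (rep in 1:8) {
    k <- sample(2:12, 1)
    cl <- lapply(seq_len(k), function(i) mk(runif(1, 0, 2000), runif(1, 0, 2000)))
    merged <- merge_clusters(cl, 400)
    centro <- do.call(rbind, lapply(cl, `[[`, "centroid"))
    comp <- oracle_merge_components(centro, 400)
    expect_equal(length(merged), length(unique(comp)))
    # member unions match component-wise
    got <- sort(vapply(merged, function(m) paste(sort(m$cell_ids), collapse = ","),
                       character(1)))
    want <- sort(unname(vapply(split(seq_len(k), comp), function(ix) {
      paste(sort(unlist(lapply(cl[ix], `[[`, "cell_ids"))), collapse = ",")
    }, character(1))))
    expect_identical(got, want)
  }
})

test_that("cell assignment is boundary inclusive and matches a full scan", {
  sq1 <- region_polygon(c(0, 100, 100, 0), c(0, 0, 100, 100))
  sq2 <- region_polygon(c(300, 400, 400, 300), c(0, 0, 100, 100))
  df <- data.frame(cell_id = c("edge", "in1", "in2", "out"),
                   x = c(100, 50, 350, 200), y = c(50, 50, 50, 50),
                   cell_type = "B")
  memb <- assign_cells_to_las(cm_from_df(df), list(sq1, sq2))
  expect_equal(memb$la_id, c(1L, 1L, 2L, NA)) # edge cell is assigned

  # no polygons: everything outside
  memb0 <- assign_cells_to_las(cm_from_df(df), list())
  expect_true(all(is.na(memb0$la_id)))

  # 1000 random cells vs exhaustive point-in-polygon scan
  set.seed(45)
  big <- data.frame(cell_id = sprintf("c%04d", 1:1000),
                    x = runif(1000, -50, 450), y = runif(1000, -50, 150),
                    cell_type = "B")
  memb2 <- assign_cells_to_las(cm_from_df(big), list(sq1, sq2))
  for (i in seq_len(1000)) {
    in1 <- point_in_polygon(big$x[i], big$y[i], sq1)
    in2 <- point_in_polygon(big$x[i], big$y[i], sq2)
    expect_equal(memb2$la_id[i],
                 if (in1) 1L else if (in2) 2L else NA_integer_)
  }

  # overlap resolution: nearest source-cluster centroid wins
  ov1 <- region_polygon(c(0, 200, 200, 0), c(0, 0, 100, 100))
  ov2 <- region_polygon(c(100, 300, 300, 100), c(0, 0, 100, 100))
  pt <- data.frame(cell_id = "p", x = 190, y = 50, cell_type = "B")
  memb3 <- assign_cells_to_las(cm_from_df(pt), list(ov1, ov2),
                               centroids = rbind(c(100, 50), c(200, 50)))
  expect_equal(memb3$la_id, 2L)
})

test_that("full detection recovers planted aggregates and is invariant", {
  par <- tissue_sim_params(n_las = 3, n_background = 800,
                           chemokine_noise_rate = 0, width = 5000,
                           height = 4000, min_la_separation = 1200,
                           n_cells_per_la = 250, strict_recovery = TRUE,
                           seed = 46)
  tg <- generate_tissue(par)
  las <- detect_lymphoid_aggregates(tg$cellmap)
  expect_length(las$aggregates, 3)
  for (la in las$aggregates) {
    best <- max(vapply(tg$truth$la_members, jaccard, numeric(1),
                       b = la$cell_ids))
    expect_gte(best, 0.95)
  }

  # every LA keeps at least min_cluster_cells of its seed cells as members
  for (la in las$aggregates) {
    expect_gte(sum(la$seed_ids %in% la$cell_ids), 15)
  }
  # membership partitions the cell map
  expect_equal(nrow(las$membership), nrow(tg$cellmap$cells))
  assigned <- unlist(lapply(las$aggregates, `[[`, "cell_ids"))
  expect_equal(sort(assigned),
               sort(las$membership$cell_id[!is.na(las$membership$la_id)]))
  # per-type counts sum to the member count
  for (la in las$aggregates) {
    expect_equal(sum(la$n_by_type), length(la$cell_ids))
  }

  # invariance to cell-row order
  cm_shuf <- tg$cellmap
  set.seed(47)
  cm_shuf$cells <- cm_shuf$cells[sample(nrow(cm_shuf$cells)), ]
  las_shuf <- detect_lymphoid_aggregates(cm_shuf)
  expect_length(las_shuf$aggregates, 3)
  ids_a <- lapply(las$aggregates, function(l) sort(l$cell_ids))
  ids_b <- lapply(las_shuf$aggregates, function(l) sort(l$cell_ids))
  expect_setequal(vapply(ids_a, paste, character(1), collapse = ","),
                  vapply(ids_b, paste, character(1), collapse = ","))

  # invariance to global translation
  cm_tr <- tg$cellmap
  cm_tr$cells$x <- cm_tr$cells$x + 12345
  cm_tr$cells$y <- cm_tr$cells$y - 500
  las_tr <- detect_lymphoid_aggregates(cm_tr)
  areas_a <- sort(vapply(las$aggregates, `[[`, numeric(1), "area_um2"))
  areas_b <- sort(vapply(las_tr$aggregates, `[[`, numeric(1), "area_um2"))
  expect_equal(areas_a, areas_b, tolerance = 1e-9)

  # tissue without chemokine-positive cells yields zero LAs
  cm0 <- tg$cellmap
  cm0$cells$CCL19 <- 0L; cm0$cells$CXCL13 <- 0L
  expect_length(detect_lymphoid_aggregates(cm0)$aggregates, 0)
})

test_that("chemokine noise does not split compact planted aggregates", {
  for (s in 1:6) {
    base <- tissue_sim_params(n_las = 3, n_background = 400,
                              chemokine_noise_rate = 0, width = 5000,
                              height = 4000, min_la_separation = 1200,
                              n_cells_per_la = 250, seed = 100 + s)
    noisy <- base; noisy$chemokine_noise_rate <- 1
    n0 <- length(detect_lymphoid_aggregates(generate_tissue(base)$cellmap)$aggregates)
    n1 <- length(detect_lymphoid_aggregates(generate_tissue(noisy)$cellmap)$aggregates)
    expect_equal(n0, 3)
    expect_equal(n1, 3) # stray singletons never split a compact planted LA
  }
})
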