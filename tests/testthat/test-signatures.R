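toy_profile <- function(n, seed) {
  set.seed(seed)
  stats::setNames(stats::rnorm(n), sprintf("g%03d", seq_len(n)))
}

toy_matrix <- function(n_cells, n_genes, seed) {
  set.seed(seed)
  matrix(stats::rnorm(n_cells * n_genes),
         nrow = n_cells,
         dimnames = list(sprintf("c%02d", seq_len(n_cells)),
                         sprintf("g%03d", seq_len(n_genes))))
}

test_that("AUCell hits the extreme scores exactly", {
  # 20 genes, top fraction 0.25 -> k = 5
  norm <- matrix(c(20:1), nrow = 1,
                 dimnames = list("cell", sprintf("g%03d", 1:20)))
  top3 <- sprintf("g%03d", 1:3)
  expect_equal(unname(aucell_score(norm, top3, top_fraction = 0.25)), 1)
  bottom3 <- sprintf("g%03d", 18:20)
  expect_equal(unname(aucell_score(norm, bottom3, top_fraction = 0.25)), 0)
  expect_error(aucell_score(norm, "missing"), class = "tlscape_param_error")
})

test_that("AUCell equals brute-force step-curve integration on random toys", {
  for (seed in 1:10) {
    n <- sample(10:50, 1)
    mat <- toy_matrix(3, n, seed)
    m <- sample(3:min(8, n - 1), 1)
    set <- sample(colnames(mat), m)
    tf <- runif(1, 0.1, 0.6)
    got <- aucell_score(mat, set, top_fraction = tf)
    for (i in 1:3) {
      expect_equal(unname(got[i]), oracle_aucell(mat[i, ], set, tf),
                   tolerance = 1e-12)
    }
    expect_true(all(got >= 0 & got <= 1))
  }
})

test_that("AUCell is invariant under strictly monotone transforms", {
  mat <- toy_matrix(4, 30, 21)
  set <- sprintf("g%03d", c(2, 9, 17))
  base <- aucell_score(mat, set, top_fraction = 0.2)
  expect_equal(aucell_score(exp(mat), set, top_fraction = 0.2), base)
  expect_equal(aucell_score(2 * mat + 7, set, top_fraction = 0.2), base)
})

test_that("ssGSEA running sum matches the independent oracle", {
  for (seed in 1:10) {
    n <- sample(10:50, 1)
    expr <- toy_profile(n, seed + 100)
    m <- sample(2:min(6, n - 2), 1)
    set <- sample(names(expr), m)
    for (alpha in c(0, 0.25, 1)) {
      expect_equal(ssgsea_score(expr, set, alpha = alpha),
                   oracle_ssgsea(expr, set, alpha),
                   tolerance = 1e-12)
    }
  }
})

test_that("ssGSEA worked 10-gene example and monotonicity in rank", {
  expr <- stats::setNames(c(10, 9, 8, 7, 6, 5, 4, 3, 2, 1),
                          sprintf("g%02d", 1:10))
  s_top <- ssgsea_score(expr, "g01")
  s_bottom <- ssgsea_score(expr, "g10")
  expect_gt(s_top, s_bottom)
  expect_equal(ssgsea_score(expr, c("g02", "g05", "g08")),
               oracle_ssgsea(expr, c("g02", "g05", "g08"), 0.25),
               tolerance = 1e-12)
})

test_that("ssGSEA is rank-invariant and fails when the set covers all genes", {
  expr <- toy_profile(25, 33)
  set <- names(expr)[c(3, 11, 19)]
  base <- ssgsea_score(expr, set)
  expect_equal(ssgsea_score(exp(expr / 2), set), base, tolerance = 1e-12)
  expect_error(ssgsea_score(expr, names(expr)),
               class = "tlscape_param_error")
})

test_that("with alpha = 0 the running sum returns to zero", {
  for (seed in 1:5) {
    expr <- toy_profile(30, seed + 50)
    set <- sample(names(expr), 7)
    n <- length(expr); m <- 7
    o <- order(-expr, seq_len(n))
    member <- names(expr)[o] %in% set
    steps <- ifelse(member, 1 / m, -1 / (n - m))
    expect_equal(sum(steps), 0, tolerance = 1e-12)
    final <- cumsum(steps)[n]
    expect_equal(final, 0, tolerance = 1e-12)
  }
})

test_that("derived marker sets recover the planted panel genes", {
  hits <- 0L
  for (s in 1:5) {
    samp <- annotated_sample(seed = s)
    truth <- samp$sim$truth$cell_true_type[
      match(samp$cells$cell_id, samp$sim$cells$cell_id)]
    sets <- derive_marker_sets(samp$norm, truth)
    panel <- marker_panel()
    ok <- all(vapply(names(panel), function(t) {
      all(panel[[t]] %in% sets[[t]])
    }, logical(1)))
    if (ok) hits <- hits + 1L
  }
  expect_gte(hits, 4L)
})

test_that("permuted labels and duplicated groups derive empty sets", {
  samp <- annotated_sample(seed = 9)
  set.seed(123)
  n_retained <- replicate(5, {
    perm <- sample(c("g1", "g2"), nrow(samp$norm), replace = TRUE)
    suppressWarnings(sets <- derive_marker_sets(samp$norm, perm))
    sum(lengths(sets))
  })
  expect_lt(mean(n_retained), 2)

  dup <- samp$norm[rep(1:30, 2), ]
  rownames(dup) <- sprintf("d%02d", 1:60)
  suppressWarnings(
    sets <- derive_marker_sets(dup, rep(c("a", "b"), each = 30)))
  expect_equal(sum(lengths(sets)), 0)
})

test_that("marker derivation threshold dominance and group-size errors", {
  samp <- annotated_sample(seed = 9)
  truth <- samp$sim$truth$cell_true_type[
    match(samp$cells$cell_id, samp$sim$cells$cell_id)]
  suppressWarnings(
    sets <- derive_marker_sets(samp$norm, truth, min_abs_log2fc = Inf))
  expect_equal(sum(lengths(sets)), 0)
  expect_error(derive_marker_sets(samp$norm, c("a", rep("b", nrow(samp$norm) - 1))),
               class = "tlscape_param_error")
})

test_that("maturity labels follow the >= median rule, ties mature", {
  regions <- tibble::tibble(
    region_id = c("r1", "r2"), sample_id = "S",
    n_cells = c(101L, 101L), area_mm2 = c(1, 1),
    centroid_x_um = 0, centroid_y_um = 0,
    maturity_score = NA_real_, maturity_label = NA_character_,
    member_cell_ids = list(c("c1", "c2"), c("c3", "c4")),
    counts_by_type = list(NULL, NULL), hull = list(NULL, NULL)
  )
  genes <- c(germinal_center_markers(), sprintf("f%02d", 1:20))
  norm <- matrix(stats::runif(4 * length(genes)), nrow = 4,
                 dimnames = list(sprintf("c%d", 1:4), genes))
  norm["c1", germinal_center_markers()] <- 5   # region r1 enriched
  out <- classify_maturity(regions, norm)
  expect_equal(out$maturity_label, c("mature", "immature"))

  # identical regions tie at the median: both mature
  tied <- regions
  tied$member_cell_ids <- list(c("c1", "c2"), c("c1", "c2"))
  out_tied <- classify_maturity(tied, norm)
  expect_equal(out_tied$maturity_label, c("mature", "mature"))

  expect_error(classify_maturity(regions[1, ], norm),
               class = "tlscape_param_error")
  nogc <- norm[, sprintf("f%02d", 1:20)]
  expect_error(classify_maturity(regions, nogc),
               class = "tlscape_param_error")
})

test_that("maturity recovery matches the planted mature flags", {
  agreements <- c()
  for (s in 1:10) {
    samp <- annotated_sample(seed = s)
    regions <- call_tls(samp$cells)
    if (nrow(regions) < 2) next
    scored <- classify_maturity(regions, samp$norm)
    rec <- truth_recovery(samp$sim$truth, regions, cells = samp$sim$cells)
    mp <- rec$matched_pairs
    planted <- samp$sim$truth$planted_regions$mature[mp$truth_region]
    got <- scored$maturity_label[match(mp$region_id, scored$region_id)] == "mature"
    agreements <- c(agreements, mean(planted == got))
  }
  expect_gte(mean(agreements), 0.9)
})
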