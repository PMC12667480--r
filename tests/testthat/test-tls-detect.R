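test_that("coordinate normalization maps extremes to the unit square", {
  cells <- tibble::tibble(cell_id = c("a", "b"), sample_id = "S",
                          x_um = c(0, 100), y_um = c(0, 200))
  pts <- normalize_coordinates(cells)
  expect_equal(unname(pts), rbind(c(0, 0), c(1, 1)), ignore_attr = TRUE)

  shifted <- dplyr::mutate(cells, x_um = x_um + 500, y_um = y_um + 500)
  expect_equal(unname(normalize_coordinates(shifted)), unname(pts),
               ignore_attr = TRUE)
})

test_that("normalization inverts exactly and rejects degenerate extents", {
  set.seed(14)
  cells <- tibble::tibble(cell_id = sprintf("c%d", 1:50), sample_id = "S",
                          x_um = runif(50, 100, 900),
                          y_um = runif(50, -50, 2000))
  pts <- normalize_coordinates(cells)
  back <- denormalize_coordinates(pts, attr(pts, "transform"))
  expect_equal(unname(back), unname(cbind(cells$x_um, cells$y_um)),
               tolerance = 1e-9)

  flat <- dplyr::mutate(cells, y_um = 5)
  expect_error(normalize_coordinates(flat), class = "tlscape_param_error")
})

test_that("the >100-cell size filter is strict", {
  # one dense knot of 99 constituent cells: a DBSCAN cluster, but too small
  set.seed(15)
  knot <- function(n, cx, cy) {
    tibble::tibble(cell_id = sprintf("k%03d_%d", seq_len(n), cx),
                   sample_id = "S",
                   x_um = runif(n, cx - 20, cx + 20),
                   y_um = runif(n, cy - 20, cy + 20),
                   cell_type = "B")
  }
  spread <- tibble::tibble(cell_id = sprintf("s%03d", 1:60), sample_id = "S",
                           x_um = runif(60, 0, 2000),
                           y_um = runif(60, 0, 2000),
                           cell_type = "B")
  cells99 <- dplyr::bind_rows(knot(99, 1000, 1000), spread)
  params <- detection_params(min_samples = 50)
  expect_equal(nrow(call_tls(cells99, params)), 0)
  cells101 <- dplyr::bind_rows(knot(101, 1000, 1000), spread)
  regions <- call_tls(cells101, params)
  expect_equal(nrow(regions), 1)
  expect_gt(regions$n_cells, 100)
})

test_that("a planted dense disc is recovered nearly completely", {
  samp <- annotated_sample(seed = 3, n_tls = 1)
  regions <- call_tls(samp$cells)
  expect_equal(nrow(regions), 1)
  truth <- samp$sim$truth
  disc_cells <- samp$sim$cells$cell_id[truth$cell_region_id == 1]
  disc_constituent <- intersect(
    disc_cells, samp$cells$cell_id[samp$cells$cell_type %in% c("B", "NKT", "DC")])
  overlap <- length(intersect(regions$member_cell_ids[[1]], disc_constituent))
  expect_gte(overlap / length(disc_constituent), 0.9)
})

test_that("collinear member cells give a degenerate zero-area region", {
  set.seed(16)
  n <- 120
  line <- tibble::tibble(cell_id = sprintf("l%03d", 1:n), sample_id = "S",
                         x_um = seq(1000, 1100, length.out = n), y_um = 1000,
                         cell_type = "B")
  # scattered cells far below the line keep the extent 2-D without joining
  # the cluster (they sit beyond the DBSCAN reach)
  spread <- tibble::tibble(cell_id = sprintf("s%03d", 1:40), sample_id = "S",
                           x_um = runif(40, 0, 2000),
                           y_um = runif(40, 0, 600),
                           cell_type = "B")
  params <- detection_params(min_samples = 60, min_cluster_cells = 100)
  expect_warning(regions <- call_tls(dplyr::bind_rows(line, spread), params),
                 "degenerate")
  expect_equal(regions$area_mm2, 0)
  expect_gte(regions$n_cells, n)
})

test_that("samples without constituent cells yield no regions, with a message", {
  cells <- tibble::tibble(cell_id = c("x", "y"), sample_id = "S",
                          x_um = c(0, 10), y_um = c(0, 10),
                          cell_type = "Cancer")
  expect_message(regions <- call_tls(cells), "no constituent")
  expect_equal(nrow(regions), 0)
})

test_that("TLS membership matches hull containment for all cell types", {
  samp <- annotated_sample(seed = 4)
  regions <- call_tls(samp$cells)
  cells <- assign_tls_membership(samp$cells, regions)
  idx <- sample(nrow(cells), 200)
  for (i in idx) {
    want <- NA_character_
    for (r in order(regions$region_id)) {
      h <- regions$hull[[r]]
      if (oracle_point_in_polygon(cells$x_um[i], cells$y_um[i],
                                  h[, 1], h[, 2])) {
        want <- regions$region_id[r]
        break
      }
    }
    expect_identical(cells$tls_id[i], want)
  }
})

test_that("points far outside every hull stay nTLS", {
  samp <- annotated_sample(seed = 4)
  regions <- call_tls(samp$cells)
  far <- tibble::tibble(cell_id = "far", sample_id = "S1",
                        x_um = 1e6, y_um = 1e6, cell_type = "B")
  out <- assign_tls_membership(far, regions)
  expect_true(is.na(out$tls_id))
})

test_that("marker validation detects planted elevation and handles nulls", {
  samp <- annotated_sample(seed = 6)
  cells <- assign_tls_membership(samp$cells, call_tls(samp$cells))
  v <- validate_tls_markers(samp$norm, cells)
  expect_true(all(v$p_adj < 0.05))
  expect_true(all(v$effect > 0))

  # identical expression in both compartments -> effect 0, p = 1
  norm0 <- samp$norm
  norm0[, c("MKI67", "CXCR5", "CCL2")] <- 1
  v0 <- validate_tls_markers(norm0, cells)
  expect_equal(v0$effect, rep(0, 3))
  expect_equal(v0$p, rep(1, 3))

  all_out <- dplyr::mutate(cells, tls_id = NA_character_)
  expect_error(validate_tls_markers(samp$norm, all_out),
               class = "tlscape_param_error")
  expect_warning(validate_tls_markers(samp$norm, cells,
                                      genes = c("MKI67", "NOPE")),
                 "absent")
})

test_that("permuted compartment labels give roughly uniform p-values", {
  samp <- annotated_sample(seed = 7)
  cells <- assign_tls_membership(samp$cells, call_tls(samp$cells))
  set.seed(77)
  ps <- replicate(40, {
    shuffled <- dplyr::mutate(cells, tls_id = sample(tls_id))
    validate_tls_markers(samp$norm, shuffled, genes = "GENE050")$p
  })
  expect_gt(stats::ks.test(ps, "punif")$p.value, 0.01)
})

test_that("score report splits strictly above the cohort median", {
  cells <- tibble::tibble(cell_id = sprintf("c%d", 1:4),
                          sample_id = c("A", "B", "C", "D"),
                          x_um = 1:4, y_um = 1:4, cell_type = "B")
  regions <- tibble::tibble(
    region_id = c("A_TLS1", "B_TLS1", "C_TLS1"),
    sample_id = c("A", "B", "C"),
    n_cells = c(150L, 300L, 200L),
    area_mm2 = c(2, 6, 4),
    centroid_x_um = 0, centroid_y_um = 0,
    maturity_score = NA_real_, maturity_label = NA_character_,
    member_cell_ids = list("c1", "c2", "c3"),
    counts_by_type = list(NULL, NULL, NULL),
    hull = list(NULL, NULL, NULL)
  )
  rep_area <- tls_score_report(cells, regions, criterion = "cumulative_area")
  # areas 2, 6, 4, 0 -> median 3; sample C (4) high, sample A (2) low
  expect_equal(setNames(rep_area$group, rep_area$sample_id),
               c(A = "low", B = "high", C = "high", D = "low"))

  rep_cells <- tls_score_report(cells, regions, criterion = "cell_count")
  expect_equal(setNames(rep_cells$group, rep_cells$sample_id),
               c(A = "low", B = "high", C = "high", D = "low"))

  # sample exactly at the median goes low
  two <- tls_score_report(cells[cells$sample_id %in% c("A", "B"), ],
                          regions[1:2, ], criterion = "cumulative_area")
  expect_equal(sort(two$group), c("high", "low"))
  expect_error(tls_score_report(cells[1, ], regions),
               class = "tlscape_param_error")
})

test_that("score report grouping equals a direct sort-based computation", {
  samp <- annotated_sample(seed = 8)
  cohort <- simulate_cohort(samp$params, 9, seed = 8)
  cells <- dplyr::bind_rows(purrr::map(cohort$samples, function(s) {
    assign_cell_types(s$cells, lognormalize(s$counts))
  }))
  regions <- call_tls(cells)
  rep <- tls_score_report(cells, regions, criterion = "cell_count")
  stat <- unname(vapply(rep$sample_id, function(s) {
    sum(regions$n_cells[regions$sample_id == s])
  }, numeric(1)))
  expect_equal(rep$group, ifelse(stat > median(stat), "high", "low"))
})

test_that("called regions are disjoint and their hull areas are bounded", {
  # The hull of a planted disc's cluster underestimates the disc area from
  # the inside (finite sample) but can be dilated outward by border points
  # lying within the DBSCAN reach (eps times the tissue extent) of the rim.
  lows <- c(); highs <- c()
  for (s in 1:10) {
    samp <- annotated_sample(seed = s)
    regions <- call_tls(samp$cells)
    rec <- truth_recovery(samp$sim$truth, regions, cells = samp$sim$cells)
    expect_true(all(regions$n_cells > 100))
    members <- unlist(regions$member_cell_ids)
    expect_equal(anyDuplicated(members), 0)
    r_um <- samp$params$tls_radius_um
    reach <- 0.08 * samp$params$tissue_side_um
    matched <- regions[match(rec$matched_pairs$region_id,
                             regions$region_id), ]
    lows <- c(lows, matched$area_mm2 >= 0.5 * pi * r_um^2 / 1e6)
    highs <- c(highs, matched$area_mm2 <= pi * (r_um + reach)^2 / 1e6)
  }
  expect_true(all(lows))
  expect_true(all(highs))
})
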