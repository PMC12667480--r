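test_that("no planted structure means empty truth and background labels", {
  sim <- simulate_sample(sim_params(n_tls = 0, n_cells_per_sample = 500), "S1")
  expect_equal(nrow(sim$truth$planted_regions), 0)
  expect_true(all(sim$truth$cell_region_id == 0))
  expect_equal(sim$truth$sample_tls_burden, 0)
})

test_that("identical parameters and seed reproduce the sample exactly", {
  p <- sim_params(n_cells_per_sample = 800, seed = 42)
  a <- simulate_sample(p, "S1")
  b <- simulate_sample(p, "S1")
  expect_identical(a$counts, b$counts)
  expect_identical(a$cells, b$cells)
  expect_identical(a$truth, b$truth)
})

test_that("parameter validation rejects out-of-range settings", {
  expect_error(sim_params(tls_immune_frac = 1.5), class = "tlscape_param_error")
  expect_error(sim_params(marker_fold = 0.5), class = "tlscape_param_error")
  expect_error(sim_params(nb_mean = 0), class = "tlscape_param_error")
  expect_error(sim_params(n_tls = 200, tls_radius_um = 150,
                          tissue_side_um = 1000),
               class = "tlscape_param_error")
})

test_that("in-disc immune fraction sits inside the binomial 99% CI", {
  p <- sim_params(n_cells_per_sample = 5000, n_tls = 3, seed = 7)
  sim <- simulate_sample(p, "S1")
  in_disc <- sim$truth$cell_region_id > 0
  n <- sum(in_disc)
  frac <- mean(sim$truth$cell_true_type[in_disc] %in% c("B", "NKT", "DC"))
  half_width <- stats::qnorm(0.995) * sqrt(0.9 * 0.1 / n)
  expect_lt(abs(frac - 0.9), half_width)

  bg <- !in_disc
  frac_bg <- mean(sim$truth$cell_true_type[bg] %in% c("B", "NKT", "DC"))
  half_bg <- stats::qnorm(0.995) * sqrt(0.1 * 0.9 / sum(bg))
  expect_lt(abs(frac_bg - 0.1), half_bg)
})

test_that("planted cells lie inside their discs, background outside", {
  sim <- simulate_sample(sim_params(seed = 5), "S1")
  tr <- sim$truth
  for (k in seq_len(nrow(tr$planted_regions))) {
    idx <- tr$cell_region_id == k
    d <- sqrt((sim$cells$x_um[idx] - tr$planted_regions$center_x_um[k])^2 +
              (sim$cells$y_um[idx] - tr$planted_regions$center_y_um[k])^2)
    expect_true(all(d <= tr$planted_regions$radius_um[k] + 1e-9))
  }
  bg <- tr$cell_region_id == 0
  for (k in seq_len(nrow(tr$planted_regions))) {
    d <- sqrt((sim$cells$x_um[bg] - tr$planted_regions$center_x_um[k])^2 +
              (sim$cells$y_um[bg] - tr$planted_regions$center_y_um[k])^2)
    expect_true(all(d > tr$planted_regions$radius_um[k] - 1e-9))
  }
})

test_that("count marginals match the negative-binomial parameterization", {
  p <- sim_params(n_cells_per_sample = 10000, n_tls = 0, marker_fold = 1,
                  gc_fold_mature = 1, off_target_frac = 1,
                  mito_frac_mean = 0, seed = 11)
  sim <- simulate_sample(p, "S1")
  genes <- colnames(sim$counts)[!startsWith(colnames(sim$counts), "MT-")]
  mu <- p$nb_mean
  v <- mu + p$nb_dispersion * mu^2
  n <- nrow(sim$counts)
  # theoretical moments of the negative binomial for the SE of the variance
  size <- 1 / p$nb_dispersion
  prob <- size / (size + mu)
  x <- 0:200
  pmf <- stats::dnbinom(x, size = size, prob = prob)
  m4 <- sum(pmf * (x - mu)^4)
  se_mean <- sqrt(v / n)
  se_var <- sqrt((m4 - v^2) / n)
  means <- colMeans(sim$counts[, genes])
  vars <- apply(sim$counts[, genes], 2, stats::var)
  expect_true(all(abs(means - mu) < 3 * se_mean + 1e-9))
  expect_gt(mean(abs(vars - v) < 3 * se_var), 0.95)
})

test_that("mitochondrial share of counts tracks mito_frac_mean", {
  sim <- simulate_sample(sim_params(seed = 3), "S1")
  expect_lt(abs(mean(sim$cells$mito_fraction) - 0.05), 0.01)
})

test_that("burden is monotone in the number of planted discs", {
  burdens <- vapply(0:5, function(k) {
    simulate_sample(sim_params(n_tls = k, n_cells_per_sample = 200,
                               seed = 2), "S1")$truth$sample_tls_burden
  }, numeric(1))
  expect_true(all(diff(burdens) >= 0))
})

test_that("cohorts vary burden, censor as requested, and reproduce", {
  p <- sim_params(n_cells_per_sample = 100, censor_frac = 0)
  co <- simulate_cohort(p, 12, seed = 5, generate_counts = FALSE)
  expect_true(all(co$survival$event == 1))
  expect_gt(stats::sd(co$burden), 0)
  co2 <- simulate_cohort(p, 12, seed = 5, generate_counts = FALSE)
  expect_identical(co$survival, co2$survival)
  expect_error(simulate_cohort(p, 1), class = "tlscape_param_error")
})

test_that("burden and survival are unlinked when the hazard coefficient is 0", {
  set.seed(1)
  cors <- vapply(1:50, function(rep) {
    p <- sim_params(survival_beta = 0, n_cells_per_sample = 100)
    co <- simulate_cohort(p, 40, seed = rep, generate_counts = FALSE)
    ev <- co$survival$event == 1
    if (sd(co$burden[ev]) == 0) return(0)
    stats::cor(co$burden[ev], co$survival$time[ev], method = "spearman")
  }, numeric(1))
  ci <- mean(cors) + c(-1, 1) * stats::qnorm(0.995) * stats::sd(cors) / sqrt(50)
  expect_true(ci[1] <= 0 && ci[2] >= 0)
})

test_that("higher burden brings longer survival under a positive coefficient", {
  wins <- vapply(1:50, function(rep) {
    p <- sim_params(survival_beta = 1, n_cells_per_sample = 100,
                    censor_frac = 0)
    co <- simulate_cohort(p, 80, seed = rep + 300, generate_counts = FALSE)
    top <- co$burden > stats::median(co$burden)
    stats::median(co$survival$time[top]) >
      stats::median(co$survival$time[!top])
  }, logical(1))
  expect_gte(mean(wins), 0.9)
})

test_that("recovery metrics are exact on identity and empty detections", {
  samp <- annotated_sample(seed = 10)
  truth <- samp$sim$truth
  # detected = exact planted memberships
  ids <- purrr::map(seq_len(nrow(truth$planted_regions)), function(k) {
    samp$sim$cells$cell_id[truth$cell_region_id == k]
  })
  regions <- tibble::tibble(
    region_id = sprintf("S1_TLS%d", seq_along(ids)),
    sample_id = "S1",
    n_cells = lengths(ids),
    area_mm2 = 1,
    centroid_x_um = truth$planted_regions$center_x_um,
    centroid_y_um = truth$planted_regions$center_y_um,
    maturity_score = NA_real_, maturity_label = NA_character_,
    member_cell_ids = ids,
    counts_by_type = vector("list", length(ids)),
    hull = vector("list", length(ids))
  )
  rec <- truth_recovery(truth, regions, cells = samp$sim$cells)
  expect_equal(rec$region_precision, 1)
  expect_equal(rec$region_recall, 1)
  expect_equal(rec$cell_label_ari, 1)

  rec0 <- truth_recovery(truth, regions[0, ], cells = samp$sim$cells)
  expect_equal(rec0$region_recall, 0)
  expect_equal(rec0$region_precision, 1)
  expect_true(rec0$flags$precision_undefined)

  other <- regions
  other$sample_id <- "S9"
  expect_error(truth_recovery(truth, other), class = "tlscape_param_error")
})

test_that("adjusted Rand index matches mclust and is null for random labels", {
  set.seed(31)
  aris <- replicate(20, {
    a <- sample(0:3, 500, replace = TRUE)
    b <- sample(0:3, 500, replace = TRUE)
    got <- adjusted_rand_index(a, b)
    ref <- mclust::adjustedRandIndex(a, b)
    expect_equal(got, ref, tolerance = 1e-12)
    got
  })
  expect_lt(abs(mean(aris)), 0.05)
  expect_equal(adjusted_rand_index(1:5, 5:1), 1)  # same partition relabeled
})
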