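#' Simulation parameters for synthetic spatial tissue
#'
#' Defines one synthetic tissue section: a square of side `tissue_side_um`
#' holding `n_cells_per_sample` cells, with `n_tls` planted circular immune
#' aggregates (TLS discs) of radius `tls_radius_um`. Cells inside a disc
#' are immune (B / NK-T / dendritic) with probability `tls_immune_frac`,
#' background cells with probability `background_immune_frac`. Counts are
#' negative binomial with mean `nb_mean` and dispersion `nb_dispersion`
#' (variance `mu + dispersion * mu^2`). Marker-class genes (the cell-type
#' panel, the TLS-associated genes and the germinal-center genes) are
#' specific: outside their expressing context they keep only
#' `off_target_frac` of the baseline mean (imaging background / spillover),
#' and in their context their mean is `nb_mean * marker_fold` (own-type
#' panel genes, TLS genes inside discs) or `nb_mean * gc_fold_mature`
#' (germinal-center genes inside mature-flagged discs). A
#' dedicated mitochondrial gene block contributes about `mito_frac_mean`
#' of each cell's counts. Cohort survival follows an exponential
#' proportional-hazards model with log-hazard coefficient `-survival_beta`
#' on the standardized TLS burden.
#'
#' @param n_cells_per_sample Cells per tissue section.
#' @param tissue_side_um Side of the square section, micrometres.
#' @param n_tls Number of planted TLS discs (cohort mean; per-sample counts
#'   vary in [simulate_cohort()]).
#' @param tls_radius_um Disc radius, micrometres.
#' @param tls_immune_frac,background_immune_frac Immune-cell probabilities
#'   inside / outside discs.
#' @param marker_fold Fold elevation (>= 1) over `nb_mean` of a type's
#'   marker genes, and of the TLS-associated genes (MKI67, CXCR5, CCL2)
#'   inside discs.
#' @param nb_mean,nb_dispersion Negative-binomial baseline mean and
#'   dispersion per gene.
#' @param mito_frac_mean Expected mitochondrial share of a cell's counts.
#' @param gc_fold_mature Fold elevation (>= 1) of germinal-center markers
#'   in mature-flagged discs.
#' @param survival_beta Log-hazard coefficient on standardized burden.
#' @param censor_frac Probability a subject is censored (at a uniform time
#'   before its event).
#' @param seed Integer seed; identical parameters and seed give
#'   byte-identical output.
#' @param tls_density_boost Cell-density multiplier of a disc relative to
#'   background (discs are denser than surrounding tissue).
#' @param tls_min_gap_um Minimum edge-to-edge spacing between planted discs
#'   (micrometres), so each planted aggregate is a spatially distinct
#'   structure rather than part of a merged mass.
#' @param off_target_frac Fraction of `nb_mean` kept by marker-class genes
#'   outside their expressing context; 1 removes marker specificity.
#' @return A validated `sim_params` list.
#' @export
sim_params <- function(n_cells_per_sample = 2500,
                       tissue_side_um = 2000,
                       n_tls = 3,
                       tls_radius_um = 150,
                       tls_immune_frac = 0.9,
                       background_immune_frac = 0.1,
                       marker_fold = 8,
                       nb_mean = 2,
                       nb_dispersion = 0.5,
                       mito_frac_mean = 0.05,
                       gc_fold_mature = 6,
                       survival_beta = 1,
                       censor_frac = 0.3,
                       seed = 1L,
                       tls_density_boost = 7,
                       tls_min_gap_um = 450,
                       off_target_frac = 0.25) {
  check_number(n_cells_per_sample, "n_cells_per_sample", lower = 1,
               integerish = TRUE)
  check_number(tissue_side_um, "tissue_side_um", lower = 0,
               allow_boundary = FALSE)
  check_number(n_tls, "n_tls", lower = 0, integerish = TRUE)
  check_number(tls_radius_um, "tls_radius_um", lower = 0,
               allow_boundary = FALSE)
  check_prob(tls_immune_frac, "tls_immune_frac")
  check_prob(background_immune_frac, "background_immune_frac")
  check_number(marker_fold, "marker_fold", lower = 1)
  check_number(nb_mean, "nb_mean", lower = 0, allow_boundary = FALSE)
  check_number(nb_dispersion, "nb_dispersion", lower = 0,
               allow_boundary = FALSE)
  check_prob(mito_frac_mean, "mito_frac_mean")
  check_number(gc_fold_mature, "gc_fold_mature", lower = 1)
  check_number(survival_beta, "survival_beta")
  check_prob(censor_frac, "censor_frac")
  check_number(seed, "seed", integerish = TRUE)
  check_number(tls_density_boost, "tls_density_boost", lower = 1)
  check_number(tls_min_gap_um, "tls_min_gap_um", lower = 0)
  check_prob(off_target_frac, "off_target_frac")
  if (off_target_frac == 0) abort_param("`off_target_frac` must be > 0.")
  if (n_tls * pi * tls_radius_um^2 >= tissue_side_um^2) {
    abort_param("Planted discs would cover the whole tissue: need n_tls * pi * r^2 < side^2.")
  }
  structure(as.list(environment()), class = "sim_params")
}

# Gene universe of the simulator: the default marker panel, germinal-center
# markers, TLS-associated genes, a mitochondrial block, and neutral filler
# genes so rank-based scores have a realistic background.
sim_gene_universe <- function() {
  panel <- unique(unlist(marker_panel(), use.names = FALSE))
  gc <- germinal_center_markers()
  tls <- c("MKI67", "CXCR5", "CCL2")
  mito <- paste0("MT-", c("ND1", "ND2", "ND3", "ND4", "ND5",
                          "CO1", "CO2", "CO3", "ATP6", "CYB"))
  filler <- sprintf("GENE%03d", seq_len(121))
  unique(c(panel, gc, tls, mito, filler))
}

immune_types <- function() c("B", "NKT", "DC")

#' Simulate one spatial tissue sample
#'
#' Places cells in the unit tissue square (TLS discs at
#' `tls_density_boost`-fold the background density), draws true cell types
#' from the in-disc / background immune mixtures, and generates
#' negative-binomial counts with the marker, germinal-center and
#' mitochondrial structure described in [sim_params()]. Disc centers are
#' sampled so discs fit inside the section and do not overlap. Odd-indexed
#' discs are flagged mature (germinal-center elevated); even-indexed discs
#' are immature.
#'
#' @param params A [sim_params()] object.
#' @param sample_id Identifier used in cell ids.
#' @return List with `cells` (per-cell tibble incl. QC stats), `counts`
#'   (integer matrix cells x genes) and `truth` (a `tls_truth`: planted
#'   regions, per-cell region id and true type, and the sample's TLS
#'   burden in mm^2 of planted disc area).
#' @export
simulate_sample <- function(params, sample_id = "S1") {
  stopifnot(inherits(params, "sim_params"))
  set.seed(params$seed)
  n <- params$n_cells_per_sample
  side <- params$tissue_side_um
  r <- params$tls_radius_um

  centers <- place_disc_centers(params$n_tls, side, r, params$tls_min_gap_um)
  mature <- if (params$n_tls > 0) seq_len(params$n_tls) %% 2L == 1L else logical(0)

  region <- sample_regions(n, centers, r, side, params$tls_density_boost)
  pos <- place_cells(region, centers, r, side)

  immune_p <- ifelse(region > 0L, params$tls_immune_frac,
                     params$background_immune_frac)
  is_immune <- runif(n) < immune_p
  type <- character(n)
  type[is_immune] <- sample(immune_types(), sum(is_immune), replace = TRUE,
                            prob = c(0.5, 0.35, 0.15))
  type[!is_immune] <- sample(c("Cancer", "Myeloid", "Fibroblast", "Endothelial"),
                             sum(!is_immune), replace = TRUE,
                             prob = c(0.45, 0.25, 0.2, 0.1))

  counts <- simulate_counts(params, type, region, mature)
  cell_id <- sprintf("%s_c%05d", sample_id, seq_len(n))
  rownames(counts) <- cell_id

  mito_genes <- startsWith(colnames(counts), "MT-")
  total <- rowSums(counts)
  cells <- tibble(
    cell_id = cell_id,
    sample_id = sample_id,
    x_um = pos[, 1],
    y_um = pos[, 2],
    detected_genes = as.integer(rowSums(counts > 0)),
    total_counts = as.integer(total),
    mito_fraction = ifelse(total > 0,
                           rowSums(counts[, mito_genes, drop = FALSE]) /
                             pmax(total, 1), 0),
    cell_type = "unassigned",
    tls_id = NA_character_
  )

  truth <- structure(list(
    sample_id = sample_id,
    planted_regions = tibble(
      region = seq_len(params$n_tls),
      center_x_um = if (params$n_tls > 0) centers[, 1] else numeric(0),
      center_y_um = if (params$n_tls > 0) centers[, 2] else numeric(0),
      radius_um = rep(r, params$n_tls),
      mature = mature
    ),
    cell_region_id = region,
    cell_true_type = type,
    sample_tls_burden = params$n_tls * pi * r^2 / 1e6
  ), class = "tls_truth")

  list(cells = cells, counts = counts, truth = truth)
}

place_disc_centers <- function(n_tls, side, r, min_gap = 0) {
  if (n_tls == 0L) return(matrix(numeric(0), ncol = 2))
  if (side <= 2 * r) abort_param("Disc diameter exceeds the tissue side.")
  min_sep <- 2 * r + min_gap
  centers <- matrix(NA_real_, nrow = n_tls, ncol = 2)
  for (i in seq_len(n_tls)) {
    for (try in seq_len(5000L)) {
      cand <- runif(2, min = r, max = side - r)
      if (i == 1L ||
          all(sqrt(rowSums(sweep(centers[seq_len(i - 1), , drop = FALSE],
                                 2, cand)^2)) > min_sep)) {
        centers[i, ] <- cand
        break
      }
    }
    if (anyNA(centers[i, ])) {
      abort_param("Could not place non-overlapping TLS discs; reduce n_tls or radius.")
    }
  }
  centers
}

sample_regions <- function(n, centers, r, side, boost) {
  n_tls <- nrow(centers)
  a_frac <- pi * r^2 / side^2
  w <- c(max(0, 1 - n_tls * a_frac), rep(boost * a_frac, n_tls))
  sample(0:n_tls, n, replace = TRUE, prob = w / sum(w))
}

place_cells <- function(region, centers, r, side) {
  n <- length(region)
  pos <- matrix(NA_real_, nrow = n, ncol = 2)
  bg <- region == 0L
  n_bg <- sum(bg)
  if (n_bg > 0L) {
    # uniform over the square minus the discs, by rejection
    xy <- matrix(runif(2 * n_bg, 0, side), ncol = 2)
    repeat {
      inside <- rep(FALSE, nrow(xy))
      for (k in seq_len(nrow(centers))) {
        inside <- inside |
          (xy[, 1] - centers[k, 1])^2 + (xy[, 2] - centers[k, 2])^2 <= r^2
      }
      if (!any(inside)) break
      xy[inside, ] <- matrix(runif(2 * sum(inside), 0, side), ncol = 2)
    }
    pos[bg, ] <- xy
  }
  for (k in seq_len(nrow(centers))) {
    idx <- which(region == k)
    if (length(idx) == 0L) next
    rad <- r * sqrt(runif(length(idx)))
    ang <- runif(length(idx), 0, 2 * pi)
    pos[idx, ] <- cbind(centers[k, 1] + rad * cos(ang),
                        centers[k, 2] + rad * sin(ang))
  }
  pos
}

simulate_counts <- function(params, type, region, mature) {
  genes <- sim_gene_universe()
  n <- length(type)
  mu <- matrix(params$nb_mean, nrow = n, ncol = length(genes),
               dimnames = list(NULL, genes))

  panel <- marker_panel()
  tls_genes <- c("MKI67", "CXCR5", "CCL2")
  gc <- germinal_center_markers()
  marker_class <- unique(c(unlist(panel, use.names = FALSE), tls_genes, gc))
  mu[, marker_class] <- params$nb_mean * params$off_target_frac
  for (t in names(panel)) {
    rows <- type == t
    if (any(rows)) mu[rows, panel[[t]]] <- params$nb_mean * params$marker_fold
  }
  in_disc <- region > 0L
  if (any(in_disc)) {
    mu[in_disc, tls_genes] <- params$nb_mean * params$marker_fold
  }
  in_mature <- region %in% which(mature)
  if (any(in_mature)) {
    mu[in_mature, gc] <- params$nb_mean * params$gc_fold_mature
  }

  mito <- startsWith(genes, "MT-")
  f <- params$mito_frac_mean
  if (f > 0) {
    nonmito_total <- rowSums(mu[, !mito, drop = FALSE])
    mu[, mito] <- (f / (1 - f)) * nonmito_total / sum(mito)
  } else {
    mu[, mito] <- 0
  }

  size <- 1 / params$nb_dispersion
  counts <- matrix(rnbinom(length(mu), mu = as.vector(mu), size = size),
                   nrow = n, dimnames = dimnames(mu))
  storage.mode(counts) <- "integer"
  counts
}

#' Simulate a cohort of tissue samples with TLS-linked survival
#'
#' Draws a per-sample number of planted discs (binomial around the
#' parameter `n_tls`, so burden varies across the cohort), simulates each
#' sample with a deterministically derived per-sample seed, and generates
#' per-sample overall survival from an exponential proportional-hazards
#' model: `time ~ Exp(rate = lambda0 * exp(-survival_beta * z))` with
#' `lambda0 = log(2) / 24` per month and `z` the standardized TLS burden.
#' With probability `censor_frac` a subject is censored at a uniform time
#' before its event.
#'
#' @param params A [sim_params()] object.
#' @param n_samples Number of samples (>= 2).
#' @param seed Cohort seed (defaults to `params$seed`).
#' @param generate_counts Set `FALSE` to skip expression and cell placement
#'   and return only planted truth and survival (fast path for survival
#'   power studies).
#' @return List with `samples` (named list of [simulate_sample()] outputs;
#'   `NULL`s when `generate_counts = FALSE`), `survival` (per-sample
#'   tibble: `sample_id`, `time`, `event`, `group = NA`), `truths` (named
#'   list of `tls_truth`), and `burden` (named numeric vector, mm^2).
#' @export
simulate_cohort <- function(params, n_samples, seed = params$seed,
                            generate_counts = TRUE) {
  stopifnot(inherits(params, "sim_params"))
  check_number(n_samples, "n_samples", lower = 2, integerish = TRUE)
  check_number(seed, "seed", integerish = TRUE)

  set.seed(seed)
  n_tls_s <- rbinom(n_samples, size = 2 * params$n_tls, prob = 0.5)
  max_fit <- floor(params$tissue_side_um^2 / (pi * params$tls_radius_um^2) / 2)
  n_tls_s <- pmin(n_tls_s, max_fit)
  sample_ids <- sprintf("S%02d", seq_len(n_samples))

  samples <- vector("list", n_samples)
  truths <- vector("list", n_samples)
  names(samples) <- names(truths) <- sample_ids
  for (i in seq_len(n_samples)) {
    p_i <- params
    p_i$n_tls <- n_tls_s[i]
    p_i$seed <- (abs(seed) * 1013L + i * 7919L) %% .Machine$integer.max
    if (generate_counts) {
      sim <- simulate_sample(p_i, sample_ids[i])
      samples[[i]] <- sim
      truths[[i]] <- sim$truth
    } else {
      truths[[i]] <- structure(list(
        sample_id = sample_ids[i],
        planted_regions = tibble(region = seq_len(p_i$n_tls)),
        cell_region_id = integer(0), cell_true_type = character(0),
        sample_tls_burden = p_i$n_tls * pi * p_i$tls_radius_um^2 / 1e6
      ), class = "tls_truth")
    }
  }

  burden <- vapply(truths, function(t) t$sample_tls_burden, numeric(1))
  z <- if (sd(burden) > 0) (burden - mean(burden)) / sd(burden) else rep(0, n_samples)

  set.seed((abs(seed) * 2027L + 17L) %% .Machine$integer.max)
  lambda0 <- log(2) / 24
  time <- rexp(n_samples, rate = lambda0 * exp(-params$survival_beta * z))
  censored <- runif(n_samples) < params$censor_frac
  obs_time <- ifelse(censored, runif(n_samples) * time, time)
  survival <- tibble(
    sample_id = sample_ids,
    time = obs_time,
    event = as.integer(!censored),
    group = NA_character_
  )

  list(samples = samples, survival = survival, truths = truths,
       burden = burden)
}
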