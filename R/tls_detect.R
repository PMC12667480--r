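#' TLS detection parameters
#'
#' Defaults for density-based TLS calling: `eps = 0.08` in per-sample
#' min-max-normalized coordinates, `min_samples = 100`, and a strict size
#' filter keeping clusters with more than `min_cluster_cells` member cells.
#' Constituent types are the TLS-forming immune populations (B, NK/T,
#' dendritic cells). `eps_units = "um"` interprets `eps` in micrometres
#' instead (no coordinate normalization).
#'
#' @param eps DBSCAN neighborhood radius (> 0).
#' @param min_samples DBSCAN core-point neighborhood size.
#' @param min_cluster_cells Clusters must exceed this many cells to be
#'   called TLS.
#' @param constituent_types Cell-type labels whose cells form TLSs.
#' @param eps_units `"normalized"` (per-sample min-max scaling to the unit
#'   square) or `"um"`.
#' @return A `detection_params` list.
#' @export
detection_params <- function(eps = 0.08, min_samples = 100,
                             min_cluster_cells = 100,
                             constituent_types = c("B", "NKT", "DC"),
                             eps_units = c("normalized", "um")) {
  check_number(eps, "eps", lower = 0, allow_boundary = FALSE)
  check_number(min_samples, "min_samples", lower = 1, integerish = TRUE)
  check_number(min_cluster_cells, "min_cluster_cells", lower = 1,
               integerish = TRUE)
  eps_units <- arg_match(eps_units)
  structure(list(eps = eps, min_samples = min_samples,
                 min_cluster_cells = min_cluster_cells,
                 constituent_types = as.character(constituent_types),
                 eps_units = eps_units),
            class = "detection_params")
}

#' Min-max normalize spatial coordinates of one sample
#'
#' Scales x and y independently to [0, 1] so the DBSCAN radius has a
#' comparable meaning across tissue sections of different physical extent.
#' The affine transform is attached for exact inverse mapping.
#'
#' @param cells Per-cell tibble of a single sample with `x_um`, `y_um`.
#' @return Matrix of normalized points with `attr(, "transform")` holding
#'   `x_min`, `x_range`, `y_min`, `y_range`.
#' @export
normalize_coordinates <- function(cells) {
  check_cells(cells)
  if (nrow(cells) < 1L) abort_param("Need at least one cell.")
  x <- cells$x_um; y <- cells$y_um
  if (any(!is.finite(x)) || any(!is.finite(y))) {
    abort_param("Coordinates must be finite.")
  }
  rx <- diff(range(x)); ry <- diff(range(y))
  if (rx == 0 || ry == 0) {
    abort_param("Degenerate spatial extent: all x or all y coordinates equal.")
  }
  pts <- cbind(x = (x - min(x)) / rx, y = (y - min(y)) / ry)
  attr(pts, "transform") <- list(x_min = min(x), x_range = rx,
                                 y_min = min(y), y_range = ry)
  pts
}

#' @rdname normalize_coordinates
#' @param points Normalized points.
#' @param transform The transform attached by [normalize_coordinates()].
#' @return Matrix of micrometre coordinates.
#' @export
denormalize_coordinates <- function(points, transform) {
  cbind(x = points[, 1] * transform$x_range + transform$x_min,
        y = points[, 2] * transform$y_range + transform$y_min)
}

#' Call TLS regions from annotated cells
#'
#' Per sample: cells of the constituent immune types are clustered with
#' [dbscan_cluster()] on (by default) min-max-normalized coordinates;
#' clusters with strictly more than `min_cluster_cells` members become TLS
#' regions. Geometry is computed on the original micrometre coordinates:
#' convex hull by monotone chain and area by the shoelace formula,
#' converted to mm^2 (1 mm^2 = 1e6 um^2). Region ids are deterministic:
#' `<sample>_TLS<rank>`, ranked by the smallest member cell index within
#' the sample.
#'
#' @param cells Annotated per-cell tibble (needs `cell_type`).
#' @param params A [detection_params()] object.
#' @return A `tls_regions` tibble: one row per region with `region_id`,
#'   `sample_id`, `n_cells`, `area_mm2`, centroid, maturity placeholders,
#'   and list-columns `member_cell_ids`, `counts_by_type`, `hull`.
#' @export
call_tls <- function(cells, params = detection_params()) {
  check_cells(cells, required = c("cell_id", "sample_id", "x_um", "y_um",
                                  "cell_type"))
  stopifnot(inherits(params, "detection_params"))
  samples <- unique(cells$sample_id)
  regions <- purrr::map(samples, function(s) {
    call_tls_sample(cells[cells$sample_id == s, , drop = FALSE], s, params)
  })
  out <- bind_rows(regions)
  if (nrow(out) == 0L) {
    out <- empty_regions()
  }
  class(out) <- c("tls_regions", class(out))
  out
}

call_tls_sample <- function(sc, sample_id, params) {
  members <- sc[sc$cell_type %in% params$constituent_types, , drop = FALSE]
  if (nrow(members) == 0L) {
    inform(sprintf("Sample %s: no constituent-type cells; no TLS called.",
                   sample_id))
    return(empty_regions())
  }
  pts <- if (params$eps_units == "normalized") {
    normalize_coordinates(members)
  } else {
    cbind(x = members$x_um, y = members$y_um)
  }
  labels <- dbscan_cluster(pts, params$eps, params$min_samples)
  ids <- setdiff(unique(labels), 0L)
  keep <- ids[vapply(ids, function(i) sum(labels == i), numeric(1)) >
                params$min_cluster_cells]
  if (length(keep) == 0L) return(empty_regions())
  # dbscan_cluster already ranks cluster ids by smallest member index
  rows <- purrr::map(seq_along(sort(keep)), function(rank) {
    cl <- sort(keep)[rank]
    mem <- members[labels == cl, , drop = FALSE]
    coords <- cbind(x = mem$x_um, y = mem$y_um)
    hull <- convex_hull(coords)
    area <- polygon_area(hull) / 1e6
    if (area == 0) {
      warn(sprintf("Sample %s: TLS cluster %d has a degenerate hull (area 0).",
                   sample_id, cl))
    }
    tibble(
      region_id = sprintf("%s_TLS%d", sample_id, rank),
      sample_id = sample_id,
      n_cells = nrow(mem),
      area_mm2 = area,
      centroid_x_um = mean(mem$x_um),
      centroid_y_um = mean(mem$y_um),
      maturity_score = NA_real_,
      maturity_label = NA_character_,
      member_cell_ids = list(mem$cell_id),
      counts_by_type = list(table(mem$cell_type)),
      hull = list(hull)
    )
  })
  bind_rows(rows)
}

empty_regions <- function() {
  tibble(
    region_id = character(0), sample_id = character(0),
    n_cells = integer(0), area_mm2 = numeric(0),
    centroid_x_um = numeric(0), centroid_y_um = numeric(0),
    maturity_score = numeric(0), maturity_label = character(0),
    member_cell_ids = list(), counts_by_type = list(), hull = list()
  )
}

#' Assign every cell to a TLS or the nTLS compartment
#'
#' A cell of any type lying strictly inside or on a region's convex hull is
#' assigned that region's id; cells in no hull get `NA` (the nTLS
#' compartment). A cell inside overlapping hulls goes to the region with
#' the smaller id.
#'
#' @param cells Per-cell tibble.
#' @param regions `tls_regions` from [call_tls()].
#' @return `cells` with `tls_id` filled (`NA` = nTLS).
#' @export
assign_tls_membership <- function(cells, regions) {
  check_cells(cells)
  cells$tls_id <- NA_character_
  if (nrow(regions) == 0L) return(cells)
  for (s in unique(regions$sample_id)) {
    idx <- which(cells$sample_id == s)
    if (length(idx) == 0L) next
    pts <- cbind(cells$x_um[idx], cells$y_um[idx])
    reg <- regions[regions$sample_id == s, , drop = FALSE]
    for (r in order(reg$region_id)) {
      inside <- points_in_hull(pts, reg$hull[[r]])
      fill <- inside & is.na(cells$tls_id[idx])
      cells$tls_id[idx[fill]] <- reg$region_id[r]
    }
  }
  cells
}

#' Validate called TLS regions with marker genes
#'
#' Tests whether TLS-associated genes (proliferation, follicular homing and
#' chemoattraction: MKI67, CXCR5, CCL2 by default) are expressed higher
#' inside TLS regions than outside, using a one-sided Wilcoxon rank-sum
#' test per gene (TLS > nTLS) with BH adjustment across the tested genes.
#'
#' @param norm Normalized matrix (cells x genes).
#' @param cells Per-cell tibble with `tls_id` assigned.
#' @param genes Validation genes.
#' @return Tibble with `gene`, `effect` (difference of compartment means),
#'   `p`, `p_adj`.
#' @export
validate_tls_markers <- function(norm, cells,
                                 genes = c("MKI67", "CXCR5", "CCL2")) {
  check_matrix(norm, "norm")
  check_cells(cells, required = c("cell_id", "sample_id", "x_um", "y_um",
                                  "tls_id"))
  cells <- cells[cells$cell_id %in% rownames(norm), , drop = FALSE]
  in_tls <- !is.na(cells$tls_id)
  if (!any(in_tls) || all(in_tls)) {
    abort_param("Both TLS and nTLS compartments must be non-empty.")
  }
  present <- intersect(genes, colnames(norm))
  skipped <- setdiff(genes, present)
  if (length(skipped) > 0L) {
    warn(sprintf("Validation gene(s) absent from matrix, skipped: %s.",
                 paste(skipped, collapse = ", ")))
  }
  if (length(present) == 0L) abort_param("No validation gene present.")
  tls_expr <- norm[cells$cell_id[in_tls], present, drop = FALSE]
  ntls_expr <- norm[cells$cell_id[!in_tls], present, drop = FALSE]
  rows <- purrr::map(present, function(g) {
    test <- wilcoxon_rank_sum(tls_expr[, g], ntls_expr[, g],
                              alternative = "greater")
    tibble(gene = g, effect = mean(tls_expr[, g]) - mean(ntls_expr[, g]),
           p = test$p)
  })
  out <- bind_rows(rows)
  out$p_adj <- bh_adjust(out$p)
  out
}

#' Per-sample TLS score report and high/low grouping
#'
#' Summarizes TLS burden per sample by one of two criteria — total
#' constituent cells across the sample's TLS regions (`"cell_count"`) or
#' cumulative TLS area in mm^2 (`"cumulative_area"`) — and stratifies the
#' cohort at the median: a sample is "high" only when its statistic is
#' strictly greater than the cohort median. Samples with no called TLS
#' contribute a statistic of 0.
#'
#' @param cells Per-cell tibble covering all cohort samples.
#' @param regions `tls_regions` for the same samples.
#' @param criterion Grouping statistic.
#' @return Tibble with per-sample `n_tls`, `total_tls_cells`,
#'   `cumulative_area_mm2`, `statistic`, `group`; the criterion and cohort
#'   median are in attributes `criterion` and `median`.
#' @export
tls_score_report <- function(cells, regions,
                             criterion = c("cell_count", "cumulative_area")) {
  criterion <- arg_match(criterion)
  check_cells(cells)
  samples <- unique(cells$sample_id)
  if (length(samples) < 2L) {
    abort_param("Median split needs at least 2 samples.")
  }
  per_sample <- purrr::map(samples, function(s) {
    reg <- regions[regions$sample_id == s, , drop = FALSE]
    tibble(sample_id = s, n_tls = nrow(reg),
           total_tls_cells = sum(reg$n_cells),
           cumulative_area_mm2 = sum(reg$area_mm2))
  })
  out <- bind_rows(per_sample)
  out$statistic <- if (criterion == "cell_count") {
    as.numeric(out$total_tls_cells)
  } else {
    out$cumulative_area_mm2
  }
  grp <- median_split(out$statistic, rule = "strict_gt")
  out$group <- as.character(grp)
  attr(out, "criterion") <- criterion
  attr(out, "median") <- attr(grp, "median")
  out
}
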