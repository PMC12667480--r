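#' Adjusted Rand index between two labelings
#'
#' Chance-corrected agreement of two partitions of the same items, from the
#' pair-counting contingency table. Returns 1 for identical partitions and
#' about 0 for independent ones; defined as 1 when the correction term is
#' degenerate (e.g., both partitions trivial).
#'
#' @param a,b Vectors of cluster labels of equal length.
#' @return A number in [-1, 1].
#' @export
adjusted_rand_index <- function(a, b) {
  if (length(a) != length(b)) abort_param("Labelings must have equal length.")
  n <- length(a)
  if (n == 0L) return(1)
  tab <- table(a, b)
  sum_ij <- sum(choose(tab, 2))
  sum_a <- sum(choose(rowSums(tab), 2))
  sum_b <- sum(choose(colSums(tab), 2))
  pairs <- choose(n, 2)
  expected <- sum_a * sum_b / pairs
  max_index <- (sum_a + sum_b) / 2
  if (max_index == expected) return(1)
  (sum_ij - expected) / (max_index - expected)
}

#' Compare detected TLS regions with the planted truth
#'
#' A detected region matches a planted disc when its centroid lies within
#' the planted radius of the disc center; matches are made one-to-one,
#' greedily by ascending centroid-to-center distance. Precision is the
#' matched fraction of detected regions and recall the matched fraction of
#' planted discs; the cell-level agreement is the adjusted Rand index of
#' the per-cell planted region id (0 = background) against the per-cell
#' detected region membership.
#'
#' When no region was detected but discs were planted, precision is
#' undefined and reported as 1 with `flags$precision_undefined = TRUE`
#' (recall is 0); symmetrically for an empty truth.
#'
#' @param truth A `tls_truth` from [simulate_sample()].
#' @param regions Detected `tls_regions` for the same sample.
#' @param cells The per-cell tibble the regions were called on (orders the
#'   per-cell labels; defaults to truth order via cell index).
#' @return Object of class `recovery_metrics`: `region_precision`,
#'   `region_recall`, `cell_label_ari`, `matched_pairs` (tibble), `flags`.
#' @export
truth_recovery <- function(truth, regions, cells = NULL) {
  stopifnot(inherits(truth, "tls_truth"))
  if (nrow(regions) > 0L &&
      !all(regions$sample_id == truth$sample_id)) {
    abort_param("Detected regions belong to a different sample than the truth.")
  }
  n_truth <- nrow(truth$planted_regions)
  n_det <- nrow(regions)
  flags <- list(precision_undefined = FALSE, recall_undefined = FALSE)

  matched <- tibble(truth_region = integer(0), region_id = character(0),
                    distance_um = numeric(0))
  if (n_truth > 0L && n_det > 0L) {
    d <- outer(seq_len(n_det), seq_len(n_truth), Vectorize(function(i, j) {
      sqrt((regions$centroid_x_um[i] - truth$planted_regions$center_x_um[j])^2 +
           (regions$centroid_y_um[i] - truth$planted_regions$center_y_um[j])^2)
    }))
    eligible <- which(d <= matrix(truth$planted_regions$radius_um,
                                  nrow = n_det, ncol = n_truth, byrow = TRUE),
                      arr.ind = TRUE)
    if (length(eligible) > 0L) {
      ord <- order(d[eligible])
      used_det <- logical(n_det); used_truth <- logical(n_truth)
      for (e in ord) {
        i <- eligible[e, 1]; j <- eligible[e, 2]
        if (!used_det[i] && !used_truth[j]) {
          used_det[i] <- TRUE; used_truth[j] <- TRUE
          matched <- bind_rows(matched, tibble(
            truth_region = j, region_id = regions$region_id[i],
            distance_um = d[i, j]))
        }
      }
    }
  }

  n_match <- nrow(matched)
  precision <- if (n_det == 0L) {
    flags$precision_undefined <- TRUE
    1
  } else n_match / n_det
  recall <- if (n_truth == 0L) {
    flags$recall_undefined <- TRUE
    1
  } else n_match / n_truth

  detected_labels <- detected_cell_labels(truth, regions, cells)
  ari <- adjusted_rand_index(truth$cell_region_id, detected_labels)

  structure(list(region_precision = precision, region_recall = recall,
                 cell_label_ari = ari, matched_pairs = matched,
                 flags = flags),
            class = "recovery_metrics")
}

# Per-cell detected region label (0 = nTLS) aligned with the truth's cell
# order. `cells` supplies the cell ids in that order; without it, member
# ids of the form <sample>_c<index> are mapped back by index.
detected_cell_labels <- function(truth, regions, cells) {
  n <- length(truth$cell_region_id)
  labels <- integer(n)
  if (nrow(regions) == 0L) return(labels)
  ids <- if (!is.null(cells)) {
    cells$cell_id
  } else {
    sprintf("%s_c%05d", truth$sample_id, seq_len(n))
  }
  for (r in seq_len(nrow(regions))) {
    m <- match(regions$member_cell_ids[[r]], ids)
    labels[m[!is.na(m)]] <- r
  }
  labels
}

#' @export
print.recovery_metrics <- function(x, ...) {
  cat(sprintf(
    "TLS recovery: precision = %.3f%s, recall = %.3f%s, cell ARI = %.3f (%d matched)\n",
    x$region_precision,
    if (x$flags$precision_undefined) " (undefined, no detections)" else "",
    x$region_recall,
    if (x$flags$recall_undefined) " (undefined, empty truth)" else "",
    x$cell_label_ari, nrow(x$matched_pairs)))
  invisible(x)
}

#' @method glance recovery_metrics
#' @export
glance.recovery_metrics <- function(x, ...) {
  tibble(region_precision = x$region_precision,
         region_recall = x$region_recall,
         cell_label_ari = x$cell_label_ari,
         n_matched = nrow(x$matched_pairs))
}
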