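#' Gene-set activity by area under the recovery curve
#'
#' Per-cell rank-based activity score: genes are ranked by decreasing
#' expression (ties broken by gene-column order), and the recovery curve
#' counts set genes among the top `k = ceiling(top_fraction * n_genes)`
#' ranks. The score is the area under this step curve divided by the
#' maximal achievable area (all set genes at the very top), so it lies in
#' [0, 1] and depends only on the ranking — any strictly increasing
#' transform of a cell's expression leaves it unchanged.
#'
#' @param norm Normalized matrix (cells x genes).
#' @param set Gene ids (character vector or GMT set).
#' @param top_fraction Fraction of top ranks integrated (default 0.05).
#' @return Named numeric vector of per-cell scores in [0, 1].
#' @export
aucell_score <- function(norm, set, top_fraction = 0.05) {
  check_matrix(norm, "norm")
  check_number(top_fraction, "top_fraction", lower = 0, upper = 1,
               allow_boundary = FALSE)
  genes <- as_gene_ids(set)
  set_idx <- which(colnames(norm) %in% genes)
  if (length(set_idx) == 0L) {
    abort_param(sprintf("No set gene present in the matrix: %s.",
                        paste(genes, collapse = ", ")))
  }
  n_genes <- ncol(norm)
  k <- max(1L, ceiling(top_fraction * n_genes))
  m <- length(set_idx)
  max_area <- sum(pmin(seq_len(k), m))
  scores <- vapply(seq_len(nrow(norm)), function(i) {
    x <- norm[i, ]
    o <- order(-x, seq_len(n_genes))
    rk <- integer(n_genes)
    rk[o] <- seq_len(n_genes)
    hits <- rk[set_idx]
    hits <- hits[hits <= k]
    if (length(hits) == 0L) return(0)
    sum(cumsum(tabulate(hits, nbins = k))) / max_area
  }, numeric(1))
  setNames(scores, rownames(norm))
}

#' Single-sample gene-set enrichment (weighted-KS running sum)
#'
#' Rank-weighted Kolmogorov-Smirnov statistic for one expression profile
#' (a cell, a TLS region mean, or a sample mean). Genes are ordered by
#' decreasing expression; walking down that list, the running sum steps up
#' at set genes by their rank weight `r^alpha` (with `r = n` for the
#' highest-expressed gene, normalized so the up-steps total 1) and down by
#' `1/(n - m)` at the other genes. The score is the sum of the running-sum
#' values over all steps (the integrated deviation from zero); it depends
#' only on gene ranks.
#'
#' @param expr Named numeric expression vector (length >= 2).
#' @param set Gene ids; must not cover every gene in `expr`.
#' @param alpha Rank-weighting exponent (>= 0; 0.25 by default, the
#'   conventional single-sample GSEA weighting).
#' @return A single numeric enrichment score.
#' @export
ssgsea_score <- function(expr, set, alpha = 0.25) {
  if (!is.numeric(expr) || length(expr) < 2L || is.null(names(expr))) {
    abort_param("`expr` must be a named numeric vector of length >= 2.")
  }
  check_number(alpha, "alpha", lower = 0)
  genes <- as_gene_ids(set)
  n <- length(expr)
  in_set <- names(expr) %in% genes
  m <- sum(in_set)
  if (m == 0L) abort_param("No set gene present in the profile.")
  if (m == n) abort_param("Set covers every gene; down-step undefined.")
  o <- order(-expr, seq_len(n))
  in_set_ord <- in_set[o]
  rank_value <- n - seq_len(n) + 1           # top-expressed gene gets n
  up <- rank_value^alpha
  up_norm <- sum(up[in_set_ord])
  steps <- ifelse(in_set_ord, up / up_norm, -1 / (n - m))
  sum(cumsum(steps))
}

#' @rdname ssgsea_score
#' @param mat Matrix of profiles (units x genes).
#' @param normalize Divide scores by their range across the scored units.
#' @return For `ssgsea_scores()`: named numeric vector, one score per row
#'   of `mat`.
#' @export
ssgsea_scores <- function(mat, set, alpha = 0.25, normalize = FALSE) {
  check_matrix(mat, "mat")
  s <- vapply(seq_len(nrow(mat)), function(i) {
    ssgsea_score(mat[i, ], set, alpha = alpha)
  }, numeric(1))
  if (normalize) {
    rng <- max(s) - min(s)
    if (rng > 0) s <- s / rng
  }
  setNames(s, rownames(mat))
}

#' Derive per-group marker gene sets by differential expression
#'
#' For each group label, runs a two-sided Wilcoxon test of the group
#' against all other cells per gene with BH adjustment across genes, and
#' retains genes with `p_adj < adj_p_max` and `|log2fc| > min_abs_log2fc`
#' (strict). The retained genes form that group's marker set; groups with
#' no retained genes yield an empty set with a warning.
#'
#' @param norm Normalized matrix (cells x genes).
#' @param labels Per-cell group labels (>= 2 groups, each >= 2 cells).
#' @param adj_p_max,min_abs_log2fc Retention thresholds.
#' @return A `gene_set_collection`, one set per group.
#' @export
derive_marker_sets <- function(norm, labels, adj_p_max = 0.05,
                               min_abs_log2fc = 0.1) {
  check_matrix(norm, "norm")
  if (length(labels) != nrow(norm)) {
    abort_param("`labels` must have one entry per cell.")
  }
  groups <- unique(as.character(labels))
  if (length(groups) < 2L) abort_param("Need at least 2 groups.")
  counts <- table(labels)
  if (any(counts < 2L)) {
    abort_param(sprintf("Every group needs >= 2 cells; too small: %s.",
                        paste(names(counts)[counts < 2], collapse = ", ")))
  }
  sets <- lapply(groups, function(g) {
    de <- de_table(norm, as.character(labels) == g)
    kept <- de$gene[de$p_adj < adj_p_max & abs(de$log2fc) > min_abs_log2fc]
    if (length(kept) == 0L) {
      warn(sprintf("Group '%s': no gene passed the marker thresholds.", g))
    }
    kept
  })
  names(sets) <- groups
  structure(sets, class = "gene_set_collection",
            description = setNames(paste("markers of", groups), groups))
}

#' Germinal-center marker genes
#'
#' The six germinal-center genes used to score TLS maturity.
#' @return Character vector of gene ids.
#' @export
germinal_center_markers <- function() {
  c("BCL6", "AICDA", "CD38", "ICOS", "CXCR5", "CXCL13")
}

#' Classify TLS maturity by germinal-center enrichment
#'
#' Each region's expression profile is the unweighted mean of the
#' log-normalized expression of its member cells; the profile is scored
#' with [ssgsea_score()] on the germinal-center marker set, and a region is
#' labeled `mature` when its score is greater than or equal to the cohort
#' median (so ties at the median are mature), `immature` otherwise.
#'
#' @param regions `tls_regions` with at least 2 regions.
#' @param norm Normalized matrix covering the member cells.
#' @param gc_set Germinal-center genes.
#' @param alpha ssGSEA weighting exponent.
#' @param normalize Normalize scores by their range across regions before
#'   the median split.
#' @return `regions` with `maturity_score` and `maturity_label` filled; the
#'   cohort median score is in `attr(, "median_score")`.
#' @export
classify_maturity <- function(regions, norm,
                              gc_set = germinal_center_markers(),
                              alpha = 0.25, normalize = FALSE) {
  if (nrow(regions) < 2L) {
    abort_param("Maturity classification needs >= 2 regions (cohort median).")
  }
  check_matrix(norm, "norm")
  if (length(intersect(as_gene_ids(gc_set), colnames(norm))) == 0L) {
    abort_param("No germinal-center gene present in the matrix.")
  }
  profiles <- t(vapply(regions$member_cell_ids, function(ids) {
    ids <- intersect(ids, rownames(norm))
    if (length(ids) == 0L) abort_param("A region has no member cells in `norm`.")
    colMeans(norm[ids, , drop = FALSE])
  }, numeric(ncol(norm))))
  rownames(profiles) <- regions$region_id
  scores <- ssgsea_scores(profiles, gc_set, alpha = alpha,
                          normalize = normalize)
  med <- median(scores)
  regions$maturity_score <- as.numeric(scores)
  regions$maturity_label <- unname(ifelse(scores >= med, "mature", "immature"))
  attr(regions, "median_score") <- med
  regions
}
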