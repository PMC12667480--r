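#' Quality-control thresholds
#'
#' Defaults follow common imaging/scRNA practice for tumor tissue: cells
#' with fewer than 500 detected genes, more than 5000 detected genes, or a
#' mitochondrial count fraction above 20% are excluded.
#'
#' @param min_genes Minimum detected genes per cell.
#' @param max_genes Maximum detected genes per cell.
#' @param max_mito_fraction Maximum mitochondrial fraction in (0, 1].
#' @return A `qc_thresholds` list.
#' @export
qc_thresholds <- function(min_genes = 500, max_genes = 5000,
                          max_mito_fraction = 0.20) {
  check_number(min_genes, "min_genes", lower = 0, integerish = TRUE)
  check_number(max_genes, "max_genes", lower = 1, integerish = TRUE)
  if (min_genes >= max_genes) abort_param("`min_genes` must be < `max_genes`.")
  check_number(max_mito_fraction, "max_mito_fraction", lower = 0, upper = 1,
               allow_boundary = TRUE)
  if (max_mito_fraction == 0) abort_param("`max_mito_fraction` must be in (0, 1].")
  structure(list(min_genes = min_genes, max_genes = max_genes,
                 max_mito_fraction = max_mito_fraction),
            class = "qc_thresholds")
}

#' Filter cells by detected genes and mitochondrial content
#'
#' Recomputes `detected_genes`, `total_counts` and `mito_fraction` from the
#' count matrix (mitochondrial genes recognized by an id prefix), then
#' retains cells with `min_genes <= detected_genes <= max_genes` and
#' `mito_fraction <= max_mito_fraction`. A cell failing several rules is
#' tallied once, under the first failing rule in the order min_genes,
#' max_genes, mito_fraction. Applying the filter to its own output removes
#' nothing.
#'
#' @param counts Integer count matrix, cells x genes.
#' @param cells Per-cell tibble aligned on `cell_id`.
#' @param thresholds A [qc_thresholds()] object.
#' @param mito_prefix Gene-id prefix marking mitochondrial genes.
#' @return List with `counts` and `cells` restricted to retained cells
#'   (QC columns refreshed) and `report`, a tibble of per-rule removal
#'   counts with `n_input` / `n_retained` attributes.
#' @export
qc_filter <- function(counts, cells, thresholds = qc_thresholds(),
                      mito_prefix = "MT-") {
  check_matrix(counts, "counts")
  check_cells(cells)
  stopifnot(inherits(thresholds, "qc_thresholds"))
  shared <- intersect(rownames(counts), cells$cell_id)
  if (length(shared) == 0L) {
    abort_param("`counts` and `cells` share no cell ids.")
  }
  counts <- counts[shared, , drop = FALSE]
  cells <- cells[match(shared, cells$cell_id), , drop = FALSE]

  mito_genes <- startsWith(colnames(counts), mito_prefix)
  detected <- rowSums(counts > 0)
  total <- rowSums(counts)
  mito <- ifelse(total > 0,
                 rowSums(counts[, mito_genes, drop = FALSE]) / pmax(total, 1), 0)

  fail_min <- detected < thresholds$min_genes
  fail_max <- !fail_min & detected > thresholds$max_genes
  fail_mito <- !fail_min & !fail_max & mito > thresholds$max_mito_fraction
  keep <- !(fail_min | fail_max | fail_mito)

  report <- tibble(
    rule = c("min_genes", "max_genes", "mito_fraction"),
    threshold = c(thresholds$min_genes, thresholds$max_genes,
                  thresholds$max_mito_fraction),
    n_removed = c(sum(fail_min), sum(fail_max), sum(fail_mito))
  )
  attr(report, "n_input") <- length(keep)
  attr(report, "n_retained") <- sum(keep)

  if (!any(keep)) {
    abort_param(paste0(
      "QC removed every cell (min_genes: ", sum(fail_min),
      ", max_genes: ", sum(fail_max), ", mito_fraction: ", sum(fail_mito), ")."))
  }

  cells <- mutate(cells,
    detected_genes = as.integer(detected),
    total_counts = as.integer(total),
    mito_fraction = mito
  )
  list(counts = counts[keep, , drop = FALSE],
       cells = cells[keep, , drop = FALSE],
       report = report)
}

#' Library-size log-normalization
#'
#' Scales each cell's counts to a common library size, then applies
#' `ln(1 + x)`: entry `ln(1 + scale * count / total_counts_of_cell)`. This
#' is the standard single-cell normalization; it makes expression
#' comparable across cells with different capture depth and is the input to
#' all signature scoring and differential expression in the pipeline.
#'
#' @param counts Integer count matrix, cells x genes.
#' @param scale Target library size (default 1e4).
#' @return Numeric matrix of the same shape and dimnames, with the
#'   normalization recorded in `attr(, "normalization")`.
#' @export
lognormalize <- function(counts, scale = 1e4) {
  check_matrix(counts, "counts")
  check_number(scale, "scale", lower = 0, allow_boundary = FALSE)
  totals <- rowSums(counts)
  if (any(totals == 0)) {
    abort_param("Cells with zero total counts present; run qc_filter() first.")
  }
  out <- log1p(scale * counts / totals)
  attr(out, "normalization") <- list(method = "lognorm", scale = scale,
                                     pseudocount = 1)
  out
}

#' Mean z-score signature score
#'
#' Per-cell score of a gene set: each present set gene is z-scored across
#' cells (genes with zero variance contribute 0), and the score is the mean
#' over present set genes. Used for marker-panel cell typing.
#'
#' @param norm Normalized matrix (cells x genes).
#' @param set Character vector of gene ids, or a gene set from [read_gmt()].
#' @return Named numeric vector of per-cell scores.
#' @export
score_signature_mean <- function(norm, set) {
  check_matrix(norm, "norm")
  genes <- as_gene_ids(set)
  present <- intersect(genes, colnames(norm))
  if (length(present) == 0L) {
    abort_param(sprintf("No set gene present in the matrix; missing: %s.",
                        paste(genes, collapse = ", ")))
  }
  sub <- norm[, present, drop = FALSE]
  mu <- colMeans(sub)
  sig <- apply(sub, 2, sd)
  z <- sweep(sub, 2, mu, "-")
  z <- sweep(z, 2, ifelse(sig > 0, sig, 1), "/")
  z[, sig == 0] <- 0
  setNames(rowMeans(z), rownames(norm))
}

#' Default marker panel for the seven major populations
#'
#' Canonical marker genes for the cell populations that make up tumor
#' tissue in imaging-based spatial data: B cells, dendritic cells, NK/T
#' cells, myeloid cells, cancer cells, endothelial cells and fibroblasts.
#' CD20 is the protein name of MS4A1, which the panel stores once.
#'
#' @return Named list mapping type label to marker gene ids. Panel order is
#'   the tie-break order in [assign_cell_types()].
#' @export
marker_panel <- function() {
  list(
    B = c("CD79A", "MS4A1"),
    DC = c("ITGAX", "CD40"),
    NKT = c("CD3D", "CD3E", "GNLY"),
    Myeloid = c("CD209", "CD68", "CD14", "CD163"),
    Cancer = c("CDKN2A", "EPCAM", "KRT18"),
    Endothelial = c("PECAM1", "CD34", "VWF"),
    Fibroblast = c("DCN", "THY1", "ACTA2")
  )
}

#' Assign cell types by marker-panel signature argmax
#'
#' Scores every panel type with [score_signature_mean()] and assigns each
#' cell the highest-scoring type; ties are broken by panel order, and cells
#' whose best score falls below `min_score` are labeled `"unassigned"`.
#'
#' @param cells Per-cell tibble; rows must match `rownames(norm)` by
#'   `cell_id`.
#' @param norm Normalized matrix (cells x genes).
#' @param panel Named list of marker genes per type (see [marker_panel()]).
#' @param min_score Minimum best score (z-mean scale) for assignment.
#' @return `cells` with `cell_type` filled; the per-type score matrix is in
#'   `attr(, "type_scores")`.
#' @export
assign_cell_types <- function(cells, norm, panel = marker_panel(),
                              min_score = 0.1) {
  check_cells(cells)
  check_matrix(norm, "norm")
  if (!all(cells$cell_id %in% rownames(norm))) {
    abort_param("Every cell in `cells` needs a row in `norm`.")
  }
  norm <- norm[cells$cell_id, , drop = FALSE]
  for (type in names(panel)) {
    if (length(intersect(panel[[type]], colnames(norm))) == 0L) {
      abort_param(sprintf("Panel type '%s' has no gene present in the matrix.",
                          type))
    }
  }
  scores <- vapply(panel, function(genes) score_signature_mean(norm, genes),
                   numeric(nrow(norm)))
  if (is.null(dim(scores))) scores <- matrix(scores, nrow = 1,
                                             dimnames = list(NULL, names(panel)))
  best <- max.col(scores, ties.method = "first")
  best_score <- scores[cbind(seq_len(nrow(scores)), best)]
  type <- ifelse(best_score >= min_score, names(panel)[best], "unassigned")
  out <- mutate(cells, cell_type = type)
  attr(out, "type_scores") <- scores
  out
}
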