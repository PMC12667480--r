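#' Wilcoxon rank-sum (Mann-Whitney) test with deterministic small-sample mode
#'
#' Two-group rank-sum test used throughout the pipeline (marker validation,
#' differential expression, score comparisons). For small samples
#' (`length(x) + length(y) <= 20` by default) the p-value is computed by full
#' enumeration of the permutation distribution of the Mann-Whitney U
#' statistic, which remains exact in the presence of ties (midranks are
#' enumerated as observed). Larger samples use the normal approximation with
#' tie-corrected variance and continuity correction.
#'
#' When every value in both groups is identical the test is vacuous and the
#' p-value is 1 by convention.
#'
#' @param x,y Numeric vectors of observations for the two groups.
#' @param alternative One of `"two.sided"`, `"greater"` (x tends larger),
#'   `"less"`.
#' @param exact Force exact enumeration (`TRUE`) or the normal approximation
#'   (`FALSE`); the default `NULL` picks exact when the total sample size is
#'   at most 20.
#' @return An object of class `wilcoxon_test`: a list with `statistic` (the
#'   Mann-Whitney U for `x`), `p`, `alternative`, `exact`, and group sizes.
#' @examples
#' wilcoxon_rank_sum(c(1, 2, 3), c(4, 5, 6))$p  # 0.1 by enumeration
#' @export
wilcoxon_rank_sum <- function(x, y,
                              alternative = c("two.sided", "greater", "less"),
                              exact = NULL) {
  alternative <- arg_match(alternative)
  if (length(x) < 1L || length(y) < 1L) {
    abort_param("Both groups must contain at least one observation.")
  }
  if (!all(is.finite(x)) || !all(is.finite(y))) {
    abort_param("Observations must be finite.")
  }
  nx <- length(x); ny <- length(y); n <- nx + ny
  if (is.null(exact)) exact <- n <= 20L

  out <- list(alternative = alternative, exact = exact, n_x = nx, n_y = ny)
  class(out) <- "wilcoxon_test"

  pooled <- c(x, y)
  r <- rank(pooled)
  u <- sum(r[seq_len(nx)]) - nx * (nx + 1) / 2
  out$statistic <- u

  if (length(unique(pooled)) == 1L) {
    out$p <- 1
    return(out)
  }

  if (exact) {
    p2 <- wilcox_exact_tails(r, nx, u)
  } else {
    p2 <- wilcox_normal_tails(r, nx, ny, u)
  }
  p <- switch(alternative,
    greater = p2$greater,
    less = p2$less,
    two.sided = min(1, 2 * min(p2$greater, p2$less))
  )
  # guard against underflow of the normal tail so p stays in (0, 1]
  out$p <- max(p, .Machine$double.xmin)
  out
}

# Exact tail probabilities by enumerating every assignment of nx of the
# pooled (mid)ranks to group x. C(20, 10) = 184756 at the default cutoff.
wilcox_exact_tails <- function(r, nx, u) {
  n <- length(r)
  offset <- nx * (nx + 1) / 2
  combos <- utils::combn(n, nx)
  us <- colSums(matrix(r[combos], nrow = nx)) - offset
  tol <- 1e-9
  list(greater = mean(us >= u - tol), less = mean(us <= u + tol))
}

# Normal approximation with tie-corrected variance and continuity correction.
wilcox_normal_tails <- function(r, nx, ny, u) {
  n <- nx + ny
  mu <- nx * ny / 2
  ties <- table(r)
  sigma2 <- (nx * ny / 12) * ((n + 1) - sum(ties^3 - ties) / (n * (n - 1)))
  if (sigma2 <= 0) return(list(greater = 1, less = 1))
  s <- sqrt(sigma2)
  list(
    greater = pnorm((u - mu - 0.5) / s, lower.tail = FALSE),
    less = pnorm((u - mu + 0.5) / s)
  )
}

#' @export
print.wilcoxon_test <- function(x, ...) {
  cat(sprintf("Wilcoxon rank-sum (%s, %s): U = %g, p = %.4g (n = %d vs %d)\n",
              x$alternative, if (x$exact) "exact" else "normal approx.",
              x$statistic, x$p, x$n_x, x$n_y))
  invisible(x)
}

#' @method glance wilcoxon_test
#' @export
glance.wilcoxon_test <- function(x, ...) {
  tibble(statistic = x$statistic, p_value = x$p, alternative = x$alternative,
         exact = x$exact, n_x = x$n_x, n_y = x$n_y)
}

#' Benjamini-Hochberg false-discovery-rate adjustment
#'
#' Step-up FDR adjustment of a vector of p-values, returned in input order.
#' Thin domain-checked wrapper over [stats::p.adjust()] with
#' `method = "BH"`.
#'
#' @param p Numeric vector of p-values in (0, 1].
#' @return Adjusted p-values, same length and order as `p`.
#' @export
bh_adjust <- function(p) {
  if (length(p) == 0L) return(numeric(0))
  if (!is.numeric(p) || any(!is.finite(p)) || any(p <= 0) || any(p > 1)) {
    abort_param("p-values must be finite and in (0, 1].")
  }
  p.adjust(p, method = "BH")
}

#' Hypergeometric over-representation analysis of gene sets
#'
#' For each set in a collection, tests whether the query gene list overlaps
#' the set more than expected by chance within a gene universe, using the
#' upper-tail hypergeometric probability P(X >= k). Sets and the query are
#' intersected with the universe first; BH adjustment is applied across sets.
#'
#' @param query Character vector of query genes (e.g., retained DEGs), or a
#'   gene set from [read_gmt()].
#' @param collection Named list of character vectors (a
#'   `gene_set_collection` from [read_gmt()] works directly).
#' @param universe Character vector of background genes; typically all genes
#'   in the expression matrix.
#' @return A tibble with one row per set: `set`, `k` (overlap), `K` (set size
#'   in universe), `n` (query size), `N` (universe size), `p`, `p_adj`,
#'   sorted by `p_adj` then `p` then set name.
#' @export
hypergeom_enrich <- function(query, collection, universe) {
  universe <- unique(as.character(universe))
  if (length(universe) == 0L) abort_param("`universe` is empty.")
  query <- intersect(unique(as_gene_ids(query)), universe)
  if (length(query) == 0L) {
    abort_param("No query gene is present in the universe.")
  }
  if (length(collection) == 0L || is.null(names(collection))) {
    abort_param("`collection` must be a named list of gene sets.")
  }
  rows <- purrr::imap(collection, function(set, name) {
    genes <- intersect(as_gene_ids(set), universe)
    k <- length(intersect(genes, query))
    K <- length(genes)
    tibble(
      set = name, k = k, K = K, n = length(query), N = length(universe),
      p = phyper(k - 1, K, length(universe) - K, length(query),
                 lower.tail = FALSE)
    )
  })
  out <- bind_rows(rows)
  out$p_adj <- bh_adjust(out$p)
  arrange(out, .data$p_adj, .data$p, .data$set)
}

#' Wilcoxon differential expression with preset retention thresholds
#'
#' Per-gene two-sided Wilcoxon rank-sum test between two groups of cells on
#' log-normalized expression, with BH adjustment across genes. The fold
#' change is computed on the de-logged scale:
#' `log2((mean(expm1(norm))_focal + 1) / (mean(expm1(norm))_rest + 1))`.
#'
#' Retention presets (strict inequalities):
#' * `"go-deg"`: `p < 0.05` and `log2fc > 0.2` (up-regulated genes feeding
#'   over-representation analysis);
#' * `"aucell-deg"`: `p_adj < 0.01` and `log2fc > 0.8`;
#' * `"marker-set"`: `p_adj < 0.05` and `|log2fc| > 0.1` (marker-set
#'   derivation).
#'
#' @param norm Normalized matrix from [lognormalize()] (cells x genes).
#' @param labels Logical (or two-level) vector along rows of `norm`; `TRUE` /
#'   the first level marks the focal group (e.g., TLS cells).
#' @param preset Which retention thresholds to apply.
#' @return A tibble of class `tls_de` with columns `gene`, `log2fc`, `p`,
#'   `p_adj`, `direction` (`up`/`down` w.r.t. the focal group), `retained`;
#'   ordered by ascending `p` then gene id. The preset is kept in
#'   `attr(, "preset")`.
#' @export
differential_expression <- function(norm, labels,
                                    preset = c("go-deg", "aucell-deg",
                                               "marker-set")) {
  preset <- arg_match(preset)
  check_matrix(norm, "norm")
  focal <- as_focal_labels(labels, nrow(norm))
  if (sum(focal) < 2L || sum(!focal) < 2L) {
    abort_param("Both groups need at least 2 cells.")
  }
  res <- de_table(norm, focal)
  thr <- de_presets()[[preset]]
  res$retained <- thr(res)
  res <- arrange(res, .data$p, .data$gene)
  attr(res, "preset") <- preset
  class(res) <- c("tls_de", class(res))
  res
}

de_presets <- function() {
  list(
    "go-deg" = function(d) d$p < 0.05 & d$log2fc > 0.2,
    "aucell-deg" = function(d) d$p_adj < 0.01 & d$log2fc > 0.8,
    "marker-set" = function(d) d$p_adj < 0.05 & abs(d$log2fc) > 0.1
  )
}

as_focal_labels <- function(labels, n) {
  if (length(labels) != n) {
    abort_param("`labels` must have one entry per cell (row of `norm`).")
  }
  if (is.logical(labels)) return(labels)
  lv <- unique(as.character(labels))
  if (length(lv) != 2L) abort_param("`labels` must define exactly 2 groups.")
  as.character(labels) == lv[1L]
}

# Shared per-gene Wilcoxon + BH + de-logged fold change.
de_table <- function(norm, focal) {
  a <- norm[focal, , drop = FALSE]
  b <- norm[!focal, , drop = FALSE]
  p <- vapply(seq_len(ncol(norm)), function(j) {
    wilcoxon_rank_sum(a[, j], b[, j], alternative = "two.sided")$p
  }, numeric(1))
  mu_a <- colMeans(expm1(a))
  mu_b <- colMeans(expm1(b))
  log2fc <- log2((mu_a + 1) / (mu_b + 1))
  tibble(
    gene = colnames(norm), log2fc = log2fc, p = p, p_adj = bh_adjust(p),
    direction = ifelse(log2fc >= 0, "up", "down")
  )
}

#' Split samples into high/low groups at the cohort median
#'
#' Median-split stratification used for TLS score groups (strict `>`, so a
#' sample exactly at the median is "low") and for signature-score groups
#' (`"gte"` puts the median sample in "high").
#'
#' @param values Numeric vector, one value per sample.
#' @param rule `"strict_gt"` (default): high iff value > median; `"gte"`:
#'   high iff value >= median.
#' @return Character vector of `"high"` / `"low"` labels along `values`,
#'   with the median in `attr(, "median")`.
#' @export
median_split <- function(values, rule = c("strict_gt", "gte")) {
  rule <- arg_match(rule)
  if (length(values) < 2L) {
    abort_param("Median split needs at least 2 samples.")
  }
  if (!is.numeric(values) || any(!is.finite(values))) {
    abort_param("`values` must be finite numbers.")
  }
  m <- median(values)
  high <- if (rule == "strict_gt") values > m else values >= m
  out <- ifelse(high, "high", "low")
  attr(out, "median") <- m
  out
}
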