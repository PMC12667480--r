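# Internal validation helpers. Errors carry condition classes so callers and
# tests can distinguish parameter misuse ("tlscape_param_error") from
# malformed input files ("tlscape_format_error").

abort_param <- function(msg, ...) {
  rlang::abort(msg, class = "tlscape_param_error", ...)
}

abort_format <- function(msg, ...) {
  rlang::abort(msg, class = "tlscape_format_error", ...)
}

check_number <- function(x, name, lower = -Inf, upper = Inf,
                         integerish = FALSE, allow_boundary = TRUE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    abort_param(sprintf("`%s` must be a single finite number.", name))
  }
  ok <- if (allow_boundary) x >= lower && x <= upper else x > lower && x < upper
  if (!ok) {
    abort_param(sprintf("`%s` = %g is outside [%g, %g].", name, x, lower, upper))
  }
  if (integerish && abs(x - round(x)) > 1e-8) {
    abort_param(sprintf("`%s` must be a whole number, got %g.", name, x))
  }
  invisible(x)
}

check_prob <- function(x, name) check_number(x, name, lower = 0, upper = 1)

check_matrix <- function(x, name = "x") {
  if (!is.matrix(x) || !is.numeric(x)) {
    abort_param(sprintf("`%s` must be a numeric matrix (cells x genes).", name))
  }
  if (is.null(rownames(x)) || is.null(colnames(x))) {
    abort_param(sprintf("`%s` must carry cell rownames and gene colnames.", name))
  }
  invisible(x)
}

check_cells <- function(cells, required = c("cell_id", "sample_id", "x_um", "y_um")) {
  if (!is.data.frame(cells)) abort_param("`cells` must be a data frame.")
  missing <- setdiff(required, names(cells))
  if (length(missing) > 0L) {
    abort_param(sprintf("`cells` is missing required column(s): %s.",
                        paste(missing, collapse = ", ")))
  }
  if (anyDuplicated(cells$cell_id)) abort_param("`cells$cell_id` must be unique.")
  invisible(cells)
}

# Resolve a gene-set argument (character vector or one element of a GMT
# collection) to a character vector of gene ids.
as_gene_ids <- function(set) {
  if (is.list(set) && !is.null(set$genes)) return(as.character(set$genes))
  as.character(set)
}
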