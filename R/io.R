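#' Read a cell-by-gene count matrix
#'
#' Two dialects, auto-detected from the extension:
#' * `.mtx` — MatrixMarket triplet in genes-x-cells orientation with sidecar
#'   files `genes.tsv` and `cells.tsv` (one id per line) next to the matrix;
#' * `.tsv` — dense table with a leading `cell_id` column and one column per
#'   gene.
#'
#' Entries must be non-negative integers; dimension or sidecar mismatches
#' raise a format error.
#'
#' @param path Path to the `.mtx` or `.tsv` file.
#' @return Integer matrix, cells as rows (rownames = cell ids), genes as
#'   columns (colnames = gene ids).
#' @export
read_counts <- function(path) {
  if (!file.exists(path)) abort_format(sprintf("File not found: %s", path))
  ext <- tolower(tools::file_ext(path))
  switch(ext,
    mtx = read_counts_mtx(path),
    tsv = read_counts_tsv(path),
    abort_format(sprintf("%s: unsupported count extension '.%s' (use .mtx or .tsv).",
                         path, ext))
  )
}

read_counts_mtx <- function(path) {
  lines <- readLines(path)
  body <- lines[!startsWith(lines, "%")]
  if (length(body) < 1L) abort_format(sprintf("%s: empty MatrixMarket file.", path))
  hdr <- as.numeric(strsplit(trimws(body[1L]), "\\s+")[[1L]])
  if (length(hdr) != 3L || any(!is.finite(hdr))) {
    abort_format(sprintf("%s: malformed MatrixMarket size line.", path))
  }
  n_entries <- length(body) - 1L
  if (n_entries != hdr[3L]) {
    abort_format(sprintf(
      "%s: header declares %d entries but body has %d.", path, hdr[3L], n_entries))
  }
  m <- Matrix::readMM(path)
  genes <- read_id_sidecar(file.path(dirname(path), "genes.tsv"), nrow(m), path)
  cells <- read_id_sidecar(file.path(dirname(path), "cells.tsv"), ncol(m), path)
  dense <- t(as.matrix(m))
  dimnames(dense) <- list(cells, genes)
  validate_count_values(dense, path)
}

read_id_sidecar <- function(side, expected, mtx_path) {
  if (!file.exists(side)) {
    abort_format(sprintf("%s: missing sidecar file %s.", mtx_path, side))
  }
  ids <- readLines(side)
  ids <- ids[nzchar(ids)]
  if (length(ids) != expected) {
    abort_format(sprintf(
      "%s: sidecar %s has %d ids but the matrix dimension is %d.",
      mtx_path, side, length(ids), expected))
  }
  if (anyDuplicated(ids)) {
    abort_format(sprintf("%s: duplicate ids in sidecar %s.", mtx_path, side))
  }
  ids
}

read_counts_tsv <- function(path) {
  tab <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  if (!"cell_id" %in% names(tab)) {
    abort_format(sprintf("%s: dense counts need a 'cell_id' column.", path))
  }
  if (anyDuplicated(tab$cell_id)) {
    abort_format(sprintf("%s: duplicate cell ids.", path))
  }
  m <- as.matrix(tab[setdiff(names(tab), "cell_id")])
  rownames(m) <- tab$cell_id
  validate_count_values(m, path)
}

validate_count_values <- function(m, path) {
  if (any(!is.finite(m)) || any(m < 0)) {
    abort_format(sprintf("%s: counts must be finite and non-negative.", path))
  }
  if (any(abs(m - round(m)) > 1e-8)) {
    abort_format(sprintf("%s: counts must be integer-valued.", path))
  }
  storage.mode(m) <- "integer"
  m
}

#' Write a count matrix
#'
#' Inverse of [read_counts()]: `.mtx` writes a MatrixMarket triplet
#' (genes x cells) plus `genes.tsv` / `cells.tsv` sidecars in the same
#' directory; `.tsv` writes the dense table.
#'
#' @param counts Integer matrix, cells x genes with dimnames.
#' @param path Output path ending in `.mtx` or `.tsv`.
#' @return `path`, invisibly.
#' @export
write_counts <- function(counts, path) {
  check_matrix(counts, "counts")
  ext <- tolower(tools::file_ext(path))
  if (ext == "mtx") {
    Matrix::writeMM(Matrix::Matrix(t(counts), sparse = TRUE), path)
    writeLines(colnames(counts), file.path(dirname(path), "genes.tsv"))
    writeLines(rownames(counts), file.path(dirname(path), "cells.tsv"))
  } else if (ext == "tsv") {
    tab <- tibble(cell_id = rownames(counts))
    tab <- dplyr::bind_cols(tab, as_tibble(counts))
    readr::write_tsv(tab, path, progress = FALSE)
  } else {
    abort_format(sprintf("%s: unsupported count extension '.%s'.", path, ext))
  }
  invisible(path)
}

#' Read gene sets from a GMT file
#'
#' Tab-separated lines: set name, description, then one or more gene ids.
#' Duplicate genes within a set are dropped (order-preserving) with a
#' warning; duplicate set names or lines with fewer than three fields are
#' format errors.
#'
#' @param path Path to a `.gmt` file.
#' @return A `gene_set_collection`: named list of character gene vectors,
#'   with per-set descriptions in `attr(, "description")`.
#' @export
read_gmt <- function(path) {
  if (!file.exists(path)) abort_format(sprintf("File not found: %s", path))
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  sets <- list(); desc <- character(0)
  for (i in seq_along(lines)) {
    fields <- strsplit(lines[i], "\t", fixed = TRUE)[[1L]]
    if (length(fields) < 3L) {
      abort_format(sprintf("%s: line %d has %d field(s); need name, description, genes.",
                           path, i, length(fields)))
    }
    name <- fields[1L]
    if (name %in% names(sets)) {
      abort_format(sprintf("%s: line %d: duplicate set name '%s'.", path, i, name))
    }
    genes <- fields[-(1:2)]
    genes <- genes[nzchar(genes)]
    if (length(genes) == 0L) {
      abort_format(sprintf("%s: line %d: set '%s' has no genes.", path, i, name))
    }
    if (anyDuplicated(genes)) {
      warn(sprintf("%s: line %d: dropped %d duplicate gene(s) in set '%s'.",
                   path, i, sum(duplicated(genes)), name))
      genes <- unique(genes)
    }
    sets[[name]] <- genes
    desc[name] <- fields[2L]
  }
  gene_set_collection(sets, description = desc)
}

#' Construct a gene-set collection
#'
#' @param sets Named list of character gene vectors (each non-empty, each
#'   deduplicated preserving order).
#' @param description Optional named character vector of descriptions.
#' @return A `gene_set_collection`.
#' @export
gene_set_collection <- function(sets, description = NULL) {
  if (is.null(names(sets)) || anyDuplicated(names(sets))) {
    abort_param("Gene sets must have unique names.")
  }
  sets <- lapply(sets, function(g) unique(as.character(g)))
  structure(sets, description = description, class = "gene_set_collection")
}

#' Write gene sets to GMT
#'
#' @param collection A `gene_set_collection` or named list of gene vectors.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_gmt <- function(collection, path) {
  desc <- attr(collection, "description")
  lines <- vapply(names(collection), function(nm) {
    d <- if (!is.null(desc) && nm %in% names(desc)) desc[[nm]] else "na"
    paste(c(nm, d, collection[[nm]]), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Read and write per-cell tables
#'
#' TSV with required columns `cell_id`, `sample_id`, `x_um`, `y_um`; the QC
#' and annotation columns (`detected_genes`, `total_counts`,
#' `mito_fraction`, `cell_type`, `tls_id`) and any extra columns are
#' preserved when present. Missing required columns and non-finite
#' coordinates are format errors that name the offender.
#'
#' @param path TSV path.
#' @return A tibble of per-cell records.
#' @export
read_cell_table <- function(path) {
  if (!file.exists(path)) abort_format(sprintf("File not found: %s", path))
  tab <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  for (col in c("cell_id", "sample_id", "x_um", "y_um")) {
    if (!col %in% names(tab)) {
      abort_format(sprintf("%s: missing required column '%s'.", path, col))
    }
  }
  bad <- which(!is.finite(tab$x_um) | !is.finite(tab$y_um))
  if (length(bad) > 0L) {
    abort_format(sprintf("%s: non-finite coordinate at row %d.", path, bad[1L]))
  }
  if (anyDuplicated(tab$cell_id)) {
    abort_format(sprintf("%s: duplicate cell ids.", path))
  }
  tab
}

#' @rdname read_cell_table
#' @param cells Per-cell tibble (e.g., with `cell_type` and `tls_id` filled).
#' @export
write_cell_labels <- function(cells, path) {
  check_cells(cells)
  readr::write_tsv(cells, path, progress = FALSE)
  invisible(path)
}

#' Read and write per-sample survival tables
#'
#' CSV with required columns `sample_id`, `time` (non-negative, months),
#' `event` (0/1); an optional `group` column is preserved.
#'
#' @param path CSV path.
#' @return A tibble with one row per sample.
#' @export
read_survival <- function(path) {
  if (!file.exists(path)) abort_format(sprintf("File not found: %s", path))
  tab <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  for (col in c("sample_id", "time", "event")) {
    if (!col %in% names(tab)) {
      abort_format(sprintf("%s: missing required column '%s'.", path, col))
    }
  }
  if (anyDuplicated(tab$sample_id)) {
    abort_format(sprintf("%s: duplicate sample ids.", path))
  }
  bad <- which(!is.finite(tab$time) | tab$time < 0)
  if (length(bad) > 0L) {
    abort_format(sprintf("%s: invalid time at row %d (must be >= 0).", path, bad[1L]))
  }
  bad <- which(!tab$event %in% c(0, 1))
  if (length(bad) > 0L) {
    abort_format(sprintf("%s: invalid event at row %d (must be 0 or 1).", path, bad[1L]))
  }
  tab
}

#' @rdname read_survival
#' @param table Survival tibble.
#' @export
write_survival <- function(table, path) {
  readr::write_csv(table, path, progress = FALSE)
  invisible(path)
}

#' Serialize and restore TLS regions
#'
#' Regions are written as CSV with one row per region (`region_id`,
#' `sample_id`, `n_cells`, `area_mm2`, maturity columns, centroid) plus the
#' convex hull as a WKT `POLYGON` string with a closed ring, and the member
#' cell ids in a `;`-separated column.
#'
#' @param regions A `tls_regions` tibble from [call_tls()].
#' @param path CSV path.
#' @return `path` invisibly for the writer; a `tls_regions` tibble for the
#'   reader.
#' @export
write_tls_regions <- function(regions, path) {
  flat <- tibble(
    region_id = regions$region_id,
    sample_id = regions$sample_id,
    n_cells = regions$n_cells,
    area_mm2 = regions$area_mm2,
    maturity_score = regions$maturity_score,
    maturity_label = regions$maturity_label,
    centroid_x_um = regions$centroid_x_um,
    centroid_y_um = regions$centroid_y_um,
    member_cell_ids = vapply(regions$member_cell_ids, paste,
                             character(1), collapse = ";"),
    hull_wkt = vapply(regions$hull, wkt_polygon, character(1))
  )
  readr::write_csv(flat, path, progress = FALSE)
  invisible(path)
}

#' @rdname write_tls_regions
#' @export
read_tls_regions <- function(path) {
  if (!file.exists(path)) abort_format(sprintf("File not found: %s", path))
  tab <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  for (col in c("region_id", "sample_id", "n_cells", "area_mm2", "hull_wkt")) {
    if (!col %in% names(tab)) {
      abort_format(sprintf("%s: missing required column '%s'.", path, col))
    }
  }
  out <- tibble(
    region_id = tab$region_id,
    sample_id = tab$sample_id,
    n_cells = as.integer(tab$n_cells),
    area_mm2 = tab$area_mm2,
    maturity_score = tab$maturity_score %||% rep(NA_real_, nrow(tab)),
    maturity_label = tab$maturity_label %||% rep(NA_character_, nrow(tab)),
    centroid_x_um = tab$centroid_x_um,
    centroid_y_um = tab$centroid_y_um,
    member_cell_ids = strsplit(tab$member_cell_ids, ";", fixed = TRUE),
    hull = lapply(tab$hull_wkt, parse_wkt_polygon, path = path)
  )
  class(out) <- c("tls_regions", class(out))
  out
}

# WKT polygon with a closed ring (first vertex repeated last). Hulls with
# fewer than 3 vertices are written as degenerate closed rings so the
# round trip is lossless.
wkt_polygon <- function(hull) {
  v <- as_xy_matrix(hull)
  if (nrow(v) == 0L) return("POLYGON EMPTY")
  ring <- rbind(v, v[1L, , drop = FALSE])
  coords <- paste(sprintf("%.10g %.10g", ring[, 1], ring[, 2]), collapse = ", ")
  sprintf("POLYGON ((%s))", coords)
}

parse_wkt_polygon <- function(wkt, path = "<wkt>") {
  if (identical(wkt, "POLYGON EMPTY")) {
    return(matrix(numeric(0), ncol = 2, dimnames = list(NULL, c("x", "y"))))
  }
  m <- regmatches(wkt, regexec("^POLYGON \\(\\((.*)\\)\\)$", wkt))[[1L]]
  if (length(m) != 2L) {
    abort_format(sprintf("%s: malformed WKT polygon '%s'.", path, wkt))
  }
  pairs <- strsplit(strsplit(m[2L], ", ", fixed = TRUE)[[1L]], " ", fixed = TRUE)
  coords <- do.call(rbind, lapply(pairs, as.numeric))
  if (ncol(coords) != 2L || any(!is.finite(coords))) {
    abort_format(sprintf("%s: malformed WKT coordinates.", path))
  }
  last <- nrow(coords)
  if (last < 2L || any(coords[1L, ] != coords[last, ])) {
    abort_format(sprintf("%s: WKT ring is not closed.", path))
  }
  v <- coords[-last, , drop = FALSE]
  colnames(v) <- c("x", "y")
  v
}
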