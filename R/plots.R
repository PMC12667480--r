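#' Spatial map of cells with TLS region hulls
#'
#' Scatter of cell positions colored by cell type, with the convex hulls
#' of called TLS regions overlaid as dashed outlines. Facets by sample.
#'
#' @param cells Per-cell tibble (annotated).
#' @param regions Optional `tls_regions` to outline.
#' @param point_size Point size.
#' @return A ggplot object.
#' @export
plot_spatial <- function(cells, regions = NULL, point_size = 0.5) {
  check_cells(cells)
  p <- ggplot2::ggplot(cells,
                       ggplot2::aes(x = .data$x_um, y = .data$y_um,
                                    color = .data$cell_type)) +
    ggplot2::geom_point(size = point_size) +
    ggplot2::coord_equal() +
    ggplot2::facet_wrap(~sample_id) +
    ggplot2::labs(x = "x (µm)", y = "y (µm)", color = "cell type") +
    ggplot2::theme_minimal()
  if (!is.null(regions) && nrow(regions) > 0L) {
    hulls <- purrr::map2(regions$hull, seq_len(nrow(regions)), function(h, i) {
      tibble(x_um = h[, 1], y_um = h[, 2],
             region_id = regions$region_id[i],
             sample_id = regions$sample_id[i])
    })
    hull_df <- bind_rows(hulls)
    p <- p + ggplot2::geom_polygon(
      data = hull_df,
      ggplot2::aes(x = .data$x_um, y = .data$y_um, group = .data$region_id),
      inherit.aes = FALSE, fill = NA, color = "black", linetype = "dashed")
  }
  p
}

#' @method autoplot km_curve
#' @export
autoplot.km_curve <- function(object, ...) {
  steps <- object$steps
  df <- tibble(time = c(0, steps$time), survival = c(1, steps$survival))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$time, y = .data$survival)) +
    ggplot2::geom_step() +
    ggplot2::ylim(0, 1) +
    ggplot2::labs(x = "time (months)", y = "survival probability") +
    ggplot2::theme_minimal()
}

#' Kaplan-Meier curves for grouped survival data
#'
#' Computes one [km_curve()] per group in a survival table and draws the
#' step curves together (e.g., high- vs low-TLS score groups).
#'
#' @param table Survival tibble with a non-missing `group` column.
#' @return A ggplot object.
#' @export
plot_km_groups <- function(table) {
  st <- check_survival(table)
  if (is.null(st$group) || any(is.na(st$group))) {
    abort_param("`table$group` must be filled for every sample.")
  }
  dfs <- purrr::map(unique(st$group), function(g) {
    fit <- km_curve(st[st$group == g, , drop = FALSE])
    tibble(time = c(0, fit$steps$time),
           survival = c(1, fit$steps$survival),
           group = g)
  })
  ggplot2::ggplot(bind_rows(dfs),
                  ggplot2::aes(x = .data$time, y = .data$survival,
                               color = .data$group)) +
    ggplot2::geom_step() +
    ggplot2::ylim(0, 1) +
    ggplot2::labs(x = "time (months)", y = "survival probability",
                  color = "TLS score") +
    ggplot2::theme_minimal()
}

#' @method autoplot tls_de
#' @export
autoplot.tls_de <- function(object, ...) {
  df <- as_tibble(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$log2fc,
                                   y = -log10(pmax(.data$p, 1e-300)),
                                   color = .data$retained)) +
    ggplot2::geom_point(size = 0.8) +
    ggplot2::scale_color_manual(values = c(`TRUE` = "firebrick",
                                           `FALSE` = "grey60")) +
    ggplot2::labs(x = "log2 fold change (TLS / nTLS)", y = "-log10 p",
                  color = "retained") +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
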