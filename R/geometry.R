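#' Convex hull of 2-D points (monotone chain)
#'
#' Andrew's monotone-chain algorithm with a deterministic vertex order:
#' vertices are returned counter-clockwise starting from the lexicographically
#' smallest point. Collinear boundary points are dropped. Degenerate inputs
#' (all points coincident or collinear) return the 1 or 2 extreme points.
#'
#' @param points Numeric matrix or data frame with 2 columns (x, y).
#' @return Numeric matrix of hull vertices (columns `x`, `y`), CCW.
#' @export
convex_hull <- function(points) {
  pts <- as_xy_matrix(points)
  if (nrow(pts) == 0L) return(pts)
  pts <- unique(pts[order(pts[, 1], pts[, 2]), , drop = FALSE])
  n <- nrow(pts)
  if (n <= 2L) return(pts)
  cross <- function(o, a, b) {
    (a[1] - o[1]) * (b[2] - o[2]) - (a[2] - o[2]) * (b[1] - o[1])
  }
  build <- function(idx) {
    h <- integer(0)
    for (i in idx) {
      while (length(h) >= 2 &&
             cross(pts[h[length(h) - 1], ], pts[h[length(h)], ], pts[i, ]) <= 0) {
        h <- h[-length(h)]
      }
      h <- c(h, i)
    }
    h
  }
  lower <- build(seq_len(n))
  upper <- build(rev(seq_len(n)))
  hull <- c(lower[-length(lower)], upper[-length(upper)])
  if (length(hull) <= 2L) {
    # all points collinear: keep the two extremes
    return(pts[c(1L, n), , drop = FALSE])
  }
  pts[hull, , drop = FALSE]
}

#' Polygon area by the shoelace formula
#'
#' @param vertices Matrix of polygon vertices (x, y), not closed (first
#'   vertex not repeated). Fewer than 3 vertices give area 0.
#' @return Non-negative area in the square of the coordinate unit.
#' @export
polygon_area <- function(vertices) {
  v <- as_xy_matrix(vertices)
  n <- nrow(v)
  if (n < 3L) return(0)
  x <- v[, 1]; y <- v[, 2]
  xn <- c(x[-1], x[1]); yn <- c(y[-1], y[1])
  abs(sum(x * yn - xn * y)) / 2
}

#' Test points for containment in a convex hull
#'
#' A point counts as a member when it lies strictly inside or on the hull
#' boundary (within a small tolerance relative to the hull extent).
#' Degenerate hulls (one or two vertices) reduce to point / segment
#' membership.
#'
#' @param points Matrix or data frame of query points (x, y).
#' @param hull CCW convex hull vertices from [convex_hull()].
#' @return Logical vector along the rows of `points`.
#' @export
points_in_hull <- function(points, hull) {
  p <- as_xy_matrix(points)
  h <- as_xy_matrix(hull)
  if (nrow(p) == 0L) return(logical(0))
  if (nrow(h) == 0L) return(rep(FALSE, nrow(p)))
  scale <- max(1, max(abs(h)))
  tol <- 1e-9 * scale
  if (nrow(h) == 1L) {
    return(abs(p[, 1] - h[1, 1]) <= tol & abs(p[, 2] - h[1, 2]) <= tol)
  }
  if (nrow(h) == 2L) {
    return(on_segment(p, h[1, ], h[2, ], tol))
  }
  inside <- rep(TRUE, nrow(p))
  nh <- nrow(h)
  for (i in seq_len(nh)) {
    a <- h[i, ]; b <- h[if (i == nh) 1L else i + 1L, ]
    cr <- (b[1] - a[1]) * (p[, 2] - a[2]) - (b[2] - a[2]) * (p[, 1] - a[1])
    inside <- inside & cr >= -tol * max(1, sqrt(sum((b - a)^2)))
  }
  inside
}

on_segment <- function(p, a, b, tol) {
  ab <- b - a
  len2 <- sum(ab^2)
  if (len2 == 0) {
    return(abs(p[, 1] - a[1]) <= tol & abs(p[, 2] - a[2]) <= tol)
  }
  t <- ((p[, 1] - a[1]) * ab[1] + (p[, 2] - a[2]) * ab[2]) / len2
  cr <- abs((p[, 1] - a[1]) * ab[2] - (p[, 2] - a[2]) * ab[1]) / sqrt(len2)
  cr <= tol & t >= -tol & t <= 1 + tol
}

as_xy_matrix <- function(points) {
  if (is.data.frame(points)) points <- as.matrix(points)
  if (is.null(dim(points))) points <- matrix(points, ncol = 2)
  if (ncol(points) != 2L) abort_param("Points must have exactly 2 columns.")
  storage.mode(points) <- "double"
  colnames(points) <- c("x", "y")
  points
}
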