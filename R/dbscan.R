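#' Density-based spatial clustering (DBSCAN)
#'
#' Deterministic DBSCAN over 2-D points with the Euclidean metric, as used to
#' delineate TLS regions from immune-cell coordinates. A point is a *core*
#' point when its eps-neighborhood (including the point itself) holds at
#' least `min_samples` points; clusters are the connected components of core
#' points under eps-reachability; a non-core point within eps of a core
#' point (*border* point) joins the cluster of its first core neighbor in
#' ascending point-index order; all remaining points are noise.
#'
#' Cluster ids are assigned by ascending smallest member index, so the
#' labeling is reproducible bit-for-bit for a fixed input order.
#'
#' @param points Matrix or data frame of 2-D coordinates.
#' @param eps Neighborhood radius (> 0), in the units of `points`.
#' @param min_samples Minimum neighborhood size for a core point (>= 1).
#' @return Integer vector of labels along rows of `points`: cluster id >= 1,
#'   or 0 for noise. Zero rows give `integer(0)`.
#' @export
dbscan_cluster <- function(points, eps, min_samples) {
  check_number(eps, "eps", lower = 0, allow_boundary = FALSE)
  check_number(min_samples, "min_samples", lower = 1, integerish = TRUE)
  pts <- as_xy_matrix(points)
  n <- nrow(pts)
  if (n == 0L) return(integer(0))
  if (any(!is.finite(pts))) abort_param("Points must be finite.")

  adj <- as.matrix(stats::dist(pts)) <= eps
  diag(adj) <- TRUE
  core <- rowSums(adj) >= min_samples

  labels <- integer(n)
  cluster <- 0L
  for (i in which(core)) {
    if (labels[i] != 0L) next
    cluster <- cluster + 1L
    queue <- i
    labels[i] <- cluster
    while (length(queue) > 0L) {
      cur <- queue[1L]; queue <- queue[-1L]
      nb <- which(adj[cur, ] & core & labels == 0L)
      labels[nb] <- cluster
      queue <- c(queue, nb)
    }
  }

  for (j in which(!core)) {
    core_nb <- which(adj[j, ] & core)
    if (length(core_nb) > 0L) labels[j] <- labels[core_nb[1L]]
  }

  relabel_by_first_member(labels)
}

# Renumber cluster ids 1..k by ascending smallest member index; 0 stays noise.
relabel_by_first_member <- function(labels) {
  ids <- unique(labels[labels != 0L])
  if (length(ids) == 0L) return(labels)
  first <- vapply(ids, function(id) min(which(labels == id)), numeric(1))
  remap <- integer(max(ids))
  remap[ids[order(first)]] <- seq_along(ids)
  out <- labels
  nz <- labels != 0L
  out[nz] <- remap[labels[nz]]
  out
}
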