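# Independent reference implementations used as oracles. Each is written
# from the definition, separately from the package code paths it checks.

# --- DBSCAN: full pairwise distances, core marking, breadth-first growth ---
oracle_dbscan <- function(pts, eps, min_samples) {
  n <- nrow(pts)
  if (n == 0L) return(integer(0))
  d2 <- outer(pts[, 1], pts[, 1], "-")^2 + outer(pts[, 2], pts[, 2], "-")^2
  nbr <- d2 <= eps^2
  is_core <- colSums(nbr) >= min_samples
  lab <- rep(0L, n)
  cl <- 0L
  for (start in seq_len(n)) {
    if (!is_core[start] || lab[start] != 0L) next
    cl <- cl + 1L
    frontier <- start
    lab[start] <- cl
    while (length(frontier) > 0L) {
      nxt <- integer(0)
      for (q in frontier) {
        reach <- which(nbr[q, ] & is_core[] & lab == 0L)
        lab[reach] <- cl
        nxt <- c(nxt, reach)
      }
      frontier <- nxt
    }
  }
  for (q in seq_len(n)) {
    if (is_core[q] || lab[q] != 0L) next
    cores_near <- which(nbr[q, ] & is_core)
    if (length(cores_near) > 0L) lab[q] <- lab[cores_near[1L]]
  }
  lab
}

# Canonical form of a clustering: renumber clusters by first appearance so
# two labelings can be compared up to relabeling (noise 0 kept as is).
canonical_partition <- function(lab) {
  out <- integer(length(lab))
  seen <- integer(0)
  for (i in seq_along(lab)) {
    if (lab[i] == 0L) next
    pos <- match(lab[i], seen)
    if (is.na(pos)) {
      seen <- c(seen, lab[i])
      pos <- length(seen)
    }
    out[i] <- pos
  }
  out
}

# --- BH step-up from the definition ---
oracle_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  q <- p[o] * m / seq_len(m)
  for (i in (m - 1):1) if (m > 1) q[i] <- min(q[i], q[i + 1])
  pmin(q, 1)[order(o)]
}

# --- Wilcoxon exact p by direct enumeration of group assignments,
#     computing the Mann-Whitney U by pairwise comparison counts ---
oracle_wilcoxon <- function(x, y, alternative = "two.sided") {
  u_stat <- function(a, b) {
    sum(outer(a, b, ">")) + 0.5 * sum(outer(a, b, "=="))
  }
  pooled <- c(x, y)
  nx <- length(x)
  obs <- u_stat(x, y)
  sets <- utils::combn(length(pooled), nx)
  us <- apply(sets, 2, function(idx) u_stat(pooled[idx], pooled[-idx]))
  pg <- mean(us >= obs - 1e-9)
  pl <- mean(us <= obs + 1e-9)
  switch(alternative,
         greater = pg, less = pl,
         two.sided = min(1, 2 * min(pg, pl)))
}

# --- Hypergeometric upper tail by direct summation of the pmf ---
oracle_hypergeom_upper <- function(k, K, n, N) {
  i <- k:min(K, n)
  sum(choose(K, i) * choose(N - K, n - i)) / choose(N, n)
}

# --- Ray casting point-in-polygon (non-convex capable) ---
oracle_point_in_polygon <- function(px, py, vx, vy) {
  n <- length(vx)
  inside <- FALSE
  j <- n
  for (i in seq_len(n)) {
    on_edge <- {
      cross <- (vx[j] - vx[i]) * (py - vy[i]) - (vy[j] - vy[i]) * (px - vx[i])
      within <- px >= min(vx[i], vx[j]) - 1e-9 && px <= max(vx[i], vx[j]) + 1e-9 &&
        py >= min(vy[i], vy[j]) - 1e-9 && py <= max(vy[i], vy[j]) + 1e-9
      abs(cross) < 1e-6 && within
    }
    if (on_edge) return(TRUE)
    if ((vy[i] > py) != (vy[j] > py)) {
      x_int <- vx[i] + (py - vy[i]) / (vy[j] - vy[i]) * (vx[j] - vx[i])
      if (px < x_int) inside <- !inside
    }
    j <- i
  }
  inside
}

# --- AUCell step-curve integration from the definition ---
oracle_aucell <- function(expr, set_genes, top_fraction) {
  n <- length(expr)
  k <- max(1, ceiling(top_fraction * n))
  ord <- names(expr)[order(-expr, seq_len(n))]
  hits_at <- cumsum(ord %in% set_genes)
  m <- sum(names(expr) %in% set_genes)
  auc <- sum(hits_at[seq_len(k)])
  best <- sum(pmin(seq_len(k), m))
  auc / best
}

# --- ssGSEA running sum from the definition ---
oracle_ssgsea <- function(expr, set_genes, alpha) {
  n <- length(expr)
  ord <- order(-expr, seq_len(n))
  member <- names(expr)[ord] %in% set_genes
  m <- sum(member)
  w <- (n:1)^alpha
  w_in <- w / sum(w[member])
  running <- 0
  total <- 0
  for (i in seq_len(n)) {
    running <- running + if (member[i]) w_in[i] else -1 / (n - m)
    total <- total + running
  }
  total
}

# --- Product-limit and log-rank by hand over a fixture ---
oracle_km <- function(time, event) {
  ts <- sort(unique(time[event == 1]))
  s <- 1
  out <- numeric(length(ts))
  for (i in seq_along(ts)) {
    n_i <- sum(time >= ts[i])
    d_i <- sum(time == ts[i] & event == 1)
    s <- s * (1 - d_i / n_i)
    out[i] <- s
  }
  list(time = ts, surv = out)
}

oracle_logrank_chi2 <- function(t1, e1, t2, e2) {
  ts <- sort(unique(c(t1[e1 == 1], t2[e2 == 1])))
  o_minus_e <- 0
  v <- 0
  obs <- 0
  for (t in ts) {
    n1 <- sum(t1 >= t); n2 <- sum(t2 >= t); nt <- n1 + n2
    d1 <- sum(t1 == t & e1 == 1); d2 <- sum(t2 == t & e2 == 1)
    d <- d1 + d2
    obs <- obs + d1
    o_minus_e <- o_minus_e + (d1 - d * n1 / nt)
    if (nt > 1) v <- v + d * (n1 / nt) * (n2 / nt) * (nt - d) / (nt - 1)
  }
  o_minus_e^2 / v
}

# Small simulated sample processed through QC/normalization/typing; shared
# by detection and signature tests.
annotated_sample <- function(seed = 1, ...) {
  p <- sim_params(seed = seed, ...)
  sim <- simulate_sample(p, "S1")
  filt <- qc_filter(sim$counts, sim$cells,
                    qc_thresholds(min_genes = 10, max_genes = 160,
                                  max_mito_fraction = 0.25))
  norm <- lognormalize(filt$counts)
  cells <- assign_cell_types(filt$cells, norm)
  list(sim = sim, cells = cells, norm = norm, params = p)
}

# A 1000-cell fixture with known per-rule QC violations, built directly:
# counts over 600 genes so the default thresholds (500 / 5000 / 20%) have
# interior room on both sides.
qc_fixture <- function() {
  set.seed(101)
  n <- 1000
  n_genes <- 600
  genes <- c(sprintf("MT-%02d", 1:10), sprintf("G%03d", 1:(n_genes - 10)))
  # baseline: every gene expressed -> 600 detected genes, mito ~ 10/600
  m <- matrix(rpois(n * n_genes, 5) + 1L, nrow = n,
              dimnames = list(sprintf("c%04d", 1:n), genes))
  low <- 1:50          # fewer than 500 detected genes
  m[low, 200:600] <- 0L
  mito_bad <- 51:90    # mito fraction pushed above 20%
  m[mito_bad, 1:10] <- 600L
  both <- 91:120       # fails min_genes AND mito; must count under min_genes
  m[both, 200:600] <- 0L
  m[both, 1:10] <- 600L
  storage.mode(m) <- "integer"
  cells <- tibble::tibble(cell_id = rownames(m), sample_id = "S1",
                          x_um = runif(n, 0, 100), y_um = runif(n, 0, 100))
  list(counts = m, cells = cells,
       expected = c(min_genes = 80, max_genes = 0, mito_fraction = 40))
}

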