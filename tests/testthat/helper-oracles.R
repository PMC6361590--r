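# Independent oracles and small constructors shared across test files.

# Brute-force O(N^2) DBSCAN with the same conventions as the package
# implementation: self-inclusive neighbour counts, clusters discovered in
# ascending seed order, border points labelled by the first cluster whose
# expansion reaches them, noise = 0.
bf_dbscan <- function(x, y, eps, min_pts) {
  n <- length(x)
  labels <- integer(n)
  if (n == 0) return(labels)
  D <- as.matrix(stats::dist(cbind(x, y)))
  nb <- D <= eps
  visited <- logical(n)
  cl <- 0L
  for (i in seq_len(n)) {
    if (visited[i]) next
    visited[i] <- TRUE
    N <- which(nb[i, ])
    if (length(N) < min_pts) next
    cl <- cl + 1L
    labels[i] <- cl
    queue <- N
    while (length(queue)) {
      q <- queue[1]
      queue <- queue[-1]
      if (labels[q] == 0L) labels[q] <- cl
      if (!visited[q]) {
        visited[q] <- TRUE
        Nq <- which(nb[q, ])
        if (length(Nq) >= min_pts) queue <- c(queue, Nq)
      }
    }
  }
  labels
}

# Partition equality up to cluster relabelling; noise (0) must match exactly.
partitions_equal <- function(l1, l2) {
  if (length(l1) != length(l2)) return(FALSE)
  if (!identical(l1 == 0L, l2 == 0L)) return(FALSE)
  f1 <- as.integer(factor(l1[l1 != 0], levels = unique(l1[l1 != 0])))
  f2 <- as.integer(factor(l2[l2 != 0], levels = unique(l2[l2 != 0])))
  identical(f1, f2)
}

# Noiseless free-energy curve evaluated on a grid (curve-level fixture).
model_curve <- function(a, b, n, offset = 0, delta_n = 1,
                        n_start = min(n), total = 1e6) {
  structure(list(n = n, dG = a * n^(2 / 3) - b * n + offset,
                 offset_applied = FALSE, offset = 0,
                 delta_n = delta_n, n_start = n_start,
                 total_clusters = total),
            class = "free_energy_curve")
}

# Truncated Boltzmann density helpers for quadrature oracles.
size_density <- function(n, a, b) exp(-(a * n^(2 / 3) - b * n))

size_cdf_oracle <- function(xs, a, b, lo, hi) {
  Z <- stats::integrate(size_density, lo, hi, a = a, b = b,
                        rel.tol = 1e-10)$value
  vapply(xs, function(x) {
    stats::integrate(size_density, lo, x, a = a, b = b,
                     rel.tol = 1e-9)$value / Z
  }, numeric(1))
}

fixed_cell_a <- 1.07e-3
fixed_cell_b <- 4.3e-6
live_cell_a <- 0.166
live_cell_b <- 0.011
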