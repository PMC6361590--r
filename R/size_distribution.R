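#' Normalized histogram of cluster sizes
#'
#' Bins collated cluster sizes into fixed-width bins starting at `n_start`
#' and normalizes per bin: `P[i] = counts[i] / total`. The defaults match
#' the super-resolution analysis convention (bin width 3e4, lower cutoff
#' 1.5e4); the live-cell molecule-count variable N is binned the same way
#' with `delta_n = 10`, `n_start = 0`.
#'
#' Empty bins are masked (`occupied = FALSE`) rather than carried as zero
#' probabilities, because the empirical free energy takes a logarithm.
#'
#' @param n_values numeric vector of sizes (all >= `n_start`; smaller values
#'   are expected to be filtered upstream and raise an error).
#' @param delta_n bin width (> 0), default 3e4.
#' @param n_start left edge of the first bin, default 1.5e4.
#' @return object of class `size_distribution`: list with `bin_edges`,
#'   `bin_centers`, `counts`, `P`, `occupied`, `delta_n`, `n_start`,
#'   `total_clusters`.
#' @export
histogram_sizes <- function(n_values, delta_n = 3e4, n_start = 1.5e4) {
  if (delta_n <= 0) stop_nucfit("'delta_n' must be > 0",
                                "nucfit_parameter_error")
  n_values <- n_values[is.finite(n_values)]
  if (any(n_values < n_start)) {
    stop_nucfit(sprintf("%d value(s) below n_start = %g; filter upstream",
                        sum(n_values < n_start), n_start),
                "nucfit_parameter_error")
  }
  if (length(n_values) < 100) {
    warning("fewer than 100 values: bins may under-sample the distribution")
  }
  n_bins <- max(1L, ceiling((max(n_values, n_start) - n_start) / delta_n))
  edges <- n_start + delta_n * (0:n_bins)
  # right-open bins [edge_i, edge_{i+1}); top value falls in the last bin
  idx <- pmin(floor((n_values - n_start) / delta_n) + 1L, n_bins)
  counts <- tabulate(idx, nbins = n_bins)
  total <- length(n_values)
  P <- if (total > 0) counts / total else rep(NA_real_, n_bins)
  structure(list(bin_edges = edges,
                 bin_centers = (edges[-1] + edges[-length(edges)]) / 2,
                 counts = counts, P = P, occupied = counts > 0,
                 delta_n = delta_n, n_start = n_start,
                 total_clusters = total),
            class = "size_distribution")
}

#' @export
print.size_distribution <- function(x, ...) {
  cat(sprintf(
    "Size distribution: %d clusters in %d bins (width %g from %g), %d occupied\n",
    x$total_clusters, length(x$counts), x$delta_n, x$n_start,
    sum(x$occupied)))
  invisible(x)
}

#' Empirical free energy from a size distribution
#'
#' The sub-critical Boltzmann relation \eqn{P(n) = A e^{-\Delta G(n)/k_B T}}
#' inverts to \eqn{\Delta G(n) = -\ln P(n)} (in units of \eqn{k_B T}, up to
#' the normalization offset \eqn{\ln A}, which is applied later via
#' [apply_normalization_offset()]). Only occupied bins carry values.
#'
#' @param dist a [histogram_sizes()] result.
#' @return object of class `free_energy_curve`: list with `n` (occupied bin
#'   centers), `dG` (kBT), `offset_applied` (FALSE), plus binning metadata.
#' @export
empirical_free_energy <- function(dist) {
  stopifnot(inherits(dist, "size_distribution"))
  if (abs(sum(dist$P) - 1) > 1e-12) {
    stop_nucfit("distribution is not normalized", "nucfit_parameter_error")
  }
  occ <- dist$occupied
  structure(list(n = dist$bin_centers[occ],
                 dG = -log(dist$P[occ]),
                 offset_applied = FALSE, offset = 0,
                 delta_n = dist$delta_n, n_start = dist$n_start,
                 total_clusters = dist$total_clusters),
            class = "free_energy_curve")
}

#' @export
print.free_energy_curve <- function(x, ...) {
  cat(sprintf("Free-energy curve: %d occupied bins, n in [%g, %g]",
              length(x$n), min(x$n), max(x$n)))
  if (x$offset_applied) cat(sprintf(", offset %+0.3f kBT applied", x$offset))
  cat("\n")
  invisible(x)
}

#' Self-consistent normalization offset (A = 1 convention)
#'
#' The per-bin probabilities satisfy
#' \eqn{P_{bin}(n) \approx \Delta n \, A \, e^{-\Delta G_{fit}(n)}} with
#' \eqn{A = 1/\int_0^{n_c} e^{-\Delta G_{fit}(n)}\,dn}. Adding
#' \eqn{\ln A + \ln \Delta n} to the empirical \eqn{-\ln P} curve therefore
#' places it on the A = 1 scale of the fitted free energy, so the
#' nucleation barrier can be read directly as the maximum of the curve.
#' The quadrature runs over \eqn{[0, n_c]} for a super-saturated fit and
#' over \eqn{[0, n_{hi}]} otherwise.
#'
#' @param curve a `free_energy_curve` (offset not yet applied).
#' @param fit a [fit_free_energy()]/[self_consistent_fit()] result supplying
#'   `a` and `b`.
#' @return the curve with `dG` shifted, `offset_applied = TRUE` and the
#'   applied offset recorded. Applying twice is an error.
#' @export
apply_normalization_offset <- function(curve, fit) {
  stopifnot(inherits(curve, "free_energy_curve"))
  if (isTRUE(curve$offset_applied)) {
    stop_nucfit("normalization offset already applied", "nucfit_offset_error")
  }
  a <- fit$a; b <- fit$b
  upper <- if (b > 0) (2 * a / (3 * b))^3 else fit$n_hi %||% max(curve$n)
  q <- tryCatch(
    stats::integrate(function(n) exp(-delta_g(n, a, b)), 0, upper,
                     rel.tol = 1e-10, subdivisions = 500L),
    error = function(e) stop_nucfit(paste("normalization quadrature failed:",
                                          conditionMessage(e)),
                                    "nucfit_numeric_error"))
  log_A <- -log(q$value)
  offset <- log_A + log(curve$delta_n)
  curve$dG <- curve$dG + offset
  curve$offset <- offset
  curve$offset_applied <- TRUE
  curve
}
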