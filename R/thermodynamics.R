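#' Critical cluster size and radius
#'
#' The free-energy maximum of \eqn{\Delta G = a n^{2/3} - b n} is at
#' \eqn{n_c = (2a/3b)^3}; under the `n = (R / 1 nm)^3` convention the
#' critical radius is \eqn{R_c = n_c^{1/3} = 2a/(3b)} nm. Both are immune
#' to a multiplicative rescaling of the size variable
#' (\eqn{(a, b) \to (a k^{2/3}, b k)}): the factor cancels on converting
#' \eqn{n_c} back to \eqn{R_c}.
#'
#' @param a surface coefficient (> 0).
#' @param b bulk coefficient; `b <= 0` (sub-saturated) has no critical
#'   point and returns a typed absence (`NULL` components with
#'   `saturation_class = "sub"`).
#' @return list with `n_c`, `R_c` (nm), `saturation_class`.
#' @export
critical_point <- function(a, b) {
  if (a <= 0) stop_nucfit("'a' must be positive", "nucfit_parameter_error")
  if (b <= 0) {
    return(list(n_c = NULL, R_c = NULL, saturation_class = "sub"))
  }
  R_c <- 2 * a / (3 * b)
  list(n_c = R_c^3, R_c = R_c, saturation_class = "super")
}

#' Nucleation barrier height
#'
#' \eqn{\Delta G(n_c) = 4a^3 / 27b^2} in units of \eqn{k_B T}. Like the
#' critical radius, the barrier is invariant under the multiplicative
#' rescaling \eqn{(a, b) \to (a k^{2/3}, b k)}.
#'
#' @inheritParams critical_point
#' @return barrier in kBT, or `NULL` (typed absence) when `b <= 0`.
#' @export
barrier_height <- function(a, b) {
  if (a <= 0) stop_nucfit("'a' must be positive", "nucfit_parameter_error")
  if (b <= 0) return(NULL)
  4 * a^3 / (27 * b^2)
}

#' Delta-method uncertainties for the critical radius and barrier
#'
#' First-order propagation of the fit covariance of (a, b) through
#' \eqn{R_c = 2a/3b} and \eqn{\Delta G(n_c) = 4a^3/27b^2}, with an optional
#' Monte-Carlo cross-check (sampling (a, b) from the bivariate normal
#' defined by the fit covariance).
#'
#' @param fit a `free_energy_fit` (super-saturated) with covariance.
#' @param monte_carlo if `TRUE`, also return Monte-Carlo standard
#'   deviations from `mc_draws` samples.
#' @param mc_draws number of Monte-Carlo draws (default 1e4).
#' @param seed seed for the Monte-Carlo cross-check.
#' @return list with `sem_Rc` (nm), `sem_barrier` (kBT) and, if requested,
#'   `mc_sem_Rc`, `mc_sem_barrier`.
#' @export
propagate_uncertainty <- function(fit, monte_carlo = FALSE,
                                  mc_draws = 1e4, seed = 1L) {
  if (fit$saturation_class != "super") {
    stop_nucfit("no critical point for a sub-saturated fit",
                "nucfit_parameter_error")
  }
  a <- fit$a; b <- fit$b
  S <- fit$covariance
  ev <- eigen(S, symmetric = TRUE, only.values = TRUE)$values
  if (any(ev < -1e-12 * max(abs(ev), 1e-300))) {
    stop_nucfit("covariance matrix is not positive semi-definite",
                "nucfit_numeric_error")
  }
  gR <- c(2 / (3 * b), -2 * a / (3 * b^2))
  gB <- c(4 * a^2 / (9 * b^2), -8 * a^3 / (27 * b^3))
  out <- list(sem_Rc = sqrt(drop(t(gR) %*% S %*% gR)),
              sem_barrier = sqrt(drop(t(gB) %*% S %*% gB)))
  if (monte_carlo) {
    L <- chol(S + diag(1e-300, 2))
    draws <- with_seed(seed, matrix(stats::rnorm(2 * mc_draws), ncol = 2) %*% L)
    aa <- a + draws[, 1]; bb <- b + draws[, 2]
    ok <- aa > 0 & bb > 0
    out$mc_sem_Rc <- stats::sd(2 * aa[ok] / (3 * bb[ok]))
    out$mc_sem_barrier <- stats::sd(4 * aa[ok]^3 / (27 * bb[ok]^2))
    out$mc_kept <- sum(ok)
  }
  out
}

#' Surface-tension, density and label-spacing bounds
#'
#' The fitted surface coefficient measures the interfacial tension only up
#' to the unknown conversion between the measured size variable and the
#' true molecule count: fixed-cell fits give \eqn{a = a^* \rho^{2/3}}
#' (\eqn{\rho} = molecules per nm^3 in the cluster) and live-cell fits give
#' \eqn{a = a^* k^{2/3}}. With \eqn{a^* = r_1^2 \sigma / k_B T} this yields
#' bounds:
#' \itemize{
#'   \item lower bound: the density cannot exceed 1 molecule/nm^3 (protein
#'     size), so \eqn{a^* \ge a_{fixed}} and
#'     \eqn{\sigma \ge a_{fixed} k_B T / r_1^2};
#'   \item live-cell upper bound: the labelled count undercounts all
#'     molecules, so \eqn{a^* \le a_{live}} and
#'     \eqn{\sigma \le a_{live} k_B T / r_1^2};
#'   \item fixed-cell upper bound: the critical cluster holds at least
#'     `N_c` molecules in radius `R_c`, giving a minimum density
#'     \eqn{\rho_{min} = N_c / R_c^3} and
#'     \eqn{\sigma \le (a_{fixed}/\rho_{min}^{2/3}) k_B T / r_1^2}.
#' }
#' Also reported: mean label spacing \eqn{R_c / N_c^{1/3}} and the label
#' volume fraction \eqn{N_c r_{label}^3 / R_c^3}.
#'
#' @param a_fixed fixed-cell surface coefficient (dimensionless).
#' @param a_live live-cell surface coefficient (dimensionless).
#' @param N_c critical molecule count from live-cell data.
#' @param R_c critical radius in nm from fixed-cell data.
#' @param T_K temperature in Kelvin (default 310, incubator conditions).
#' @param r1_nm monomer length scale in nm (default 1).
#' @param r_label_nm labelled-protein Stokes radius in nm (default 1.5).
#' @return object of class `surface_tension_estimate`: list with
#'   `rho_min_per_nm3`, `sigma_lower_Npm`, `sigma_upper_live_Npm`,
#'   `sigma_upper_fixed_Npm`, `spacing_nm`, `label_volume_fraction`,
#'   and the inputs.
#' @export
surface_tension_bounds <- function(a_fixed, a_live, N_c, R_c,
                                   T_K = 310, r1_nm = 1, r_label_nm = 1.5) {
  vals <- c(a_fixed = a_fixed, a_live = a_live, N_c = N_c, R_c = R_c,
            T_K = T_K, r1_nm = r1_nm)
  if (any(vals <= 0)) {
    stop_nucfit("all inputs must be positive", "nucfit_parameter_error")
  }
  kB <- 1.380649e-23           # J/K
  r1_m <- r1_nm * 1e-9
  kT_over_r1sq <- kB * T_K / r1_m^2   # N/m per unit a*
  rho_min <- N_c / R_c^3
  structure(list(
    rho_min_per_nm3 = rho_min,
    sigma_lower_Npm = a_fixed * kT_over_r1sq,
    sigma_upper_live_Npm = a_live * kT_over_r1sq,
    sigma_upper_fixed_Npm = a_fixed / rho_min^(2 / 3) * kT_over_r1sq,
    spacing_nm = R_c / N_c^(1 / 3),
    label_volume_fraction = N_c * r_label_nm^3 / R_c^3,
    inputs = as.list(c(vals, r_label_nm = r_label_nm))),
    class = "surface_tension_estimate")
}

#' @export
print.surface_tension_estimate <- function(x, ...) {
  cat("Surface-tension bounds (condensate-cytoplasm interface)\n")
  cat(sprintf("  minimum density: %.3g molecules/nm^3\n", x$rho_min_per_nm3))
  cat(sprintf("  sigma lower bound: %.2g N/m\n", x$sigma_lower_Npm))
  cat(sprintf("  sigma upper bounds: %.2g (live), %.2g (fixed) N/m\n",
              x$sigma_upper_live_Npm, x$sigma_upper_fixed_Npm))
  cat(sprintf("  label spacing %.3g nm, volume fraction %.2g\n",
              x$spacing_nm, x$label_volume_fraction))
  invisible(x)
}

#' Thermodynamic summary of a nucleation fit
#'
#' Bundles critical point, barrier (both the closed form and the maximum of
#' the offset fitted curve, which agree by construction) and delta-method
#' uncertainties.
#'
#' @param fit a `free_energy_fit`.
#' @param monte_carlo passed to [propagate_uncertainty()].
#' @return object of class `nucleation_parameters`.
#' @export
nucleation_parameters <- function(fit, monte_carlo = FALSE) {
  cp <- critical_point(fit$a, fit$b)
  if (cp$saturation_class == "sub") {
    return(structure(list(a = fit$a, b = fit$b, saturation_class = "sub",
                          n_c = NULL, R_c = NULL, barrier = NULL,
                          sem_Rc = NULL, sem_barrier = NULL),
                     class = "nucleation_parameters"))
  }
  un <- propagate_uncertainty(fit, monte_carlo = monte_carlo)
  structure(list(a = fit$a, b = fit$b, saturation_class = "super",
                 n_c = cp$n_c, R_c = cp$R_c,
                 barrier = barrier_height(fit$a, fit$b),
                 barrier_curve_max = delta_g(cp$n_c, fit$a, fit$b),
                 sem_Rc = un$sem_Rc, sem_barrier = un$sem_barrier),
            class = "nucleation_parameters")
}

#' @export
print.nucleation_parameters <- function(x, ...) {
  if (x$saturation_class == "sub") {
    cat("Sub-saturated system: no critical point, no nucleation barrier\n")
  } else {
    cat(sprintf("n_c = %.4g, R_c = %.4g (+/- %.2g) nm, barrier = %.3g (+/- %.2g) kBT\n",
                x$n_c, x$R_c, x$sem_Rc, x$barrier, x$sem_barrier))
  }
  invisible(x)
}
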