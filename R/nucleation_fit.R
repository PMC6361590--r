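#' Surface-energy asymptote diagnostic
#'
#' For small clusters the free energy is dominated by the surface term, so a
#' log-log plot of \eqn{\Delta G} against n should be linear with slope
#' \eqn{\gamma_1 = 2/3}. This fits (i) the log-log slope and (ii) the surface
#' coefficient `a_est` by OLS of \eqn{\Delta G} on \eqn{n^{2/3}} (with free
#' intercept absorbing any normalization offset), over the low-n range.
#' The conventional diagnostic range is `n < 2e5` on a fine histogram
#' (bin width 5e3).
#'
#' @param curve a `free_energy_curve`.
#' @param n_max upper end of the diagnostic range (default 2e5).
#' @return list with `gamma1`, `gamma1_sem`, `a_est`, `a_sem`,
#'   `n_bins_used`.
#' @export
fit_surface_asymptote <- function(curve, n_max = 2e5) {
  stopifnot(inherits(curve, "free_energy_curve"))
  in_range <- curve$n < n_max
  n <- curve$n[in_range]
  dG <- curve$dG[in_range]
  pos <- dG > 0
  if (any(!pos)) {
    warning(sprintf(
      "%d non-positive dG value(s) in asymptote range excluded (offset not applied or noise)",
      sum(!pos)))
    n <- n[pos]; dG <- dG[pos]
  }
  if (length(n) < 5) {
    stop_nucfit("need at least 5 occupied bins below n_max",
                "nucfit_parameter_error")
  }
  ll <- stats::lm(log(dG) ~ log(n))
  sl <- summary(ll)$coefficients
  pw <- stats::lm(dG ~ I(n^(2 / 3)))
  sp <- summary(pw)$coefficients
  list(gamma1 = unname(sl["log(n)", "Estimate"]),
       gamma1_sem = unname(sl["log(n)", "Std. Error"]),
       a_est = unname(sp[2, "Estimate"]),
       a_sem = unname(sp[2, "Std. Error"]),
       n_bins_used = length(n))
}

#' Residual after subtracting the surface term
#'
#' Subtracts a fitted surface term \eqn{a n^{2/3}} from the free-energy
#' curve. For a super-saturated system the residual is linear in n
#' (log-log slope \eqn{\gamma_2 = 1}) with negative slope \eqn{-b}; a
#' sub-saturated system gives a positive slope.
#'
#' @param curve a `free_energy_curve`.
#' @param a surface coefficient to subtract (> 0).
#' @param noise_floor residual magnitudes below this (kBT) are considered
#'   unresolved; if all residuals fall below it, `gamma2` is `NA` and the
#'   result is flagged.
#' @return list with `residual` (data.frame `n`, `r`), `gamma2`,
#'   `gamma2_sem`, `slope`, `slope_sem`.
#' @export
subtract_surface <- function(curve, a, noise_floor = 1e-12) {
  stopifnot(inherits(curve, "free_energy_curve"))
  if (a <= 0) stop_nucfit("'a' must be positive", "nucfit_parameter_error")
  n <- curve$n
  r <- curve$dG - a * n^(2 / 3)
  # the linear fit keeps a free intercept (any residual normalization
  # constant lands there); the log-log exponent gamma2 reads |r| directly,
  # so the curve should be on the A = 1 scale (offset applied) when gamma2
  # is to be interpreted
  lin <- stats::lm(r ~ n)
  slin <- summary(lin)$coefficients
  r_centered <- r
  if (all(abs(r_centered) <= noise_floor)) {
    return(list(residual = data.frame(n = n, r = r), gamma2 = NA_real_,
                gamma2_sem = NA_real_,
                slope = unname(slin["n", "Estimate"]),
                slope_sem = unname(slin["n", "Std. Error"]),
                flagged = "residuals within noise floor"))
  }
  ok <- abs(r_centered) > noise_floor
  ll <- stats::lm(log(abs(r_centered[ok])) ~ log(n[ok]))
  sll <- summary(ll)$coefficients
  list(residual = data.frame(n = n, r = r),
       gamma2 = unname(sll[2, "Estimate"]),
       gamma2_sem = if (nrow(sll) > 1 && ncol(sll) > 1)
         unname(sll[2, "Std. Error"]) else NA_real_,
       slope = unname(slin["n", "Estimate"]),
       slope_sem = unname(slin["n", "Std. Error"]),
       flagged = NULL)
}

#' Fit the nucleation free-energy form on a fixed range
#'
#' Ordinary least squares of \eqn{\Delta G} on the basis
#' \eqn{\{n^{2/3}, n, 1\}} over occupied bins in `[n_lo, n_hi]`. The model
#' is \eqn{\Delta G = a n^{2/3} - b n + c}: the reported `b` is positive for
#' a super-saturated system (negative fitted coefficient on n) and negative
#' for a sub-saturated one. The free intercept absorbs the normalization
#' and bin-width constant, which by the scale-invariance argument cannot
#' affect a, b, the critical radius or the barrier.
#'
#' @param curve a `free_energy_curve`.
#' @param n_lo,n_hi fit range (inclusive).
#' @param weights optional per-bin weights (e.g. Poisson counts); default
#'   unweighted.
#' @return object of class `free_energy_fit`: list with `a`, `b`, `sem_a`,
#'   `sem_b`, `intercept`, `sem_intercept`, `covariance` (of (a, b), with
#'   sign convention matching the reported b), `n_lo`, `n_hi`,
#'   `saturation_class` ("super" or "sub"), `n_bins_used`, `iterations`.
#' @export
fit_free_energy <- function(curve, n_lo = min(curve$n), n_hi = max(curve$n),
                            weights = NULL) {
  stopifnot(inherits(curve, "free_energy_curve"))
  if (n_lo >= n_hi) stop_nucfit("'n_lo' must be below 'n_hi'",
                                "nucfit_range_error")
  sel <- curve$n >= n_lo & curve$n <= n_hi
  n <- curve$n[sel]; dG <- curve$dG[sel]
  if (length(n) < 6) {
    stop_nucfit(sprintf("need >= 6 occupied bins in fit range (got %d)",
                        length(n)), "nucfit_fit_error")
  }
  X <- cbind(surface = n^(2 / 3), bulk = n)
  fit <- if (is.null(weights)) stats::lm(dG ~ X) else
    stats::lm(dG ~ X, weights = weights[sel])
  if (any(is.na(stats::coef(fit)))) {
    stop_nucfit("rank-deficient design: fit range too narrow",
                "nucfit_fit_error")
  }
  cf <- summary(fit)$coefficients
  V <- stats::vcov(fit)
  a <- unname(cf["Xsurface", "Estimate"])
  bulk <- unname(cf["Xbulk", "Estimate"])
  b <- -bulk  # b > 0 <=> super-saturated
  # covariance of (a, b): flipping the sign of the bulk coefficient flips
  # the cross-covariance sign
  Sab <- V[c("Xsurface", "Xbulk"), c("Xsurface", "Xbulk")]
  Sab[1, 2] <- -Sab[1, 2]; Sab[2, 1] <- -Sab[2, 1]
  dimnames(Sab) <- list(c("a", "b"), c("a", "b"))
  structure(list(a = a, b = b,
                 sem_a = unname(cf["Xsurface", "Std. Error"]),
                 sem_b = unname(cf["Xbulk", "Std. Error"]),
                 intercept = unname(cf["(Intercept)", "Estimate"]),
                 sem_intercept = unname(cf["(Intercept)", "Std. Error"]),
                 covariance = Sab,
                 n_lo = n_lo, n_hi = n_hi,
                 saturation_class = if (b > 0) "super" else "sub",
                 n_bins_used = length(n), iterations = 1L,
                 sigma = summary(fit)$sigma),
            class = "free_energy_fit")
}

#' @export
print.free_energy_fit <- function(x, ...) {
  cat(sprintf("Nucleation free-energy fit (%s-saturated)\n",
              x$saturation_class))
  cat(sprintf("  a = %.4g +/- %.2g, b = %.4g +/- %.2g (kBT units)\n",
              x$a, x$sem_a, x$b, x$sem_b))
  cat(sprintf("  fit range n in [%g, %g], %d bins, %d iteration(s)\n",
              x$n_lo, x$n_hi, x$n_bins_used, x$iterations))
  if (x$saturation_class == "super") {
    cp <- critical_point(x$a, x$b)
    cat(sprintf("  n_c = %.4g, R_c = %.4g nm, barrier = %.3g kBT\n",
                cp$n_c, cp$R_c, barrier_height(x$a, x$b)))
  }
  invisible(x)
}

#' Poisson maximum-likelihood fit of the binned size distribution
#'
#' Fits the same model as [fit_free_energy()] -- \eqn{\Delta G} linear in
#' \eqn{\{n^{2/3}, n, 1\}} -- but as a Poisson log-link GLM on the raw bin
#' counts, \eqn{E[c_i] = \exp(const - a n_i^{2/3} + b n_i)}, over all bins
#' in range including empty ones. For sparsely populated histogram tails
#' this is the consistent estimator: ordinary least squares on
#' \eqn{-\ln \hat P} cannot use empty bins and caps the empirical free
#' energy of one-count bins at \eqn{\ln(total)}, which biases the critical
#' radius at fine bin widths. The GLM is also bin-width consistent, which
#' is what makes the fitted critical radius insensitive to the histogram
#' resolution.
#'
#' @param dist a [histogram_sizes()] result.
#' @param n_lo,n_hi fit range over bin centers (inclusive).
#' @return a `free_energy_fit` (same structure as [fit_free_energy()],
#'   with `method = "poisson"`).
#' @export
fit_free_energy_counts <- function(dist, n_lo = NULL, n_hi = NULL) {
  stopifnot(inherits(dist, "size_distribution"))
  n_lo <- n_lo %||% min(dist$bin_centers[dist$occupied])
  n_hi <- n_hi %||% max(dist$bin_centers[dist$occupied])
  if (n_lo >= n_hi) stop_nucfit("'n_lo' must be below 'n_hi'",
                                "nucfit_range_error")
  sel <- dist$bin_centers >= n_lo & dist$bin_centers <= n_hi
  n <- dist$bin_centers[sel]
  y <- dist$counts[sel]
  if (sum(y > 0) < 6) {
    stop_nucfit(sprintf("need >= 6 occupied bins in fit range (got %d)",
                        sum(y > 0)), "nucfit_fit_error")
  }
  X <- cbind(surface = n^(2 / 3), bulk = n)
  g <- suppressWarnings(stats::glm(y ~ X, family = stats::poisson()))
  if (!g$converged || any(is.na(stats::coef(g)))) {
    stop_nucfit("Poisson fit did not converge or design is rank-deficient",
                "nucfit_fit_error")
  }
  cf <- summary(g)$coefficients
  V <- stats::vcov(g)
  # log-mean = const - dG  =>  a = -coef(n^{2/3}), b = +coef(n)
  a <- -unname(cf["Xsurface", "Estimate"])
  b <- unname(cf["Xbulk", "Estimate"])
  Sab <- V[c("Xsurface", "Xbulk"), c("Xsurface", "Xbulk")]
  Sab[1, 2] <- -Sab[1, 2]; Sab[2, 1] <- -Sab[2, 1]
  dimnames(Sab) <- list(c("a", "b"), c("a", "b"))
  structure(list(a = a, b = b,
                 sem_a = unname(cf["Xsurface", "Std. Error"]),
                 sem_b = unname(cf["Xbulk", "Std. Error"]),
                 intercept = -unname(cf["(Intercept)", "Estimate"]),
                 sem_intercept = unname(cf["(Intercept)", "Std. Error"]),
                 covariance = Sab, n_lo = n_lo, n_hi = n_hi,
                 saturation_class = if (b > 0) "super" else "sub",
                 n_bins_used = length(n), iterations = 1L,
                 method = "poisson"),
            class = "free_energy_fit")
}

#' Self-consistent fit of the size distribution
#'
#' The nucleation form is only valid below the critical size, so the fit
#' range must end below \eqn{n_c} -- which is itself a fit output. The
#' range is determined self-consistently: fit on `[n_lo, n_hi]`, compute
#' \eqn{n_c = (2a/3b)^3}, set `n_hi` to 80% of the critical size, repeat
#' until the relative change in \eqn{n_c} is below `tol` (default 1%, below
#' the ~2% bin-width robustness floor of the procedure) or `max_iter`
#' iterations. The 80% cut is applied in n by default (`rule = "n"`,
#' matching the worked convention n_hi ~ 0.8 n_c); `rule = "R"` instead
#' cuts at 80% of the critical radius, i.e. `n_hi = 0.512 n_c`.
#'
#' If the fitted bulk coefficient comes out sub-saturated (no critical
#' point) the full-range fit is returned with `saturation_class = "sub"`.
#'
#' @param dist a [histogram_sizes()] result.
#' @param n_lo lower end of the fit range (defaults to the first occupied
#'   bin center).
#' @param rule "n" or "R" interpretation of the 80% cut.
#' @param frac cut fraction (default 0.8).
#' @param tol convergence tolerance on the relative change of n_c.
#' @param max_iter iteration cap (default 50).
#' @param weights optional per-bin weights (OLS engine only).
#' @param method fitting engine: `"auto"` (default) uses the Poisson count
#'   likelihood ([fit_free_energy_counts()]) when `dist` is a
#'   `size_distribution` and OLS on the curve otherwise; `"poisson"` and
#'   `"ols"` force the choice.
#' @return a `free_energy_fit` with `iterations` and `nc_history` recording
#'   the iteration path.
#' @export
self_consistent_fit <- function(dist, n_lo = NULL,
                                rule = c("n", "R"), frac = 0.8,
                                tol = 0.01, max_iter = 50L, weights = NULL,
                                method = c("auto", "poisson", "ols")) {
  rule <- match.arg(rule)
  method <- match.arg(method)
  is_dist <- inherits(dist, "size_distribution")
  if (method == "auto") method <- if (is_dist) "poisson" else "ols"
  if (method == "poisson" && !is_dist) {
    stop_nucfit("the Poisson engine needs a size_distribution (bin counts)",
                "nucfit_parameter_error")
  }
  curve <- if (is_dist) empirical_free_energy(dist) else dist
  if (is.null(n_lo)) n_lo <- min(curve$n)
  span <- range(curve$n)
  if (span[2] < 4 * curve$n_start) {
    warning("distribution spans less than [n_start, 4 n_start]; fit may be unstable")
  }
  engine <- if (method == "poisson") {
    function(lo, hi, w) fit_free_energy_counts(dist, lo, hi)
  } else {
    function(lo, hi, w) fit_free_energy(curve, lo, hi, w)
  }
  cut_frac <- if (rule == "n") frac else frac^3
  n_hi <- max(curve$n)
  fit <- engine(n_lo, n_hi, weights)
  if (fit$saturation_class == "sub") {
    fit$nc_history <- numeric(0)
    return(fit)
  }
  nc_cur <- (2 * fit$a / (3 * fit$b))^3
  nc_history <- nc_cur
  prev_bins <- NA_integer_
  stable_bins <- 0L
  for (it in seq_len(max_iter)) {
    n_hi_new <- cut_frac * nc_cur
    if (n_hi_new <= n_lo) {
      stop_nucfit("fit range collapsed: the n_hi update fell below n_lo",
                  "nucfit_range_collapse")
    }
    n_hi_new <- min(n_hi_new, max(curve$n))
    top_bin <- max(which(curve$n <= n_hi_new))
    fit_new <- engine(n_lo, n_hi_new, weights)
    if (fit_new$saturation_class == "sub") {
      stop_nucfit(
        "iteration left the super-saturated branch; range selection diverged",
        "nucfit_convergence_error")
    }
    nc_new <- (2 * fit_new$a / (3 * fit_new$b))^3
    rel <- abs(nc_new - nc_cur) / nc_cur
    fit <- fit_new
    nc_history <- c(nc_history, nc_new)
    # the fit depends on n_hi only through the set of included bins: once
    # that set stops changing the update has reached its discrete fixed
    # point (to within one bin of resolution)
    stable_bins <- if (identical(top_bin, prev_bins)) stable_bins + 1L else 0L
    if (rel < tol || stable_bins >= 2L) {
      fit$iterations <- it
      fit$nc_history <- nc_history
      return(fit)
    }
    prev_bins <- top_bin
    # averaged iterates: sparse tail bins make the raw update oscillate
    # (adding/removing one few-count bin can move n_c by several percent);
    # averaging damps the cycles without moving the fixed point
    nc_prev_avg <- nc_cur
    nc_cur <- if (it == 1L) nc_new else nc_cur + (nc_new - nc_cur) / it
    if (it >= 3L && abs(nc_cur - nc_prev_avg) / nc_prev_avg < tol / 2) {
      # the averaged iterate has settled even though the raw update still
      # flips one boundary bin in and out: accept the averaged range
      n_hi_fin <- min(cut_frac * nc_cur, max(curve$n))
      fit <- engine(n_lo, n_hi_fin, weights)
      if (fit$saturation_class == "sub") {
        stop_nucfit("averaged refit left the super-saturated branch",
                    "nucfit_convergence_error")
      }
      fit$iterations <- it + 1L
      fit$nc_history <- c(nc_history, (2 * fit$a / (3 * fit$b))^3)
      fit$cycle_damped <- TRUE
      return(fit)
    }
  }
  stop_nucfit(sprintf(
    "self-consistent range did not converge in %d iterations (last n_c: %s)",
    max_iter, paste(signif(utils::tail(nc_history, 4), 4), collapse = ", ")),
    "nucfit_convergence_error")
}
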