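#' Photobleaching correction of intensity traces
#'
#' Fits a single exponential \eqn{I_{mean}(t) = I_0 e^{-\lambda t}} to the
#' mean intensity across traces (least squares on the log of the mean) and
#' divides every trace by \eqn{e^{-\lambda t}}. A non-decaying mean
#' (\eqn{\lambda \le 0}) triggers a warning and the identity correction.
#'
#' @param traces long data.frame with columns `trace_id`, `t_s`,
#'   `intensity_counts` (the layout written by
#'   [generate_intensity_traces()]), or a single trace without `trace_id`.
#' @param mean_series optional two-column data.frame (`t_s`, `intensity`)
#'   giving the measured imaging-plane mean intensity to fit instead of the
#'   trace mean (the plane mean is the better estimate of bleaching since
#'   individual clusters genuinely grow and shrink).
#' @return list with `traces` (input plus `intensity_corrected`), `lambda`
#'   (1/s), `I0`.
#' @export
bleach_correct <- function(traces, mean_series = NULL) {
  if (is.null(traces$trace_id)) traces$trace_id <- "trace_1"
  src <- if (!is.null(mean_series)) {
    data.frame(t = mean_series[[1]], I = mean_series[[2]])
  } else {
    agg <- stats::aggregate(intensity_counts ~ t_s, data = traces, FUN = mean)
    data.frame(t = agg$t_s, I = agg$intensity_counts)
  }
  if (nrow(src) < 5) {
    stop_nucfit("need at least 5 time points to fit the bleach decay",
                "nucfit_parameter_error")
  }
  if (any(src$I <= 0)) {
    stop_nucfit("mean intensity must be positive to fit an exponential",
                "nucfit_parameter_error")
  }
  fit <- stats::lm(log(I) ~ t, data = src)
  lambda <- -unname(stats::coef(fit)["t"])
  if (lambda <= 0) {
    warning("mean intensity does not decay (lambda <= 0); applying identity correction")
    lambda <- 0
  }
  traces$intensity_corrected <- traces$intensity_counts *
    exp(lambda * traces$t_s)
  list(traces = traces, lambda = lambda,
       I0 = exp(unname(stats::coef(fit)[1])))
}

#' Convert fluorescence intensity to estimated molecule count
#'
#' `N = I / I_single`, with `I_single` the average single-molecule
#' intensity (24 counts under the reference imaging conditions). N is left
#' real-valued: rounding would bias the small-N bins of the size
#' distribution.
#'
#' @param I intensity counts (>= 0).
#' @param I_single single-molecule intensity in counts (> 0).
#' @return estimated number of fluorescent molecules.
#' @export
intensity_to_count <- function(I, I_single = 24) {
  if (I_single <= 0) stop_nucfit("'I_single' must be positive",
                                 "nucfit_parameter_error")
  if (any(I < 0, na.rm = TRUE)) {
    stop_nucfit("negative intensities are not interpretable",
                "nucfit_parameter_error")
  }
  I / I_single
}

#' Fit the nucleation free energy to live-cell molecule counts
#'
#' Applies the same histogram / negative-log / self-consistent-fit
#' machinery as the fixed-cell path, but on the molecule-count variable N
#' (default bin width 10, starting at 0). Reports the fit together with
#' `N_c = (2a/3b)^3` and the barrier.
#'
#' @param N vector of estimated molecule counts (>= 500 values).
#' @param bin_width histogram bin width in molecules (default 10).
#' @param n_start left edge of the first bin (default 0).
#' @param self_consistent use the 80%-of-critical-size range rule
#'   (default TRUE).
#' @return list with `fit` (a `free_energy_fit`), `params`
#'   (a `nucleation_parameters`), `dist`.
#' @export
fit_livecell_distribution <- function(N, bin_width = 10, n_start = 0,
                                      self_consistent = TRUE) {
  if (length(N) < 500) {
    stop_nucfit("need at least 500 values for a stable live-cell fit",
                "nucfit_parameter_error")
  }
  dist <- histogram_sizes(N, delta_n = bin_width, n_start = n_start)
  fit <- if (self_consistent) self_consistent_fit(dist) else
    fit_free_energy(empirical_free_energy(dist))
  list(fit = fit, params = nucleation_parameters(fit), dist = dist)
}

#' Classify traces as growing, shrinking or stable
#'
#' Labels each (bleach-corrected) trace by the relative change between its
#' first and last time point: more than `threshold` (default 10%) up is
#' "growing", more than `threshold` down is "shrinking", otherwise
#' "stable".
#'
#' @param traces long data.frame with `trace_id`, `t_s` and a value column
#'   (`intensity_corrected` if present, else `intensity_counts`).
#' @param threshold relative-change threshold (default 0.10).
#' @return data.frame `trace_id`, `start`, `end`, `rel_change`, `label`
#'   ("growing", "shrinking", "stable", or "unclassifiable" when the start
#'   value is 0).
#' @export
classify_traces <- function(traces, threshold = 0.10) {
  val_col <- if ("intensity_corrected" %in% names(traces))
    "intensity_corrected" else "intensity_counts"
  ids <- unique(traces$trace_id)
  rows <- lapply(ids, function(id) {
    tr <- traces[traces$trace_id == id, ]
    tr <- tr[order(tr$t_s), ]
    s <- tr[[val_col]][1]
    e <- tr[[val_col]][nrow(tr)]
    if (s == 0) {
      return(data.frame(trace_id = id, start = s, end = e,
                        rel_change = NA_real_, label = "unclassifiable"))
    }
    rc <- (e - s) / s
    lab <- if (rc > threshold) "growing" else
      if (rc < -threshold) "shrinking" else "stable"
    data.frame(trace_id = id, start = s, end = e, rel_change = rc,
               label = lab)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Growth-law fit of a single trace
#'
#' OLS slope of N against t (the coarsening prediction is linear growth,
#' \eqn{N(t) \propto t}, equivalent to \eqn{R \propto t^{1/3}}), plus the
#' time exponent from a log-log fit of \eqn{|N - N_0|} against t, with
#' \eqn{N_0} the fitted intercept. The exponent fit is skipped (NA) when
#' \eqn{N - N_0} changes sign, since the power law is then undefined.
#'
#' @param trace data.frame with `t_s` and a value column
#'   (`intensity_corrected` preferred); values must be strictly positive
#'   and there must be at least 10 points.
#' @return list with `slope`, `slope_sem`, `intercept`, `exponent`,
#'   `exponent_sem`.
#' @export
growth_law_fit <- function(trace) {
  val_col <- if ("intensity_corrected" %in% names(trace))
    "intensity_corrected" else "intensity_counts"
  trace <- trace[order(trace$t_s), ]
  N <- trace[[val_col]]; t <- trace$t_s
  if (length(N) < 10) stop_nucfit("need at least 10 points",
                                  "nucfit_parameter_error")
  if (any(N <= 0)) stop_nucfit("trace values must be strictly positive",
                               "nucfit_parameter_error")
  fit <- stats::lm(N ~ t)
  cf <- summary(fit)$coefficients
  N0 <- unname(cf["(Intercept)", "Estimate"])
  dev <- N - N0
  expo <- expo_sem <- NA_real_
  pos <- t > 0
  if (all(dev[pos] > 0) || all(dev[pos] < 0)) {
    lfit <- stats::lm(log(abs(dev[pos])) ~ log(t[pos]))
    lcf <- summary(lfit)$coefficients
    expo <- unname(lcf[2, "Estimate"])
    expo_sem <- unname(lcf[2, "Std. Error"])
  }
  list(slope = unname(cf["t", "Estimate"]),
       slope_sem = unname(cf["t", "Std. Error"]),
       intercept = N0, exponent = expo, exponent_sem = expo_sem)
}

#' Check intensity additivity at a merger event
#'
#' Condensates coalesce on contact, and the merged droplet's intensity
#' should equal the sum of its precursors. Compares the post-merger trace
#' value at its first time point with the sum of the two precursor values
#' at their last pre-merger time points (all bleach-corrected), and passes
#' if the relative residual is within `tolerance`.
#'
#' @param pre1,pre2 precursor traces (data.frames with `t_s` and a value
#'   column).
#' @param post post-merger trace.
#' @param tolerance relative residual tolerance (default 0.15).
#' @param max_gap_s maximum allowed gap between precursor end and merger
#'   start (default 2 sampling steps is typical; in seconds, default 31).
#' @return list with `pass`, `residual`, `I_pre1`, `I_pre2`, `I_post`.
#' @export
check_merger_additivity <- function(pre1, pre2, post, tolerance = 0.15,
                                    max_gap_s = 31) {
  val <- function(tr) {
    vc <- if ("intensity_corrected" %in% names(tr)) "intensity_corrected"
      else "intensity_counts"
    tr <- tr[order(tr$t_s), ]
    list(first_t = tr$t_s[1], last_t = tr$t_s[nrow(tr)],
         first = tr[[vc]][1], last = tr[[vc]][nrow(tr)])
  }
  v1 <- val(pre1); v2 <- val(pre2); vp <- val(post)
  if (vp$first_t < max(v1$last_t, v2$last_t) ||
      vp$first_t - max(v1$last_t, v2$last_t) > max_gap_s) {
    stop_nucfit("time bases misaligned: post-merger trace does not start at the merger",
                "nucfit_alignment_error")
  }
  total_pre <- v1$last + v2$last
  residual <- abs(vp$first - total_pre) / total_pre
  list(pass = residual <= tolerance, residual = residual,
       I_pre1 = v1$last, I_pre2 = v2$last, I_post = vp$first)
}
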