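#' Configuration for the synthetic-data generator
#'
#' Collects the parameters of the stochastic model used to emulate
#' single-molecule localization experiments: cluster sizes are drawn from the
#' truncated Boltzmann law \eqn{P(n) \propto e^{-(a n^{2/3} - b n)}}, each
#' cluster is rendered as a uniform disc of molecules obeying the cube law
#' (localization count \eqn{\propto R^3}), and every molecule emits a
#' geometric number of localizations ("blinking") jittered by the
#' localization error.
#'
#' Defaults emulate the conditions of the fixed-cell experiments: a
#' (25 um)^2 field imaged over 10,000 frames accumulating on the order of
#' 50,000 localizations, a lower size cutoff n_min = 1.5e4 (the smallest
#' reliably measured cluster, diameter about 50 nm), 20 nm localization
#' error, and a labelled-molecule density of one tracer per thousand size
#' units.
#'
#' @param a dimensionless surface coefficient (> 0). Default is the
#'   fixed-cell estimate 1.07e-3.
#' @param b dimensionless bulk coefficient, signed; positive = super-saturated.
#'   Default 4.3e-6 (fixed-cell estimate).
#' @param n_min lower size cutoff for sampled clusters (default 1.5e4).
#' @param n_max upper truncation used when `b <= 0` (sub-saturated branch,
#'   where the density has unbounded support); ignored when `b > 0`.
#' @param n_clusters number of clusters per generated cell (default 50).
#' @param field_size linear field of view in nm (default 25000).
#' @param n_frames number of acquisition frames (default 10000).
#' @param n_background_molecules unclustered background molecules per cell
#'   (default 1000, keeping the default map near the ~50,000-localization
#'   budget); these blink like clustered molecules and generate the
#'   spurious small clusters seen in unclustered tracer controls.
#' @param blink_mean mean localizations emitted per molecule (default 5).
#' @param rho_label labelled molecules per unit n (default 1e-3).
#' @param loc_sigma localization error standard deviation in nm (default 20).
#' @param seed integer seed; mandatory for reproducible generation.
#' @return object of class `generator_config` (a validated list).
#' @export
generator_config <- function(a = 1.07e-3, b = 4.3e-6,
                             n_min = 1.5e4, n_max = 5e6,
                             n_clusters = 50,
                             field_size = 25000, n_frames = 10000,
                             n_background_molecules = 1000,
                             blink_mean = 5, rho_label = 1e-3,
                             loc_sigma = 20, seed = 1L) {
  if (!is.numeric(a) || a <= 0) {
    stop_nucfit("'a' must be positive", "nucfit_parameter_error")
  }
  if (n_min < 1) {
    stop_nucfit("'n_min' must be >= 1", "nucfit_parameter_error")
  }
  if (loc_sigma < 0) {
    stop_nucfit("'loc_sigma' must be >= 0", "nucfit_parameter_error")
  }
  if (blink_mean < 1) {
    stop_nucfit("'blink_mean' must be >= 1", "nucfit_parameter_error")
  }
  if (b > 0) {
    n_c <- (2 * a / (3 * b))^3
    if (n_min >= n_c) {
      stop_nucfit(sprintf(
        "n_min (%g) must lie below the critical size n_c = (2a/3b)^3 = %g",
        n_min, n_c), "nucfit_invalid_range")
    }
  }
  structure(list(a = a, b = b, n_min = n_min, n_max = n_max,
                 n_clusters = n_clusters, field_size = field_size,
                 n_frames = n_frames,
                 n_background_molecules = n_background_molecules,
                 blink_mean = blink_mean, rho_label = rho_label,
                 loc_sigma = loc_sigma, seed = as.integer(seed)),
            class = "generator_config")
}

#' @export
print.generator_config <- function(x, ...) {
  cat("Synthetic-data generator configuration\n")
  cat(sprintf("  free energy: a = %g, b = %g (%s-saturated)\n", x$a, x$b,
              if (x$b > 0) "super" else "sub"))
  cat(sprintf("  size range: [%g, %g]\n", x$n_min,
              if (x$b > 0) (2 * x$a / (3 * x$b))^3 else x$n_max))
  cat(sprintf("  field %g nm, %d clusters, %d background molecules\n",
              x$field_size, x$n_clusters, x$n_background_molecules))
  cat(sprintf("  blink mean %g, rho_label %g, loc_sigma %g nm, seed %d\n",
              x$blink_mean, x$rho_label, x$loc_sigma, x$seed))
  invisible(x)
}

# Tabulated inverse-CDF machinery for the truncated Boltzmann size law.
# Returns grid and normalized cumulative weights on [lo, hi].
size_law_cdf_grid <- function(a, b, lo, hi, grid_n = 8193L) {
  grid <- seq(lo, hi, length.out = grid_n)
  logf <- -(a * grid^(2 / 3) - b * grid)
  logf <- logf - max(logf)
  f <- exp(logf)
  dx <- diff(grid)
  increments <- dx * (f[-length(f)] + f[-1]) / 2
  cdf <- c(0, cumsum(increments))
  cdf <- cdf / cdf[length(cdf)]
  list(grid = grid, cdf = cdf)
}

#' Sample cluster sizes from the truncated Boltzmann law
#'
#' Draws i.i.d. sizes n from the density proportional to
#' \eqn{\exp(-(a n^{2/3} - b n))}. For a super-saturated configuration
#' (`b > 0`) the support is `[n_min, n_c]` with \eqn{n_c = (2a/3b)^3}: the
#' Boltzmann form only describes sub-critical clusters. For `b <= 0` the
#' support is `[n_min, n_max]`.
#'
#' Sampling is by inverse transform on a dense tabulated CDF (trapezoidal
#' integration on an 8193-point grid), which keeps the Kolmogorov-Smirnov
#' discrepancy against the exact law well below sampling noise at 1e5 draws.
#'
#' @param cfg a [generator_config()].
#' @param n_draws number of sizes to draw; defaults to `cfg$n_clusters`.
#' @param seed optional seed overriding `cfg$seed`.
#' @return numeric vector of sizes.
#' @export
sample_cluster_sizes <- function(cfg, n_draws = cfg$n_clusters,
                                 seed = cfg$seed) {
  stopifnot(inherits(cfg, "generator_config"))
  if (n_draws == 0) {
    return(numeric(0))
  }
  hi <- if (cfg$b > 0) (2 * cfg$a / (3 * cfg$b))^3 else cfg$n_max
  tab <- size_law_cdf_grid(cfg$a, cfg$b, cfg$n_min, hi)
  with_seed(seed, {
    u <- stats::runif(n_draws)
    stats::approx(tab$cdf, tab$grid, xout = u, ties = "ordered")$y
  })
}

# Geometric blink model: localizations per molecule, support {1, 2, ...},
# mean = blink_mean (memoryless stand-in; the real blink statistics of the
# fluorophore are not characterized).
draw_blinks <- function(n_molecules, blink_mean) {
  if (n_molecules == 0) return(integer(0))
  1L + stats::rgeom(n_molecules, prob = 1 / blink_mean)
}

#' Render cluster sizes into a synthetic localization map
#'
#' Each cluster of size n becomes a disc of radius \eqn{R = n^{1/3}} nm
#' containing `round(rho_label * n)` uniformly placed molecules (so the
#' localization count scales as \eqn{R^3}, the cube law observed for
#' homogeneously labelled clusters). Every molecule, clustered or
#' background, emits a geometric number of localizations (mean
#' `blink_mean`), each jittered by an isotropic Gaussian of sd `loc_sigma`
#' and assigned a uniform random frame.
#'
#' @param sizes numeric vector of cluster sizes n; cluster centres are placed
#'   uniformly such that each disc fits inside the field.
#' @param cfg a [generator_config()].
#' @param cell_id label stored with the map.
#' @param seed optional seed overriding `cfg$seed`.
#' @return a `localization_map`: list with `points` (data.frame `frame`,
#'   `x_nm`, `y_nm`), `field_size`, `cell_id`, and a `ground_truth`
#'   data.frame (`cluster_id`, `x_nm`, `y_nm`, `R_nm`, `n_true`,
#'   `n_molecules`, `n_localizations`).
#' @export
generate_localization_map <- function(sizes, cfg, cell_id = "cell_1",
                                      seed = cfg$seed) {
  stopifnot(inherits(cfg, "generator_config"))
  if (any(sizes < 0)) {
    stop_nucfit("cluster sizes must be non-negative", "nucfit_parameter_error")
  }
  radii <- sizes^(1 / 3)
  if (any(radii > cfg$field_size / 2)) {
    stop_nucfit("cluster radius exceeds half the field size",
                "nucfit_geometry_error")
  }
  res <- with_seed(seed, {
    k <- length(sizes)
    xs <- ys <- frames <- list()
    gt <- data.frame(cluster_id = integer(0), x_nm = numeric(0),
                     y_nm = numeric(0), R_nm = numeric(0),
                     n_true = numeric(0), n_molecules = integer(0),
                     n_localizations = integer(0))
    if (k > 0) {
      cx <- stats::runif(k, radii, cfg$field_size - radii)
      cy <- stats::runif(k, radii, cfg$field_size - radii)
      n_loc <- integer(k)
      n_mol <- integer(k)
      for (i in seq_len(k)) {
        m <- as.integer(round(cfg$rho_label * sizes[i]))
        n_mol[i] <- m
        if (m == 0) { n_loc[i] <- 0L; next }
        theta <- stats::runif(m, 0, 2 * pi)
        r <- radii[i] * sqrt(stats::runif(m))
        mx <- cx[i] + r * cos(theta)
        my <- cy[i] + r * sin(theta)
        blinks <- draw_blinks(m, cfg$blink_mean)
        tot <- sum(blinks)
        n_loc[i] <- tot
        xs[[length(xs) + 1L]] <- rep(mx, blinks) +
          stats::rnorm(tot, 0, cfg$loc_sigma)
        ys[[length(ys) + 1L]] <- rep(my, blinks) +
          stats::rnorm(tot, 0, cfg$loc_sigma)
        frames[[length(frames) + 1L]] <-
          sample.int(cfg$n_frames, tot, replace = TRUE) - 1L
      }
      gt <- data.frame(cluster_id = seq_len(k), x_nm = cx, y_nm = cy,
                       R_nm = radii, n_true = sizes, n_molecules = n_mol,
                       n_localizations = n_loc)
    }
    if (cfg$n_background_molecules > 0) {
      m <- cfg$n_background_molecules
      mx <- stats::runif(m, 0, cfg$field_size)
      my <- stats::runif(m, 0, cfg$field_size)
      blinks <- draw_blinks(m, cfg$blink_mean)
      tot <- sum(blinks)
      xs[[length(xs) + 1L]] <- rep(mx, blinks) +
        stats::rnorm(tot, 0, cfg$loc_sigma)
      ys[[length(ys) + 1L]] <- rep(my, blinks) +
        stats::rnorm(tot, 0, cfg$loc_sigma)
      frames[[length(frames) + 1L]] <-
        sample.int(cfg$n_frames, tot, replace = TRUE) - 1L
    }
    pts <- data.frame(frame = as.integer(unlist(frames) %||% integer(0)),
                      x_nm = as.numeric(unlist(xs) %||% numeric(0)),
                      y_nm = as.numeric(unlist(ys) %||% numeric(0)))
    # jitter can push localizations outside the field; clamp to the sensor
    pts$x_nm <- pmin(pmax(pts$x_nm, 0), cfg$field_size)
    pts$y_nm <- pmin(pmax(pts$y_nm, 0), cfg$field_size)
    list(points = pts, ground_truth = gt)
  })
  structure(list(points = res$points, field_size = cfg$field_size,
                 cell_id = cell_id, ground_truth = res$ground_truth),
            class = "localization_map")
}

#' @export
print.localization_map <- function(x, ...) {
  cat(sprintf("Localization map '%s': %d localizations in (%g nm)^2",
              x$cell_id, nrow(x$points), x$field_size))
  if (!is.null(x$ground_truth) && nrow(x$ground_truth) > 0) {
    cat(sprintf(" (%d ground-truth clusters)", nrow(x$ground_truth)))
  }
  cat("\n")
  invisible(x)
}

#' Generate synthetic live-cell cluster intensities
#'
#' Draws molecule counts N from the truncated Boltzmann law with live-cell
#' parameters and converts them to fluorescence intensities
#' \eqn{I = N \cdot I_{single} (1 + \epsilon)}, with multiplicative Gaussian
#' measurement noise of coefficient of variation `noise_cv`.
#'
#' @param a,b live-cell free-energy parameters (defaults: the light-sheet
#'   estimates a = 0.166, b = 0.011).
#' @param n_samples number of clusters.
#' @param I_single average single-molecule intensity in camera counts
#'   (default 24).
#' @param noise_cv coefficient of variation of the intensity noise.
#' @param n_min lower truncation of N (default 1 molecule).
#' @param seed integer seed.
#' @return data.frame with columns `cluster_id`, `N_true`,
#'   `intensity_counts`.
#' @export
generate_livecell_intensities <- function(a = 0.166, b = 0.011,
                                          n_samples = 2800, I_single = 24,
                                          noise_cv = 0.05, n_min = 1,
                                          seed = 1L) {
  if (I_single <= 0) {
    stop_nucfit("'I_single' must be positive", "nucfit_parameter_error")
  }
  if (noise_cv < 0) {
    stop_nucfit("'noise_cv' must be non-negative", "nucfit_parameter_error")
  }
  cfg <- generator_config(a = a, b = b, n_min = n_min, seed = seed)
  N <- sample_cluster_sizes(cfg, n_draws = n_samples, seed = seed)
  eps <- with_seed(seed + 1L, stats::rnorm(n_samples, 0, noise_cv))
  data.frame(cluster_id = seq_len(n_samples), N_true = N,
             intensity_counts = N * I_single * (1 + eps))
}

#' Generate synthetic live-cell intensity traces
#'
#' Each trace follows the linear growth law \eqn{N(t) = N_0 + g t} (g
#' signed), multiplied by exponential photobleaching
#' \eqn{e^{-\lambda t}} and multiplicative Gaussian noise. Optional scripted
#' merger events replace two traces by one whose pre-noise intensity is the
#' sum of its precursors from the merger time onward.
#'
#' @param trace_spec data.frame with columns `trace_id`, `N0` (initial
#'   intensity in counts), `g` (signed growth rate, counts/s).
#' @param bleach_rate photobleaching decay constant lambda in 1/s.
#' @param dt sampling cadence in seconds (default 15, the per-stack
#'   acquisition interval).
#' @param duration total duration in seconds (default 360, i.e. 6 min);
#'   must be a multiple of `dt`.
#' @param noise_cv multiplicative noise CV (default 0).
#' @param mergers optional data.frame with columns `pre1`, `pre2`
#'   (trace_ids), `t_merge` (s), `new_id`.
#' @param seed integer seed.
#' @return data.frame `trace_id`, `t_s`, `intensity_counts`, `clipped`
#'   (logical: TRUE where noise drove the value negative and it was clipped
#'   to 0), with the noise-free trace in `intensity_true`.
#' @export
generate_intensity_traces <- function(trace_spec, bleach_rate = 0,
                                      dt = 15, duration = 360,
                                      noise_cv = 0, mergers = NULL,
                                      seed = 1L) {
  if (dt <= 0) stop_nucfit("'dt' must be positive", "nucfit_parameter_error")
  if (abs(duration / dt - round(duration / dt)) > 1e-9) {
    stop_nucfit("'duration' must be a multiple of 'dt'",
                "nucfit_parameter_error")
  }
  times <- seq(0, duration, by = dt)
  curves <- lapply(seq_len(nrow(trace_spec)), function(i) {
    trace_spec$N0[i] + trace_spec$g[i] * times
  })
  names(curves) <- as.character(trace_spec$trace_id)
  alive_from <- stats::setNames(rep(0, nrow(trace_spec)),
                                names(curves))
  alive_to <- stats::setNames(rep(duration, nrow(trace_spec)),
                              names(curves))
  if (!is.null(mergers)) {
    for (j in seq_len(nrow(mergers))) {
      p1 <- as.character(mergers$pre1[j]); p2 <- as.character(mergers$pre2[j])
      tm <- mergers$t_merge[j]
      if (!p1 %in% names(curves) || !p2 %in% names(curves)) {
        stop_nucfit("merger refers to unknown trace", "nucfit_parameter_error")
      }
      new_id <- as.character(mergers$new_id[j])
      curves[[new_id]] <- curves[[p1]] + curves[[p2]]
      alive_from[new_id] <- tm
      alive_to[new_id] <- duration
      alive_to[p1] <- tm - dt / 2  # parent traces end just before the merger
      alive_to[p2] <- tm - dt / 2
    }
  }
  out <- with_seed(seed, {
    rows <- lapply(names(curves), function(id) {
      keep <- times >= alive_from[id] & times <= alive_to[id]
      tt <- times[keep]
      true_val <- curves[[id]][keep] * exp(-bleach_rate * tt)
      noisy <- true_val * (1 + stats::rnorm(length(tt), 0, noise_cv))
      clipped <- noisy < 0
      noisy[clipped] <- 0
      data.frame(trace_id = id, t_s = tt, intensity_counts = noisy,
                 intensity_true = true_val, clipped = clipped)
    })
    do.call(rbind, rows)
  })
  rownames(out) <- NULL
  out
}
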