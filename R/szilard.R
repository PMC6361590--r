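#' Build a Szilard rate model
#'
#' The Szilard mechanism maintains a super-saturated steady state through
#' continuous monomer production, free-energy-governed condensation, and
#' preferential clearance of super-critical clusters. The theory specifies
#' only the energetics; the kinetic closure used here is surface-limited
#' attachment, \eqn{k_{on}(n) = k_{att0} n^{2/3}} (attachment flux scales
#' with cluster surface area, consistent with diffusion-limited coarsening,
#' \eqn{R \propto t^{1/3}}), with detachment fixed by detailed balance:
#' \deqn{k_{off}(n) = k_{on}(n-1) \exp(\Delta G(n) - \Delta G(n-1)).}
#' A constant-attachment alternative (`attachment = "constant"`,
#' \eqn{k_{on} = k_{att0}}) is provided.
#'
#' @param a,b free-energy parameters (kBT units).
#' @param k_att0 attachment rate constant (1/time; per unit surface for the
#'   default closure).
#' @param J monomer production rate (monomers/time).
#' @param kappa clearance rate (1/time) applied to clusters of size
#'   `n >= n_clear`.
#' @param n_clear clearance threshold; defaults to the critical size
#'   (rounded up) when `b > 0`, otherwise `n_max + 1` (no clearance band).
#' @param n_max state-space truncation (reflecting top).
#' @param clearance_mode `"remove"` (cleared mass leaves the system,
#'   degradation) or `"recycle"` (cleared clusters dissolve back into the
#'   monomer pool).
#' @param attachment `"surface"` or `"constant"`.
#' @param nucleation_mode `"per_monomer"` (default: dimers form at total
#'   rate `k_on(1) * M`, embedding every lineage in the same birth-death
#'   chain the master-equation oracle solves) or `"mass_action"`
#'   (`k_nuc * M (M-1) / 2`).
#' @param k_nuc dimerization constant for `"mass_action"` mode.
#' @return object of class `szilard_model` with the validated rate tables.
#' @export
build_rate_model <- function(a, b, k_att0 = 1, J = 0, kappa = 0,
                             n_clear = NULL, n_max = 100,
                             clearance_mode = c("remove", "recycle"),
                             attachment = c("surface", "constant"),
                             nucleation_mode = c("per_monomer", "mass_action"),
                             k_nuc = k_att0) {
  clearance_mode <- match.arg(clearance_mode)
  attachment <- match.arg(attachment)
  nucleation_mode <- match.arg(nucleation_mode)
  if (k_att0 < 0 || J < 0 || kappa < 0) {
    stop_nucfit("rates must be non-negative", "nucfit_parameter_error")
  }
  if (a < 0) stop_nucfit("'a' must be >= 0", "nucfit_parameter_error")
  n_max <- as.integer(n_max)
  sizes <- seq_len(n_max)
  dG <- a * sizes^(2 / 3) - b * sizes   # allows a = 0 (flat) for testing
  kon <- if (attachment == "surface") k_att0 * sizes^(2 / 3) else
    rep(k_att0, n_max)
  ddG <- c(NA, diff(dG))                # dG(n) - dG(n-1)
  if (any(ddG[-1] > 700)) {
    stop_nucfit("exp(dG step) overflows: rates not representable",
                "nucfit_rate_cap_error")
  }
  koff <- c(0, kon[-n_max] * exp(ddG[-1]))  # koff(1) unused
  if (any(!is.finite(koff))) {
    stop_nucfit("non-finite detachment rate", "nucfit_rate_cap_error")
  }
  if (is.null(n_clear)) {
    n_clear <- if (b > 0) min(n_max + 1L, as.integer(ceiling((2 * a / (3 * b))^3)))
      else n_max + 1L
  }
  structure(list(a = a, b = b, k_att0 = k_att0, J = J, kappa = kappa,
                 n_clear = as.integer(n_clear), n_max = n_max,
                 clearance_mode = clearance_mode, attachment = attachment,
                 nucleation_mode = nucleation_mode, k_nuc = k_nuc,
                 sizes = sizes, dG = dG, kon = kon, koff = koff),
            class = "szilard_model")
}

#' @export
print.szilard_model <- function(x, ...) {
  cat(sprintf("Szilard model: a = %g, b = %g, n_max = %d\n", x$a, x$b, x$n_max))
  cat(sprintf("  k_att0 = %g (%s attachment), J = %g, kappa = %g at n >= %d (%s)\n",
              x$k_att0, x$attachment, x$J, x$kappa, x$n_clear,
              x$clearance_mode))
  invisible(x)
}

#' Kinetic Monte Carlo simulation of the Szilard process
#'
#' Statistically exact (Gillespie) event-driven simulation of monomer
#' production, dimer nucleation, attachment/detachment and clearance. The
#' state is the monomer pool plus the multiset of cluster sizes (tracked as
#' counts per size, truncated at `n_max` with a reflecting top).
#'
#' @param model a [build_rate_model()].
#' @param t_max simulated time horizon.
#' @param seed integer seed.
#' @param pool0 initial monomer count.
#' @param counts0 optional initial cluster counts for sizes `2..n_max`
#'   (vector of length `n_max - 1`).
#' @param max_events event cap guarding against rate explosions (default
#'   5e6; exceeding it aborts with the state attached).
#' @param record_dt cadence for trajectory snapshots (default `t_max/200`).
#' @return object of class `szilard_trajectory`: snapshot times, per-size
#'   count matrix, pool and super-critical count series, time-averaged
#'   occupancies, final state and exact mass bookkeeping
#'   (`initial + produced = pool + in_clusters + cleared` in remove mode).
#' @export
kmc_simulate <- function(model, t_max, seed = 1L, pool0 = 0,
                         counts0 = NULL, max_events = 5e6,
                         record_dt = t_max / 200) {
  stopifnot(inherits(model, "szilard_model"))
  if (is.null(counts0)) counts0 <- integer(model$n_max - 1L)
  stopifnot(length(counts0) == model$n_max - 1L)
  initial_mass <- pool0 + sum(seq(2, model$n_max) * counts0)
  res <- with_seed(seed, .kmc_cpp(
    model$kon, model$koff, model$J, model$kappa, model$n_clear,
    model$n_max,
    ifelse(model$clearance_mode == "recycle", 1L, 0L),
    ifelse(model$nucleation_mode == "mass_action", 1L, 0L),
    model$k_nuc, as.numeric(pool0), as.integer(counts0),
    as.numeric(t_max), as.numeric(max_events), as.numeric(record_dt)))
  if (res$events >= max_events && res$t_end < t_max) {
    stop_nucfit(paste0("event cap reached at t = ", signif(res$t_end, 4),
                       " (rate explosion?); state attached to condition"),
                "nucfit_event_cap_error")
  }
  in_clusters <- sum(seq(2, model$n_max) * res$counts)
  structure(list(model = model, t_end = res$t_end, events = res$events,
                 pool = res$pool, counts = res$counts,
                 sizes = seq(2, model$n_max),
                 produced = res$produced,
                 cleared_mass = res$cleared_mass,
                 cleared_clusters = res$cleared_clusters,
                 initial_mass = initial_mass,
                 mass_in_clusters = in_clusters,
                 avg_counts = res$avg_counts, avg_pool = res$avg_pool,
                 snap_t = res$snap_t, snap_pool = res$snap_pool,
                 snap_super = res$snap_super, snapshots = res$snapshots),
            class = "szilard_trajectory")
}

#' @export
print.szilard_trajectory <- function(x, ...) {
  cat(sprintf("Szilard KMC trajectory: t = %g, %g events\n", x$t_end, x$events))
  cat(sprintf("  pool %g, %g clusters (mass %g), cleared %g clusters (mass %g)\n",
              x$pool, sum(x$counts), x$mass_in_clusters,
              x$cleared_clusters, x$cleared_mass))
  invisible(x)
}

#' Stationary distribution of the truncated birth-death-clearance chain
#'
#' Dense linear-algebra solution of the single-cluster master equation on
#' sizes `1..n_max`: transitions `n -> n+1` at `k_on(n)`, `n -> n-1` at
#' `k_off(n)`, and clearance `n -> 1` at `kappa` for `n >= n_clear`
#' (cleared material re-enters as monomers, closing the chain). With
#' `kappa = 0` and reflecting truncation the stationary law is exactly
#' Boltzmann, \eqn{\pi(n) \propto e^{-\Delta G(n)}}. This is the
#' independent oracle for [kmc_simulate()].
#'
#' @param model a [build_rate_model()] with `n_max <= 200`.
#' @return numeric vector `pi` over sizes `1..n_max` (sums to 1).
#' @export
master_equation_solve <- function(model) {
  stopifnot(inherits(model, "szilard_model"))
  m <- model$n_max
  if (m > 200) {
    stop_nucfit("dense solve limited to n_max <= 200", "nucfit_parameter_error")
  }
  Q <- matrix(0, m, m)
  for (s in seq_len(m)) {
    if (s < m) Q[s, s + 1] <- model$kon[s]
    if (s > 1) Q[s, s - 1] <- model$koff[s]
    if (model$kappa > 0 && s >= model$n_clear) {
      Q[s, 1] <- Q[s, 1] + model$kappa
    }
    Q[s, s] <- Q[s, s] - sum(Q[s, -s])
  }
  A <- t(Q)
  A[m, ] <- 1              # replace one balance row with normalization
  rhs <- c(rep(0, m - 1), 1)
  pi_hat <- tryCatch(solve(A, rhs),
                     error = function(e) stop_nucfit(
                       paste("singular generator:", conditionMessage(e)),
                       "nucfit_numeric_error"))
  pi_hat[abs(pi_hat) < 1e-300] <- 0
  pi_hat / sum(pi_hat)
}

#' Washout experiment: phase-scheduled Szilard simulation
#'
#' Simulates the in-silico analogue of a stress/washout protocol: phases
#' differ in their bulk parameter b (super-saturation level), production
#' rate, or clearance rate, and the final state of each phase seeds the
#' next. Raising b mimics proteasome inhibition; restoring it mimics the
#' washout; setting `kappa = 0` mimics loss of the size-selective clearance
#' machinery, in which case super-critical clusters persist after washout.
#'
#' @param model baseline [build_rate_model()].
#' @param schedule data.frame with columns `duration` and any of
#'   `b`, `J`, `kappa` (NA = keep baseline value).
#' @param seed integer seed.
#' @param pool0,counts0 initial state passed to the first phase.
#' @param record_dt snapshot cadence within phases.
#' @return list of `szilard_trajectory`, one per phase, with phase-offset
#'   absolute times in `snap_t_abs`.
#' @export
washout_experiment <- function(model, schedule, seed = 1L,
                               pool0 = 0, counts0 = NULL,
                               record_dt = NULL) {
  stopifnot(inherits(model, "szilard_model"), nrow(schedule) >= 1)
  out <- vector("list", nrow(schedule))
  t0 <- 0
  for (ph in seq_len(nrow(schedule))) {
    b_ph <- if ("b" %in% names(schedule) && !is.na(schedule$b[ph]))
      schedule$b[ph] else model$b
    J_ph <- if ("J" %in% names(schedule) && !is.na(schedule$J[ph]))
      schedule$J[ph] else model$J
    k_ph <- if ("kappa" %in% names(schedule) && !is.na(schedule$kappa[ph]))
      schedule$kappa[ph] else model$kappa
    m_ph <- build_rate_model(model$a, b_ph, model$k_att0, J_ph, k_ph,
                             n_clear = model$n_clear, n_max = model$n_max,
                             clearance_mode = model$clearance_mode,
                             attachment = model$attachment,
                             nucleation_mode = model$nucleation_mode,
                             k_nuc = model$k_nuc)
    dur <- schedule$duration[ph]
    traj <- kmc_simulate(m_ph, dur, seed = seed + ph, pool0 = pool0,
                         counts0 = counts0,
                         record_dt = record_dt %||% (dur / 100))
    traj$snap_t_abs <- traj$snap_t + t0
    out[[ph]] <- traj
    pool0 <- traj$pool
    counts0 <- traj$counts
    t0 <- t0 + dur
  }
  out
}
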