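# Small-state-space models used throughout: nucleation energetics scaled so
# the critical size sits inside a tractable chain (n_c = 27 for
# a = 1.5, b = 1/3; the barrier is 4a^3/27b^2 = 4.5 kBT).
szmod <- function(a = 1.5, b = 1 / 3, ...) build_rate_model(a, b, ...)

test_that("rate model: detailed balance and degenerate energetics", {
  m <- szmod(k_att0 = 2, n_max = 60)
  n <- 2:60
  expect_equal(m$koff[n], m$kon[n - 1] * exp(m$dG[n] - m$dG[n - 1]),
               tolerance = 1e-14)
  # flat free energy: detachment mirrors attachment
  mf <- build_rate_model(0, 0, k_att0 = 1, n_max = 30)
  expect_equal(mf$koff[2:30], mf$kon[1:29], tolerance = 1e-14)
  expect_error(build_rate_model(1, 0.5, k_att0 = -1),
               class = "nucfit_parameter_error")
})

test_that("k_off/k_on crosses unity at the critical size (n_c +/- 1)", {
  # scale-reduced chain (n_c = 27)
  m <- szmod(n_max = 60)
  ratio <- m$koff[2:60] / m$kon[1:59]
  sizes <- 2:60
  expect_true(all(ratio[sizes < 26] > 1))   # sub-critical: shrink
  expect_true(all(ratio[sizes > 28] < 1))   # super-critical: grow
  # same statement for the fixed-cell parameters via the detailed-balance
  # identity koff(n)/kon(n-1) = exp(dG(n) - dG(n-1)), checked at n_c
  a <- 1.07e-3; b <- 4.3e-6
  n_c <- (2 * a / (3 * b))^3
  n_lo <- floor(n_c) - 1; n_hi <- ceiling(n_c) + 1
  expect_gt(exp(delta_g(n_lo, a, b) - delta_g(n_lo - 1, a, b)), 1)
  expect_lt(exp(delta_g(n_hi, a, b) - delta_g(n_hi - 1, a, b)), 1)
})

test_that("Ostwald drift: net growth rate changes sign at n_c", {
  m <- szmod(n_max = 60)
  drift <- m$kon - m$koff  # per-cluster net growth rate
  sizes <- seq_len(60)
  # analytic oracle: drift(n) < 0 iff the dG step exceeds the surface
  # prefactor term (2/3) ln(n/(n-1)); that crossing sits at or below n_c
  # (exactly at n_c for the detailed-balance ratio koff(n)/kon(n-1),
  # tested above)
  dstep <- diff(m$dG)                     # dG(n) - dG(n-1) at index n-1
  step_ok <- c(FALSE, dstep > (2 / 3) * log(sizes[-1] / (sizes[-1] - 1)))
  for (n in 2:59) {
    if (step_ok[n]) expect_lt(drift[n], 0) else expect_gt(drift[n], 0)
  }
  crossing <- max(which(step_ok))
  expect_lte(crossing, 27 + 1)
  expect_true(all(drift[sizes > 28 & sizes < 60] > 0))
})

test_that("master equation: Boltzmann law under reflecting truncation", {
  # b = 0, kappa = 0: pure sub-saturated birth-death chain
  m0 <- build_rate_model(1.5, 0, k_att0 = 1, n_max = 50)
  p0 <- master_equation_solve(m0)
  pb <- exp(-m0$dG); pb <- pb / sum(pb)
  expect_equal(p0, pb, tolerance = 1e-12)
  # super-saturated with kappa = 0 likewise Boltzmann (reflecting top)
  m <- szmod(n_max = 50)
  p <- master_equation_solve(m)
  pbm <- exp(-m$dG); pbm <- pbm / sum(pbm)
  expect_equal(p, pbm, tolerance = 1e-12)
})

test_that("KMC with no production and empty state does nothing", {
  m <- szmod(J = 0, n_max = 40)
  tr <- kmc_simulate(m, t_max = 10, seed = 1, pool0 = 0)
  expect_equal(tr$events, 0)
  expect_equal(sum(tr$counts), 0)
  expect_equal(tr$pool, 0)
})

test_that("KMC trajectories are reproducible and conserve mass exactly", {
  m <- szmod(k_att0 = 1, J = 100, kappa = 2, n_max = 50)
  tr1 <- kmc_simulate(m, t_max = 100, seed = 7, pool0 = 150)
  tr2 <- kmc_simulate(m, t_max = 100, seed = 7, pool0 = 150)
  expect_identical(tr1$counts, tr2$counts)
  expect_identical(tr1$events, tr2$events)
  # remove mode: initial + produced = pool + in clusters + cleared
  expect_equal(tr1$initial_mass + tr1$produced,
               tr1$pool + tr1$mass_in_clusters + tr1$cleared_mass)
  # recycle mode: cleared mass returns to the pool
  mr <- szmod(k_att0 = 1, J = 100, kappa = 2, n_max = 50,
              clearance_mode = "recycle")
  tr3 <- kmc_simulate(mr, t_max = 100, seed = 7, pool0 = 150)
  expect_equal(tr3$cleared_mass, 0)
  expect_equal(tr3$initial_mass + tr3$produced,
               tr3$pool + tr3$mass_in_clusters)
  expect_gt(tr3$cleared_clusters, 0)
})

test_that("KMC stationary sub-critical distribution matches the
          master-equation oracle (TV < 0.05)", {
  # high-barrier regime (4a^3/27b^2 = 7.2 kBT): the nucleation current is
  # small, which is the regime in which clearance can preserve the
  # sub-critical Boltzmann shape
  m <- build_rate_model(2.4, 0.533, k_att0 = 1, J = 5, kappa = 2,
                        n_clear = 28, n_max = 50)
  tr <- kmc_simulate(m, t_max = 300, seed = 3, pool0 = 2000,
                     max_events = 8e6)
  pi_hat <- master_equation_solve(m)
  sub <- 2:(m$n_clear - 1)
  p_kmc <- tr$avg_counts[sub - 1] / sum(tr$avg_counts[sub - 1])
  p_me <- pi_hat[sub] / sum(pi_hat[sub])
  expect_lt(0.5 * sum(abs(p_kmc - p_me)), 0.05)
  # ... and against the Boltzmann law itself (exp(-dG), the quantity the
  # steady state is meant to preserve)
  pb <- exp(-m$dG[sub]); pb <- pb / sum(pb)
  expect_lt(0.5 * sum(abs(p_kmc - pb)), 0.05)
})

test_that("clearance fate (remove vs recycle) changes the pool, not the
          sub-critical shape", {
  m1 <- szmod(k_att0 = 1, J = 100, kappa = 2, n_max = 50)
  m2 <- szmod(k_att0 = 1, J = 100, kappa = 2, n_max = 50,
              clearance_mode = "recycle")
  tr1 <- kmc_simulate(m1, t_max = 150, seed = 5, pool0 = 200,
                      max_events = 8e6)
  tr2 <- kmc_simulate(m2, t_max = 150, seed = 6, pool0 = 200,
                      max_events = 8e6)
  sub <- 2:(m1$n_clear - 1)
  p1 <- tr1$avg_counts[sub - 1] / sum(tr1$avg_counts[sub - 1])
  p2 <- tr2$avg_counts[sub - 1] / sum(tr2$avg_counts[sub - 1])
  expect_lt(0.5 * sum(abs(p1 - p2)), 0.05)
  expect_gt(tr2$avg_pool, tr1$avg_pool)
})

test_that("without clearance, super-critical mass keeps growing", {
  m <- szmod(k_att0 = 1, J = 30, kappa = 0, n_max = 80, n_clear = 28)
  for (sd in 1:5) {
    counts0 <- integer(79)
    counts0[30 - 2 + 1] <- 3   # seed three clusters just above n_c
    tr <- kmc_simulate(m, t_max = 60, seed = sd, pool0 = 500,
                       counts0 = counts0, max_events = 6e6)
    super_mass <- tr$snapshots %*% ifelse(tr$sizes >= 28, tr$sizes, 0)
    q <- length(super_mass) %/% 4
    expect_gt(mean(super_mass[(3 * q):length(super_mass)]),
              mean(super_mass[1:q]))
  }
})

test_that("washout: clearance decides whether super-critical clusters
          persist after the stress is lifted", {
  run_wash <- function(kappa, seed) {
    m <- build_rate_model(a = 2.4, b = 0.533, k_att0 = 1, J = 10,
                          kappa = kappa, n_clear = 28, n_max = 60)
    sched <- data.frame(duration = c(20, 60, 40), b = c(NA, 1.066, NA))
    tr <- washout_experiment(m, sched, seed = seed, pool0 = 1500)
    super <- unlist(lapply(tr, function(x) x$snap_super))
    post <- tr[[3]]$snap_super
    list(peak = max(super),
         end = mean(utils::tail(post, 10)))   # time-averaged end population
  }
  for (sd in 1:3) {
    w_on <- run_wash(0.25, sd)
    expect_gt(w_on$peak, 5)                    # stress built a population
    expect_lt(w_on$end, 0.1 * w_on$peak)       # clearance removed it
    w_off <- run_wash(0, sd)
    expect_gte(w_off$end, 0.5 * w_off$peak)    # no clearance: persists
  }
})

test_that("null schedule phases are statistically identical", {
  m <- szmod(k_att0 = 1, J = 50, kappa = 1, n_max = 50)
  sched <- data.frame(duration = c(150, 150))
  tr <- washout_experiment(m, sched, seed = 11, pool0 = 100)
  s1 <- mean(tr[[1]]$snap_super[-(1:50)])  # discard burn-in
  s2 <- mean(tr[[2]]$snap_super)
  expect_lt(abs(s1 - s2), 3 * (stats::sd(tr[[2]]$snap_super) + 0.5))
})

test_that("rate-cap guard trips on unrepresentable energetics", {
  expect_error(build_rate_model(a = 1, b = -800, k_att0 = 1, n_max = 10),
               class = "nucfit_rate_cap_error")
})
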