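test_that("bleach correction inverts its forward model", {
  # constant traces under pure exponential bleaching: exact inversion
  spec <- data.frame(trace_id = paste0("t", 1:3), N0 = c(200, 800, 1500),
                     g = c(0, 0, 0))
  lambda <- 3.2e-3
  tr <- generate_intensity_traces(spec, bleach_rate = lambda, noise_cv = 0)
  bc <- bleach_correct(tr)
  expect_equal(bc$lambda, lambda, tolerance = 1e-9)
  for (id in spec$trace_id) {
    v <- bc$traces$intensity_corrected[bc$traces$trace_id == id]
    expect_equal(v / v[1], rep(1, length(v)), tolerance = 1e-9)
  }
  # flat input: fitted decay is numerically zero, output unchanged
  tr0 <- generate_intensity_traces(spec, bleach_rate = 0, noise_cv = 0)
  bc0 <- bleach_correct(tr0)
  expect_equal(bc0$lambda, 0, tolerance = 1e-12)
  expect_equal(bc0$traces$intensity_corrected, tr0$intensity_counts,
               tolerance = 1e-12)
  # rising mean (no decay to fit): warning and identity correction
  specg <- data.frame(trace_id = "g", N0 = 500, g = 0.5)
  trg <- generate_intensity_traces(specg, bleach_rate = 0, noise_cv = 0)
  expect_warning(bcg <- bleach_correct(trg), "does not decay")
  expect_equal(bcg$lambda, 0)
  expect_equal(bcg$traces$intensity_corrected, trg$intensity_counts)
  expect_error(bleach_correct(tr0[tr0$t_s < 60, ]),
               class = "nucfit_parameter_error")
})

test_that("per-trace growth slopes recover after bleach correction", {
  # balanced growth spec keeps the plane mean purely exponential, as in
  # the imaging-plane average the correction is fitted on
  for (sd in 1:20) {
    g <- 1200 * 0.4 / 360
    spec <- data.frame(trace_id = paste0("t", 1:4),
                       N0 = c(1200, 1200, 900, 900),
                       g = c(g, -g, g / 2, -g / 2))
    tr <- generate_intensity_traces(spec, bleach_rate = 2.5e-3,
                                    noise_cv = 0.01, seed = sd)
    bc <- bleach_correct(tr)
    sl <- growth_law_fit(bc$traces[bc$traces$trace_id == "t1", ])
    expect_lt(abs(sl$slope - g) / g, 0.05)
  }
})

test_that("intensity-to-count conversion", {
  expect_equal(intensity_to_count(2400), 100)
  expect_equal(intensity_to_count(24), 1)
  expect_equal(intensity_to_count(0), 0)
  expect_false(is.integer(intensity_to_count(30)))  # N stays real-valued
  expect_error(intensity_to_count(-5), class = "nucfit_parameter_error")
  expect_error(intensity_to_count(10, I_single = 0),
               class = "nucfit_parameter_error")
})

test_that("live-cell distribution fit recovers the generating law", {
  tab <- generate_livecell_intensities(noise_cv = 0, seed = 5)
  N <- intensity_to_count(tab$intensity_counts)
  res <- fit_livecell_distribution(N, bin_width = 10)
  expect_lt(abs(res$fit$a - live_cell_a), 3 * res$fit$sem_a)
  expect_lt(abs(res$fit$b - live_cell_b), 3 * res$fit$sem_b)
  expect_gt(res$params$n_c, 500)
  expect_lt(res$params$n_c, 2000)
  # bin width 20 vs 10: same curve within the stochastic floor at 2,800
  # clusters (a few percent on each parameter)
  res20 <- fit_livecell_distribution(N, bin_width = 20)
  expect_lt(abs(res20$fit$a - res$fit$a) / res$fit$a, 0.10)
  expect_lt(abs(res20$fit$b - res$fit$b) / res$fit$b, 0.10)
  expect_error(fit_livecell_distribution(N[1:100]),
               class = "nucfit_parameter_error")
})

test_that("noiseless binned model curve is recovered exactly (OLS path)", {
  N <- seq(5, 950, by = 10)
  cv <- model_curve(live_cell_a, live_cell_b, N, delta_n = 10, n_start = 0)
  f <- fit_free_energy(cv)
  expect_equal(f$a, live_cell_a, tolerance = 1e-10)
  expect_equal(f$b, live_cell_b, tolerance = 1e-10)
})

test_that("trace classification thresholds and scale invariance", {
  mk <- function(id, n0, n1) data.frame(trace_id = id,
                                        t_s = c(0, 180, 360),
                                        intensity_counts = c(n0,
                                                             (n0 + n1) / 2,
                                                             n1))
  traces <- rbind(mk("up", 1000, 1400), mk("flat", 1000, 1050),
                  mk("down", 1000, 850), mk("zero", 0, 10))
  lab <- classify_traces(traces)
  expect_identical(lab$label[match(c("up", "flat", "down", "zero"),
                                   lab$trace_id)],
                   c("growing", "stable", "shrinking", "unclassifiable"))
  # rescaling all intensities leaves labels unchanged
  tr2 <- traces
  tr2$intensity_counts <- tr2$intensity_counts * 17.3
  expect_identical(classify_traces(tr2)$label, lab$label)
})

test_that("growth-law fit: exact exponents and generator slopes", {
  t <- seq(0, 360, by = 15)
  lin <- data.frame(t_s = t, intensity_counts = 500 + 2 * t)
  gl <- growth_law_fit(lin)
  expect_equal(gl$slope, 2, tolerance = 1e-10)
  expect_equal(gl$exponent, 1, tolerance = 1e-10)
  # N ~ t means R = N^{1/3} ~ t^{1/3}
  cube <- data.frame(t_s = t[-1],
                     intensity_counts = (30 * t[-1])^(1 / 3))
  lf <- stats::lm(log(intensity_counts) ~ log(t_s), data = cube)
  expect_equal(unname(stats::coef(lf)[2]), 1 / 3, tolerance = 1e-10)
  # sign changes make the exponent undefined
  osc <- data.frame(t_s = t, intensity_counts = 500 + 20 * sin(t / 30))
  expect_true(is.na(growth_law_fit(osc)$exponent))
})

test_that("merger additivity checks pass and fail as designed", {
  mk <- function(id, t, v) data.frame(trace_id = id, t_s = t,
                                      intensity_counts = v)
  pre1 <- mk("a", c(0, 15, 30), c(480, 490, 500))
  pre2 <- mk("b", c(0, 15, 30), c(310, 305, 300))
  post_ok <- mk("m", c(45, 60), c(800, 805))
  post_bad <- mk("m", c(45, 60), c(600, 610))
  r1 <- check_merger_additivity(pre1, pre2, post_ok)
  expect_true(r1$pass)
  expect_equal(r1$residual, 0)
  r2 <- check_merger_additivity(pre1, pre2, post_bad)
  expect_false(r2$pass)
  expect_equal(r2$residual, 0.25)
  # misaligned time bases
  expect_error(check_merger_additivity(pre1, pre2, mk("m", c(0, 15), c(800, 800))),
               class = "nucfit_alignment_error")
})

test_that("scripted generator mergers pass additivity at >= 95%", {
  passes <- 0L
  total <- 0L
  for (sd in 1:10) {
    spec <- data.frame(trace_id = paste0("t", 1:20),
                       N0 = rep(c(500, 300), 10), g = 0)
    mg <- data.frame(pre1 = paste0("t", seq(1, 19, by = 2)),
                     pre2 = paste0("t", seq(2, 20, by = 2)),
                     t_merge = 180,
                     new_id = paste0("m", 1:10))
    tr <- generate_intensity_traces(spec, mergers = mg, noise_cv = 0.05,
                                    seed = sd)
    for (j in 1:10) {
      res <- check_merger_additivity(
        tr[tr$trace_id == mg$pre1[j], ],
        tr[tr$trace_id == mg$pre2[j], ],
        tr[tr$trace_id == mg$new_id[j], ])
      passes <- passes + res$pass
      total <- total + 1L
    }
  }
  expect_gte(passes / total, 0.95)
})

test_that("a 40% six-minute rise is classified as growing end to end", {
  g <- 1000 * 0.4 / 360
  spec <- data.frame(trace_id = c("w", "x"), N0 = c(1000, 1000),
                     g = c(g, -g))
  tr <- generate_intensity_traces(spec, bleach_rate = 2e-3, noise_cv = 0.01,
                                  seed = 2)
  bc <- bleach_correct(tr)
  lab <- classify_traces(bc$traces)
  expect_identical(lab$label[lab$trace_id == "w"], "growing")
  expect_identical(lab$label[lab$trace_id == "x"], "shrinking")
})

test_that("matched live and fixed synthetic systems give the same barrier", {
  # the same underlying energetics seen through two measurement scalings:
  # live counts with k = 1 and fixed sizes with rho = 3.3e-4 nm^-3
  # (a = a* rho^{2/3}, b = b* rho); the barrier is scale-invariant
  rho <- 3.3e-4
  a_fixed <- live_cell_a * rho^(2 / 3)
  b_fixed <- live_cell_b * rho
  B_true <- barrier_height(live_cell_a, live_cell_b)
  expect_equal(barrier_height(a_fixed, b_fixed), B_true, tolerance = 1e-12)

  live <- fit_livecell_distribution(
    intensity_to_count(generate_livecell_intensities(noise_cv = 0,
                                                     seed = 7)$intensity_counts))
  cfg_f <- generator_config(a = a_fixed, b = b_fixed, n_min = 1.5e4, seed = 8)
  fit_f <- self_consistent_fit(histogram_sizes(
    sample_cluster_sizes(cfg_f, n_draws = 5000)))
  B_live <- live$params$barrier
  B_fixed <- barrier_height(fit_f$a, fit_f$b)
  sem_live <- propagate_uncertainty(live$fit)$sem_barrier
  sem_fixed <- propagate_uncertainty(fit_f)$sem_barrier
  expect_lt(abs(B_live - B_fixed),
            3 * sqrt(sem_live^2 + sem_fixed^2))
})
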