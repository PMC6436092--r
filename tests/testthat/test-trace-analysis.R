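test_that("moving-window smoothing has the expected behavior", {
  expect_equal(smooth_trace(toy_trace(rep(2, 10)))$ratio, rep(2, 10))
  expect_equal(smooth_trace(toy_trace(c(0, 3, 0)))$ratio[2], 1)
  expect_error(smooth_trace(toy_trace(1:4), window = 5), "larger")
  # variance of a 3-point mean of white noise is ~1/3 the raw variance
  set.seed(2)
  tr <- toy_trace(rnorm(1000))
  expect_equal(var(smooth_trace(tr)$ratio) / var(tr$ratio), 1 / 3,
               tolerance = 0.15)
})

test_that("QC removes low expressers and jumpy traces, keeping ties", {
  flat <- function(id, level) {
    cell_trace(id, seq(0, 2, 0.2), rep(1, 11),
               nuc = rep(level, 11), cyto = rep(level, 11))
  }
  equal <- lapply(1:100, flat, level = 500)
  res <- qc_filter(equal)
  expect_equal(length(res$kept), 100)

  jumpy <- flat(1, 500); jumpy$ratio[5] <- jumpy$ratio[4] + 0.30
  mild <- flat(2, 500); mild$ratio[5] <- mild$ratio[4] + 0.20
  res2 <- qc_filter(c(list(jumpy, mild), lapply(3:30, flat, level = 500)),
                    expression_percentile = 0)
  expect_false(1 %in% vapply(res2$kept, function(t) t$cell_id, 1))
  expect_true(2 %in% vapply(res2$kept, function(t) t$cell_id, 1))
  expect_equal(res2$removed$reason, "noisy")

  # exactly the 5% zero-expression cells are removed
  cohort <- c(lapply(1:95, flat, level = 500), lapply(96:100, flat, level = 0))
  res3 <- qc_filter(cohort)
  expect_setequal(res3$removed$cell_id, 96:100)
  expect_true(all(res3$removed$reason == "low_expression"))
})

test_that("landmark callers recover the simulated ground truth", {
  expect_true(is.na(call_cdk2_rise(toy_trace(rep(0.3, 60)))))
  expect_true(is.na(call_apc_inactivation(
    toy_trace(rep(0.3, 60), degron = rep(0, 60)))))

  cell <- simulate_population(1, config = quiet_config(), seed = 1)[[1]]
  rise <- call_cdk2_rise(smooth_trace(cell$trace))
  apc <- call_apc_inactivation(cell$trace)
  expect_equal(rise, cell$true_cdk2_rise, tolerance = 0.4)
  expect_equal(apc, cell$true_apc_inactivation, tolerance = 0.4)

  # noisy cohort: median |call - truth| < 0.4 h, mean lag ~ degron_lag
  cells <- simulate_population(150, "cycling", seed = 1)
  calls <- vapply(cells, function(c) {
    c(call_cdk2_rise(smooth_trace(c$trace)), call_apc_inactivation(c$trace))
  }, numeric(2))
  err <- abs(calls[1, ] - vapply(cells, `[[`, 1, "true_cdk2_rise"))
  expect_lt(median(err, na.rm = TRUE), 0.4)
  lag <- calls[2, ] - calls[1, ]
  expect_equal(mean(lag, na.rm = TRUE), 3, tolerance = 0.3)
})

test_that("polynomial-residual metric is exact on cubics and calibrated", {
  t <- seq(0, 8, by = 0.2)
  cubic <- 0.2 + 0.1 * t + 0.01 * t^2 - 0.001 * t^3
  fp <- fluctuation_polyfit(cell_trace(1, t, cubic), 0, activity_gate = Inf)
  expect_lt(max(fp$sq_dev), 1e-20)

  # adding any cubic to a trace leaves the residuals unchanged
  set.seed(9)
  resid <- rnorm(length(t), 0, 0.03)
  f1 <- fluctuation_polyfit(cell_trace(1, t, cubic + resid), 0,
                            activity_gate = Inf)
  f2 <- fluctuation_polyfit(cell_trace(1, t, resid), 0, activity_gate = Inf)
  expect_equal(f1$sq_dev, f2$sq_dev, tolerance = 1e-10)

  # scaling deviations by c scales the squared deviations by c^2
  f3 <- fluctuation_polyfit(cell_trace(1, t, cubic + 2 * resid), 0,
                            activity_gate = Inf)
  expect_equal(f3$sq_dev, 4 * f1$sq_dev, tolerance = 1e-10)

  # a sinusoidal residual of amplitude a has mean squared deviation ~a^2/2
  a <- 0.05
  fs <- fluctuation_polyfit(
    cell_trace(1, t, cubic + a * sin(2 * pi * t / 1.5)), 0,
    activity_gate = Inf)
  expect_equal(mean(fs$sq_dev), a^2 / 2, tolerance = 0.15)

  # stressed traces score higher than dip-free traces after S entry
  stressed <- simulate_population(60, config = stress_model_config(), seed = 2)
  calm <- simulate_population(60, config = stress_model_config(n_events = 0),
                              seed = 2)
  prof <- function(cells) {
    population_profile(lapply(cells, function(c) {
      fluctuation_polyfit(smooth_trace(c$trace), c$true_cdk2_rise)
    }))
  }
  ps <- prof(stressed); pc <- prof(calm)
  shared <- intersect(ps$aligned_time, pc$aligned_time)
  win <- shared[shared >= 3.5 & shared <= 5.5]
  expect_true(all(ps$mean[match(win, ps$aligned_time)] >
                    pc$mean[match(win, pc$aligned_time)]))
})

test_that("second-derivative metric zeroes lines and matches quadratics", {
  t <- seq(0, 6, by = 0.2)
  lin <- fluctuation_second_derivative(cell_trace(1, t, 0.3 + 0.2 * t), 0)
  expect_lt(max(lin$score), 1e-18)
  c0 <- 0.4
  quad <- fluctuation_second_derivative(cell_trace(1, t, 0.5 * c0 * t^2), 0)
  expect_equal(unique(round(quad$score, 10)), c0^2)

  # rank agreement with the polyfit metric across a dip-amplitude grid
  grid <- c(0.02, 0.05, 0.1, 0.15, 0.2)
  scores <- vapply(grid, function(alpha) {
    cells <- simulate_population(
      25, config = stress_model_config(amplitude = alpha), seed = 11)
    poly <- mean(unlist(lapply(cells, function(c) {
      fluctuation_polyfit(smooth_trace(c$trace), 5,
                          activity_gate = Inf)$sq_dev
    })))
    sder <- mean(unlist(lapply(cells, function(c) {
      fluctuation_second_derivative(smooth_trace(c$trace), 5)$score
    })))
    c(poly, sder)
  }, numeric(2))
  expect_gt(cor(scores[1, ], scores[2, ], method = "kendall"), 0.8)
})

test_that("population profiles aggregate mean, SEM and n per timepoint", {
  s <- function(vals) data.frame(aligned_time = seq_along(vals) * 0.2,
                                 sq_dev = vals)
  same <- population_profile(list(s(c(1, 2)), s(c(1, 2)), s(c(1, 2))))
  expect_equal(same$sem, c(0, 0))
  two <- population_profile(list(s(0), s(2)))
  expect_equal(two$mean, 1)
  expect_equal(two$sem, 1)
  expect_equal(two$n, 2)
})

test_that("S-phase slope fits the crossing-bounded window", {
  t <- seq(0, 12, by = 0.2)
  line <- cell_trace(1, t, 0.8 + 0.08 * (t - 0))
  expect_equal(s_phase_slope(line, 0), 0.08, tolerance = 1e-10)
  plateau <- cell_trace(1, t, pmin(0.8 + 0.1 * t, 1.2))
  res <- s_phase_slope(plateau, 0)
  expect_true(is.na(res))
  expect_equal(attr(res, "reason"), "never crosses")

  # unstressed cells climb faster than stressed ones (same baseline slope);
  # a higher ramp offset keeps the 1.5 crossing well inside S phase
  stressed <- simulate_population(
    80, config = stress_model_config(ramp_offset = 0.8), seed = 3)
  calm <- simulate_population(
    80, config = stress_model_config(ramp_offset = 0.8, n_events = 0),
    seed = 3)
  sl <- function(cells) {
    v <- vapply(cells, function(c) {
      as.numeric(s_phase_slope(c$trace, c$true_apc_inactivation))
    }, numeric(1))
    v[!is.na(v)]
  }
  ht <- stats::wilcox.test(sl(calm), sl(stressed), alternative = "greater")
  expect_lt(ht$p.value, 0.01)
})

test_that("percent change and recovery metrics follow their definitions", {
  t <- seq(0, 6, by = 0.2)
  tr <- cell_trace(1, t, c(rep(1, 10), rep(0.8, 21)))
  expect_equal(percent_change(tr, drug_add = 2), -20)
  expect_equal(percent_change(cell_trace(1, t, rep(1, 31)), 2), 0)

  # piecewise-linear toy: pre-level 1.0, washout at 0.2 rising 0.1/frame
  ramp <- c(rep(1, 10), rep(0.15, 5), 0.2 + 0.1 * 0:15)
  trw <- cell_trace(1, seq(0, by = 0.2, length.out = length(ramp)), ramp)
  rec <- recovery_metrics(trw, drug_add = 2, washout = 3)
  expect_equal(rec$recovery_time, 36)
  # already above half-level at washout
  high <- cell_trace(1, t, c(rep(1, 10), rep(0.9, 21)))
  expect_equal(recovery_metrics(high, 2, 3)$recovery_time, 0)
})

test_that("autocorrelation profiles find the oscillation half-period", {
  t <- seq(0, 12, by = 0.2)
  sine <- cell_trace(1, t, sin(2 * pi * t / 2))
  seg <- data.frame(start = 0, end = 12)
  ap <- autocorrelation_profile(list(sine), seg, max_lag = 2)
  expect_equal(ap$anticorrelation_lag, 1)
  expect_lt(min(ap$acf), -0.8)

  # white noise stays within the large-sample null band
  set.seed(14)
  wn <- cell_trace(1, seq(0, by = 0.2, length.out = 400), rnorm(400))
  apn <- autocorrelation_profile(list(wn), data.frame(start = 0, end = 79.8),
                                 max_lag = 4)
  expect_true(all(abs(apn$acf[-1]) < 3 / sqrt(400)))
})
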