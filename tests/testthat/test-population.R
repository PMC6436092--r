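test_that("percentile ranks use the mean-rank convention", {
  expect_equal(percentile_rank(c(10, 20, 30, 40))[3], 62.5)
  x <- c(3, 1, 4, 1, 5, 9, 2, 6)
  expect_equal(percentile_rank(x), percentile_rank(log(x)))
  expect_equal(which.max(percentile_rank(x)), which.max(x))
  expect_true(all(percentile_rank(x) >= 0 & percentile_rank(x) <= 100))
})

test_that("delta-nucleotide records gate positives and difference ranks", {
  set.seed(6)
  pos <- data.frame(cell_id = 1:40,
                    edu = rlnorm(40, log(50), 0.3),
                    brdu = rlnorm(40, log(50), 0.3),
                    cdk2_at_edu = runif(40, 0.5, 1.5),
                    cdk2_at_brdu = runif(40, 0.5, 1.5))
  neg <- data.frame(cell_id = 41:60,
                    edu = rlnorm(20, log(0.5), 0.4),
                    brdu = rlnorm(20, log(0.5), 0.4),
                    cdk2_at_edu = 0.5, cdk2_at_brdu = 0.5)
  rec <- delta_nucleotide(rbind(pos, neg))
  expect_setequal(rec$cell_id, 1:40)
  expect_equal(rec$delta_rate, rec$brdu_rate - rec$edu_rate)
  expect_equal(rec$delta_cdk2, rec$cdk2_at_brdu - rec$cdk2_at_edu)
  expect_error(delta_nucleotide(pos[1, ]), "fewer than 2")

  # coupled simulation: rate changes track CDK2 changes
  cells <- lapply(simulate_population(300, config = stress_model_config(),
                                      seed = 1),
                  couple_synthesis_rate, coupling_gain = 1)
  set.seed(1)
  pc <- simulate_pulse_chase(cells)
  rec2 <- delta_nucleotide(pc)
  expect_gt(cor(rec2$delta_cdk2, rec2$delta_rate, method = "spearman"), 0.5)
})

test_that("delta-CDK2 binning reports 7 bins and a bin-level regression", {
  rec <- data.frame(delta_cdk2 = runif(300, -0.1, 0.2499),
                    delta_rate = 0)
  bs <- bin_by_delta_cdk2(rec, min_per_bin = 10)
  expect_equal(nrow(bs$bins), 7)
  expect_true(all(bs$bins$median == 0))
  expect_true(is.na(bs$regression_r2))
  # out-of-range records are excluded
  rec2 <- data.frame(delta_cdk2 = c(-0.5, 0.5), delta_rate = c(1, 1))
  expect_equal(sum(bin_by_delta_cdk2(rec2)$bins$n), 0)

  # strongly coupled, low-noise simulation: monotone medians, high r2
  cells <- lapply(simulate_population(400, config = stress_model_config(),
                                      seed = 2),
                  couple_synthesis_rate, coupling_gain = 1)
  set.seed(2)
  pc <- simulate_pulse_chase(cells, noise_cv = 0.1, stain_cv = 0.02)
  bs2 <- bin_by_delta_cdk2(delta_nucleotide(pc), min_per_bin = 10)
  med <- bs2$bins$median[!is.na(bs2$bins$median) & bs2$bins$n >= 10]
  expect_true(all(diff(med) > 0) || bs2$regression_r2 > 0.9)
  expect_gt(bs2$regression_r2, 0.9)
})

test_that("S-duration estimator reads the boxcar width, scale-free", {
  set.seed(13)
  t <- runif(4000, 0, 12)
  edu <- ifelse(t < 6, 100, 0) + rnorm(4000, 0, 1)
  d <- s_phase_duration(t, edu)
  expect_equal(d$duration, 6)
  d3 <- s_phase_duration(t, 3 * edu)
  expect_equal(d3$duration, 6)
  expect_equal(d3$curve$median_norm, d$curve$median_norm, tolerance = 1e-12)
  expect_error(s_phase_duration(t, rep(0, 4000)), "positive area")
})

test_that("timepoint-wise rank tests apply the Bonferroni cap", {
  set.seed(15)
  base <- matrix(rnorm(40 * 10), 40, 10)
  same <- compare_timeseries(base, base, aligned_time = 1:10)
  expect_true(all(same$p_adj == 1))

  # one clearly shifted timepoint: adjusted p = m * raw p
  shifted <- base
  shifted[, 4] <- shifted[, 4] + 3
  res <- compare_timeseries(base, shifted, aligned_time = 1:10)
  m <- sum(!is.na(res$p))
  expect_equal(res$p_adj, pmin(1, m * res$p))
  expect_lt(res$p_adj[4], 0.05)

  # QR vs cycling fluctuation profiles separate in early S phase
  prof_series <- function(regime, n) {
    cells <- simulate_population(n, regime, seed = 4)
    Filter(Negate(is.null), lapply(cells, function(c) {
      tr <- smooth_trace(c$trace)
      rise <- call_cdk2_rise(tr)
      if (is.na(rise)) return(NULL)
      fluctuation_polyfit(tr, rise)
    }))
  }
  ts <- compare_timeseries(prof_series("quiescence_release", 100),
                           prof_series("cycling", 100))
  early <- ts[ts$aligned_time >= 3.5 & ts$aligned_time <= 5.5, ]
  sig <- !is.na(early$p_adj) & early$p_adj < 0.05
  runs <- rle(sig)
  expect_gte(max(runs$lengths[runs$values]), 3)
})

test_that("group comparisons pick the conventional test branch", {
  set.seed(2)
  x <- rnorm(100)
  same <- compare_groups(list(a = x, b = x))
  expect_gt(same$p_value, 0.9)

  g <- compare_groups(list(a = rnorm(100, 0), b = rnorm(100, 1)))
  expect_equal(g$test, "t-test")
  expect_lt(g$p_value, 1e-6)

  skewed <- compare_groups(list(a = rexp(80), b = rexp(80, 0.5)))
  expect_equal(skewed$test, "Mann-Whitney U")

  const <- compare_groups(list(a = rep(1, 10), b = rnorm(10)))
  expect_equal(const$test, "Mann-Whitney U")  # zero variance -> rank branch

  three_n <- compare_groups(list(a = rnorm(60), b = rnorm(60, 1),
                                 c = rnorm(60, 2)))
  expect_equal(three_n$test, "one-way ANOVA + Tukey")
  expect_equal(nrow(three_n$pairwise), 3)

  three_r <- compare_groups(list(a = rexp(60), b = rexp(60, 0.5),
                                 c = rexp(60, 0.25)))
  expect_equal(three_r$test, "Kruskal-Wallis + Dunn")
  expect_true(all(c("z", "p_adj") %in% names(three_r$pairwise)))
})

test_that("experiment scenarios run end to end and are reproducible", {
  dir1 <- withr::local_tempdir()
  dir2 <- withr::local_tempdir()
  cfg <- list(scenario = "washout", out_dir = dir1, n_cells = 40, seed = 9,
              suppression_fractions = c(0.2, 0.4))
  s1 <- run_experiment(cfg)
  cfg$out_dir <- dir2
  s2 <- run_experiment(cfg)
  expect_equal(s1$washout, s2$washout)
  expect_true(all(diff(s1$washout$median_percent_change) < 0))
  expect_true(file.exists(file.path(dir1, "manifest.json")))
  expect_error(run_experiment(list(scenario = "bogus", out_dir = dir1)),
               "unknown scenario")

  dir3 <- withr::local_tempdir()
  s3 <- run_experiment(list(scenario = "simulate_only", out_dir = dir3,
                            n_cells = 5, seed = 2))
  expect_true(file.exists(file.path(dir3, "traces.csv")))
  expect_true(file.exists(file.path(dir3, "truth.json")))

  dir4 <- withr::local_tempdir()
  s4 <- run_experiment(list(scenario = "nucleotide", out_dir = dir4,
                            n_cells = 150, seed = 3))
  expect_gt(s4$spearman, 0.3)
  expect_true(file.exists(file.path(dir4, "delta_cdk2_bins.csv")))
})
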