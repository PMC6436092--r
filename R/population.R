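#' Mean-rank percentile of each value within a population
#'
#' `100 * (rank - 0.5) / n` with ties averaged; invariant under any
#' strictly monotone transform of the values.
#'
#' @param x Numeric vector.
#' @return Percentiles in (0, 100).
#' @export
percentile_rank <- function(x) {
  100 * (rank(x, ties.method = "average") - 0.5) / length(x)
}

# 1-D two-class Otsu threshold on log intensities (for stain positivity)
otsu_1d <- function(x, n_bins = 256) {
  x <- x[is.finite(x)]
  h <- graphics::hist(x, breaks = n_bins, plot = FALSE)
  counts <- h$counts
  mids <- h$mids
  w <- counts / sum(counts)
  mu <- cumsum(w * mids)
  omega <- cumsum(w)
  mu_t <- mu[length(mu)]
  sigma_b <- (mu_t * omega - mu)^2 / (omega * (1 - omega))
  sigma_b[!is.finite(sigma_b)] <- 0
  mids[which.max(sigma_b)]
}

#' Per-cell change in nucleotide incorporation rate vs change in CDK2
#'
#' Gates S-phase cells (positive for both stains; default positivity is a
#' two-class Otsu threshold on log intensities, or an absolute threshold
#' when given), converts each stain intensity to its mean-rank percentile
#' within the positive population, and computes per-cell deltas:
#' `delta_rate = brdu_rate - edu_rate` and
#' `delta_cdk2 = cdk2_at_brdu - cdk2_at_edu`.
#'
#' @param cells Data frame with columns `cell_id`, `edu`, `brdu`,
#'   `cdk2_at_edu`, `cdk2_at_brdu`.
#' @param positivity_threshold Optional named list or single number giving
#'   absolute positivity thresholds for `edu` and `brdu`; `NULL` (default)
#'   uses Otsu on log intensities.
#' @return Data frame of nucleotide records for the gated cells, with
#'   `edu_rate`, `brdu_rate`, `delta_rate`, `delta_cdk2`.
#' @export
delta_nucleotide <- function(cells, positivity_threshold = NULL) {
  need <- c("cell_id", "edu", "brdu", "cdk2_at_edu", "cdk2_at_brdu")
  stopifnot(all(need %in% names(cells)))
  thr <- function(v) {
    if (!is.null(positivity_threshold)) {
      if (is.list(positivity_threshold)) positivity_threshold else
        list(edu = positivity_threshold, brdu = positivity_threshold)
    } else NULL
  }
  gate <- function(v, nm) {
    t <- if (is.null(positivity_threshold)) {
      exp(otsu_1d(log(pmax(v, .Machine$double.eps))))
    } else if (is.list(positivity_threshold)) {
      positivity_threshold[[nm]]
    } else positivity_threshold
    v > t
  }
  pos <- gate(cells$edu, "edu") & gate(cells$brdu, "brdu")
  rec <- cells[pos, , drop = FALSE]
  if (nrow(rec) < 2) stop("fewer than 2 double-positive cells; cannot rank")
  rec$edu_rate <- percentile_rank(rec$edu)
  rec$brdu_rate <- percentile_rank(rec$brdu)
  rec$delta_rate <- rec$brdu_rate - rec$edu_rate
  rec$delta_cdk2 <- rec$cdk2_at_brdu - rec$cdk2_at_edu
  rec
}

#' Bin nucleotide records by the change in CDK2 activity
#'
#' Half-open bins `[left, right)` over the stated edge range (default
#' -0.10 to 0.25 in steps of 0.05, i.e. 7 bins); values outside the range
#' are excluded. Per bin: median `delta_rate`, SEM, and n; bins below
#' `min_per_bin` are flagged. An unweighted least-squares line through
#' (bin center, bin median) gives the regression r-squared (`NA` when the
#' medians are degenerate).
#'
#' @param records Data frame from [delta_nucleotide()].
#' @param edges Bin edges (activity units).
#' @param min_per_bin Minimum cells per reported bin (default 70).
#' @return A list with `bins` (data frame: `left`, `right`, `center`,
#'   `median`, `sem`, `n`, `flagged`) and `regression_r2`.
#' @export
bin_by_delta_cdk2 <- function(records, edges = seq(-0.10, 0.25, by = 0.05),
                              min_per_bin = 70) {
  stopifnot(nrow(records) > 0, length(edges) >= 2)
  k <- findInterval(records$delta_cdk2, edges, rightmost.closed = FALSE)
  inside <- k >= 1 & k <= length(edges) - 1 &
    records$delta_cdk2 < edges[length(edges)]
  k <- k[inside]
  v <- records$delta_rate[inside]
  bins <- data.frame(
    left = edges[-length(edges)], right = edges[-1],
    center = (edges[-length(edges)] + edges[-1]) / 2
  )
  bins$median <- NA_real_; bins$sem <- NA_real_; bins$n <- 0L
  for (b in seq_len(nrow(bins))) {
    vb <- v[k == b]
    bins$n[b] <- length(vb)
    if (length(vb) > 0) {
      bins$median[b] <- stats::median(vb)
      bins$sem[b] <- if (length(vb) > 1) stats::sd(vb) / sqrt(length(vb)) else NA
    }
  }
  bins$flagged <- bins$n < min_per_bin
  ok <- !is.na(bins$median)
  r2 <- NA_real_
  if (sum(ok) >= 3 && stats::sd(bins$median[ok]) > 0) {
    fit <- stats::lm(median ~ center, data = bins[ok, ])
    r2 <- summary(fit)$r.squared
  }
  list(bins = bins, regression_r2 = r2)
}

#' S-phase duration from EdU intensity binned by time since S entry
#'
#' Cells are binned by their time since APC/C-Cdh1 inactivation; the
#' median EdU intensity per bin is computed and the curve rescaled to unit
#' area (so the estimate is invariant to global intensity scaling). The
#' duration is the total span of the contiguous run of bins - the run
#' containing the curve maximum - whose normalized median exceeds
#' `threshold_fraction` times the curve maximum.
#'
#' @param time_since_apc Hours since APC/C inactivation, one per cell.
#' @param edu EdU intensity per cell.
#' @param bin_width Bin width (h), default 1.
#' @param threshold_fraction Fraction of the curve maximum defining
#'   "during S" bins (default 0.25).
#' @param min_per_bin Minimum cells per reported bin (default 50).
#' @return A list with `duration` (h) and `curve` (data frame: `bin_start`,
#'   `median`, `median_norm`, `n`).
#' @export
s_phase_duration <- function(time_since_apc, edu, bin_width = 1,
                             threshold_fraction = 0.25, min_per_bin = 50) {
  stopifnot(length(time_since_apc) == length(edu))
  b <- floor(time_since_apc / bin_width)
  sp <- split(edu, b)
  curve <- data.frame(
    bin_start = as.numeric(names(sp)) * bin_width,
    median = vapply(sp, stats::median, numeric(1)),
    n = vapply(sp, length, numeric(1))
  )
  curve <- curve[curve$n >= min_per_bin, ]
  curve <- curve[order(curve$bin_start), ]
  auc <- sum(curve$median * bin_width)
  if (!is.finite(auc) || auc <= 0) stop("EdU curve has no positive area")
  curve$median_norm <- curve$median / auc
  peak <- which.max(curve$median_norm)
  above <- curve$median_norm > threshold_fraction * curve$median_norm[peak]
  # contiguous run containing the maximum
  lo <- peak
  while (lo > 1 && above[lo - 1]) lo <- lo - 1
  hi <- peak
  while (hi < nrow(curve) && above[hi + 1]) hi <- hi + 1
  list(duration = (hi - lo + 1) * bin_width, curve = curve)
}

#' Timepoint-wise rank-sum comparison of two aligned groups
#'
#' Two-sided Mann-Whitney U test per shared aligned time point,
#' Bonferroni-corrected by the number of tested time points (time points
#' with fewer than two cells in either group are skipped and excluded
#' from the correction factor).
#'
#' @param group_a,group_b Matrices (cells x timepoints) with identical
#'   column meaning, or lists of per-cell data frames with `aligned_time`
#'   and a value column (converted internally).
#' @param aligned_time Column times; required when matrices are given.
#' @return Data frame with `aligned_time`, `p`, `p_adj`, `n_a`, `n_b`.
#' @export
compare_timeseries <- function(group_a, group_b, aligned_time = NULL) {
  to_mat <- function(g) {
    if (is.matrix(g)) return(g)
    times <- sort(unique(unlist(lapply(g, function(d) round(d$aligned_time, 6)))))
    m <- matrix(NA_real_, length(g), length(times))
    for (i in seq_along(g)) {
      j <- match(round(g[[i]]$aligned_time, 6), times)
      m[i, j] <- g[[i]][[2]]
    }
    attr(m, "times") <- times
    m
  }
  ma <- to_mat(group_a); mb <- to_mat(group_b)
  if (is.null(aligned_time)) {
    ta <- attr(ma, "times"); tb <- attr(mb, "times")
    shared <- intersect(ta, tb)
    ma <- ma[, match(shared, ta), drop = FALSE]
    mb <- mb[, match(shared, tb), drop = FALSE]
    aligned_time <- shared
  }
  p <- rep(NA_real_, length(aligned_time))
  n_a <- n_b <- integer(length(aligned_time))
  for (j in seq_along(aligned_time)) {
    va <- ma[, j]; va <- va[!is.na(va)]
    vb <- mb[, j]; vb <- vb[!is.na(vb)]
    n_a[j] <- length(va); n_b[j] <- length(vb)
    if (length(va) >= 2 && length(vb) >= 2) {
      p[j] <- stats::wilcox.test(va, vb, exact = FALSE)$p.value
    }
  }
  m <- sum(!is.na(p))
  data.frame(aligned_time = aligned_time, p = p,
             p_adj = pmin(1, m * p), n_a = n_a, n_b = n_b)
}

# Dunn's pairwise rank comparisons after a Kruskal-Wallis test
dunn_test <- function(values, groups) {
  groups <- factor(groups)
  N <- length(values)
  r <- rank(values)
  rbar <- tapply(r, groups, mean)
  n <- tapply(r, groups, length)
  ties <- table(values)
  tie_corr <- sum(ties^3 - ties) / (12 * (N - 1))
  lv <- levels(groups)
  pairs <- utils::combn(lv, 2)
  res <- data.frame(group1 = pairs[1, ], group2 = pairs[2, ])
  res$z <- NA_real_
  for (k in seq_len(ncol(pairs))) {
    i <- pairs[1, k]; j <- pairs[2, k]
    se <- sqrt((N * (N + 1) / 12 - tie_corr) * (1 / n[[i]] + 1 / n[[j]]))
    res$z[k] <- (rbar[[i]] - rbar[[j]]) / se
  }
  res$p <- 2 * stats::pnorm(-abs(res$z))
  res$p_adj <- pmin(1, res$p * ncol(pairs))
  res
}

#' Compare two or more groups with the conventional test hierarchy
#'
#' Normality is assessed per group by a Shapiro-Wilk test at
#' `alpha_normality`; if all groups pass (and have positive variance) a
#' parametric branch is used (Welch t-test for two groups, one-way ANOVA
#' with Tukey's HSD for more), otherwise a rank branch (Mann-Whitney U for
#' two groups, Kruskal-Wallis with Dunn's pairwise comparisons for more).
#' A zero-variance group forces the rank branch.
#'
#' @param samples Named list of numeric vectors (>= 2 values each).
#' @param alpha_normality Significance level of the normality check.
#' @return A list with `test` (name), `statistic`, `p_value`, `normal`
#'   (logical), and `pairwise` (data frame of adjusted pairwise
#'   comparisons, or `NULL` for two groups).
#' @export
compare_groups <- function(samples, alpha_normality = 0.05) {
  stopifnot(length(samples) >= 2, all(vapply(samples, length, 1L) >= 2))
  if (is.null(names(samples))) {
    names(samples) <- paste0("group", seq_along(samples))
  }
  normal <- all(vapply(samples, function(v) {
    if (stats::sd(v) == 0) return(FALSE)
    n <- length(v)
    if (n < 3) return(FALSE)
    if (n > 5000) v <- sample(v, 5000)
    stats::shapiro.test(v)$p.value > alpha_normality
  }, logical(1)))
  values <- unlist(samples, use.names = FALSE)
  groups <- rep(names(samples), vapply(samples, length, 1L))
  if (length(samples) == 2) {
    if (normal) {
      ht <- stats::t.test(samples[[1]], samples[[2]])
      list(test = "t-test", statistic = unname(ht$statistic),
           p_value = ht$p.value, normal = normal, pairwise = NULL)
    } else {
      ht <- stats::wilcox.test(samples[[1]], samples[[2]], exact = FALSE)
      list(test = "Mann-Whitney U", statistic = unname(ht$statistic),
           p_value = ht$p.value, normal = normal, pairwise = NULL)
    }
  } else {
    if (normal) {
      fit <- stats::aov(values ~ factor(groups))
      an <- summary(fit)[[1]]
      tk <- stats::TukeyHSD(fit)[[1]]
      pw <- data.frame(comparison = rownames(tk), diff = tk[, "diff"],
                       p_adj = tk[, "p adj"], row.names = NULL)
      list(test = "one-way ANOVA + Tukey", statistic = an$`F value`[1],
           p_value = an$`Pr(>F)`[1], normal = normal, pairwise = pw)
    } else {
      kw <- stats::kruskal.test(values, factor(groups))
      list(test = "Kruskal-Wallis + Dunn", statistic = unname(kw$statistic),
           p_value = kw$p.value, normal = normal,
           pairwise = dunn_test(values, groups))
    }
  }
}
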