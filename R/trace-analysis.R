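#' Smooth a trace with a centered moving mean
#'
#' The activity ratio is smoothed with a centered moving window (default
#' three time points); endpoints use the truncated window.
#'
#' @param trace A [cell_trace()].
#' @param window Odd window length in frames.
#' @return The trace with a smoothed `ratio`.
#' @export
smooth_trace <- function(trace, window = 3) {
  stopifnot(window >= 1, window %% 2 == 1)
  n <- length(trace$ratio)
  if (window > n) stop("window larger than trace")
  half <- (window - 1) / 2
  sm <- vapply(seq_len(n), function(i) {
    mean(trace$ratio[max(1, i - half):min(n, i + half)])
  }, numeric(1))
  trace$ratio <- sm
  trace
}

#' Quality-control filter for a trace cohort
#'
#' Removes (a) cells in the bottom `expression_percentile` of mean total
#' reporter intensity (nuclear + cytoplasmic, averaged over frames); ties
#' at the percentile boundary are kept; and (b) traces with any
#' frame-to-frame ratio change larger than `jump_threshold`.
#'
#' @param traces List of [cell_trace()] objects.
#' @param expression_percentile Percent of lowest-expressing cells to drop
#'   (default 5).
#' @param jump_threshold Maximum allowed `|delta ratio|` between
#'   consecutive frames (default 0.25).
#' @return A list with elements `kept` (traces) and `removed` (data frame
#'   of `cell_id`, `reason`).
#' @export
qc_filter <- function(traces, expression_percentile = 5,
                      jump_threshold = 0.25) {
  stopifnot(length(traces) >= 1)
  expr <- vapply(traces, function(tr) {
    if (is.null(tr$nuc) || is.null(tr$cyto)) return(Inf)
    mean(tr$nuc + tr$cyto)
  }, numeric(1))
  cutoff <- stats::quantile(expr, expression_percentile / 100, type = 7)
  low <- expr < cutoff            # strict: boundary ties are kept
  noisy <- vapply(traces, function(tr) {
    any(abs(diff(tr$ratio)) > jump_threshold)
  }, logical(1))
  removed <- data.frame(
    cell_id = vapply(traces, function(tr) tr$cell_id, numeric(1)),
    reason = ifelse(low, "low_expression", ifelse(noisy, "noisy", NA))
  )
  keep <- !(low | noisy)
  list(kept = traces[keep], removed = removed[!keep, , drop = FALSE])
}

#' Call the time of initial CDK2 activity rise
#'
#' The baseline is the 10th percentile of the ratio over the first
#' `baseline_window` hours. A candidate crossing is the first time the
#' (smoothed) ratio exceeds baseline + `rise_delta` and stays above it for
#' at least `hold_frames` consecutive frames; the reported onset is that
#' crossing back-extrapolated to the baseline using the local slope (a
#' least-squares line over the hour after the crossing), so the detection
#' delta does not bias the call.
#'
#' @param trace A smoothed [cell_trace()].
#' @param rise_delta Activity increase over baseline required (default 0.1).
#' @param baseline_window Hours of trace used for the baseline (default 5).
#' @param hold_frames Consecutive frames required above threshold.
#' @return Rise time (h), or `NA` if the trace never rises.
#' @export
call_cdk2_rise <- function(trace, rise_delta = 0.1, baseline_window = 5,
                           hold_frames = 3) {
  r <- trace$ratio
  base <- stats::quantile(r[trace$time <= baseline_window], 0.1, names = FALSE)
  above <- r > base + rise_delta
  idx <- sustained_run_start(above, hold_frames)
  if (is.na(idx)) return(NA_real_)
  onset_backextrapolate(trace$time, r, idx, level = base + rise_delta,
                        delta = rise_delta)
}

# refine a threshold-crossing index: linearly interpolate the crossing
# time, estimate the local slope over the following hour, and extrapolate
# back by delta / slope to the signal onset
onset_backextrapolate <- function(time, x, idx, level, delta) {
  t_cross <- time[idx]
  if (idx > 1 && x[idx] > x[idx - 1]) {
    t_cross <- time[idx - 1] +
      (level - x[idx - 1]) / (x[idx] - x[idx - 1]) * (time[idx] - time[idx - 1])
  }
  win <- which(time >= t_cross & time <= t_cross + 1)
  onset <- t_cross
  if (length(win) >= 3) {
    slope <- stats::coef(stats::lm(x[win] ~ time[win]))[[2]]
    if (is.finite(slope) && slope > 1e-6) {
      onset <- t_cross - delta / slope
    }
  }
  max(onset, time[1])
}

# first index starting a run of >= k TRUEs, NA if none
sustained_run_start <- function(x, k) {
  x[is.na(x)] <- FALSE
  r <- rle(x)
  ends <- cumsum(r$lengths)
  hit <- which(r$values & r$lengths >= k)
  if (length(hit) == 0) return(NA_integer_)
  ends[hit[1]] - r$lengths[hit[1]] + 1L
}

#' Call the time of APC/C-Cdh1 inactivation from the degron trace
#'
#' The candidate is the first time the degron signal exceeds
#' `rise_fraction` of its trace maximum while increasing for at least
#' `hold_frames` subsequent frames (assessed on a 3-point smoothed degron
#' signal); the reported onset back-extrapolates the crossing to zero
#' signal using the local accumulation slope, so the detection fraction
#' does not bias the call.
#'
#' @param trace A [cell_trace()] with a degron series.
#' @param rise_fraction Fraction of the degron maximum (default 0.05).
#' @param hold_frames Number of subsequent increasing frames required.
#' @return Inactivation time (h), or `NA` if the degron never accumulates.
#' @export
call_apc_inactivation <- function(trace, rise_fraction = 0.05,
                                  hold_frames = 3) {
  if (is.null(trace$degron)) return(NA_real_)
  d <- trace$degron
  n <- length(d)
  if (n < hold_frames + 1) return(NA_real_)
  dmax <- max(d)
  if (dmax <= 0) return(NA_real_)
  # smooth the degron lightly so single-frame noise does not break the
  # monotonicity requirement
  half <- 1
  ds <- vapply(seq_len(n), function(i) {
    mean(d[max(1, i - half):min(n, i + half)])
  }, numeric(1))
  inc <- c(diff(ds) > 0, FALSE)
  cand <- ds > rise_fraction * dmax
  ok <- vapply(seq_len(n - hold_frames), function(i) {
    cand[i] && all(inc[i:(i + hold_frames - 1)])
  }, logical(1))
  idx <- which(ok)
  if (length(idx) == 0) return(NA_real_)
  level <- rise_fraction * dmax
  onset_backextrapolate(trace$time, ds, idx[1], level = level, delta = level)
}

#' Polynomial-residual fluctuation metric
#'
#' Fits a least-squares polynomial of the stated degree to the trace
#' segment starting at `align_at`. The fit domain ends at the trace end or
#' at the first frame where the fitted value exceeds `activity_gate`,
#' whichever comes first (one truncation-and-refit pass). Returns the
#' squared difference between trace and fit per time point, on a time axis
#' relative to the first frame at or after `align_at` (so aligned times of
#' different cells fall on a shared grid even when the alignment event is
#' called between frames).
#'
#' @param trace A (smoothed) [cell_trace()].
#' @param align_at Alignment time (h), typically the called CDK2 rise.
#' @param degree Polynomial degree (default 3).
#' @param activity_gate Upper activity gate (default 1.3); use `Inf` to
#'   disable gating.
#' @return A data frame with `aligned_time` (h) and `sq_dev`, or `NULL`
#'   if the segment is shorter than `degree + 2` frames.
#' @export
fluctuation_polyfit <- function(trace, align_at, degree = 3,
                                activity_gate = 1.3) {
  sel <- trace$time >= align_at
  t <- trace$time[sel]
  r <- trace$ratio[sel]
  if (length(t) < degree + 2) return(NULL)
  align_frame <- t[1]
  fit_once <- function(t, r) {
    tc <- t - t[1]
    fit <- stats::lm(r ~ stats::poly(tc, degree, raw = TRUE))
    stats::fitted(fit)
  }
  fv <- fit_once(t, r)
  over <- which(fv > activity_gate)
  if (length(over) > 0 && over[1] > degree + 2) {
    t <- t[seq_len(over[1] - 1)]
    r <- r[seq_len(over[1] - 1)]
    fv <- fit_once(t, r)
  }
  data.frame(aligned_time = t - align_frame, sq_dev = (r - fv)^2)
}

#' Second-derivative fluctuation metric
#'
#' The squared central second difference of the ratio, divided by
#' `frame_interval^4`, i.e. the squared finite-difference estimate of the
#' second time derivative (units: activity^2 per h^4). Linear trends score
#' zero; a pure quadratic `c/2 * t^2` scores the constant `c^2`.
#'
#' @param trace A (smoothed) [cell_trace()].
#' @param align_at Alignment time (h); the time axis is relative to the
#'   first frame at or after it.
#' @return A data frame with `aligned_time` and `score` (one row per
#'   interior frame of the segment).
#' @export
fluctuation_second_derivative <- function(trace, align_at) {
  sel <- trace$time >= align_at
  t <- trace$time[sel]
  r <- trace$ratio[sel]
  if (length(t) < 3) stop("need at least 3 frames after align_at")
  dt <- trace$frame_interval
  d2 <- (r[1:(length(r) - 2)] - 2 * r[2:(length(r) - 1)] + r[3:length(r)]) / dt^2
  data.frame(aligned_time = t[2:(length(t) - 1)] - t[1], score = d2^2)
}

#' Population summary of aligned per-cell series
#'
#' Averages per-cell series (e.g. squared deviations from
#' [fluctuation_polyfit()]) on a shared aligned time axis: per time point
#' the mean, the standard error of the mean, and the number of cells.
#' Time points with fewer than `min_cells` contributing cells are dropped.
#'
#' @param series List of data frames with columns `aligned_time` and a
#'   value column (the second column is used).
#' @param min_cells Minimum cells per reported time point (default 2).
#' @return A data frame with `aligned_time`, `mean`, `sem`, `n`.
#' @export
population_profile <- function(series, min_cells = 2) {
  series <- Filter(Negate(is.null), series)
  stopifnot(length(series) >= 1)
  all <- do.call(rbind, lapply(series, function(d) {
    data.frame(aligned_time = round(d$aligned_time, 6), value = d[[2]])
  }))
  sp <- split(all$value, all$aligned_time)
  out <- data.frame(
    aligned_time = as.numeric(names(sp)),
    mean = vapply(sp, mean, numeric(1)),
    sem = vapply(sp, function(v) {
      if (length(v) > 1) stats::sd(v) / sqrt(length(v)) else NA_real_
    }, numeric(1)),
    n = vapply(sp, length, numeric(1))
  )
  out <- out[out$n >= min_cells, ]
  rownames(out) <- NULL
  out[order(out$aligned_time), ]
}

#' Rate of CDK2 activity increase during S phase
#'
#' Least-squares slope of the ratio from S-phase entry to the first frame
#' at which the ratio reaches `crossing`. Cells whose trace never crosses
#' are excluded.
#'
#' @param trace A [cell_trace()].
#' @param s_entry S-phase entry time (h), e.g. the called APC/C
#'   inactivation.
#' @param crossing Activity threshold ending the fit window (default 1.5).
#' @return Slope (activity units per h), or `NA` with attribute `reason`
#'   if excluded.
#' @export
s_phase_slope <- function(trace, s_entry, crossing = 1.5) {
  sel <- which(trace$time >= s_entry)
  if (length(sel) == 0) return(structure(NA_real_, reason = "no frames"))
  cross <- sel[which(trace$ratio[sel] >= crossing)[1]]
  if (is.na(cross)) return(structure(NA_real_, reason = "never crosses"))
  idx <- sel[1]:cross
  if (length(idx) < 3) stop("fewer than 3 frames in the fit window")
  stats::coef(stats::lm(trace$ratio[idx] ~ trace$time[idx]))[[2]]
}

# index of the frame closest to a given time
nearest_frame <- function(trace, t) which.min(abs(trace$time - t))

#' Percent change in CDK2 activity after drug addition
#'
#' `100 * (ratio(drug_add + horizon) - ratio(frame before drug_add)) /
#' ratio(frame before drug_add)`.
#'
#' @param trace A [cell_trace()].
#' @param drug_add Drug addition time (h).
#' @param horizon Hours after addition at which the change is read
#'   (default 1).
#' @return Percent change.
#' @export
percent_change <- function(trace, drug_add, horizon = 1) {
  pre_idx <- max(which(trace$time < drug_add))
  post_idx <- nearest_frame(trace, drug_add + horizon)
  if (length(pre_idx) == 0 || post_idx > length(trace$time)) {
    stop("reference frames outside the trace")
  }
  ref <- trace$ratio[pre_idx]
  if (ref <= 0) stop("reference ratio is not positive")
  100 * (trace$ratio[post_idx] - ref) / ref
}

#' Recovery metrics after drug washout
#'
#' `recovery_time` is the linearly interpolated first time after washout
#' at which the ratio reaches half of its value in the frame immediately
#' preceding drug addition. `halflife` is estimated from the post-washout
#' deficit: the pre-pulse trend (a least-squares line over the
#' `pre_window` hours before drug addition) is extrapolated forward, the
#' deficit `trend - ratio` is computed per frame, and an exponential decay
#' is fitted by least squares on the log deficit over the frames from
#' washout until the deficit first drops below `deficit_floor` times its
#' initial value (or turns non-positive).
#'
#' @param trace A [cell_trace()].
#' @param drug_add,washout Drug addition and washout times (h).
#' @param pre_window Hours of pre-pulse trace used for the reference trend
#'   (default 1).
#' @param deficit_floor Fraction of the initial deficit below which frames
#'   are dropped from the half-life fit (default 0.15).
#' @return A list with `recovery_time` (min) and `halflife` (min); either
#'   may be `NA` if recovery is incomplete or the fit is not possible.
#' @export
recovery_metrics <- function(trace, drug_add, washout, pre_window = 1,
                             deficit_floor = 0.15) {
  stopifnot(washout > drug_add, washout < max(trace$time))
  pre_idx <- max(which(trace$time < drug_add))
  pre_level <- trace$ratio[pre_idx]
  half_level <- 0.5 * pre_level

  post <- which(trace$time >= washout)
  r_post <- trace$ratio[post]
  t_post <- trace$time[post]

  recovery_time <- NA_real_
  if (r_post[1] >= half_level) {
    recovery_time <- 0
  } else {
    k <- which(r_post >= half_level)[1]
    if (!is.na(k)) {
      t0 <- t_post[k - 1]; t1 <- t_post[k]
      r0 <- r_post[k - 1]; r1 <- r_post[k]
      t_cross <- t0 + (half_level - r0) / (r1 - r0) * (t1 - t0)
      recovery_time <- (t_cross - washout) * 60
    }
  }

  # half-life of the deficit relative to the extrapolated pre-pulse trend
  halflife <- NA_real_
  win <- which(trace$time < drug_add & trace$time >= drug_add - pre_window)
  if (length(win) >= 3) {
    fit <- stats::lm(trace$ratio[win] ~ trace$time[win])
    trend <- stats::coef(fit)[[1]] + stats::coef(fit)[[2]] * t_post
    deficit <- trend - r_post
    if (deficit[1] > 0) {
      keep <- deficit > deficit_floor * deficit[1]
      stop_at <- which(!keep)[1]
      idx <- if (is.na(stop_at)) seq_along(deficit) else seq_len(stop_at - 1)
      if (length(idx) >= 4) {
        lfit <- stats::lm(log(deficit[idx]) ~ t_post[idx])
        k <- stats::coef(lfit)[[2]]
        if (k < 0) halflife <- -log(2) / k * 60
      }
    }
  }
  list(recovery_time = recovery_time, halflife = halflife)
}

#' Mean autocorrelation of detrended S-phase segments
#'
#' Each cell's S-phase segment is detrended by subtracting a cubic
#' least-squares fit, its autocorrelation (normalized to 1 at lag 0) is
#' computed, and the per-lag values are averaged across cells. The
#' anticorrelation lag is the lag of the profile minimum in
#' `(0, max_lag]`. Cells whose segment is shorter than `max_lag + 1` hours
#' are skipped (autocorrelation estimates at lags close to the segment
#' length are noisy for a single cell but average out across the
#' population).
#'
#' @param traces List of [cell_trace()] objects.
#' @param segments Data frame with one row per trace giving `start` and
#'   `end` times (h) of the S-phase segment.
#' @param max_lag Maximum lag (h).
#' @return A list with `lag` (h), `acf` (mean profile), `n_cells`, and
#'   `anticorrelation_lag` (h).
#' @export
autocorrelation_profile <- function(traces, segments, max_lag = 4) {
  stopifnot(length(traces) == nrow(segments))
  dt <- traces[[1]]$frame_interval
  lag_max <- round(max_lag / dt)
  acfs <- list()
  for (i in seq_along(traces)) {
    tr <- traces[[i]]
    sel <- tr$time >= segments$start[i] & tr$time <= segments$end[i]
    t <- tr$time[sel]; r <- tr$ratio[sel]
    if ((max(t) - min(t)) < max_lag + 1) next
    tc <- t - t[1]
    res <- stats::resid(stats::lm(r ~ stats::poly(tc, 3, raw = TRUE)))
    a <- stats::acf(res, lag.max = lag_max, plot = FALSE,
                    demean = TRUE)$acf[, 1, 1]
    if (length(a) == lag_max + 1) acfs[[length(acfs) + 1]] <- a
  }
  if (length(acfs) == 0) stop("no segment long enough for the requested lag")
  prof <- colMeans(do.call(rbind, acfs))
  lags <- (0:lag_max) * dt
  min_idx <- which.min(prof[-1]) + 1
  list(lag = lags, acf = prof, n_cells = length(acfs),
       anticorrelation_lag = lags[min_idx])
}
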