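#' Construct a per-cell trace object
#'
#' @param cell_id Cell identifier.
#' @param time Frame times (h), strictly increasing with constant spacing.
#' @param ratio Cytoplasmic:nuclear activity ratio per frame.
#' @param nuc,cyto Nuclear and cytoplasmic reporter intensities per frame.
#' @param degron Degron (APC/C-Cdh1 substrate) intensity per frame.
#' @param qc_flags Character vector of QC flags.
#' @return An object of class `cell_trace`.
#' @export
cell_trace <- function(cell_id, time, ratio, nuc = NULL, cyto = NULL,
                       degron = NULL, qc_flags = character(0)) {
  n <- length(time)
  stopifnot(length(ratio) == n,
            is.null(nuc) || length(nuc) == n,
            is.null(cyto) || length(cyto) == n,
            is.null(degron) || length(degron) == n)
  if (n > 1) {
    dt <- diff(time)
    stopifnot(all(dt > 0), diff(range(dt)) < 1e-8)
  }
  structure(list(cell_id = cell_id, time = time, ratio = ratio,
                 nuc = nuc, cyto = cyto, degron = degron,
                 frame_interval = if (n > 1) time[2] - time[1] else NA_real_,
                 qc_flags = qc_flags),
            class = "cell_trace")
}

#' Sample stress event times for one S phase
#'
#' With no `event_spacing`, event centers are `n_events` independent
#' uniform draws on `[s_start, s_end]` (the default Monte Carlo model).
#' With `event_spacing` set, events sit on a regular grid of that period
#' with a uniform random phase and Gaussian jitter, clamped to the S-phase
#' window; this variant encodes a dominant fluctuation period.
#'
#' @param config A [stress_model_config()].
#' @return A data frame with columns `t_i` (h) and `amplitude`.
#' @export
sample_stress_events <- function(config) {
  if (is.null(config$event_spacing)) {
    n <- config$n_events
    t_i <- if (n > 0) stats::runif(n, config$s_start, config$s_end) else numeric(0)
  } else {
    period <- config$event_spacing
    phase <- stats::runif(1, 0, period)
    centers <- seq(config$s_start + phase, config$s_end, by = period)
    t_i <- centers + stats::rnorm(length(centers), 0, config$event_jitter_sd)
    t_i <- pmin(pmax(t_i, config$s_start), config$s_end)
  }
  amp <- if (config$amplitude_sd > 0) {
    pmax(0, stats::rnorm(length(t_i), config$amplitude, config$amplitude_sd))
  } else {
    rep(config$amplitude, length(t_i))
  }
  data.frame(t_i = t_i, amplitude = amp)
}

#' Piecewise-linear CDK2 activity baseline
#'
#' Zero before `g0_end`, then a linear ramp
#' `ramp_offset + ramp_slope * (t - s_start)` through the end of the trace.
#' With the default `ramp_offset` the ramp is continuous (zero) at `g0_end`.
#'
#' @param t Times (h) within `[0, trace_end]`.
#' @param config A [stress_model_config()].
#' @return Activity values at `t`.
#' @export
cdk2_baseline <- function(t, config) {
  if (any(t < 0 | t > config$trace_end)) {
    stop("t outside the trace domain [0, trace_end]")
  }
  ifelse(t < config$g0_end, 0,
         config$ramp_offset + config$ramp_slope * (t - config$s_start))
}

#' Subtract Gaussian stress dips from a baseline activity series
#'
#' Applies `baseline(t) - sum_i amplitude_i * exp(-(t - t_i)^2 / dip_shape)`.
#' Values are not clipped below zero unless `config$clip_at_zero` is set.
#'
#' @param baseline Activity series sampled on the frame grid.
#' @param events Data frame of events as from [sample_stress_events()].
#' @param config A [stress_model_config()].
#' @param time Frame times matching `baseline`; defaults to
#'   [frame_grid()] of `config`.
#' @return Activity series with dips applied.
#' @export
apply_stress_dips <- function(baseline, events, config,
                              time = frame_grid(config)) {
  stopifnot(length(baseline) == length(time))
  out <- baseline
  if (nrow(events) > 0) {
    for (k in seq_len(nrow(events))) {
      out <- out - events$amplitude[k] *
        exp(-(time - events$t_i[k])^2 / config$dip_shape)
    }
  }
  if (config$clip_at_zero) out <- pmax(out, 0)
  out
}

# Latent degron signal: 0 before APC/C inactivation, then a linear rise to
# 1 over degron_rise_span hours.
degron_signal <- function(time, apc_time, config) {
  pmin(pmax((time - apc_time) / config$degron_rise_span, 0), 1)
}

simulate_cell <- function(config, cell_id, seed) {
  set.seed(seed)
  time <- frame_grid(config)
  events <- sample_stress_events(config)
  activity <- apply_stress_dips(cdk2_baseline(time, config), events, config,
                                time = time)
  ratio <- activity + stats::rnorm(length(time), 0, config$noise_sd)
  apc_time <- config$g0_end + config$degron_lag
  degron <- degron_signal(time, apc_time, config) +
    stats::rnorm(length(time), 0, config$degron_noise_sd)
  # per-cell expression level; reporter intensities consistent with the ratio
  nuc_level <- stats::rlnorm(1, log(300), 0.3)
  nuc <- rep(nuc_level, length(time))
  cyto <- ratio * nuc_level
  trace <- cell_trace(cell_id, time, ratio, nuc = nuc, cyto = cyto,
                      degron = degron)
  structure(list(
    trace = trace,
    activity = activity,            # latent, noise-free activity
    events = events,
    true_cdk2_rise = config$g0_end,
    true_apc_inactivation = apc_time,
    true_s_end = config$s_end,
    true_s_duration = config$s_end - apc_time,
    true_synthesis_rate = NULL,
    config = config
  ), class = "simulated_cell")
}

#' Simulate a population of single-cell CDK2 traces
#'
#' Per cell: stress events are sampled, Gaussian dips subtracted from the
#' linear baseline, measurement noise added to the ratio, and a degron
#' trace started `degron_lag` hours after the CDK2 rise. Ground truth
#' (event times, landmark times, S duration) is stored on each cell. The
#' result is a pure function of `(config, seed)`: cell `i` uses a
#' deterministic substream of the root seed.
#'
#' @param n_cells Number of cells (>= 1).
#' @param regime `"cycling"` or `"quiescence_release"`; ignored when
#'   `config` is supplied.
#' @param config Optional [stress_model_config()] overriding the preset.
#' @param seed Root seed; defaults to `config$seed`.
#' @return A list of `simulated_cell` objects.
#' @export
simulate_population <- function(n_cells,
                                regime = c("cycling", "quiescence_release"),
                                config = NULL, seed = NULL) {
  stopifnot(n_cells >= 1)
  if (is.null(config)) config <- regime_config(match.arg(regime))
  if (is.null(seed)) seed <- config$seed
  lapply(seq_len(n_cells), function(i) {
    simulate_cell(config, cell_id = i, seed = cell_seed(seed, i))
  })
}

#' Simulate a drug pulse / washout experiment
#'
#' During the pulse the activity ratio is pulled toward
#' `(1 - suppression_fraction)` times its value at drug addition, with a
#' pull strength `min(1, suppression_fraction / stall_saturation)` (so a
#' zero dose is an exact identity and any appreciable dose both drops the
#' level and stalls the ramp); after washout the deficit relative to the
#' unperturbed trace decays exponentially with the protocol half-life.
#' Measurement noise is added after the perturbation. Ground truth
#' (protocol, unperturbed activity) is stored per cell.
#'
#' @param protocol A [washout_protocol()].
#' @param n_cells Number of cells.
#' @param config A [stress_model_config()]; defaults to [washout_config()].
#' @param seed Root seed; defaults to `config$seed`.
#' @return A list of `simulated_cell` objects with a `protocol` element.
#' @export
simulate_washout <- function(protocol, n_cells, config = washout_config(),
                             seed = NULL) {
  stopifnot(inherits(protocol, "washout_protocol"))
  if (protocol$t_add < 0 || protocol$t_washout > config$trace_end) {
    stop("washout protocol window outside the trace domain")
  }
  if (is.null(seed)) seed <- config$seed
  hl_h <- protocol$recovery_halflife / 60
  f <- protocol$suppression_fraction
  lapply(seq_len(n_cells), function(i) {
    cell <- simulate_cell(config, cell_id = i, seed = cell_seed(seed, i))
    time <- cell$trace$time
    u <- cell$activity
    # pre-pulse reference: the last drug-free frame before addition
    u_add <- u[max(which(time < protocol$t_add))]
    u_wash <- stats::approx(time, u, xout = protocol$t_washout)$y
    s <- min(1, f / protocol$stall_saturation)
    pert <- u
    in_pulse <- time >= protocol$t_add & time < protocol$t_washout
    pert[in_pulse] <- u[in_pulse] + ((1 - f) * u_add - u[in_pulse]) * s
    post <- time >= protocol$t_washout
    d0 <- s * (u_wash - (1 - f) * u_add)
    pert[post] <- u[post] -
      d0 * 2^(-(time[post] - protocol$t_washout) / hl_h)
    # re-noise the perturbed latent activity with the cell's substream
    set.seed(cell_seed(seed + 7919L, i))
    ratio <- pert + stats::rnorm(length(time), 0, config$noise_sd)
    cell$trace$ratio <- ratio
    cell$trace$cyto <- ratio * cell$trace$nuc
    cell$unperturbed_activity <- cell$activity
    cell$activity <- pert
    cell$protocol <- protocol
    cell
  })
}

#' Couple the DNA synthesis rate to instantaneous CDK2 activity
#'
#' Attaches a relative synthesis-rate series to a simulated cell: zero
#' outside the S-phase window `[APC inactivation, s_end]`, and inside it a
#' monotone increasing function of the latent CDK2 activity,
#' `max(0, 1 + gain * (A(t) - A(t_apc)))`. With `coupling_gain = 0` the
#' rate is constant during S phase.
#'
#' @param cell A `simulated_cell`.
#' @param coupling_gain Dimensionless sensitivity of the rate to activity
#'   changes.
#' @return The cell with `true_synthesis_rate` filled in.
#' @export
couple_synthesis_rate <- function(cell, coupling_gain = 1) {
  stopifnot(inherits(cell, "simulated_cell"))
  time <- cell$trace$time
  a <- cell$activity
  a_apc <- stats::approx(time, a, xout = cell$true_apc_inactivation)$y
  rate <- pmax(0, 1 + coupling_gain * (a - a_apc))
  rate[time < cell$true_apc_inactivation | time > cell$true_s_end] <- 0
  cell$true_synthesis_rate <- rate
  cell$coupling_gain <- coupling_gain
  cell
}

#' Integrated nucleotide incorporation over a pulse window
#'
#' Integrates a cell's synthesis rate over `[t_start, t_start + duration]`
#' by trapezoidal quadrature on the frame grid; this is the noise-free
#' EdU/BrdU intensity for a pulse of that length.
#'
#' @param cell A `simulated_cell` with a coupled synthesis rate.
#' @param t_start Pulse start (h).
#' @param duration Pulse length (h), e.g. `10/60` for a 10-min pulse.
#' @return Integrated (relative) incorporation.
#' @export
pulse_incorporation <- function(cell, t_start, duration = 10 / 60) {
  stopifnot(!is.null(cell$true_synthesis_rate))
  time <- cell$trace$time
  rate_fun <- stats::approxfun(time, cell$true_synthesis_rate, rule = 2)
  grid <- seq(t_start, t_start + duration, length.out = 9)
  vals <- rate_fun(grid)
  sum((vals[-1] + vals[-length(vals)]) / 2 * diff(grid))
}

#' Flatten simulated cells to a long-format trace table
#'
#' @param cells List of `simulated_cell` or `cell_trace` objects.
#' @return A data frame with columns `cell_id`, `frame`, `time_h`, `ratio`,
#'   `nuc`, `cyto`, `degron`.
#' @export
traces_to_df <- function(cells) {
  do.call(rbind, lapply(cells, function(x) {
    tr <- if (inherits(x, "simulated_cell")) x$trace else x
    data.frame(cell_id = tr$cell_id,
               frame = seq_along(tr$time),
               time_h = tr$time,
               ratio = tr$ratio,
               nuc = if (is.null(tr$nuc)) NA_real_ else tr$nuc,
               cyto = if (is.null(tr$cyto)) NA_real_ else tr$cyto,
               degron = if (is.null(tr$degron)) NA_real_ else tr$degron)
  }))
}

#' Write simulated traces and their ground truth to disk
#'
#' Emits a long-format CSV of the traces plus a JSON sidecar holding the
#' per-cell ground truth (event times, landmark times, S duration).
#'
#' @param cells List of `simulated_cell` objects.
#' @param dir Output directory (created if needed).
#' @return Invisibly, the paths written.
#' @export
write_traces <- function(cells, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  csv <- file.path(dir, "traces.csv")
  utils::write.csv(traces_to_df(cells), csv, row.names = FALSE)
  truth <- lapply(cells, function(x) {
    list(cell_id = x$trace$cell_id,
         events = x$events$t_i,
         amplitudes = x$events$amplitude,
         true_cdk2_rise = x$true_cdk2_rise,
         true_apc_inactivation = x$true_apc_inactivation,
         true_s_duration = x$true_s_duration)
  })
  js <- file.path(dir, "truth.json")
  jsonlite::write_json(truth, js, auto_unbox = TRUE, digits = NA)
  invisible(c(csv, js))
}

#' Read a long-format trace table back into `cell_trace` objects
#'
#' @param path Path to a CSV as written by [write_traces()].
#' @return A list of `cell_trace` objects.
#' @export
read_traces <- function(path) {
  df <- utils::read.csv(path)
  lapply(split(df, df$cell_id), function(d) {
    d <- d[order(d$frame), ]
    cell_trace(d$cell_id[1], d$time_h, d$ratio, nuc = d$nuc,
               cyto = d$cyto, degron = d$degron)
  })
}
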