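#' Stress-dip model configuration
#'
#' Builds the parameter set for the Monte Carlo CDK2 trace simulator. The
#' model assumes CDK2 activity (the cytoplasmic:nuclear reporter ratio) is
#' zero in G0/early G1, rises linearly from a configured G1 rise time
#' through S phase and G2, and is transiently suppressed by Gaussian-shaped
#' replication-stress dips centered at stochastic times within S phase:
#'
#'   CDK2(t) = CDK2_linear(t) - sum_i alpha_i * exp(-(t - t_i)^2 / dip_shape)
#'
#' Each dip has a full width at half-maximal suppression of
#' `2 * sqrt(dip_shape * log(2))` hours (about 1 h at the default
#' `dip_shape = 0.5`).
#'
#' @param g0_end Time (h) of the initial CDK2 activity rise; activity is 0
#'   before this point. The linear ramp starts here.
#' @param s_start,s_end S-phase window (h). Stress dips are centered inside
#'   this window. `s_start` should equal `g0_end + degron_lag` so that
#'   S entry coincides with APC/C-Cdh1 inactivation.
#' @param trace_end Last simulated time (h).
#' @param ramp_slope Slope of the linear CDK2 ramp (activity units per h).
#' @param ramp_offset Ramp value at `s_start`. Defaults to
#'   `ramp_slope * (s_start - g0_end)` so the ramp is continuous (zero) at
#'   `g0_end`.
#' @param n_events Number of stress dips per S phase when event times are
#'   sampled uniformly (the default model uses 20).
#' @param amplitude Dip amplitude alpha (activity units); identical for all
#'   events unless `amplitude_sd > 0`.
#' @param amplitude_sd Standard deviation of per-event amplitudes; 0 (the
#'   default) gives identical amplitudes.
#' @param dip_shape Denominator of the squared-time term in the dip
#'   exponential (h^2); default 0.5.
#' @param event_spacing Optional dip spacing period (h). When `NULL`
#'   (default) event times are independent uniform draws on
#'   `[s_start, s_end]`; when set, events sit on a regular grid of this
#'   period with a random phase and Gaussian jitter, which encodes a
#'   dominant fluctuation period (anticorrelation lag = spacing / 2).
#' @param event_jitter_sd Jitter (h) of grid-spaced event times.
#' @param degron_lag Lag (h) from CDK2 rise to APC/C-Cdh1 inactivation
#'   (degron accumulation onset); default 3.
#' @param degron_rise_span Time (h) over which the degron signal ramps from
#'   0 to its maximum after APC/C inactivation.
#' @param degron_noise_sd Additive Gaussian noise on the (unit-max) degron
#'   signal.
#' @param noise_sd Additive Gaussian measurement noise on the activity
#'   ratio, per frame.
#' @param frame_interval Sampling interval (h); default 0.2 (12 min).
#' @param clip_at_zero If `TRUE`, dip-suppressed activity is floored at 0.
#'   Off by default: the model is an unclipped sum.
#' @param puncta_rate Mean number of gamma-H2AX puncta per nucleus handed
#'   to the image renderer for this condition.
#' @param seed Root seed for the per-cell random substreams.
#'
#' @return An object of class `stress_model_config` (a validated list).
#' @seealso [regime_config()], [simulate_population()]
#' @export
stress_model_config <- function(g0_end = 5, s_start = 8, s_end = 14,
                                trace_end = 18,
                                ramp_slope = 0.2, ramp_offset = NULL,
                                n_events = 20,
                                amplitude = 0.1, amplitude_sd = 0,
                                dip_shape = 0.5,
                                event_spacing = NULL, event_jitter_sd = 0.15,
                                degron_lag = 3, degron_rise_span = NULL,
                                degron_noise_sd = 0.005,
                                noise_sd = 0.02, frame_interval = 0.2,
                                clip_at_zero = FALSE,
                                puncta_rate = 6,
                                seed = 1L) {
  if (is.null(ramp_offset)) ramp_offset <- ramp_slope * (s_start - g0_end)
  if (is.null(degron_rise_span)) degron_rise_span <- trace_end - s_start
  cfg <- list(
    g0_end = g0_end, s_start = s_start, s_end = s_end, trace_end = trace_end,
    ramp_slope = ramp_slope, ramp_offset = ramp_offset,
    n_events = as.integer(n_events),
    amplitude = amplitude, amplitude_sd = amplitude_sd,
    dip_shape = dip_shape,
    event_spacing = event_spacing, event_jitter_sd = event_jitter_sd,
    degron_lag = degron_lag, degron_rise_span = degron_rise_span,
    degron_noise_sd = degron_noise_sd,
    noise_sd = noise_sd, frame_interval = frame_interval,
    clip_at_zero = isTRUE(clip_at_zero),
    puncta_rate = puncta_rate,
    seed = as.integer(seed)
  )
  class(cfg) <- "stress_model_config"
  validate_config(cfg)
  cfg
}

validate_config <- function(cfg) {
  stopifnot(
    cfg$g0_end <= cfg$s_start, cfg$s_start < cfg$s_end,
    cfg$s_end <= cfg$trace_end,
    cfg$n_events >= 0, cfg$amplitude >= 0, cfg$dip_shape > 0,
    cfg$frame_interval > 0, cfg$noise_sd >= 0,
    is.null(cfg$event_spacing) || cfg$event_spacing > 0
  )
  invisible(cfg)
}

#' Regime presets: continuous cycling vs quiescence release
#'
#' Returns a [stress_model_config()] encoding the two experimental regimes
#' as simulator parameters. Continuously cycling cells have a 6-h S phase
#' and a dominant dip spacing of 2.4 h (anticorrelation lag 1.2 h); cells
#' released from mitogen starvation (quiescence release) have a 9-h S phase,
#' denser (1.6-h spacing) and larger dips giving roughly twice the per-hour
#' suppression burden, a shallower net ramp, and twice the gamma-H2AX
#' puncta burden. These are emulation targets for the regime phenomenology,
#' not measurements.
#'
#' @param regime `"cycling"` or `"quiescence_release"`.
#' @param ... Overrides passed on to [stress_model_config()].
#' @return A `stress_model_config`.
#' @export
regime_config <- function(regime = c("cycling", "quiescence_release"), ...) {
  regime <- match.arg(regime)
  if (regime == "cycling") {
    cfg <- stress_model_config(
      g0_end = 5, s_start = 8, s_end = 14, trace_end = 18,
      ramp_slope = 0.2, event_spacing = 2.4, amplitude = 0.1,
      puncta_rate = 6, ...
    )
  } else {
    cfg <- stress_model_config(
      g0_end = 10, s_start = 13, s_end = 22, trace_end = 26,
      ramp_slope = 0.15, event_spacing = 1.6, amplitude = 0.13,
      puncta_rate = 12, ...
    )
  }
  cfg$regime <- regime
  cfg
}

#' Drug pulse / washout protocol
#'
#' Describes a replication-stress drug pulse (e.g. aphidicolin): during
#' `[t_add, t_washout]` CDK2 activity is pulled toward
#' `(1 - suppression_fraction)` times its pre-pulse value (fork stalling
#' also halts the ramp; the pull strength saturates at
#' `suppression_fraction >= stall_saturation`, so a zero dose leaves the
#' trace untouched). After washout the remaining deficit relative to the
#' unperturbed trace decays exponentially with the given half-life
#' (default 40 min).
#'
#' @param t_add,t_washout Drug addition and washout times (h).
#' @param suppression_fraction Dose-proportional fractional drop in CDK2
#'   activity during the pulse, in `[0, 1]`.
#' @param recovery_halflife Post-washout recovery half-life (min).
#' @param stall_saturation Suppression fraction at which the ramp stall
#'   saturates (default 0.05).
#' @return An object of class `washout_protocol`.
#' @export
washout_protocol <- function(t_add = 10, t_washout = 11,
                             suppression_fraction = 0.3,
                             recovery_halflife = 40,
                             stall_saturation = 0.05) {
  stopifnot(t_add < t_washout,
            suppression_fraction >= 0, suppression_fraction <= 1,
            recovery_halflife > 0, stall_saturation > 0)
  structure(list(t_add = t_add, t_washout = t_washout,
                 suppression_fraction = suppression_fraction,
                 recovery_halflife = recovery_halflife,
                 stall_saturation = stall_saturation),
            class = "washout_protocol")
}

#' Default configuration for washout experiments
#'
#' The cycling timeline with endogenous stress dips switched off: during
#' and shortly after a strong exogenous stress pulse the drug response
#' dominates the trace, so the washout scenario isolates the drug kinetics.
#'
#' @param ... Overrides passed on to [stress_model_config()].
#' @return A `stress_model_config`.
#' @export
washout_config <- function(...) {
  stress_model_config(n_events = 0L, event_spacing = NULL, ...)
}

#' Frame grid of a configuration
#'
#' @param config A `stress_model_config`.
#' @return Numeric vector of frame times (h) from 0 to `trace_end`.
#' @export
frame_grid <- function(config) {
  seq(0, config$trace_end, by = config$frame_interval)
}

# Deterministic per-cell substream: cell i of a run with root seed s gets
# seed (s + 1000003 * i) mod (2^31 - 1), so populations are reproducible
# under any iteration order.
cell_seed <- function(root_seed, i) {
  as.integer((as.numeric(root_seed) + 1000003 * i) %% 2147483647)
}
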