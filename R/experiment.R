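#' Simulate an EdU/BrdU pulse-chase measurement on coupled cells
#'
#' Each cell receives a 10-min EdU pulse at a random time around its S
#' phase, a 50-min chase, and a 10-min BrdU pulse. Intensities are the
#' integrated synthesis rate over each pulse window times `scale`. The
#' dominant intensity variability (cell size, staining and segmentation
#' efficiency) is common to both stains of one cell, so the noise model is
#' a shared per-cell lognormal factor (`noise_cv`) times a small
#' independent per-stain lognormal factor (`stain_cv`), plus an additive
#' background.
#' CDK2 activity at each pulse is read from the (noisy) ratio trace at the
#' nearest frame. Pulse start times are uniform on
#' `[apc - 1 h, s_end + 1 h - window]`, so a fraction of cells is pulsed
#' outside S phase and serves as the stain-negative population for gating.
#'
#' @param cells List of `simulated_cell` objects with coupled synthesis
#'   rates (see [couple_synthesis_rate()]).
#' @param edu_duration,gap,brdu_duration Pulse design (h); defaults 10 min,
#'   50 min, 10 min.
#' @param scale Intensity units per unit integrated rate.
#' @param noise_cv Lognormal sdlog of the shared per-cell intensity factor.
#' @param stain_cv Lognormal sdlog of the independent per-stain factor.
#' @param background Mean additive background intensity.
#' @return Data frame with `cell_id`, `edu`, `brdu`, `cdk2_at_edu`,
#'   `cdk2_at_brdu`, `t_edu`, `t_brdu`.
#' @export
simulate_pulse_chase <- function(cells, edu_duration = 10 / 60,
                                 gap = 50 / 60, brdu_duration = 10 / 60,
                                 scale = 100, noise_cv = 0.2,
                                 stain_cv = 0.05, background = 1) {
  window <- edu_duration + gap + brdu_duration
  do.call(rbind, lapply(cells, function(cell) {
    stopifnot(!is.null(cell$true_synthesis_rate))
    t_edu <- stats::runif(1, cell$true_apc_inactivation - 1,
                          cell$true_s_end + 1 - window)
    t_brdu <- t_edu + edu_duration + gap
    cell_factor <- stats::rlnorm(1, 0, noise_cv)
    noisy <- function(x) {
      x * scale * cell_factor * stats::rlnorm(1, 0, stain_cv) +
        background * stats::rlnorm(1, 0, 0.5)
    }
    tr <- cell$trace
    data.frame(
      cell_id = tr$cell_id,
      edu = noisy(pulse_incorporation(cell, t_edu, edu_duration)),
      brdu = noisy(pulse_incorporation(cell, t_brdu, brdu_duration)),
      cdk2_at_edu = tr$ratio[nearest_frame(tr, t_edu + edu_duration / 2)],
      cdk2_at_brdu = tr$ratio[nearest_frame(tr, t_brdu + brdu_duration / 2)],
      t_edu = t_edu, t_brdu = t_brdu
    )
  }))
}

#' Simulate a fixed-cell EdU time course for S-duration estimation
#'
#' Each cell is pulsed with EdU (10 min) once, at a uniformly random time
#' since its APC/C inactivation within `window`; the measured intensity is
#' the integrated synthesis rate with multiplicative lognormal noise and a
#' small additive background.
#'
#' @param cells List of coupled `simulated_cell` objects.
#' @param window Range (h) of times since APC/C inactivation to sample.
#' @param pulse_duration Pulse length (h).
#' @param scale Intensity units per unit integrated rate.
#' @param noise_cv Lognormal sdlog of the intensity noise.
#' @param background Mean additive background intensity.
#' @return Data frame with `cell_id`, `time_since_apc`, `edu`.
#' @export
simulate_edu_timecourse <- function(cells, window = c(0, 12),
                                    pulse_duration = 10 / 60, scale = 100,
                                    noise_cv = 0.2, background = 0.2) {
  do.call(rbind, lapply(cells, function(cell) {
    u <- stats::runif(1, window[1], window[2])
    t_pulse <- cell$true_apc_inactivation + u
    t_pulse <- min(t_pulse, max(cell$trace$time) - pulse_duration)
    inc <- pulse_incorporation(cell, t_pulse, pulse_duration)
    data.frame(cell_id = cell$trace$cell_id,
               time_since_apc = u,
               edu = inc * scale * stats::rlnorm(1, 0, noise_cv) +
                 background * stats::rlnorm(1, 0, 0.5))
  }))
}

#' Render and quantify a gamma-H2AX cohort
#'
#' Renders one nucleus per small field with a Poisson-distributed number
#' of puncta (mean `config$puncta_rate`), applies the field noise model,
#' then recovers the puncta pixel count through segmentation and the
#' top-hat pipeline. Returns truth and measurement per cell.
#'
#' @param n_cells Number of nuclei.
#' @param config A [stress_model_config()] (supplies `puncta_rate`).
#' @param seed Root seed.
#' @param tile_px Field side (px).
#' @param punctum_radius_um,punctum_intensity Punctum geometry/contrast.
#' @param h2ax_base Diffuse nuclear gamma-H2AX level.
#' @return Data frame with `cell_id`, `n_puncta`, `truth_px`,
#'   `measured_px`.
#' @export
render_h2ax_cohort <- function(n_cells, config, seed = config$seed,
                               tile_px = 100, punctum_radius_um = 0.65,
                               punctum_intensity = 250, h2ax_base = 120) {
  spec <- field_spec(tile_px, tile_px,
                     positions = data.frame(row = tile_px / 2,
                                            col = tile_px / 2))
  do.call(rbind, lapply(seq_len(n_cells), function(i) {
    set.seed(cell_seed(seed + 104729L, i))
    n_p <- stats::rpois(1, config$puncta_rate)
    st <- data.frame(cell_id = i, ratio = 1, nuc = 300, h2ax = h2ax_base,
                     h2b = 400)
    fr <- render_frame(st, spec, channels = c("h2b", "h2ax"), noise = FALSE)
    if (n_p > 0) {
      fr <- render_puncta(fr, 1, n_p, punctum_radius_um = punctum_radius_um,
                          punctum_intensity = punctum_intensity)
    }
    fr <- apply_noise(fr)
    mask <- segment_nuclei(fr$channels$h2b, spec$um_per_px)
    measured <- if (max(mask$labels) >= 1) {
      quantify_h2ax(fr$channels$h2ax, mask, 1)
    } else NA_integer_
    data.frame(cell_id = i, n_puncta = n_p,
               truth_px = unname(fr$ground_truth$puncta_px[as.character(i)]),
               measured_px = measured)
  }))
}

# fluctuation profile of a population: smooth, align at called CDK2 rise,
# cubic-residual metric, population mean/SEM
population_fluctuation_profile <- function(cells, activity_gate = 1.3,
                                           min_cells = 2) {
  series <- lapply(cells, function(cell) {
    tr <- smooth_trace(cell$trace)
    rise <- call_cdk2_rise(tr)
    if (is.na(rise)) return(NULL)
    fluctuation_polyfit(tr, rise, activity_gate = activity_gate)
  })
  list(profile = population_profile(series, min_cells = min_cells),
       series = series)
}

#' Run a named experiment scenario end to end
#'
#' Executes one of the packaged scenarios with logged parameters and
#' seeds, writing tidy CSV/JSON outputs and a machine-readable manifest to
#' `out_dir`. Scenarios:
#' \describe{
#'   \item{`simulate_only`}{simulate a population and write traces + truth.}
#'   \item{`regimes`}{cycling vs quiescence-release comparison:
#'     fluctuation profiles with timepoint-wise rank tests,
#'     autocorrelation lags, and EdU-based S durations.}
#'   \item{`washout`}{drug dose series over suppression fractions: median
#'     percent change and recovery metrics per dose.}
#'   \item{`nucleotide`}{EdU/BrdU pulse-chase: delta-rate records, CDK2
#'     delta binning, and the bin-level regression.}
#' }
#'
#' @param config A list with `scenario`, `out_dir`, and optionally
#'   `n_cells` (default 200), `seed` (default 1), `regime`,
#'   `suppression_fractions`, `coupling_gain`.
#' @return Invisibly, the summary list written to the manifest.
#' @export
run_experiment <- function(config) {
  stopifnot(is.list(config), !is.null(config$scenario), !is.null(config$out_dir))
  scenario <- config$scenario
  out <- config$out_dir
  n <- if (is.null(config$n_cells)) 200L else config$n_cells
  seed <- if (is.null(config$seed)) 1L else config$seed
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  summary <- list(scenario = scenario, n_cells = n, seed = seed)

  if (scenario == "simulate_only") {
    regime <- if (is.null(config$regime)) "cycling" else config$regime
    cells <- simulate_population(n, regime, seed = seed)
    write_traces(cells, out)
    summary$regime <- regime

  } else if (scenario == "regimes") {
    cyc <- simulate_population(n, "cycling", seed = seed)
    qr <- simulate_population(n, "quiescence_release", seed = seed)
    fc <- population_fluctuation_profile(cyc)
    fq <- population_fluctuation_profile(qr)
    utils::write.csv(fc$profile, file.path(out, "fluctuation_cycling.csv"),
                     row.names = FALSE)
    utils::write.csv(fq$profile, file.path(out, "fluctuation_qr.csv"),
                     row.names = FALSE)
    ts <- compare_timeseries(Filter(Negate(is.null), fq$series),
                             Filter(Negate(is.null), fc$series))
    utils::write.csv(ts, file.path(out, "timepoint_tests.csv"),
                     row.names = FALSE)
    seg <- function(cells) data.frame(
      start = vapply(cells, function(c) c$true_apc_inactivation, 1),
      end = vapply(cells, function(c) c$true_s_end, 1))
    ac <- autocorrelation_profile(lapply(cyc, `[[`, "trace"), seg(cyc))
    aq <- autocorrelation_profile(lapply(qr, `[[`, "trace"), seg(qr))
    set.seed(seed)
    dur <- function(cells) {
      coupled <- lapply(cells, couple_synthesis_rate)
      tc <- simulate_edu_timecourse(coupled)
      s_phase_duration(tc$time_since_apc, tc$edu,
                       min_per_bin = min(50, floor(n / 20)))$duration
    }
    summary$anticorrelation_lag <- list(cycling = ac$anticorrelation_lag,
                                        quiescence_release = aq$anticorrelation_lag)
    summary$s_duration <- list(cycling = dur(cyc), quiescence_release = dur(qr))

  } else if (scenario == "washout") {
    fr <- if (is.null(config$suppression_fractions)) {
      c(0.1, 0.2, 0.3, 0.4)
    } else config$suppression_fractions
    res <- do.call(rbind, lapply(fr, function(f) {
      prot <- washout_protocol(suppression_fraction = f)
      cells <- simulate_washout(prot, n, seed = seed)
      pc <- vapply(cells, function(c) {
        percent_change(c$trace, prot$t_add)
      }, numeric(1))
      rm <- lapply(cells, function(c) {
        recovery_metrics(c$trace, prot$t_add, prot$t_washout)
      })
      data.frame(suppression_fraction = f,
                 median_percent_change = stats::median(pc),
                 median_recovery_time = stats::median(
                   vapply(rm, `[[`, 1, "recovery_time"), na.rm = TRUE),
                 median_halflife = stats::median(
                   vapply(rm, `[[`, 1, "halflife"), na.rm = TRUE))
    }))
    utils::write.csv(res, file.path(out, "washout_doses.csv"),
                     row.names = FALSE)
    summary$washout <- res

  } else if (scenario == "nucleotide") {
    gain <- if (is.null(config$coupling_gain)) 1 else config$coupling_gain
    # endogenous-stress model: 20 uniformly timed dips per S phase
    cells <- simulate_population(n, config = stress_model_config(), seed = seed)
    cells <- lapply(cells, couple_synthesis_rate, coupling_gain = gain)
    set.seed(seed)
    pc <- simulate_pulse_chase(cells)
    rec <- delta_nucleotide(pc)
    utils::write.csv(rec, file.path(out, "nucleotide_records.csv"),
                     row.names = FALSE)
    bs <- bin_by_delta_cdk2(rec, min_per_bin = min(70, floor(nrow(rec) / 10)))
    utils::write.csv(bs$bins, file.path(out, "delta_cdk2_bins.csv"),
                     row.names = FALSE)
    summary$regression_r2 <- bs$regression_r2
    summary$spearman <- stats::cor(rec$delta_cdk2, rec$delta_rate,
                                   method = "spearman")

  } else {
    stop("unknown scenario: ", scenario)
  }

  jsonlite::write_json(summary, file.path(out, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(summary)
}
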