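#' Generator presets for the reference study conditions
#'
#' These presets freeze the simulation conditions used throughout the
#' package's validation: the parameter values are the published sham-group
#' activity levels of maturing hippocampal cultures, plus a planted-burst
#' configuration for duration-accuracy validation of the TSR burst detector.
#'
#' @details
#' * `preset_sham_div14_raster()` — 5-minute, 59-electrode recording with
#'   large network bursts at 27.87 bursts / 5 min carrying 506.54 spikes
#'   each on average (the sham DIV 14 levels), 0.3-s Gaussian-envelope
#'   bursts spanning the whole array, and sparse basal background activity
#'   (0.1 spikes/s/electrode network-wide).
#' * `preset_burst_validation(rate)` — planted non-overlapping bursts with a
#'   uniform intra-burst envelope (crisp boundaries) at the requested burst
#'   rate, no background; used to measure duration-estimation accuracy at
#'   burst rates up to 5 Hz.
#' * `preset_sham_calcium()` — 50 cells, 300 s at 4 Hz with transients at
#'   1.55 oscillations/min (sham DIV 14 frequency) of mean planted duration
#'   9.67 s (sham DIV 10 duration).
#'
#' @param seed integer RNG seed.
#' @param rate configured burst rate, bursts/s (validation preset).
#' @return a [raster_sim_config()] or [calcium_sim_config()].
#' @name presets
NULL

#' @rdname presets
#' @export
preset_sham_div14_raster <- function(seed = 1L) {
  raster_sim_config(
    duration = 300,
    background_rate = 0.1,
    burst_rate = 27.87 / 300,
    burst_duration_mean = 0.3,
    burst_duration_sd = 0,
    spikes_per_burst_mean = 506.54,
    burst_electrode_span = 59,
    burst_envelope = "gaussian",
    burst_min_gap = 0.15,
    seed = seed
  )
}

#' @rdname presets
#' @param duration recording length for the validation runs, seconds.
#' @export
preset_burst_validation <- function(rate, seed = 1L, duration = 60) {
  stopifnot(rate > 0)
  raster_sim_config(
    duration = duration,
    background_rate = 0,
    burst_rate = rate,
    burst_duration_mean = if (rate >= 4) 0.04 else 0.1,
    burst_duration_sd = 0,
    spikes_per_burst_mean = 250,
    burst_electrode_span = 59,
    burst_envelope = "uniform",
    burst_min_gap = 0.15,
    seed = seed
  )
}

#' @rdname presets
#' @export
preset_sham_calcium <- function(seed = 1L) {
  calcium_sim_config(
    n_cells = 50,
    duration = 300,
    frame_rate = 4,
    event_rate = 1.55,
    event_duration_mean = 9.67,
    event_duration_sd = 1,
    amplitude = 100,
    rise_tau = 0.8,
    decay_tau = 10,
    clearance = 1,
    noise_sd = 2,
    baseline = 50,
    event_min_gap = 1,
    seed = seed
  )
}
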