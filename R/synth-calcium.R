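#' Configuration for the calcium-trace generator
#'
#' Parameters of the planted fluorescence model. Each cell's trace is a
#' baseline plus Gaussian noise plus a train of non-overlapping calcium
#' transients. A transient occupying `[onset, onset + duration]` has an
#' exponential rise to the configured amplitude (`rise_tau`), a slow
#' exponential decay (`decay_tau`), and a short linear clearance ramp that
#' returns the trace to baseline exactly at the planted end — transients
#' therefore have a well-defined finite support, which is what makes planted
#' durations recoverable quantities. Traces are sampled at `frame_rate` and
#' clipped to the 8-bit intensity range \[0, 255\].
#'
#' @param n_cells number of cells (ROIs).
#' @param duration recording length, seconds.
#' @param frame_rate imaging rate, Hz (default 4).
#' @param event_rate transient rate per cell, oscillations/min. Onsets use
#'   the same hard-core renewal scheme as the burst generator, so the planted
#'   stationary rate equals the configured one and events never overlap.
#' @param event_duration_mean,event_duration_sd planted transient duration
#'   mean and SD, seconds.
#' @param amplitude transient amplitude, intensity units.
#' @param rise_tau,decay_tau rise and decay time constants, seconds.
#' @param clearance short terminal ramp length, seconds.
#' @param noise_sd Gaussian noise SD, intensity units.
#' @param baseline resting intensity in \[0, 255\].
#' @param event_min_gap guaranteed gap between consecutive transients, s.
#' @param seed integer RNG seed.
#' @return a `calcium_sim_config` list.
#' @export
calcium_sim_config <- function(n_cells = 50,
                               duration = 300,
                               frame_rate = 4,
                               event_rate = 1,
                               event_duration_mean = 8,
                               event_duration_sd = 1,
                               amplitude = 100,
                               rise_tau = 0.8,
                               decay_tau = 10,
                               clearance = 1,
                               noise_sd = 2,
                               baseline = 50,
                               event_min_gap = 1,
                               seed = 1L) {
  cfg <- list(
    n_cells = as.integer(n_cells), duration = duration,
    frame_rate = frame_rate, event_rate = event_rate,
    event_duration_mean = event_duration_mean,
    event_duration_sd = event_duration_sd,
    amplitude = amplitude, rise_tau = rise_tau, decay_tau = decay_tau,
    clearance = clearance, noise_sd = noise_sd, baseline = baseline,
    event_min_gap = event_min_gap, seed = seed
  )
  class(cfg) <- "calcium_sim_config"
  cfg
}

validate_calcium_config <- function(config) {
  if (config$frame_rate <= 0) stop_invalid("invalid config: frame_rate must be positive")
  if (config$n_cells < 1) stop_invalid("invalid config: n_cells must be >= 1")
  if (config$duration <= 0) stop_invalid("invalid config: duration must be positive")
  if (config$event_duration_mean <= 0) {
    stop_invalid("invalid config: event_duration_mean must be positive")
  }
  if (config$noise_sd < 0) stop_invalid("invalid config: noise_sd must be >= 0")
  if (config$baseline + config$amplitude > 255) {
    stop_invalid("invalid config: baseline + amplitude must not exceed 255")
  }
  if (config$event_rate > 0) {
    mean_interval <- 60 / config$event_rate
    if (mean_interval <= config$event_duration_mean + config$event_min_gap) {
      stop_invalid(paste(
        "invalid config: event_rate too high for the configured duration",
        "and gap (transients would overlap)"))
    }
  }
  invisible(config)
}

# transient waveform on time grid t (s, relative to onset), planted duration d
transient_shape <- function(t, d, amplitude, rise_tau, decay_tau, clearance) {
  rise_len <- min(3 * rise_tau, 0.4 * d)
  clear_len <- min(clearance, 0.2 * d)
  f <- numeric(length(t))
  inside <- t >= 0 & t <= d
  tr <- t[inside]
  rise_norm <- 1 - exp(-rise_len / rise_tau)
  peak_of <- function(s) amplitude * (1 - exp(-s / rise_tau)) / rise_norm
  decay_end <- d - clear_len
  residual <- amplitude * exp(-(decay_end - rise_len) / decay_tau)
  v <- numeric(length(tr))
  ph1 <- tr < rise_len
  v[ph1] <- peak_of(tr[ph1])
  ph2 <- tr >= rise_len & tr < decay_end
  v[ph2] <- amplitude * exp(-(tr[ph2] - rise_len) / decay_tau)
  ph3 <- tr >= decay_end
  v[ph3] <- residual * (d - tr[ph3]) / clear_len
  f[inside] <- v
  f
}

#' Fluorescence-trace container
#'
#' @param intensity numeric matrix, frames x cells, values in \[0, 255\].
#' @param frame_rate imaging rate, Hz.
#' @param roi_ids optional ROI identifiers (default `1:n_cells`).
#' @return object of class `fluorescence_traces`.
#' @export
fluorescence_traces <- function(intensity, frame_rate = 4, roi_ids = NULL) {
  intensity <- as.matrix(intensity)
  if (frame_rate <= 0) stop_invalid("frame_rate must be positive")
  if (any(intensity < 0 | intensity > 255)) {
    stop_invalid("intensities must lie in [0, 255]")
  }
  roi_ids <- roi_ids %||% seq_len(ncol(intensity))
  colnames(intensity) <- roi_ids
  structure(
    list(intensity = intensity, frame_rate = frame_rate,
         roi_ids = as.integer(roi_ids),
         duration = nrow(intensity) / frame_rate),
    class = "fluorescence_traces")
}

#' @export
print.fluorescence_traces <- function(x, ...) {
  cat(sprintf("<fluorescence_traces> %d ROIs, %d frames @ %g Hz (%.0f s)\n",
              ncol(x$intensity), nrow(x$intensity), x$frame_rate, x$duration))
  invisible(x)
}

#' Simulate ROI fluorescence traces with planted calcium transients
#'
#' @param config a [calcium_sim_config()].
#' @return list with `traces` (a [fluorescence_traces()]) and `ground_truth`:
#'   list with `transients` (data frame `roi_id`, `start`, `end`, per-cell
#'   non-overlapping and within the recording).
#' @examples
#' sim <- simulate_calcium(calcium_sim_config(n_cells = 3, duration = 60,
#'                                            event_rate = 1, seed = 3))
#' head(sim$ground_truth$transients)
#' @export
simulate_calcium <- function(config) {
  stopifnot(inherits(config, "calcium_sim_config"))
  validate_calcium_config(config)
  n_frames <- floor(config$duration * config$frame_rate)
  t_grid <- (seq_len(n_frames) - 1) / config$frame_rate

  with_seed(config$seed, {
    intensity <- matrix(config$baseline, n_frames, config$n_cells)
    gt <- vector("list", config$n_cells)
    for (cell in seq_len(config$n_cells)) {
      events <- data.frame(start = numeric(0), end = numeric(0))
      if (config$event_rate > 0) {
        mean_interval <- 60 / config$event_rate
        slack <- mean_interval - config$event_duration_mean -
          config$event_min_gap
        prev_end <- -runif(1) * mean_interval
        repeat {
          d <- config$event_duration_mean
          if (config$event_duration_sd > 0) {
            d <- max(1, rnorm(1, d, config$event_duration_sd))
          }
          onset <- prev_end + config$event_min_gap + rexp(1, 1 / slack)
          if (onset < 0) onset <- 0
          if (onset + d >= config$duration) break
          events <- rbind(events, data.frame(start = onset, end = onset + d))
          intensity[, cell] <- intensity[, cell] +
            transient_shape(t_grid - onset, d, config$amplitude,
                            config$rise_tau, config$decay_tau,
                            config$clearance)
          prev_end <- onset + d
        }
      }
      gt[[cell]] <- if (nrow(events)) {
        cbind(roi_id = cell, events)
      } else {
        data.frame(roi_id = integer(0), start = numeric(0), end = numeric(0))
      }
    }
    if (config$noise_sd > 0) {
      intensity <- intensity +
        matrix(rnorm(length(intensity), 0, config$noise_sd),
               nrow(intensity), ncol(intensity))
    }
    intensity[intensity < 0] <- 0
    intensity[intensity > 255] <- 255
    list(
      traces = fluorescence_traces(intensity, config$frame_rate),
      ground_truth = list(transients = do.call(rbind, gt))
    )
  })
}
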