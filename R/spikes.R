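#' Zero-phase band-pass filter for extracellular recordings
#'
#' Applies a 2nd-order Butterworth band-pass forward and backward
#' (zero-phase) to every channel. Defaults to the 300 Hz - 8 kHz band used
#' for extracellular action potentials; the DC component is removed by the
#' band-pass itself.
#'
#' @param recording a `voltage_recording` (see [simulate_voltage()]).
#' @param low,high band edges, Hz; must satisfy `0 < low < high < Nyquist`.
#' @return the filtered `voltage_recording` (same length), with attribute
#'   `filtered = TRUE`.
#' @export
bandpass_filter <- function(recording, low = 300, high = 8000) {
  stopifnot(inherits(recording, "voltage_recording"))
  nyq <- recording$sample_rate / 2
  if (!(low > 0 && high > low)) {
    stop_invalid("invalid band: need 0 < low < high")
  }
  if (high >= nyq) {
    stop_invalid("invalid band: high cutoff must be below the Nyquist frequency (%g Hz)", nyq)
  }
  bf <- signal::butter(2, c(low, high) / nyq, type = "pass")
  out <- recording
  out$data <- apply(recording$data, 2, function(x) {
    signal::filtfilt(bf, x)
  })
  dim(out$data) <- dim(recording$data)
  dimnames(out$data) <- dimnames(recording$data)
  attr(out, "filtered") <- TRUE
  out
}

#' Median-based noise estimate and spike threshold
#'
#' Estimates the standard deviation of a band-passed signal *without* its
#' spikes as `sigma = median(|x|) / 0.6745`; 0.6745 is the upper quartile of
#' the standard normal, which maps the median absolute value of Gaussian
#' noise onto its SD. Because at most a small fraction of samples belong to
#' spikes, the median is nearly insensitive to them, unlike the raw SD.
#' The detection threshold is `T = Ns * sigma`.
#'
#' @param signal numeric vector, one filtered channel (uV).
#' @param detection_coeff the spike detection coefficient `Ns` (default 4,
#'   which detects amplitudes above roughly 20 uV on 5-uV noise).
#' @return object of class `noise_estimate`: list with `sigma` (uV),
#'   `threshold` (uV) and `detection_coeff`.
#' @export
estimate_noise_sigma <- function(signal, detection_coeff = 4) {
  if (!length(signal)) stop_invalid("cannot estimate noise from an empty signal")
  if (detection_coeff <= 0) stop_invalid("detection_coeff must be positive")
  sigma <- median(abs(signal)) / 0.6745
  structure(
    list(sigma = sigma, threshold = detection_coeff * sigma,
         detection_coeff = detection_coeff),
    class = "noise_estimate")
}

#' @export
print.noise_estimate <- function(x, ...) {
  cat(sprintf("<noise_estimate> sigma = %.3g uV, threshold = %.3g uV (Ns = %g)\n",
              x$sigma, x$threshold, x$detection_coeff))
  invisible(x)
}

#' Threshold spike detection from voltage
#'
#' Per channel, a noise sigma is estimated from the signal median
#' ([estimate_noise_sigma()]) and samples with `|x| > Ns * sigma` are grouped
#' into suprathreshold excursions; the spike time is the extremal-magnitude
#' sample of each excursion. Crossings closer than the refractory interval to
#' the previously accepted spike are suppressed (minimal inter-spike
#' interval, default 1 ms). Detection uses signal magnitude, so both
#' polarities are caught.
#'
#' @param recording a `voltage_recording`; band-pass filtered first unless
#'   already filtered (set `filter = FALSE` to skip).
#' @param Ns spike detection coefficient (> 0).
#' @param refractory_ms minimal inter-spike interval, ms.
#' @param band band-pass edges (Hz) used when filtering internally.
#' @param filter whether to band-pass the recording first.
#' @return a [spike_raster()], sorted, with per-channel times at least the
#'   refractory interval apart.
#' @export
detect_spikes <- function(recording, Ns = 4, refractory_ms = 1,
                          band = c(300, 8000), filter = TRUE) {
  stopifnot(inherits(recording, "voltage_recording"))
  if (Ns <= 0) stop_invalid("invalid parameter: Ns must be positive")
  if (refractory_ms < 0) stop_invalid("refractory_ms must be non-negative")
  if (filter && !isTRUE(attr(recording, "filtered"))) {
    recording <- bandpass_filter(recording, band[1], band[2])
  }
  fs <- recording$sample_rate
  refr <- refractory_ms / 1000
  ids <- recording$channel_ids
  out_channel <- integer(0)
  out_time <- numeric(0)
  for (ci in seq_along(ids)) {
    x <- recording$data[, ci]
    est <- estimate_noise_sigma(x, Ns)
    idx <- which(abs(x) > est$threshold)
    if (!length(idx)) next
    grp <- cumsum(c(1L, diff(idx) > 1L))
    peaks <- vapply(split(idx, grp), function(ii) {
      ii[which.max(abs(x[ii]))]
    }, integer(1))
    times <- (sort(peaks) - 1) / fs
    times <- times[dedup_mask(times, refr)]
    out_channel <- c(out_channel, rep.int(ids[ci], length(times)))
    out_time <- c(out_time, times)
  }
  spike_raster(data.frame(channel = out_channel, time = out_time),
               duration = recording$duration,
               geometry = recording$geometry,
               min_isi = refr)
}
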