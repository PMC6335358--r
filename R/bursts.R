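#' Total spiking rate (TSR) series
#'
#' Counts spikes from all electrodes in consecutive half-open time bins
#' `[t, t + bin_width)` aligned to t = 0. The default 50-ms bin is the
#' canonical window for network-burst detection.
#'
#' @param raster a [spike_raster()].
#' @param bin_width_ms bin width in milliseconds.
#' @return object of class `tsr_series`: list with `counts` (integer, spikes
#'   per bin over all electrodes), `bin_start` (s), `bin_width` (s) and
#'   `duration` (s). `sum(counts)` always equals the raster spike count.
#' @export
compute_tsr <- function(raster, bin_width_ms = 50) {
  stopifnot(inherits(raster, "spike_raster"))
  if (bin_width_ms <= 0) stop_invalid("bin_width_ms must be positive")
  bw <- bin_width_ms / 1000
  n_bins <- max(1L, as.integer(ceiling(raster$duration / bw - 1e-9)))
  bins <- pmin(floor(raster$spikes$time / bw) + 1L, n_bins)
  counts <- tabulate(bins, nbins = n_bins)
  structure(
    list(counts = as.integer(counts),
         bin_start = (seq_len(n_bins) - 1L) * bw,
         bin_width = bw,
         duration = raster$duration),
    class = "tsr_series")
}

#' @export
print.tsr_series <- function(x, ...) {
  cat(sprintf("<tsr_series> %d bins of %g ms, %d spikes\n",
              length(x$counts), 1000 * x$bin_width, sum(x$counts)))
  invisible(x)
}

#' Detect network bursts from the TSR
#'
#' A burst threshold `T_burst = threshold_coeff * sd(TSR)` is computed from
#' the raw TSR series (bursts included, no mean subtraction; the coefficient
#' 0.1 is the empirical standard). Contiguous runs of suprathreshold bins
#' form candidate bursts; runs separated by at most `gap_bins` subthreshold
#' bins are merged. A candidate qualifies as a network burst only if its
#' peak 50-ms bin holds at least `min_spikes` spikes on at least
#' `min_electrodes` distinct electrodes.
#'
#' With `refine = TRUE` (default) burst bounds are the first and last spike
#' times inside the suprathreshold run; with `refine = FALSE` they are the
#' outer bin edges. Bin-edge bounds quantize durations by up to one bin per
#' side, which matters for sub-second bursts.
#'
#' @param tsr a [compute_tsr()] series.
#' @param raster the [spike_raster()] the TSR was computed from.
#' @param threshold_coeff multiplier on `sd(TSR)` for the burst threshold.
#' @param min_spikes,min_electrodes acceptance criterion applied to the
#'   burst's peak bin (the classical ">= 4 spikes on >= 4 electrodes in
#'   50 ms" definition).
#' @param gap_bins merge suprathreshold runs separated by at most this many
#'   subthreshold bins.
#' @param refine refine bounds to actual first/last spike times.
#' @return object of class `network_bursts`: data frame with columns
#'   `start`, `end` (s), `n_spikes`, `n_electrodes`, `peak_spikes`,
#'   `peak_electrodes`; attribute `threshold` holds `T_burst`.
#' @export
detect_network_bursts <- function(tsr, raster, threshold_coeff = 0.1,
                                  min_spikes = 4, min_electrodes = 4,
                                  gap_bins = 1, refine = TRUE) {
  stopifnot(inherits(tsr, "tsr_series"), inherits(raster, "spike_raster"))
  if (threshold_coeff <= 0) stop_invalid("threshold_coeff must be positive")
  if (abs(tsr$duration - raster$duration) > tsr$bin_width) {
    stop_invalid("tsr and raster cover different intervals")
  }
  empty <- data.frame(start = numeric(0), end = numeric(0),
                      n_spikes = integer(0), n_electrodes = integer(0),
                      peak_spikes = integer(0), peak_electrodes = integer(0))
  sigma_tsr <- sd(tsr$counts)
  if (is.na(sigma_tsr) || sigma_tsr == 0) {
    return(structure(empty, threshold = 0, class = c("network_bursts",
                                                     "data.frame")))
  }
  t_burst <- threshold_coeff * sigma_tsr
  supra <- tsr$counts > t_burst
  if (!any(supra)) {
    return(structure(empty, threshold = t_burst,
                     class = c("network_bursts", "data.frame")))
  }
  r <- rle(supra)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  runs <- cbind(start = starts[r$values], end = ends[r$values])
  ## merge runs separated by <= gap_bins subthreshold bins
  merged <- list()
  cur <- runs[1, ]
  if (nrow(runs) > 1) {
    for (k in 2:nrow(runs)) {
      if (runs[k, "start"] - cur["end"] - 1L <= gap_bins) {
        cur["end"] <- runs[k, "end"]
      } else {
        merged[[length(merged) + 1L]] <- cur
        cur <- runs[k, ]
      }
    }
  }
  merged[[length(merged) + 1L]] <- cur

  bw <- tsr$bin_width
  tt <- raster$spikes$time
  ch <- raster$spikes$channel
  rows <- lapply(merged, function(rn) {
    t0 <- (rn["start"] - 1L) * bw
    t1 <- rn["end"] * bw
    sel <- which(tt >= t0 & tt < t1)
    if (!length(sel)) return(NULL)
    seg <- rn["start"]:rn["end"]
    pk <- seg[which.max(tsr$counts[seg])]
    pk_sel <- sel[tt[sel] >= (pk - 1L) * bw & tt[sel] < pk * bw]
    peak_spikes <- length(pk_sel)
    peak_electrodes <- length(unique(ch[pk_sel]))
    if (peak_spikes < min_spikes || peak_electrodes < min_electrodes) {
      return(NULL)
    }
    if (refine) {
      start <- min(tt[sel]); end <- max(tt[sel])
    } else {
      start <- t0; end <- t1
    }
    data.frame(start = start, end = end,
               n_spikes = length(sel),
               n_electrodes = length(unique(ch[sel])),
               peak_spikes = peak_spikes,
               peak_electrodes = peak_electrodes)
  })
  rows <- rows[!vapply(rows, is.null, logical(1))]
  out <- if (length(rows)) do.call(rbind, rows) else empty
  rownames(out) <- NULL
  structure(out, threshold = t_burst,
            class = c("network_bursts", "data.frame"))
}

#' Classify network bursts as small or large
#'
#' Size class is assigned from the burst's maximum 50-ms-bin spike count:
#' 4-100 spikes is a small burst, 101 or more a large one (bursts below 4
#' are rejected upstream by [detect_network_bursts()]).
#'
#' @param bursts a `network_bursts` data frame.
#' @param large_threshold minimum peak-bin spike count of a large burst.
#' @return the input with an added `size_class` column (`"small"`/`"large"`).
#' @export
classify_bursts <- function(bursts, large_threshold = 101) {
  stopifnot(inherits(bursts, "network_bursts"))
  bursts$size_class <- ifelse(bursts$peak_spikes >= large_threshold,
                              "large", "small")
  bursts
}

#' Summary statistics of network-burst activity
#'
#' @param bursts a classified `network_bursts` data frame (see
#'   [classify_bursts()]).
#' @param recording_duration recording length in seconds.
#' @return list with `n_large_per_5min`, `n_small_per_5min`,
#'   `mean_spikes_per_large_burst`, `mean_burst_duration` (s).
#' @export
burst_statistics <- function(bursts, recording_duration) {
  stopifnot(inherits(bursts, "network_bursts"))
  if (recording_duration <= 0) stop_invalid("recording_duration must be positive")
  if (is.null(bursts$size_class)) bursts <- classify_bursts(bursts)
  scale5 <- 300 / recording_duration
  large <- bursts[bursts$size_class == "large", , drop = FALSE]
  small <- bursts[bursts$size_class == "small", , drop = FALSE]
  list(
    n_large_per_5min = nrow(large) * scale5,
    n_small_per_5min = nrow(small) * scale5,
    mean_spikes_per_large_burst =
      if (nrow(large)) mean(large$n_spikes) else 0,
    mean_burst_duration =
      if (nrow(bursts)) mean(bursts$end - bursts$start) else 0
  )
}

#' Network activation profile of a burst
#'
#' For each electrode firing inside the burst, the latency of its first
#' spike relative to the burst start. The latency ordering exposes how
#' activity propagates from the burst-initiating site through the network;
#' silent electrodes are omitted.
#'
#' @param burst one row of a `network_bursts` data frame (or any list with
#'   `start` and `end` in seconds).
#' @param raster the [spike_raster()].
#' @return data frame with columns `electrode` and `latency_ms`, sorted by
#'   latency.
#' @export
activation_profile <- function(burst, raster) {
  stopifnot(inherits(raster, "spike_raster"))
  start <- burst$start; end <- burst$end
  if (is.null(start) || is.null(end) || end <= start) {
    stop_invalid("burst must have start < end")
  }
  if (start < 0 || end > raster$duration) {
    stop_invalid("burst lies outside the raster interval")
  }
  sel <- raster$spikes$time >= start & raster$spikes$time <= end
  if (!any(sel)) {
    return(data.frame(electrode = integer(0), latency_ms = numeric(0)))
  }
  first <- tapply(raster$spikes$time[sel], raster$spikes$channel[sel], min)
  out <- data.frame(electrode = as.integer(names(first)),
                    latency_ms = 1000 * (as.numeric(first) - start))
  out <- out[order(out$latency_ms), , drop = FALSE]
  rownames(out) <- NULL
  out
}
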