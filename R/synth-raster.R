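#' Configuration for the spike-raster generator
#'
#' Parameters of the planted-activity model: homogeneous Poisson background
#' spiking on each electrode, network bursts drawn from a hard-core renewal
#' process (each burst a cloud of spikes spread over a chosen electrode span
#' within a short interval), and optional hub-structured spike propagation
#' with distance-proportional conduction delays.
#'
#' @param duration recording length, seconds.
#' @param background_rate basal Poisson rate, spikes/s/electrode.
#' @param background_electrodes optional integer subset of electrode ids that
#'   carry background activity; `NULL` means all electrodes.
#' @param burst_rate network-burst rate, bursts/s. The generator uses renewal
#'   intervals `duration + gap + Exp(slack)` whose mean equals `1/burst_rate`,
#'   so the planted stationary rate matches the configured one exactly while
#'   bursts never overlap.
#' @param burst_duration_mean,burst_duration_sd mean and SD of the burst
#'   envelope length, seconds (`sd = 0` gives fixed-length bursts).
#' @param spikes_per_burst_mean mean number of spikes per burst (Poisson).
#' @param burst_electrode_span number of distinct electrodes each burst is
#'   spread over (must be >= 4, the defining span of a network burst).
#' @param burst_envelope `"gaussian"` (truncated at +-2 SD, SD = duration/4;
#'   a sharp-onset bell, the default) or `"uniform"` (constant spike density
#'   up to the bounds; the right choice when planted bursts must have crisp
#'   boundaries, e.g. for duration-accuracy validation).
#' @param burst_min_gap guaranteed silent gap between consecutive bursts,
#'   seconds.
#' @param hub_ids electrode ids acting as hubs (sources of planted functional
#'   edges); empty for none.
#' @param hub_out_degree number of target electrodes per hub.
#' @param propagation_probability per-edge probability that a source spike is
#'   copied to the target, in \[0, 1\].
#' @param conduction_velocity propagation speed, um/ms; a copied spike
#'   arrives delayed by distance/velocity.
#' @param jitter_sd Gaussian jitter SD added to each propagation delay, ms.
#' @param seed integer RNG seed; all generator randomness flows from it.
#' @return a `raster_sim_config` list.
#' @export
raster_sim_config <- function(duration = 300,
                              background_rate = 0.1,
                              background_electrodes = NULL,
                              burst_rate = 0,
                              burst_duration_mean = 0.3,
                              burst_duration_sd = 0,
                              spikes_per_burst_mean = 100,
                              burst_electrode_span = 59,
                              burst_envelope = c("gaussian", "uniform"),
                              burst_min_gap = 0.15,
                              hub_ids = integer(),
                              hub_out_degree = 12,
                              propagation_probability = 0,
                              conduction_velocity = 300,
                              jitter_sd = 0,
                              seed = 1L) {
  burst_envelope <- match.arg(burst_envelope)
  cfg <- list(
    duration = duration,
    background_rate = background_rate,
    background_electrodes = background_electrodes,
    burst_rate = burst_rate,
    burst_duration_mean = burst_duration_mean,
    burst_duration_sd = burst_duration_sd,
    spikes_per_burst_mean = spikes_per_burst_mean,
    burst_electrode_span = as.integer(burst_electrode_span),
    burst_envelope = burst_envelope,
    burst_min_gap = burst_min_gap,
    hub_ids = as.integer(hub_ids),
    hub_out_degree = as.integer(hub_out_degree),
    propagation_probability = propagation_probability,
    conduction_velocity = conduction_velocity,
    jitter_sd = jitter_sd,
    seed = seed
  )
  class(cfg) <- "raster_sim_config"
  cfg
}

validate_raster_config <- function(config, geometry) {
  if (!is.numeric(config$duration) || config$duration <= 0) {
    stop_invalid("invalid config: duration must be positive")
  }
  if (config$background_rate < 0 || config$burst_rate < 0) {
    stop_invalid("invalid config: rates must be non-negative")
  }
  if (config$burst_rate > 0) {
    if (config$burst_electrode_span < 4) {
      stop_invalid("invalid config: burst_electrode_span must be >= 4")
    }
    if (config$burst_electrode_span > geometry$n_electrodes) {
      stop_invalid("invalid config: burst_electrode_span exceeds electrode count")
    }
    if (config$burst_duration_mean <= 0) {
      stop_invalid("invalid config: burst_duration_mean must be positive")
    }
    mean_interval <- 1 / config$burst_rate
    if (mean_interval <= config$burst_duration_mean + config$burst_min_gap) {
      stop_invalid(paste(
        "invalid config: burst_rate too high for the configured burst",
        "duration and minimum gap (bursts would overlap)"))
    }
  }
  if (config$propagation_probability < 0 || config$propagation_probability > 1) {
    stop_invalid("invalid config: propagation_probability must be in [0, 1]")
  }
  if (length(config$hub_ids) &&
      !all(config$hub_ids %in% geometry$electrode_ids)) {
    stop_invalid("invalid config: hub_ids not present in geometry")
  }
  if (!is.null(config$background_electrodes) &&
      !all(config$background_electrodes %in% geometry$electrode_ids)) {
    stop_invalid("invalid config: background_electrodes not in geometry")
  }
  invisible(config)
}

#' Simulate a spike raster with planted ground truth
#'
#' Generates background Poisson spiking, non-overlapping network bursts, and
#' (optionally) hub-structured propagated spikes with distance-proportional
#' delays, and returns both the raster and the planted ground truth.
#'
#' Ground-truth burst intervals record the *realized* bounds — the first and
#' last planted spike of each burst after the per-channel minimal-ISI rule is
#' applied — together with the surviving spike count, since these are the
#' quantities a detector can be asked to recover.
#'
#' @param config a [raster_sim_config()].
#' @param geometry an [mea_geometry()].
#' @return list with elements `raster` (a [spike_raster()]) and
#'   `ground_truth`: list with `burst_intervals` (data frame `start`, `end`,
#'   `n_spikes`), `edges` (data frame `source`, `target`, `probability`) and
#'   the realized per-channel spike counts.
#' @examples
#' sim <- simulate_raster(raster_sim_config(duration = 10, burst_rate = 0.5,
#'                                          spikes_per_burst_mean = 50,
#'                                          seed = 7))
#' n_spikes(sim$raster)
#' @export
simulate_raster <- function(config, geometry = mea_geometry()) {
  stopifnot(inherits(config, "raster_sim_config"))
  validate_geometry(geometry)
  validate_raster_config(config, geometry)
  ids <- geometry$electrode_ids
  dur <- config$duration
  min_isi <- 1e-3

  with_seed(config$seed, {
    channel <- integer(0)
    time <- numeric(0)
    burst_tag <- integer(0) # 0 = background / propagated, k = burst k

    ## background: homogeneous Poisson per electrode
    bg_ids <- config$background_electrodes %||% ids
    if (config$background_rate > 0) {
      for (id in bg_ids) {
        n <- rpois(1L, config$background_rate * dur)
        if (n > 0) {
          channel <- c(channel, rep.int(id, n))
          time <- c(time, runif(n, 0, dur))
          burst_tag <- c(burst_tag, rep.int(0L, n))
        }
      }
    }

    ## network bursts: hard-core renewal onsets
    n_bursts <- 0L
    if (config$burst_rate > 0) {
      mean_interval <- 1 / config$burst_rate
      slack <- mean_interval - config$burst_duration_mean - config$burst_min_gap
      prev_end <- -runif(1) * mean_interval # random phase
      repeat {
        d <- config$burst_duration_mean
        if (config$burst_duration_sd > 0) {
          d <- max(0.02, rnorm(1, d, config$burst_duration_sd))
        }
        onset <- prev_end + config$burst_min_gap + rexp(1, 1 / slack)
        if (onset < 0) onset <- 0
        if (onset + d >= dur) break
        n_b <- rpois(1L, config$spikes_per_burst_mean)
        if (n_b > 0L) {
          n_bursts <- n_bursts + 1L
          elec <- sample(ids, config$burst_electrode_span)
          tt <- switch(config$burst_envelope,
            uniform = runif(n_b, onset, onset + d),
            gaussian = {
              u <- runif(n_b, pnorm(-2), pnorm(2))
              onset + d / 2 + qnorm(u) * d / 4
            })
          channel <- c(channel, sample(elec, n_b, replace = TRUE))
          time <- c(time, tt)
          burst_tag <- c(burst_tag, rep.int(n_bursts, n_b))
        }
        prev_end <- onset + d
      }
    }

    ## hub propagation along planted directed edges
    edges <- data.frame(source = integer(0), target = integer(0),
                        probability = numeric(0))
    if (length(config$hub_ids) && config$hub_out_degree > 0) {
      dmat <- electrode_distances(geometry)
      for (h in config$hub_ids) {
        targets <- sample(setdiff(ids, h),
                          min(config$hub_out_degree,
                              geometry$n_electrodes - 1L))
        edges <- rbind(edges, data.frame(
          source = h, target = targets,
          probability = config$propagation_probability))
      }
      ## propagate from the pre-propagation spikes only (single hop)
      src_channel <- channel
      src_time <- time
      for (k in seq_len(nrow(edges))) {
        src_t <- src_time[src_channel == edges$source[k]]
        if (!length(src_t)) next
        sel <- runif(length(src_t)) < edges$probability[k]
        if (!any(sel)) next
        delay_ms <- dmat[as.character(edges$source[k]),
                         as.character(edges$target[k])] /
          config$conduction_velocity
        tcopy <- src_t[sel] + delay_ms / 1000
        if (config$jitter_sd > 0) {
          tcopy <- tcopy + rnorm(length(tcopy), 0, config$jitter_sd / 1000)
        }
        ok <- tcopy >= 0 & tcopy < dur
        if (any(ok)) {
          channel <- c(channel, rep.int(edges$target[k], sum(ok)))
          time <- c(time, tcopy[ok])
          burst_tag <- c(burst_tag, rep.int(0L, sum(ok)))
        }
      }
    }

    ## per-channel sort + minimal-ISI rule
    if (length(time)) {
      ord <- order(channel, time)
      channel <- channel[ord]; time <- time[ord]; burst_tag <- burst_tag[ord]
      keep <- logical(length(time))
      for (id in unique(channel)) {
        idx <- which(channel == id)
        keep[idx] <- dedup_mask(time[idx], min_isi)
      }
      channel <- channel[keep]; time <- time[keep]; burst_tag <- burst_tag[keep]
    }

    ## realized ground truth
    if (n_bursts > 0L) {
      bi <- lapply(seq_len(n_bursts), function(k) {
        tk <- time[burst_tag == k]
        if (!length(tk)) return(NULL)
        data.frame(start = min(tk), end = max(tk), n_spikes = length(tk))
      })
      burst_intervals <- do.call(rbind, bi)
      burst_intervals <- burst_intervals[order(burst_intervals$start), ,
                                         drop = FALSE]
      rownames(burst_intervals) <- NULL
    } else {
      burst_intervals <- data.frame(start = numeric(0), end = numeric(0),
                                    n_spikes = integer(0))
    }

    raster <- spike_raster(
      data.frame(channel = channel, time = time),
      duration = dur, geometry = geometry, min_isi = min_isi)
    list(
      raster = raster,
      ground_truth = list(
        burst_intervals = burst_intervals,
        edges = edges,
        n_spikes_per_channel = table(factor(channel, levels = ids))
      )
    )
  })
}

#' Synthesize extracellular voltage from a spike raster
#'
#' Adds a biphasic (negative-then-positive) 1-ms spike waveform of the given
#' peak amplitude at each raster spike time on top of Gaussian noise. The
#' waveform's extremal (negative) peak is aligned to the spike time, matching
#' the detector's extremal-sample timestamp convention.
#'
#' @param raster a [spike_raster()].
#' @param noise_sd Gaussian noise SD per channel, uV.
#' @param spike_amplitude waveform peak magnitude, uV (> 0).
#' @param sample_rate sampling rate, Hz.
#' @param waveform_duration_ms length of the biphasic template, ms.
#' @param seed RNG seed for the noise.
#' @return object of class `voltage_recording`: list with `data` (matrix,
#'   samples x channels, uV), `sample_rate`, `duration`, `channel_ids`,
#'   `geometry`.
#' @export
simulate_voltage <- function(raster, noise_sd = 5, spike_amplitude = 30,
                             sample_rate = 20000, waveform_duration_ms = 1,
                             seed = 1L) {
  stopifnot(inherits(raster, "spike_raster"))
  if (spike_amplitude <= 0) stop_invalid("spike_amplitude must be positive")
  if (noise_sd < 0) stop_invalid("noise_sd must be non-negative")
  n_samp <- round(raster$duration * sample_rate)
  if (nrow(raster$spikes) &&
      any(round(raster$spikes$time * sample_rate) >= n_samp)) {
    stop_invalid("spike times extend beyond the recording duration")
  }
  ids <- raster$geometry$electrode_ids
  L <- max(4L, round(sample_rate * waveform_duration_ms / 1000))
  w <- -spike_amplitude * sin(2 * pi * seq(0, L - 1) / L)
  peak <- which.max(abs(w)) # index of extremal (negative) lobe

  with_seed(seed, {
    data <- if (noise_sd > 0) {
      matrix(rnorm(n_samp * length(ids), 0, noise_sd), n_samp, length(ids))
    } else {
      matrix(0, n_samp, length(ids))
    }
    colnames(data) <- ids
    if (nrow(raster$spikes)) {
      col <- match(raster$spikes$channel, ids)
      centre <- round(raster$spikes$time * sample_rate) + 1L
      for (k in seq_along(col)) {
        i0 <- centre[k] - peak + 1L
        src <- seq_len(L)
        idx <- i0 + src - 1L
        ok <- idx >= 1L & idx <= n_samp
        data[idx[ok], col[k]] <- data[idx[ok], col[k]] + w[src[ok]]
      }
    }
    structure(
      list(data = data, sample_rate = sample_rate,
           duration = raster$duration, channel_ids = ids,
           geometry = raster$geometry),
      class = "voltage_recording")
  })
}

#' @export
print.voltage_recording <- function(x, ...) {
  cat(sprintf("<voltage_recording> %d channels, %.1f s @ %g kHz\n",
              ncol(x$data), x$duration, x$sample_rate / 1000))
  invisible(x)
}
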