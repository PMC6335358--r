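#' Spike raster container
#'
#' A spike raster holds per-electrode ordered spike times over a fixed
#' recording duration — the hinge between spike detection, burst analysis
#' and connectivity inference.
#'
#' @param spikes data frame with integer column `channel` (electrode id) and
#'   numeric column `time` (seconds). May have zero rows.
#' @param duration recording duration in seconds.
#' @param geometry the [mea_geometry()] the channels refer to.
#' @param min_isi minimal inter-spike interval (seconds) the raster is
#'   expected to respect per channel; stored for reference.
#' @return object of class `spike_raster`: list with `spikes` (sorted by
#'   channel then time), `duration`, `geometry`, `min_isi`.
#' @export
spike_raster <- function(spikes, duration, geometry = mea_geometry(),
                         min_isi = 1e-3) {
  stopifnot(is.data.frame(spikes), all(c("channel", "time") %in% names(spikes)))
  if (!is.numeric(duration) || length(duration) != 1L || duration <= 0) {
    stop_invalid("duration must be a positive scalar")
  }
  validate_geometry(geometry)
  spikes <- data.frame(channel = as.integer(spikes$channel),
                       time = as.numeric(spikes$time))
  if (nrow(spikes)) {
    if (any(!spikes$channel %in% geometry$electrode_ids)) {
      stop_invalid("raster contains channels absent from the geometry")
    }
    if (any(spikes$time < 0 | spikes$time >= duration)) {
      stop_invalid("spike times must lie in [0, duration)")
    }
    spikes <- spikes[order(spikes$channel, spikes$time), , drop = FALSE]
    rownames(spikes) <- NULL
  }
  structure(
    list(spikes = spikes, duration = duration, geometry = geometry,
         min_isi = min_isi),
    class = "spike_raster"
  )
}

#' Number of spikes in a raster
#' @param raster a [spike_raster()].
#' @return integer spike count.
#' @export
n_spikes <- function(raster) {
  stopifnot(inherits(raster, "spike_raster"))
  nrow(raster$spikes)
}

# split spike times by channel, covering every electrode in the geometry
# (empty channels give numeric(0))
channel_times <- function(raster) {
  ids <- raster$geometry$electrode_ids
  out <- split(raster$spikes$time,
               factor(raster$spikes$channel, levels = ids))
  lapply(out, as.numeric)
}

#' @export
print.spike_raster <- function(x, ...) {
  cat(sprintf(
    "<spike_raster> %d spikes on %d/%d electrodes, %.1f s\n",
    nrow(x$spikes), length(unique(x$spikes$channel)),
    x$geometry$n_electrodes, x$duration))
  invisible(x)
}

#' Raster plot of spike times
#'
#' Basic diagnostic raster diagram: one row per electrode, a tick per spike.
#'
#' @param x a [spike_raster()].
#' @param ... passed to [graphics::plot()].
#' @export
plot.spike_raster <- function(x, ...) {
  ids <- x$geometry$electrode_ids
  row <- match(x$spikes$channel, ids)
  graphics::plot(x$spikes$time, row, pch = "|", cex = 0.5,
                 xlab = "time (s)", ylab = "electrode", yaxt = "n",
                 xlim = c(0, x$duration), ylim = c(0.5, length(ids) + 0.5),
                 ...)
  graphics::axis(2, at = seq_along(ids), labels = ids, cex.axis = 0.4, las = 2)
  invisible(x)
}
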