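# small geometries and hand-built objects used across tests

geo6 <- function() {
  mea_geometry(n_rows = 2, n_cols = 3, drop_corners = FALSE,
               reference_id = NA)
}

geo4 <- function() {
  mea_geometry(n_rows = 2, n_cols = 2, drop_corners = FALSE,
               reference_id = NA)
}

make_raster <- function(channel, time, duration, geometry = geo6()) {
  spike_raster(data.frame(channel = channel, time = time),
               duration = duration, geometry = geometry)
}

empty_raster <- function(duration = 10, geometry = geo6()) {
  make_raster(integer(0), numeric(0), duration, geometry)
}

# voltage recording built directly from a sample matrix (zero-noise tests)
make_recording <- function(data, sample_rate = 20000, geometry = NULL) {
  data <- as.matrix(data)
  geometry <- geometry %||%
    mea_geometry(n_rows = 2, n_cols = max(2, ceiling(ncol(data) / 2)),
                 drop_corners = FALSE, reference_id = NA)
  ids <- geometry$electrode_ids[seq_len(ncol(data))]
  colnames(data) <- ids
  structure(
    list(data = data, sample_rate = sample_rate,
         duration = nrow(data) / sample_rate,
         channel_ids = ids, geometry = geometry),
    class = "voltage_recording")
}

`%||%` <- function(x, y) if (is.null(x)) y else x

# a hand-made network_bursts table (for statistics arithmetic)
make_bursts <- function(start, end, n_spikes, peak_spikes,
                        n_electrodes = 5L) {
  n_electrodes <- rep_len(n_electrodes, length(start))
  structure(
    data.frame(start = start, end = end, n_spikes = n_spikes,
               n_electrodes = n_electrodes, peak_spikes = peak_spikes,
               peak_electrodes = n_electrodes),
    class = c("network_bursts", "data.frame"))
}
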