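# independent brute-force oracles

# exhaustive O(n_i * n_j) pair scan: a j-spike is delayed-synchronous with
# channel i if some i-spike shifted by tau_ij lies within +-delta/2 of it
brute_force_synchrony <- function(raster, velocity = 300, delta_ms = 2) {
  geo <- raster$geometry
  ids <- geo$electrode_ids
  dm <- electrode_distances(geo)
  half <- delta_ms / 2000
  n <- length(ids)
  M <- matrix(0L, n, n, dimnames = list(ids, ids))
  tl <- split(raster$spikes$time,
              factor(raster$spikes$channel, levels = ids))
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (i == j) next
      ti <- tl[[i]]
      tj <- tl[[j]]
      if (!length(ti) || !length(tj)) next
      tau <- dm[i, j] / velocity / 1000
      cnt <- 0L
      for (t2 in tj) {
        if (any(abs(t2 - ti - tau) <= half + 1e-12)) cnt <- cnt + 1L
      }
      M[i, j] <- cnt
    }
  }
  M
}

# match detected bursts to planted intervals by maximal overlap and return
# per-planted-burst relative duration errors (1 for a missed burst)
burst_duration_errors <- function(detected, planted) {
  vapply(seq_len(nrow(planted)), function(k) {
    if (!nrow(detected)) return(1)
    ov <- pmin(detected$end, planted$end[k]) -
      pmax(detected$start, planted$start[k])
    j <- which.max(ov)
    if (ov[j] <= 0) return(1)
    pd <- planted$end[k] - planted$start[k]
    abs((detected$end[j] - detected$start[j]) - pd) / pd
  }, numeric(1))
}
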