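#' Pairwise conduction delays between electrodes
#'
#' Delays are proportional to electrode distance: `tau_ij = d_ij / velocity`,
#' with zero on the diagonal.
#'
#' @param geometry an [mea_geometry()].
#' @param velocity conduction velocity, um/ms.
#' @return symmetric matrix of delays in ms, dimnames = electrode ids.
#' @export
pairwise_delays <- function(geometry, velocity = 300) {
  if (velocity <= 0) stop_invalid("invalid parameter: velocity must be positive")
  electrode_distances(geometry) / velocity
}

#' Delayed-synchrony cross-correlation matrix
#'
#' For every ordered electrode pair (i, j), counts the spikes on j that fall
#' within a tolerance window `[t_i + tau_ij - delta/2, t_i + tau_ij + delta/2]`
#' around some spike `t_i` on i shifted by the conduction delay `tau_ij`
#' (each j-spike counted at most once), and normalizes by the number of
#' spikes received by the putative postsynaptic channel:
#' `C_ij = n_synchr_ij / n_j`. This proportion of transmitted spikes is the
#' spike-train analogue of a cross-correlation coefficient.
#'
#' @param raster a [spike_raster()].
#' @param velocity conduction velocity, um/ms (sets `tau` via
#'   [pairwise_delays()]).
#' @param delta_ms tolerance interval `delta`, ms.
#' @return object of class `connectivity_matrix`: list with `C` (n x n,
#'   in \[0,1\], zero diagonal), `n_synchr`, `n_post` (spike count per
#'   electrode), `delay` (ms), `delta_ms`, `velocity` and `undefined`
#'   (logical matrix flagging pairs with an empty target channel, whose
#'   coefficient is reported as 0).
#' @export
delayed_synchrony <- function(raster, velocity = 300, delta_ms = 2) {
  stopifnot(inherits(raster, "spike_raster"))
  if (delta_ms <= 0) stop_invalid("delta_ms must be positive")
  geometry <- raster$geometry
  ids <- geometry$electrode_ids
  n <- length(ids)
  tau <- pairwise_delays(geometry, velocity) # ms
  half <- delta_ms / 2000 # s
  times <- channel_times(raster)
  C <- matrix(0, n, n, dimnames = list(ids, ids))
  n_synchr <- matrix(0L, n, n, dimnames = list(ids, ids))
  undefined <- matrix(FALSE, n, n, dimnames = list(ids, ids))
  n_post <- vapply(times, length, integer(1))
  for (i in seq_len(n)) {
    ti <- times[[i]]
    for (j in seq_len(n)) {
      if (i == j) next
      tj <- times[[j]]
      if (!length(tj)) {
        undefined[i, j] <- TRUE
        next
      }
      if (!length(ti)) next
      ## a j-spike is delayed-synchronous if some i-spike (shifted by tau)
      ## lies within +-delta/2 of it
      x <- tj - tau[i, j] / 1000
      pos <- findInterval(x, ti)
      lo <- pos >= 1L
      near_left <- lo & (x - ti[pmax(pos, 1L)]) <= half + 1e-12
      hi <- pos < length(ti)
      near_right <- hi & (ti[pmin(pos + 1L, length(ti))] - x) <= half + 1e-12
      m <- sum(near_left | near_right)
      n_synchr[i, j] <- m
      C[i, j] <- m / length(tj)
    }
  }
  structure(
    list(C = C, n_synchr = n_synchr, n_post = n_post, delay = tau,
         delta_ms = delta_ms, velocity = velocity, undefined = undefined),
    class = "connectivity_matrix")
}

#' @export
print.connectivity_matrix <- function(x, ...) {
  cat(sprintf(
    "<connectivity_matrix> %d electrodes, delta = %g ms, velocity = %g um/ms\n",
    nrow(x$C), x$delta_ms, x$velocity))
  cat(sprintf("  max C = %.3f, nonzero pairs = %d\n",
              max(x$C), sum(x$C > 0)))
  invisible(x)
}

#' Significant-edge functional graph
#'
#' Retains the largest `fraction` (default 5%) of the delayed-synchrony
#' coefficients over all `n * (n - 1)` admissible ordered pairs and builds
#' the directed functional graph. Exactly `floor(fraction * n * (n - 1))`
#' edges are retained (fewer if not that many positive coefficients exist);
#' ties at the cut are broken by lexicographic (source, target) order so the
#' selection is deterministic.
#'
#' @param cm a [delayed_synchrony()] connectivity matrix.
#' @param fraction fraction of admissible ordered pairs retained, in (0, 1).
#' @return a directed [igraph][igraph::graph_from_data_frame] graph whose
#'   vertices are all electrodes (names = ids) and whose edges carry the
#'   coefficient as `weight`.
#' @export
significant_edges <- function(cm, fraction = 0.05) {
  stopifnot(inherits(cm, "connectivity_matrix"))
  if (fraction <= 0 || fraction >= 1) {
    stop_invalid("fraction must be in (0, 1)")
  }
  ids <- rownames(cm$C)
  n <- length(ids)
  k <- floor(fraction * n * (n - 1))
  src <- rep(seq_len(n), times = n)
  tgt <- rep(seq_len(n), each = n)
  off <- src != tgt
  src <- src[off]; tgt <- tgt[off]
  w <- cm$C[cbind(src, tgt)]
  ord <- order(-w, src, tgt)
  take <- ord[seq_len(min(k, length(ord)))]
  take <- take[w[take] > 0]
  edges <- data.frame(from = ids[src[take]], to = ids[tgt[take]],
                      weight = w[take])
  g <- igraph::graph_from_data_frame(edges, directed = TRUE,
                                     vertices = data.frame(name = ids))
  g <- igraph::set_graph_attr(g, "fraction", fraction)
  g
}

#' Hub electrodes of a functional graph
#'
#' Hubs are the electrodes carrying a disproportionately large number of
#' significant connections: total degree (in + out) of at least
#' `min_degree`. The default of 10 reflects the typical connections-per-hub
#' scale in maturing cultures.
#'
#' @param graph a directed functional graph from [significant_edges()].
#' @param min_degree minimum total degree of a hub.
#' @return object of class `hub_set`: list with `hubs` (data frame
#'   `electrode`, `connections`, `hub_coefficient`, sorted by decreasing
#'   degree), `n_hubs`, `mean_connections` and `degree` (named vector over
#'   all electrodes).
#' @export
find_hubs <- function(graph, min_degree = 10) {
  stopifnot(igraph::is_igraph(graph))
  deg <- igraph::degree(graph, mode = "all")
  m <- igraph::ecount(graph)
  hub_idx <- which(deg >= min_degree)
  hubs <- data.frame(
    electrode = as.integer(names(deg)[hub_idx]),
    connections = as.integer(deg[hub_idx]),
    hub_coefficient = if (m > 0) deg[hub_idx] / m else rep(NA_real_,
                                                           length(hub_idx)))
  hubs <- hubs[order(-hubs$connections, hubs$electrode), , drop = FALSE]
  rownames(hubs) <- NULL
  structure(
    list(hubs = hubs,
         n_hubs = nrow(hubs),
         mean_connections = if (nrow(hubs)) mean(hubs$connections) else 0,
         degree = deg),
    class = "hub_set")
}

#' @export
print.hub_set <- function(x, ...) {
  cat(sprintf("<hub_set> %d hubs, mean connections %.2f\n",
              x$n_hubs, x$mean_connections))
  invisible(x)
}

#' Hub coefficient of an electrode
#'
#' The ratio of an electrode's connection count to the total number of
#' connections in the graph — the electrode's share of the network's
#' functional links.
#'
#' @param graph a functional graph from [significant_edges()].
#' @param electrode electrode id.
#' @return fraction in \[0, 1\].
#' @export
hub_coefficient <- function(graph, electrode) {
  stopifnot(igraph::is_igraph(graph))
  m <- igraph::ecount(graph)
  if (m == 0) stop_invalid("hub coefficient undefined on a graph with no edges")
  v <- as.character(electrode)
  if (!v %in% igraph::V(graph)$name) {
    stop_invalid("electrode %s not in graph", v)
  }
  unname(igraph::degree(graph, v = v, mode = "all") / m)
}

#' Percentage of functional connections shared by two sessions
#'
#' Overlap between two functional graphs of the same culture (e.g. two
#' recording days): the percentage of the first session's directed edges
#' also present in the second.
#'
#' @param g1,g2 functional graphs over the same vertex set.
#' @return overlap percentage in \[0, 100\].
#' @export
network_overlap <- function(g1, g2) {
  stopifnot(igraph::is_igraph(g1), igraph::is_igraph(g2))
  v1 <- igraph::V(g1)$name
  v2 <- igraph::V(g2)$name
  if (!setequal(v1, v2)) stop_invalid("graphs must share one vertex set")
  e1 <- igraph::as_edgelist(g1)
  e2 <- igraph::as_edgelist(g2)
  if (nrow(e1) == 0) {
    stop_invalid("overlap undefined: first graph has no edges")
  }
  key1 <- paste(e1[, 1], e1[, 2], sep = "->")
  key2 <- paste(e2[, 1], e2[, 2], sep = "->")
  100 * length(intersect(key1, key2)) / length(unique(key1))
}
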