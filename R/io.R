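#' Write / read a spike raster as CSV
#'
#' Column layout: `channel_id, spike_time_s`, preceded by a comment line
#' carrying the recording duration. Times are serialized with 17 significant
#' digits so a write -> read round trip reproduces them bit for bit.
#'
#' @param raster a [spike_raster()].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_raster <- function(raster, path) {
  stopifnot(inherits(raster, "spike_raster"))
  lines <- c(
    sprintf("# duration_s=%.17g", raster$duration),
    "channel_id,spike_time_s",
    sprintf("%d,%.17g", raster$spikes$channel, raster$spikes$time)
  )
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_raster
#' @param geometry geometry the channels refer to.
#' @param strict if `TRUE`, malformed rows, negative times or unsorted
#'   channels abort with an error naming the offending line; otherwise
#'   offending rows are dropped/repaired with a warning.
#' @return for `read_raster`, a [spike_raster()].
#' @export
read_raster <- function(path, geometry = mea_geometry(), strict = FALSE) {
  lines <- readLines(path)
  duration <- NA_real_
  if (length(lines) && startsWith(lines[1], "#")) {
    m <- regmatches(lines[1], regexec("duration_s=([-0-9.eE+]+)", lines[1]))[[1]]
    if (length(m) == 2) duration <- as.numeric(m[2])
    lines <- lines[-1]
  }
  if (!length(lines) || lines[1] != "channel_id,spike_time_s") {
    stop_invalid("%s: expected header 'channel_id,spike_time_s'", path)
  }
  body <- lines[-1]
  body_line_no <- seq_along(body) + (if (is.na(duration)) 1L else 2L)
  body <- body[nzchar(body)]
  parts <- strsplit(body, ",", fixed = TRUE)
  bad <- which(lengths(parts) != 2L)
  if (length(bad)) {
    stop_invalid("%s: malformed row at line %d", path, body_line_no[bad[1]])
  }
  channel <- suppressWarnings(as.integer(vapply(parts, `[`, "", 1L)))
  time <- suppressWarnings(as.numeric(vapply(parts, `[`, "", 2L)))
  bad <- which(is.na(channel) | is.na(time))
  if (length(bad)) {
    stop_invalid("%s: unparseable value at line %d", path, body_line_no[bad[1]])
  }
  neg <- which(time < 0)
  if (length(neg)) {
    if (strict) {
      stop_invalid("%s: negative spike time at line %d", path,
                   body_line_no[neg[1]])
    }
    warning(sprintf("%s: dropping %d negative spike time(s)", path,
                    length(neg)))
    channel <- channel[-neg]; time <- time[-neg]
  }
  if (is.unsorted(order(channel, time))) {
    if (strict) stop_invalid("%s: spike times are not sorted", path)
  }
  if (is.na(duration)) {
    duration <- if (length(time)) max(time) + 1e-6 else 1
  }
  spike_raster(data.frame(channel = channel, time = time),
               duration = duration, geometry = geometry)
}

#' Write / read fluorescence traces as CSV
#'
#' Layout: comment line with the frame rate, then `time_s` plus one
#' `roi_<id>` column per cell.
#'
#' @param traces a [fluorescence_traces()].
#' @param path file path.
#' @return `path` invisibly; `read_traces` returns a
#'   [fluorescence_traces()].
#' @export
write_traces <- function(traces, path) {
  stopifnot(inherits(traces, "fluorescence_traces"))
  t_s <- (seq_len(nrow(traces$intensity)) - 1) / traces$frame_rate
  header <- paste(c("time_s", paste0("roi_", traces$roi_ids)), collapse = ",")
  rows <- apply(cbind(t_s, traces$intensity), 1, function(v) {
    paste(sprintf("%.9g", v), collapse = ",")
  })
  writeLines(c(sprintf("# frame_rate_hz=%.17g", traces$frame_rate),
               header, rows), path)
  invisible(path)
}

#' @rdname write_traces
#' @export
read_traces <- function(path) {
  first <- readLines(path, n = 1L)
  frame_rate <- NA_real_
  skip <- 0L
  if (startsWith(first, "#")) {
    m <- regmatches(first, regexec("frame_rate_hz=([-0-9.eE+]+)", first))[[1]]
    if (length(m) == 2) frame_rate <- as.numeric(m[2])
    skip <- 1L
  }
  df <- read.csv(path, skip = skip, check.names = FALSE)
  roi_cols <- grep("^roi_", names(df))
  if (!length(roi_cols)) stop_invalid("%s: no roi_<id> columns found", path)
  if (is.na(frame_rate)) {
    dt <- diff(df$time_s)
    frame_rate <- 1 / median(dt)
  }
  fluorescence_traces(as.matrix(df[, roi_cols, drop = FALSE]),
                      frame_rate = frame_rate,
                      roi_ids = as.integer(sub("^roi_", "",
                                               names(df)[roi_cols])))
}

#' Write detected bursts as CSV
#'
#' @param bursts a (classified) `network_bursts` data frame.
#' @param path file path.
#' @export
write_bursts <- function(bursts, path) {
  stopifnot(inherits(bursts, "network_bursts"))
  if (is.null(bursts$size_class)) bursts <- classify_bursts(bursts)
  df <- data.frame(start_s = bursts$start, end_s = bursts$end,
                   n_spikes = bursts$n_spikes,
                   n_electrodes = bursts$n_electrodes,
                   class = bursts$size_class)
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Write a connectivity matrix as CSV plus JSON metadata
#'
#' @param cm a [delayed_synchrony()] result.
#' @param path_csv path of the coefficient-matrix CSV (electrode ids as row
#'   and column names).
#' @param path_json path of the metadata JSON (`delta_ms`, `velocity`,
#'   per-electrode spike counts).
#' @export
write_connectivity <- function(cm, path_csv, path_json) {
  stopifnot(inherits(cm, "connectivity_matrix"))
  write.csv(cm$C, path_csv, row.names = TRUE)
  jsonlite::write_json(
    list(delta_ms = cm$delta_ms, velocity_um_per_ms = cm$velocity,
         n_post = as.list(stats::setNames(as.numeric(cm$n_post),
                                          rownames(cm$C)))),
    path_json, auto_unbox = TRUE, digits = NA)
  invisible(path_csv)
}

#' Write / read a functional graph
#'
#' `write_functional_graph` writes GraphML (via igraph) and, optionally, a
#' `source,target,weight` edge-list CSV next to it.
#'
#' @param graph an igraph functional graph.
#' @param path GraphML output path.
#' @param edge_csv optional edge-list CSV path.
#' @export
write_functional_graph <- function(graph, path, edge_csv = NULL) {
  stopifnot(igraph::is_igraph(graph))
  igraph::write_graph(graph, path, format = "graphml")
  if (!is.null(edge_csv)) {
    el <- igraph::as_edgelist(graph)
    df <- data.frame(source = el[, 1], target = el[, 2],
                     weight = igraph::E(graph)$weight %||%
                       rep(NA_real_, nrow(el)))
    write.csv(df, edge_csv, row.names = FALSE)
  }
  invisible(path)
}

#' @rdname write_functional_graph
#' @export
read_functional_graph <- function(path) {
  igraph::read_graph(path, format = "graphml")
}

#' Write / read generator ground truth as JSON
#'
#' @param ground_truth the `ground_truth` element returned by
#'   [simulate_raster()] or [simulate_calcium()].
#' @param path file path.
#' @export
write_ground_truth <- function(ground_truth, path) {
  gt <- rapply(ground_truth, function(x) {
    if (inherits(x, "table")) as.list(stats::setNames(as.numeric(x),
                                                      names(x))) else x
  }, how = "replace")
  jsonlite::write_json(gt, path, auto_unbox = TRUE, digits = NA,
                       dataframe = "columns")
  invisible(path)
}

#' @rdname write_ground_truth
#' @export
read_ground_truth <- function(path) {
  jsonlite::read_json(path, simplifyVector = TRUE)
}
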