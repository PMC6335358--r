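#' Two-point smoothing of a fluorescence trace
#'
#' Filters a trace by averaging neighbouring points:
#' `y[k] = (F[k] + F[k+1]) / 2`. The output is one sample shorter.
#'
#' @param f numeric vector of intensities.
#' @return numeric vector of length `length(f) - 1`.
#' @export
smooth_trace <- function(f) {
  if (length(f) < 2) stop_invalid("trace must have at least 2 samples")
  (f[-length(f)] + f[-1]) / 2
}

#' First difference of a trace
#'
#' The simple derivative: `d[k] = F[k+1] - F[k]`.
#'
#' @param f numeric vector.
#' @return numeric vector of length `length(f) - 1`.
#' @export
derivative_trace <- function(f) {
  if (length(f) < 2) stop_invalid("trace must have at least 2 samples")
  diff(f)
}

#' Detect calcium transients by derivative thresholding
#'
#' The trace is smoothed by two-point averaging, differentiated, and
#' thresholded at `accuracy_coeff` times the SD of the derivative.
#' A transient opens at the first sample of a positive suprathreshold run
#' and closes at the last sample of the next negative suprathreshold run
#' (`|d| > threshold`, `d < 0`); an unmatched start is closed at the trace
#' end. Because the threshold is proportional to the derivative's own SD,
#' detection is invariant to baseline shifts and to rescaling the trace.
#'
#' Two guards make the bare algorithm robust: a suprathreshold run must span
#' at least `min_run` consecutive samples (an isolated noise excursion never
#' opens or closes an event, while even a single-frame intensity step still
#' yields a two-sample run after smoothing), and events shorter than
#' `min_duration` are discarded.
#'
#' @param f numeric intensity trace, or a [fluorescence_traces()] object
#'   (then all ROIs are processed and a `roi_id` column is added).
#' @param frame_rate sampling rate, Hz (taken from the object when `f` is a
#'   [fluorescence_traces()]).
#' @param accuracy_coeff detection accuracy coefficient multiplying the
#'   derivative SD (> 0).
#' @param min_run minimum length of a suprathreshold run, samples.
#' @param min_duration minimum transient duration, seconds.
#' @param ... passed between methods.
#' @return data frame with one row per transient: `start`, `end`, `duration`
#'   (s) and `peak_amplitude` (intensity above the level at onset).
#' @export
detect_transients <- function(f, ...) UseMethod("detect_transients")

#' @rdname detect_transients
#' @export
detect_transients.default <- function(f, frame_rate = 4, accuracy_coeff = 2,
                                      min_run = 2, min_duration = 1, ...) {
  if (accuracy_coeff <= 0) stop_invalid("accuracy_coeff must be positive")
  if (length(f) < 3) stop_invalid("trace too short for transient detection")
  empty <- data.frame(start = numeric(0), end = numeric(0),
                      duration = numeric(0), peak_amplitude = numeric(0))
  y <- smooth_trace(f)
  d <- derivative_trace(y)
  sdd <- sd(d)
  if (is.na(sdd) || sdd == 0) {
    warning("flat trace: derivative SD is zero, no transients detected")
    return(empty)
  }
  thr <- accuracy_coeff * sdd
  lab <- integer(length(d))
  lab[d > thr] <- 1L
  lab[d < -thr] <- -1L
  r <- rle(lab)
  run_end <- cumsum(r$lengths)
  run_start <- run_end - r$lengths + 1L
  ## derivative sample k is centred on original frame k + 1 -> time k / fr
  t_of <- function(k) k / frame_rate
  events <- list()
  open_start <- NA_integer_
  for (q in seq_along(r$values)) {
    if (r$lengths[q] < min_run) next
    if (is.na(open_start) && r$values[q] == 1L) {
      open_start <- run_start[q]
    } else if (!is.na(open_start) && r$values[q] == -1L) {
      events[[length(events) + 1L]] <- c(open_start, run_end[q])
      open_start <- NA_integer_
    }
  }
  if (!is.na(open_start)) {
    events[[length(events) + 1L]] <- c(open_start, length(d))
  }
  if (!length(events)) return(empty)
  out <- do.call(rbind, lapply(events, function(ev) {
    start <- t_of(ev[1]); end <- t_of(ev[2])
    frames <- (ev[1]):min(ev[2] + 2L, length(f))
    data.frame(start = start, end = end, duration = end - start,
               peak_amplitude = max(f[frames]) - f[ev[1]])
  }))
  out <- out[out$duration >= min_duration, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' @rdname detect_transients
#' @export
detect_transients.fluorescence_traces <- function(f, accuracy_coeff = 2,
                                                  min_run = 2,
                                                  min_duration = 1, ...) {
  res <- lapply(seq_along(f$roi_ids), function(ci) {
    tr <- suppressWarnings(
      detect_transients.default(f$intensity[, ci],
                                frame_rate = f$frame_rate,
                                accuracy_coeff = accuracy_coeff,
                                min_run = min_run,
                                min_duration = min_duration))
    if (nrow(tr)) cbind(roi_id = f$roi_ids[ci], tr) else
      data.frame(roi_id = integer(0), start = numeric(0), end = numeric(0),
                 duration = numeric(0), peak_amplitude = numeric(0))
  })
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}

#' Population summary of calcium activity
#'
#' @param transients data frame of detected transients with a `roi_id`
#'   column (from [detect_transients()] on a [fluorescence_traces()]).
#' @param n_cells total number of cells examined (> 0).
#' @param duration_s recording length, seconds.
#' @return list with `percent_active_cells` (a cell is active if it shows at
#'   least one transient), `oscillations_per_min` (mean rate over active
#'   cells; 0 when no cell is active), `oscillations_per_min_all_cells`
#'   (mean over all cells) and `mean_duration` (s, over all transients).
#' @export
summarize_calcium <- function(transients, n_cells, duration_s) {
  if (n_cells <= 0) stop_invalid("n_cells must be positive")
  if (duration_s <= 0) stop_invalid("duration_s must be positive")
  stopifnot(is.data.frame(transients), "roi_id" %in% names(transients))
  per_cell <- table(transients$roi_id)
  n_active <- length(per_cell)
  minutes <- duration_s / 60
  rate_active <- if (n_active) mean(as.numeric(per_cell) / minutes) else 0
  list(
    percent_active_cells = 100 * n_active / n_cells,
    oscillations_per_min = rate_active,
    oscillations_per_min_all_cells =
      sum(as.numeric(per_cell)) / n_cells / minutes,
    mean_duration = if (nrow(transients)) mean(transients$duration) else 0
  )
}
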