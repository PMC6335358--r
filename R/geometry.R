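#' Planar multielectrode-array geometry
#'
#' Builds the electrode layout of a planar MEA. The default reproduces the
#' standard 59-electrode recording grid: an 8 x 8 array at 200 um pitch with
#' the four corner positions absent and one electrode reserved as internal
#' reference, leaving 59 recording channels. Electrode ids follow the usual
#' column-row convention (id = 10 * column + row).
#'
#' @param n_rows,n_cols grid dimensions.
#' @param pitch centre-to-centre electrode spacing in micrometres.
#' @param drop_corners remove the four corner positions (standard layouts
#'   have no electrodes there).
#' @param reference_id id of the electrode used as internal reference and
#'   therefore not recorded; `NA` keeps all grid electrodes.
#' @return an object of class `mea_geometry`: a list with `electrode_ids`
#'   (integer), `positions` (matrix with columns `x`, `y`, in um, one row per
#'   electrode), `pitch` (um) and `n_electrodes`.
#' @examples
#' geo <- mea_geometry()
#' geo$n_electrodes # 59
#' @export
mea_geometry <- function(n_rows = 8L, n_cols = 8L, pitch = 200,
                         drop_corners = TRUE, reference_id = 15L) {
  stopifnot(n_rows >= 2L, n_cols >= 2L, pitch > 0)
  grid <- expand.grid(row = seq_len(n_rows), col = seq_len(n_cols))
  if (drop_corners) {
    corner <- (grid$row %in% c(1L, n_rows)) & (grid$col %in% c(1L, n_cols))
    grid <- grid[!corner, , drop = FALSE]
  }
  ids <- as.integer(10L * grid$col + grid$row)
  if (!is.na(reference_id)) {
    keep <- ids != as.integer(reference_id)
    grid <- grid[keep, , drop = FALSE]
    ids <- ids[keep]
  }
  pos <- cbind(x = (grid$col - 1) * pitch, y = (grid$row - 1) * pitch)
  rownames(pos) <- ids
  geo <- structure(
    list(
      electrode_ids = ids,
      positions = pos,
      pitch = pitch,
      n_electrodes = length(ids)
    ),
    class = "mea_geometry"
  )
  validate_geometry(geo)
  geo
}

validate_geometry <- function(geo) {
  stopifnot(inherits(geo, "mea_geometry"))
  if (anyDuplicated(geo$electrode_ids)) {
    stop_invalid("electrode ids must be unique")
  }
  if (anyDuplicated(geo$positions)) {
    stop_invalid("electrode positions must be distinct")
  }
  if (nrow(geo$positions) != geo$n_electrodes ||
      length(geo$electrode_ids) != geo$n_electrodes) {
    stop_invalid("geometry fields disagree on the number of electrodes")
  }
  invisible(geo)
}

#' Pairwise electrode distances
#'
#' @param geometry an [mea_geometry()].
#' @return symmetric matrix of Euclidean distances in um, dimnames set to
#'   electrode ids.
#' @export
electrode_distances <- function(geometry) {
  validate_geometry(geometry)
  d <- as.matrix(dist(geometry$positions))
  dimnames(d) <- list(geometry$electrode_ids, geometry$electrode_ids)
  d
}

#' @export
print.mea_geometry <- function(x, ...) {
  cat(sprintf("<mea_geometry> %d electrodes, pitch %g um\n",
              x$n_electrodes, x$pitch))
  invisible(x)
}
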