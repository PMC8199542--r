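#' Physical geometry of the sensing grid
#'
#' Cell centers are laid out on a regular lattice with the grid center at the
#' origin. The X (medial-lateral, ML) coordinate increases with column index,
#' the Y (anterior-posterior, AP) coordinate with row index. Defaults describe
#' the prototype: 16 x 16 cells at 2 cm pitch, i.e. a 32 x 32 cm active area.
#'
#' `centers_x` / `centers_y` may be given explicitly (used when a reduced
#' resolution keeps a subset of lines at their original physical positions).
#'
#' @param n_rows,n_cols cell counts
#' @param pitch center-to-center spacing, cm
#' @param centers_x column-center X coordinates, cm (length `n_cols`)
#' @param centers_y row-center Y coordinates, cm (length `n_rows`)
#' @return an object of class `mat_geometry`
#' @export
mat_geometry <- function(n_rows = 16, n_cols = 16, pitch = 2.0,
                         centers_x = NULL, centers_y = NULL) {
  stopifnot(n_rows >= 1, n_cols >= 1, pitch > 0)
  if (is.null(centers_x)) centers_x <- (seq_len(n_cols) - (n_cols + 1) / 2) * pitch
  if (is.null(centers_y)) centers_y <- (seq_len(n_rows) - (n_rows + 1) / 2) * pitch
  stopifnot(length(centers_x) == n_cols, length(centers_y) == n_rows)
  structure(list(n_rows = as.integer(n_rows), n_cols = as.integer(n_cols),
                 pitch = pitch, centers_x = centers_x, centers_y = centers_y),
            class = "mat_geometry")
}

#' @export
print.mat_geometry <- function(x, ...) {
  cat(sprintf("Mat geometry: %d x %d cells, pitch %g cm (extent %g x %g cm)\n",
              x$n_rows, x$n_cols, x$pitch,
              x$n_cols * x$pitch, x$n_rows * x$pitch))
  invisible(x)
}

#' Time-stamped sequence of mat frames
#'
#' Container for a uniformly sampled sequence of per-cell images (pressure,
#' conductance, or raw voltage — units are recorded, and the CoP centroid is
#' invariant to any proportional unit, so conductance serves directly as a
#' pressure proxy).
#'
#' @param timestamps sample times, seconds, strictly increasing, uniform
#' @param frames numeric array `[n_rows, n_cols, n_frames]`
#' @param geometry a [mat_geometry()]
#' @param units one of "pressure", "siemens", "volts"
#' @param v_cc supply voltage, required when `units == "volts"`
#' @return an object of class `pressure_sequence`
#' @export
pressure_sequence <- function(timestamps, frames, geometry,
                              units = c("pressure", "siemens", "volts"),
                              v_cc = NULL) {
  units <- match.arg(units)
  stopifnot(is.array(frames), length(dim(frames)) == 3L,
            dim(frames)[1] == geometry$n_rows,
            dim(frames)[2] == geometry$n_cols,
            dim(frames)[3] == length(timestamps))
  if (length(timestamps) > 1 && any(diff(timestamps) <= 0))
    stop("timestamps must be strictly increasing")
  if (units == "volts" && is.null(v_cc))
    stop("v_cc is required for voltage frames")
  structure(list(timestamps = as.numeric(timestamps), frames = frames,
                 geometry = geometry, units = units, v_cc = v_cc),
            class = "pressure_sequence")
}

#' @export
print.pressure_sequence <- function(x, ...) {
  fs <- if (length(x$timestamps) > 1) 1 / stats::median(diff(x$timestamps)) else NA
  cat(sprintf("Frame sequence: %d frames of %d x %d [%s], fs ~ %.3g Hz\n",
              length(x$timestamps), x$geometry$n_rows, x$geometry$n_cols,
              x$units, fs))
  invisible(x)
}

#' Center-of-pressure trajectory
#'
#' A time series of CoP positions: `x_ml` is the medial-lateral coordinate,
#' `y_ap` the anterior-posterior coordinate, both in cm.
#'
#' @param timestamps sample times, seconds
#' @param x_ml,y_ap coordinates, cm
#' @return a data.frame of class `cop_trajectory` with columns `t`, `x_ml`,
#'   `y_ap`
#' @export
cop_trajectory <- function(timestamps, x_ml, y_ap) {
  stopifnot(length(timestamps) == length(x_ml),
            length(x_ml) == length(y_ap))
  structure(data.frame(t = as.numeric(timestamps),
                       x_ml = as.numeric(x_ml),
                       y_ap = as.numeric(y_ap)),
            class = c("cop_trajectory", "data.frame"))
}
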