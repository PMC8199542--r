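#' Per-cell conductance grid of a resistive sensor mat
#'
#' Holds the quantity the crosstalk inversion recovers: the conductance of each
#' sensing cell at a row-column crossing, in siemens.
#'
#' @param g nonnegative numeric matrix of per-cell conductance, siemens
#' @return an object of class `cell_grid` (a matrix with attributes)
#' @export
cell_grid <- function(g) {
  g <- as.matrix(g)
  stopifnot(is.numeric(g), all(is.finite(g)), all(g >= 0))
  structure(g, class = c("cell_grid", "matrix", "array"))
}

#' Inversion settings for crosstalk elimination
#'
#' @param max_iter maximum fixed-point iterations (>= 1)
#' @param tol convergence tolerance on the max elementwise conductance
#'   residual, siemens
#' @param damping step factor in (0, 1]
#' @param floor_g conductance floor, siemens: values below it are treated as
#'   exactly zero in the network solve to avoid ill-conditioned floating nodes
#' @return an object of class `inversion_settings`
#' @export
inversion_settings <- function(max_iter = 100L, tol = 1e-9, damping = 1.0,
                               floor_g = 1e-9) {
  stopifnot(max_iter >= 1, tol > 0, damping > 0, damping <= 1, floor_g >= 0)
  structure(list(max_iter = as.integer(max_iter), tol = tol,
                 damping = damping, floor_g = floor_g),
            class = "inversion_settings")
}

#' Equivalent conductance seen between one row and one column line
#'
#' In a row-column resistive array the current injected at the selected row
#' line and drained at the selected column line does not only cross the
#' addressed cell: it also takes series detours through other cells sharing
#' those lines (the "ghost effect"). The measured quantity is therefore the
#' two-point effective conductance of the whole resistor network, with all
#' unselected lines floating. It is computed by nodal analysis on the bipartite
#' graph whose nodes are the row and column lines and whose edges are the
#' cells; parallel detours only add conductance, so the result is always
#' `>= g[row, col]`.
#'
#' @param grid a [cell_grid()] (or plain nonnegative matrix)
#' @param row,col 1-based selected row and column line
#' @param floor_g conductance floor (see [inversion_settings()])
#' @return equivalent conductance, siemens
#' @export
forward_equivalent <- function(grid, row, col, floor_g = 1e-9) {
  g <- unclass(as.matrix(grid))
  stopifnot(row >= 1, row <= nrow(g), col >= 1, col <= ncol(g))
  eq <- .eq_map(g, floor_g)
  eq[row, col]
}

#' Equivalent conductance map of the whole array
#'
#' Applies [forward_equivalent()] to every row-column pair, i.e. simulates one
#' full multiplexer scan of the mat. This is the forward model whose inversion
#' removes crosstalk.
#'
#' @inheritParams forward_equivalent
#' @return matrix of equivalent conductance, siemens, same shape as `grid`
#' @export
forward_equivalent_all <- function(grid, floor_g = 1e-9) {
  g <- unclass(as.matrix(grid))
  .eq_map(g, floor_g)
}

#' Remove row-column crosstalk from a measured equivalent map
#'
#' Inverts the network forward model: finds a per-cell conductance grid whose
#' full-scan equivalent map reproduces the measurement, started at the
#' measurement itself and stopped when the max elementwise residual drops
#' below `tol` or after `max_iter` steps. The default algorithm is a projected
#' Newton iteration using the analytic network Jacobian (the sensitivity of a
#' row-column measurement to a cell is the squared per-unit voltage drop
#' across that cell), which converges quadratically even when the crosstalk
#' exceeds the direct-cell conductance — the regime a fully loaded mat
#' actually operates in. `method = "fixed_point"` selects the cheaper damped
#' crosstalk subtraction `g <- clamp0(g - damping * (forward(g) - meas))`,
#' which is only convergent when the crosstalk term is a contraction (lightly
#' loaded or sparse grids). Non-convergence is flagged, never raised, and the
#' best iterate is returned.
#'
#' @param meas measured equivalent conductance matrix, siemens (nonnegative)
#' @param settings an [inversion_settings()]
#' @param method `"newton"` (default) or `"fixed_point"`
#' @param g0 optional starting grid (e.g. the previous frame's solution when
#'   inverting a recording frame by frame)
#' @return a [cell_grid()] with attributes `converged` (logical),
#'   `iterations`, and `residual` (siemens)
#' @export
remove_crosstalk <- function(meas, settings = inversion_settings(),
                             method = c("newton", "fixed_point"), g0 = NULL) {
  method <- match.arg(method)
  m <- unclass(as.matrix(meas))
  stopifnot(all(is.finite(m)), all(m >= 0))
  res <- .invert_map(m, settings$damping, settings$tol,
                     settings$max_iter, settings$floor_g, method,
                     if (is.null(g0)) NULL else unclass(as.matrix(g0)))
  out <- cell_grid(res$g)
  attr(out, "converged") <- res$converged
  attr(out, "iterations") <- res$iterations
  attr(out, "residual") <- res$residual
  out
}
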