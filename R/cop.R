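#' Center-of-pressure trajectory from a frame sequence
#'
#' Per frame, values below a noise floor (a fraction of that frame's maximum)
#' are zeroed, then the CoP is the pressure-weighted centroid of the cell
#' centers: `X = sum(p_ij * x_j) / sum(p_ij)`, `Y = sum(p_ij * y_i) / sum(p_ij)`.
#' Proportionality constants cancel, so conductance frames are used directly.
#' The floor suppresses crosstalk residue and quantization background that
#' would otherwise bias the centroid toward the grid center.
#'
#' A frame whose total is zero after flooring has no defined CoP; its value is
#' carried forward from the previous frame and the trajectory is flagged (an
#' empty first frame is an error).
#'
#' @param seq a [pressure_sequence()] (pressure or conductance units)
#' @param noise_floor fraction of the per-frame maximum below which cells are
#'   zeroed; default 0.01
#' @return a [cop_trajectory()]; attribute `n_empty` counts carried-forward
#'   frames
#' @export
compute_cop <- function(seq, noise_floor = 0.01) {
  geom <- seq$geometry
  d <- dim(seq$frames)
  nf <- d[3]
  M <- matrix(seq$frames, nrow = d[1] * d[2], ncol = nf)
  if (noise_floor > 0) {
    fmax <- apply(M, 2, max)
    M[M < rep(fmax * noise_floor, each = nrow(M))] <- 0
  }
  xcell <- rep(geom$centers_x, each = geom$n_rows)
  ycell <- rep(geom$centers_y, times = geom$n_cols)
  tot <- colSums(M)
  x <- as.numeric(crossprod(M, xcell)) / tot
  y <- as.numeric(crossprod(M, ycell)) / tot
  empty <- tot <= 0
  if (empty[1]) stop("first frame has zero total pressure: CoP undefined")
  n_empty <- sum(empty)
  if (n_empty > 0) {
    for (k in which(empty)) { x[k] <- x[k - 1]; y[k] <- y[k - 1] }
    warning(sprintf("%d empty frame(s): CoP carried forward", n_empty))
  }
  out <- cop_trajectory(seq$timestamps, x, y)
  attr(out, "n_empty") <- n_empty
  out
}

#' Emulate a lower-resolution mat by line selection
#'
#' Keeps only every other row and column line (those with original index
#' congruent to `phase` modulo 2), turning a 16 x 16 recording into an 8 x 8
#' one. This mimics physically removing half the lines: retained cells keep
#' their original physical center coordinates and their values are selected,
#' not re-aggregated.
#'
#' @param seq a [pressure_sequence()] with even dimensions
#' @param phase 0 (keep lines 1, 3, ...) or 1 (keep lines 2, 4, ...); default 0
#' @return a [pressure_sequence()] on the reduced grid
#' @export
downsample_grid <- function(seq, phase = 0) {
  geom <- seq$geometry
  if (geom$n_rows %% 2 != 0 || geom$n_cols %% 2 != 0)
    stop("downsample_grid requires even row and column counts")
  stopifnot(phase %in% c(0, 1))
  ri <- seq.int(1 + phase, geom$n_rows, by = 2)
  ci <- seq.int(1 + phase, geom$n_cols, by = 2)
  sub_geom <- mat_geometry(n_rows = length(ri), n_cols = length(ci),
                           pitch = 2 * geom$pitch,
                           centers_x = geom$centers_x[ci],
                           centers_y = geom$centers_y[ri])
  pressure_sequence(seq$timestamps, seq$frames[ri, ci, , drop = FALSE],
                    sub_geom, units = seq$units, v_cc = seq$v_cc)
}

#' Align two CoP trajectories by cross-correlation
#'
#' The instruments are started independently, so their recordings are offset
#' by an unknown integer number of samples. The lag is found by maximizing,
#' over `[-max_lag, +max_lag]`, the summed cross-correlation of the
#' mean-removed ML and AP components. A positive lag means `b` is delayed:
#' `b[k]` lines up with `a[k - lag]`. Ties are broken toward the smallest
#' `|lag|`, then toward the negative lag.
#'
#' @param a,b [cop_trajectory()] objects of equal sampling rate
#' @param max_lag search half-width, samples
#' @return list with `lag` (samples), `a_aligned`, `b_aligned` (trimmed to the
#'   overlap), and `peak_correlation` (normalized, summed over axes / 2; values
#'   below 0.5 suggest a suspicious alignment and trigger a warning)
#' @export
align_trajectories <- function(a, b, max_lag = 25) {
  n <- min(nrow(a), nrow(b))
  if (n - max_lag < 10) stop("series too short for the requested max_lag")
  ax <- a$x_ml[seq_len(n)] - mean(a$x_ml[seq_len(n)])
  ay <- a$y_ap[seq_len(n)] - mean(a$y_ap[seq_len(n)])
  bx <- b$x_ml[seq_len(n)] - mean(b$x_ml[seq_len(n)])
  by <- b$y_ap[seq_len(n)] - mean(b$y_ap[seq_len(n)])

  lags <- -max_lag:max_lag
  lags <- lags[order(abs(lags), lags)]       # tie-break: smallest |lag|, then negative
  best <- -Inf; best_lag <- 0L; best_norm <- 0
  for (L in lags) {
    if (L >= 0) { ia <- seq_len(n - L); ib <- ia + L }
    else        { ib <- seq_len(n + L); ia <- ib - L }
    s <- sum(ax[ia] * bx[ib]) + sum(ay[ia] * by[ib])
    if (s > best) {
      best <- s
      best_lag <- L
      den <- sqrt(sum(ax[ia]^2) * sum(bx[ib]^2)) + sqrt(sum(ay[ia]^2) * sum(by[ib]^2))
      best_norm <- if (den > 0) (sum(ax[ia] * bx[ib]) + sum(ay[ia] * by[ib])) / den else 0
    }
  }
  L <- best_lag
  if (L >= 0) { ia <- seq_len(n - L); ib <- ia + L }
  else        { ib <- seq_len(n + L); ia <- ib - L }
  if (best_norm < 0.5)
    warning(sprintf("suspicious alignment: peak correlation %.2f < 0.5", best_norm))
  list(lag = L,
       a_aligned = cop_trajectory(a$t[ia], a$x_ml[ia], a$y_ap[ia]),
       b_aligned = cop_trajectory(b$t[ib], b$x_ml[ib], b$y_ap[ib]),
       peak_correlation = best_norm)
}

#' Sway statistics of a CoP trajectory
#'
#' The standard deviation of the ML and AP components over the trial, with the
#' population denominator N:
#' `sigma_ML = sqrt( sum_i (X_i - mean(X))^2 / N )` and likewise for AP.
#'
#' @param traj a [cop_trajectory()] with at least 2 points
#' @return list of class `sway_stats`: `sigma_ml`, `sigma_ap` (cm), `n_points`
#' @export
sway_std <- function(traj) {
  n <- nrow(traj)
  if (n < 2) stop("at least 2 trajectory points are required")
  pop_sd <- function(v) sqrt(mean((v - mean(v))^2))
  structure(list(sigma_ml = pop_sd(traj$x_ml),
                 sigma_ap = pop_sd(traj$y_ap),
                 n_points = n),
            class = "sway_stats")
}

#' @export
print.sway_stats <- function(x, ...) {
  cat(sprintf("Sway: sigma_ML = %.4f cm, sigma_AP = %.4f cm (N = %d)\n",
              x$sigma_ml, x$sigma_ap, x$n_points))
  invisible(x)
}
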