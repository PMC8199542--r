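#' First-order sensor time-response model
#'
#' The piezoresistive material does not follow pressure instantaneously; a
#' separate step-input experiment on a single cell shows an exponential
#' approach with time constant `tau` = 0.25 s. Discretized at sampling period
#' `ts`, the sensor acts as the exponential smoother
#' `x[k] = a x[k-1] + (1 - a) u[k]` with `a = exp(-ts/tau)`, which is exactly
#' invertible by a two-coefficient FIR filter (see
#' [deconvolve_first_order()]).
#'
#' @param tau time constant, seconds (> 0); default 0.25 s
#' @param ts sampling period, seconds (> 0); default 0.1 s (10 Hz scan)
#' @return an object of class `dynamics_model` with fields `tau`, `ts` and the
#'   derived smoothing coefficient `a` in (0, 1)
#' @export
dynamics_model <- function(tau = 0.25, ts = 0.1) {
  stopifnot(tau > 0, ts > 0)
  a <- exp(-ts / tau)
  structure(list(tau = tau, ts = ts, a = a), class = "dynamics_model")
}

#' @export
print.dynamics_model <- function(x, ...) {
  cat(sprintf("First-order sensor model: tau = %g s, Ts = %g s, a = %.6f\n",
              x$tau, x$ts, x$a))
  invisible(x)
}

#' Apply the first-order sensor response to a series
#'
#' `x[k] = a x[k-1] + (1 - a) u[k]`, zero initial condition (`x[0] = 0` before
#' the first sample). Output length equals input length. Accepts a vector (one
#' series) or a matrix (one series per column).
#'
#' @param u input series (vector, or matrix with series in columns)
#' @param model a [dynamics_model()]
#' @return smoothed series, same shape as `u`
#' @export
apply_first_order <- function(u, model) {
  a <- model$a
  out <- stats::filter(u * (1 - a), a, method = "recursive")
  if (is.matrix(u)) {
    out <- matrix(as.numeric(out), nrow = nrow(u), ncol = ncol(u))
  } else {
    out <- as.numeric(out)
  }
  out
}

#' Exact inverse of the first-order sensor response
#'
#' The corrected value at time k is obtained from the measured values at k and
#' k - 1 by the two-coefficient FIR filter
#' `y[k] = x[k]/(1 - a) + x[k-1] * a/(a - 1)` (with `x[0] = 0` before the first
#' sample) — the exact left-inverse of [apply_first_order()] under the same
#' initial condition. The coefficients sum to 1, so DC gain is 1.
#'
#' @param x measured series (vector, or matrix with series in columns)
#' @param model a [dynamics_model()]
#' @return deconvolved series, same shape as `x`
#' @export
deconvolve_first_order <- function(x, model) {
  a <- model$a
  if (is.matrix(x)) {
    xm1 <- rbind(0, x[-nrow(x), , drop = FALSE])
  } else {
    xm1 <- c(0, x[-length(x)])
  }
  x / (1 - a) + xm1 * a / (a - 1)
}

#' Discrete step response of the first-order model
#'
#' Unit-amplitude step applied with the first sample; the k-th output sample
#' equals `1 - exp(-(k)*ts/tau)` for k = 1, 2, ... because each sample reflects
#' the response one full sampling period after step onset. Timestamps are
#' returned accordingly as `t_k = k * ts`.
#'
#' @param model a [dynamics_model()]
#' @param duration length of the response, seconds
#' @param amplitude step amplitude
#' @return data.frame with columns `t` (seconds) and `x` (response)
#' @export
step_response <- function(model, duration = 10, amplitude = 1) {
  n <- ceiling(duration / model$ts)
  x <- apply_first_order(rep(amplitude, n), model)
  data.frame(t = seq_len(n) * model$ts, x = x)
}

#' Estimate the sensor time constant from a sampled step response
#'
#' Least-squares fit of `c * (1 - exp(-t/tau))` to a sampled step response,
#' the same procedure used to calibrate the sensor from a single-cell
#' pressure-step experiment.
#'
#' @param t sample times, seconds (time measured from step onset)
#' @param x sampled response
#' @return list with `tau` (seconds), `c` (asymptote) and the `nls` fit
#' @export
fit_time_constant <- function(t, x) {
  stopifnot(length(t) == length(x), length(t) >= 3)
  c0 <- max(x)
  tau0 <- t[which.min(abs(x - (1 - exp(-1)) * c0))]
  if (!is.finite(tau0) || tau0 <= 0) tau0 <- diff(range(t)) / 5
  # Levenberg-Marquardt: stable also on noiseless (zero-residual) responses,
  # where plain Gauss-Newton step halving aborts.
  fit <- minpack.lm::nlsLM(x ~ cc * (1 - exp(-t / tau)),
                           start = list(cc = c0, tau = tau0),
                           control = minpack.lm::nls.lm.control(maxiter = 200))
  est <- stats::coef(fit)
  list(tau = unname(est["tau"]), c = unname(est["cc"]), fit = fit)
}
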