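#' Intraclass correlation coefficient for absolute agreement
#'
#' Two-way model, absolute agreement, single measurement — ICC(A,1) in
#' McGraw-Wong notation: the standard reading of "ICC for agreement" between
#' two fixed instruments, in which a systematic offset between instruments
#' counts as disagreement. From the two-way mean squares (MSR over subjects,
#' MSC over instruments, MSE residual):
#' `ICC = (MSR - MSE) / (MSR + (k-1) MSE + (k/n)(MSC - MSE))`, k = 2.
#'
#' @param reference per-subject values from the reference instrument, cm
#' @param test per-subject values from the instrument under test, cm
#' @return ICC (dimensionless, in [-1, 1]); `NA` with a warning when total
#'   variance is zero (undefined)
#' @export
icc_agreement <- function(reference, test) {
  n <- length(reference)
  stopifnot(n == length(test), n >= 2)
  y <- cbind(reference, test)
  k <- 2
  grand <- mean(y)
  row_m <- rowMeans(y)
  col_m <- colMeans(y)
  ssr <- k * sum((row_m - grand)^2)
  ssc <- n * sum((col_m - grand)^2)
  sst <- sum((y - grand)^2)
  sse <- sst - ssr - ssc
  msr <- ssr / (n - 1)
  msc <- ssc / (k - 1)
  mse <- sse / ((n - 1) * (k - 1))
  den <- msr + (k - 1) * mse + (k / n) * (msc - mse)
  if (den <= 0) {
    warning("zero total variance: ICC undefined")
    return(NA_real_)
  }
  (msr - mse) / den
}

#' Mean absolute error against the reference instrument
#'
#' The reference (force-platform) value is taken as the true value.
#'
#' @inheritParams icc_agreement
#' @return MAE, cm
#' @export
mean_absolute_error <- function(reference, test) {
  stopifnot(length(reference) == length(test), length(reference) >= 1)
  mean(abs(test - reference))
}

#' Convert a voltage frame sequence to equivalent conductance
#'
#' Inverts the readout divider cell by cell ([resistance_from_voltage()]);
#' open-circuit readings map to zero conductance. The result is the measured
#' equivalent map still containing network crosstalk.
#'
#' @param seq a [pressure_sequence()] in volts
#' @param circuit a [readout_circuit()]
#' @return a [pressure_sequence()] in siemens
#' @export
voltages_to_conductance <- function(seq, circuit) {
  stopifnot(seq$units == "volts")
  v <- seq$frames
  v[v <= 0] <- .Machine$double.eps          # quantized-to-zero floor readings
  r <- resistance_from_voltage(v, circuit)
  g <- ifelse(is.infinite(r), 0, 1 / pmax(r, 1e-3))
  pressure_sequence(seq$timestamps, array(g, dim = dim(v)), seq$geometry,
                    units = "siemens")
}

#' Apply one processing variant to a voltage recording
#'
#' The processing chains under comparison:
#' \describe{
#'   \item{`raw`}{circuit inversion only — the equivalent conductance is used
#'     directly, crosstalk and all.}
#'   \item{`base`}{circuit inversion + per-frame crosstalk elimination
#'     ([remove_crosstalk()]).}
#'   \item{`first_order`}{base + per-cell deconvolution of the first-order
#'     sensor lag ([deconvolve_first_order()]).}
#'   \item{`eight_by_eight`}{base processing run on the half-resolution
#'     recording ([downsample_grid()]).}
#' }
#'
#' @param seq voltage [pressure_sequence()]
#' @param variant one of `"raw"`, `"base"`, `"first_order"`, `"eight_by_eight"`
#' @param circuit a [readout_circuit()]
#' @param inversion an [inversion_settings()]
#' @param dynamics a [dynamics_model()] (used by `first_order`)
#' @param geq optional precomputed conductance sequence (skips the circuit
#'   inversion); `base_grid` an optional precomputed base result to reuse
#' @param base_grid see `geq`
#' @return conductance [pressure_sequence()]; attribute `n_nonconverged`
#'   counts frames whose crosstalk inversion did not reach tolerance
#' @export
process_variant <- function(seq, variant = c("base", "raw", "first_order",
                                             "eight_by_eight"),
                            circuit = readout_circuit(),
                            inversion = inversion_settings(),
                            dynamics = dynamics_model(),
                            geq = NULL, base_grid = NULL) {
  variant <- match.arg(variant)
  if (is.null(geq)) geq <- voltages_to_conductance(seq, circuit)
  if (variant == "raw") return(geq)
  if (variant == "eight_by_eight") geq <- downsample_grid(geq)

  if (variant %in% c("base", "first_order") && !is.null(base_grid)) {
    out <- base_grid
  } else {
    d <- dim(geq$frames)
    frames <- array(0, dim = d)
    n_bad <- 0L
    # each frame is inverted from scratch: warm-starting from the previous
    # frame can pin the projected Newton iteration to a stale active set
    for (k in seq_len(d[3])) {
      res <- .invert_map(geq$frames[, , k], inversion$damping, inversion$tol,
                         inversion$max_iter, inversion$floor_g, "newton", NULL)
      frames[, , k] <- res$g
      if (!res$converged) n_bad <- n_bad + 1L
    }
    out <- pressure_sequence(geq$timestamps, frames, geq$geometry,
                             units = "siemens")
    attr(out, "n_nonconverged") <- n_bad
  }
  if (variant == "first_order") {
    d <- dim(out$frames)
    xm <- t(matrix(out$frames, nrow = d[1] * d[2], ncol = d[3]))
    ym <- deconvolve_first_order(xm, dynamics)
    bad <- attr(out, "n_nonconverged")
    out <- pressure_sequence(out$timestamps, array(t(ym), dim = d),
                             out$geometry, units = "siemens")
    attr(out, "n_nonconverged") <- bad
  }
  out
}

#' Run the full variant-comparison harness on a synthetic cohort
#'
#' Reproduces the study design: for every subject and trial the mat voltage
#' recording is processed under each variant, the CoP is extracted, aligned
#' once per trial against the platform channel (alignment computed from the
#' base processing and shared across variants so differences reflect
#' processing, not alignment jitter), the first `ceiling(5 tau / ts)` samples
#' of the overlap are discarded (sensor-lag startup transient), and per-trial
#' sway statistics feed the agreement measures.
#'
#' @param cohort a [simulate_cohort()] dataset
#' @param variants processing variants to evaluate
#' @param inversion an [inversion_settings()]
#' @param noise_floor centroid noise floor passed to [compute_cop()]
#' @param max_lag alignment search half-width, samples
#' @param burn_in samples of the aligned overlap to discard before computing
#'   sway statistics; default `NULL` uses `ceiling(5 tau / ts)` (the sensor
#'   start-up transient). Set 0 to score the full overlap, e.g. when the
#'   per-trial sway targets must coincide exactly with the scored window
#' @return a data.frame of class `variant_report` with columns `variant`,
#'   `trial`, `metric`, `icc`, `mae`, `n`; attributes: `recovery` (per-variant
#'   mean absolute error of the mat sigma against the trial's ground truth),
#'   `per_subject` (the long per-subject table), `n_dropped`
#' @export
run_variant_comparison <- function(cohort,
                                   variants = c("raw", "base", "first_order",
                                                "eight_by_eight"),
                                   inversion = inversion_settings(),
                                   noise_floor = 0.01, max_lag = 25,
                                   burn_in = NULL) {
  cfg <- cohort$config
  dyn <- if (is.null(cfg$dynamics)) dynamics_model(ts = 1 / cfg$fs) else cfg$dynamics
  burn <- if (is.null(burn_in)) ceiling(5 * dyn$tau / dyn$ts) else as.integer(burn_in)
  rows <- list()
  n_dropped <- 0L

  for (s in seq_len(cfg$n_subjects)) {
    for (trial in cfg$trials) {
      rec <- cohort$recordings[[s]][[trial]]
      ok <- TRUE
      res <- tryCatch({
        geq <- voltages_to_conductance(rec$mat_voltages, cfg$circuit)
        base <- process_variant(rec$mat_voltages, "base", cfg$circuit,
                                inversion, dyn, geq = geq)
        base_cop <- compute_cop(base, noise_floor)
        al <- suppressWarnings(
          align_trajectories(rec$platform_cop, base_cop, max_lag))
        keep_a <- seq.int(burn + 1L, nrow(al$a_aligned))
        plat_stats <- sway_std(al$a_aligned[keep_a, ])

        out <- list()
        for (v in variants) {
          proc <- process_variant(rec$mat_voltages, v, cfg$circuit, inversion,
                                  dyn, geq = geq,
                                  base_grid = if (v %in% c("base", "first_order")) base else NULL)
          cop <- compute_cop(proc, noise_floor)
          # re-trim this variant's trajectory with the shared lag
          L <- al$lag
          nn <- min(nrow(rec$platform_cop), nrow(cop))
          if (L >= 0) { ib <- seq.int(1L + L, nn) } else { ib <- seq_len(nn + L) }
          mat_traj <- cop[ib, ]
          keep <- seq.int(burn + 1L, nrow(mat_traj))
          out[[v]] <- sway_std(cop_trajectory(mat_traj$t[keep],
                                              mat_traj$x_ml[keep],
                                              mat_traj$y_ap[keep]))
        }
        list(platform = plat_stats, mat = out,
             peak = al$peak_correlation, lag = al$lag)
      }, error = function(e) {
        warning(sprintf("subject %d trial %s dropped: %s", s, trial,
                        conditionMessage(e)))
        ok <<- FALSE
        NULL
      })
      if (!ok) { n_dropped <- n_dropped + 1L; next }
      for (v in variants) {
        rows[[length(rows) + 1L]] <- data.frame(
          subject = s, trial = trial, variant = v,
          platform_sigma_ml = res$platform$sigma_ml,
          platform_sigma_ap = res$platform$sigma_ap,
          mat_sigma_ml = res$mat[[v]]$sigma_ml,
          mat_sigma_ap = res$mat[[v]]$sigma_ap,
          sigma_ml_true = rec$sigma_ml_true,
          sigma_ap_true = rec$sigma_ap_true,
          lag = res$lag, peak_correlation = res$peak)
      }
    }
  }
  per_subject <- do.call(rbind, rows)

  report <- list()
  recovery <- list()
  for (v in variants) {
    dv <- per_subject[per_subject$variant == v, ]
    for (trial in cfg$trials) {
      dt <- dv[dv$trial == trial, ]
      for (metric in c("sigma_ml", "sigma_ap")) {
        ref <- dt[[paste0("platform_", metric)]]
        tst <- dt[[paste0("mat_", metric)]]
        report[[length(report) + 1L]] <- data.frame(
          variant = v, trial = trial,
          metric = if (metric == "sigma_ml") "sigma_ML" else "sigma_AP",
          icc = icc_agreement(ref, tst),
          mae = mean_absolute_error(ref, tst),
          n = nrow(dt))
      }
    }
    recovery[[v]] <- mean(abs(c(dv$mat_sigma_ml - dv$sigma_ml_true,
                                dv$mat_sigma_ap - dv$sigma_ap_true)))
  }
  out <- do.call(rbind, report)
  class(out) <- c("variant_report", "data.frame")
  attr(out, "recovery") <- unlist(recovery)
  attr(out, "per_subject") <- per_subject
  attr(out, "n_dropped") <- n_dropped
  out
}
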