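#' Postural sway model for synthetic trials
#'
#' Each axis of the CoP is an AR(1) process rescaled so its realized
#' population standard deviation equals the target exactly — the ground-truth
#' sway of every synthetic trial is therefore known by construction. The AR(1)
#' coefficient sets the smoothness: the default 0.95 at 10 Hz corresponds to a
#' correlation time of about 2 s, typical of single-legged quiet standing.
#'
#' @param sigma_ml_target,sigma_ap_target target sway, cm (> 0)
#' @param smoothness AR(1) coefficient in [0, 1); default 0.95
#' @param duration trial length, seconds; default 60
#' @param fs sampling rate, Hz; default 10
#' @param seed integer seed, or NULL to use the current RNG state
#' @return an object of class `sway_model`
#' @export
sway_model <- function(sigma_ml_target = 0.7, sigma_ap_target = 1.1,
                       smoothness = 0.95, duration = 60, fs = 10,
                       seed = NULL) {
  stopifnot(sigma_ml_target > 0, sigma_ap_target > 0,
            smoothness >= 0, smoothness < 1, duration > 0, fs > 0)
  structure(list(sigma_ml_target = sigma_ml_target,
                 sigma_ap_target = sigma_ap_target,
                 smoothness = smoothness, duration = duration, fs = fs,
                 seed = seed),
            class = "sway_model")
}

#' Foot-load model for synthetic pressure images
#'
#' The foot is rendered as a single 2-D Gaussian blob: only the centroid and
#' its temporal statistics matter downstream, so no anatomical silhouette is
#' attempted. Conductance is proportional to pressure (the sensing material's
#' approximately linear regime) on top of a small unpressed baseline.
#'
#' @param load total vertical force, newtons; default 729 N (a 74.3 kg subject)
#' @param spread_ml,spread_ap Gaussian footprint standard deviations, cm
#' @param conductance_per_pressure siemens per newton of cell load
#' @param baseline_g unpressed cell conductance, siemens
#' @return an object of class `foot_model`
#' @export
foot_model <- function(load = 729, spread_ml = 3.0, spread_ap = 5.0,
                       conductance_per_pressure = 2e-5, baseline_g = 1e-6) {
  stopifnot(load > 0, spread_ml > 0, spread_ap > 0,
            conductance_per_pressure > 0, baseline_g >= 0)
  structure(list(load = load, spread_ml = spread_ml, spread_ap = spread_ap,
                 conductance_per_pressure = conductance_per_pressure,
                 baseline_g = baseline_g),
            class = "foot_model")
}

#' Generate a synthetic CoP sway trajectory
#'
#' Per axis: draw an AR(1) series `z[k] = phi z[k-1] + e[k]` (white Gaussian
#' innovations), remove its mean and rescale so the population standard
#' deviation equals the target exactly. Deterministic given `model$seed`.
#'
#' @param model a [sway_model()]
#' @return a [cop_trajectory()] with attributes `sigma_ml_true`,
#'   `sigma_ap_true` (equal to the targets by construction)
#' @export
generate_sway <- function(model) {
  if (!is.null(model$seed)) set.seed(model$seed)
  n <- round(model$duration * model$fs)
  ar1 <- function(n, phi, target) {
    z <- as.numeric(stats::filter(stats::rnorm(n), phi, method = "recursive"))
    z <- z - mean(z)
    s <- sqrt(mean(z^2))
    if (s == 0) stop("degenerate sway realization")
    z * target / s
  }
  x <- ar1(n, model$smoothness, model$sigma_ml_target)
  y <- ar1(n, model$smoothness, model$sigma_ap_target)
  out <- cop_trajectory(seq_len(n) / model$fs, x, y)
  attr(out, "sigma_ml_true") <- model$sigma_ml_target
  attr(out, "sigma_ap_true") <- model$sigma_ap_target
  out
}

#' Render pressure frames from a CoP trajectory
#'
#' Each frame is a discretized 2-D Gaussian load centered at the instantaneous
#' CoP, renormalized so the per-frame total equals the subject load exactly.
#' Errors if the CoP leaves the mat extent; warns if it comes within two
#' footprint spreads of the edge (truncation then starts to bias the
#' centroid).
#'
#' @param cop a [cop_trajectory()]
#' @param foot a [foot_model()]
#' @param geom a [mat_geometry()]
#' @return a [pressure_sequence()] in pressure units (newtons per cell)
#' @export
render_pressure <- function(cop, foot, geom) {
  half_x <- geom$n_cols * geom$pitch / 2
  half_y <- geom$n_rows * geom$pitch / 2
  if (any(abs(cop$x_ml) > half_x) || any(abs(cop$y_ap) > half_y))
    stop("CoP trajectory leaves the mat extent")
  if (any(abs(cop$x_ml) > half_x - 2 * foot$spread_ml) ||
      any(abs(cop$y_ap) > half_y - 2 * foot$spread_ap))
    warning("CoP within 2 spreads of the mat edge: footprint truncation may bias the centroid")
  n <- nrow(cop)
  frames <- array(0, dim = c(geom$n_rows, geom$n_cols, n))
  for (k in seq_len(n)) {
    gx <- exp(-(geom$centers_x - cop$x_ml[k])^2 / (2 * foot$spread_ml^2))
    gy <- exp(-(geom$centers_y - cop$y_ap[k])^2 / (2 * foot$spread_ap^2))
    f <- outer(gy, gx)
    frames[, , k] <- f * (foot$load / sum(f))
  }
  pressure_sequence(cop$t, frames, geom, units = "pressure")
}

#' Simulate one mat trial through the full physical chain
#'
#' Composes the forward physics per frame: Gaussian foot pressure -> per-cell
#' conductance (`baseline_g + conductance_per_pressure * p`) -> per-cell
#' first-order sensor lag over time (the time response lives in the
#' piezoresistive material, i.e. in the pressure-to-conductance relation,
#' upstream of the electrical scan) -> full-scan equivalent conductance with
#' row-column crosstalk -> per-cell resistance -> divider readout voltage ->
#' uniform ADC quantization over `[0, v_cc]`. A reference force-platform
#' channel records the true CoP plus small iid Gaussian noise, and the mat
#' channel is delayed by a random integer start offset (the instruments are
#' started independently), so alignment is exercised downstream.
#'
#' @param sway a [sway_model()] (its `seed` drives all randomness of the trial)
#' @param foot a [foot_model()]
#' @param geom a [mat_geometry()]
#' @param circuit a [readout_circuit()]
#' @param dynamics a [dynamics_model()], or NULL to disable sensor lag
#' @param adc_bits ADC resolution; `Inf` disables quantization; default 12
#' @param platform_noise_sd reference-channel noise, cm; default 0.02
#' @param max_offset largest start offset, samples; default 20
#' @param include_crosstalk simulate the network crosstalk (default TRUE);
#'   FALSE short-circuits the scan to the ideal per-cell conductance
#' @return an object of class `trial_recording`: `true_cop`, `platform_cop`,
#'   `mat_voltages` (a [pressure_sequence()] in volts), `start_offset`, and
#'   ground-truth sigmas
#' @export
simulate_trial <- function(sway, foot = foot_model(), geom = mat_geometry(),
                           circuit = readout_circuit(),
                           dynamics = dynamics_model(tau = 0.25, ts = 1 / sway$fs),
                           adc_bits = 12, platform_noise_sd = 0.02,
                           max_offset = 20, include_crosstalk = TRUE) {
  if (!is.null(sway$seed)) set.seed(sway$seed)
  offset <- sample.int(max_offset + 1L, 1L) - 1L
  true_cop <- generate_sway(sway_model(sway$sigma_ml_target, sway$sigma_ap_target,
                                       sway$smoothness, sway$duration, sway$fs,
                                       seed = NULL))
  n <- nrow(true_cop)
  platform_cop <- cop_trajectory(true_cop$t,
                                 true_cop$x_ml + stats::rnorm(n, 0, platform_noise_sd),
                                 true_cop$y_ap + stats::rnorm(n, 0, platform_noise_sd))

  # mat channel delayed by `offset` samples (holds the starting posture before)
  idx <- pmax(seq_len(n) - offset, 1L)
  mat_cop <- cop_trajectory(true_cop$t, true_cop$x_ml[idx], true_cop$y_ap[idx])
  pres <- render_pressure(mat_cop, foot, geom)

  nc <- geom$n_rows * geom$n_cols
  gcells <- foot$baseline_g + foot$conductance_per_pressure * pres$frames
  if (!is.null(dynamics)) {
    gmat <- t(matrix(gcells, nrow = nc, ncol = n))  # time in rows, cells in cols
    gmat <- apply_first_order(gmat, dynamics)
    gcells <- array(t(gmat), dim = dim(gcells))
  }
  volts <- array(0, dim = dim(pres$frames))
  for (k in seq_len(n)) {
    g <- gcells[, , k]
    geq <- if (include_crosstalk) .eq_map(g, 1e-12) else g
    r <- ifelse(geq > 0, 1 / geq, Inf)
    volts[, , k] <- voltage_from_resistance(r, circuit)
  }
  if (is.finite(adc_bits)) {
    q <- circuit$v_cc / (2^adc_bits - 1)
    volts <- pmin(pmax(round(volts / q) * q, 0), circuit$v_cc)
  }

  structure(list(true_cop = true_cop,
                 platform_cop = platform_cop,
                 mat_voltages = pressure_sequence(true_cop$t, volts, geom,
                                                  units = "volts",
                                                  v_cc = circuit$v_cc),
                 start_offset = offset,
                 sigma_ml_true = sway$sigma_ml_target,
                 sigma_ap_true = sway$sigma_ap_target,
                 circuit = circuit, foot = foot, dynamics = dynamics,
                 adc_bits = adc_bits),
            class = "trial_recording")
}

#' Cohort configuration for the synthetic study
#'
#' Defaults reproduce the study conditions: 42 subjects, two single-legged
#' trials each (right leg RL, left leg LL), 60 s at 10 Hz on a 16 x 16 mat.
#' Per-subject sway targets are drawn from a log-normal centered near the
#' reference-platform values (median sigma_ML 0.7 cm, sigma_AP 1.1 cm) with
#' `sigma_sdlog` controlling between-subject heterogeneity (0 = perfectly
#' homogeneous cohort); subject weight is drawn from a normal of mean 74.3 kg,
#' SD 16.34 kg, truncated to [45, 120] kg.
#'
#' @param n_subjects cohort size (>= 2); default 42
#' @param trials trial labels; default `c("RL", "LL")`
#' @param sigma_ml_median,sigma_ap_median medians of the per-subject sway
#'   targets, cm
#' @param sigma_sdlog log-normal sdlog of the sway targets; default 0.3
#' @param platform_noise_sd reference-channel noise, cm
#' @param adc_bits ADC resolution (Inf to disable quantization)
#' @param duration,fs trial length (s) and sampling rate (Hz)
#' @param smoothness AR(1) sway coefficient
#' @param max_offset largest planted start offset, samples
#' @param geom,circuit,dynamics physical models (NULL dynamics disables lag)
#' @param include_crosstalk simulate the network crosstalk
#' @param master_seed integer master seed
#' @return an object of class `cohort_config`
#' @export
cohort_config <- function(n_subjects = 42, trials = c("RL", "LL"),
                          sigma_ml_median = 0.7, sigma_ap_median = 1.1,
                          sigma_sdlog = 0.3, platform_noise_sd = 0.02,
                          adc_bits = 12, duration = 60, fs = 10,
                          smoothness = 0.95, max_offset = 20,
                          geom = mat_geometry(), circuit = readout_circuit(),
                          dynamics = dynamics_model(tau = 0.25, ts = 1 / fs),
                          include_crosstalk = TRUE, master_seed = 1L) {
  stopifnot(n_subjects >= 2, length(trials) >= 1, sigma_sdlog >= 0)
  structure(list(n_subjects = as.integer(n_subjects), trials = trials,
                 sigma_ml_median = sigma_ml_median,
                 sigma_ap_median = sigma_ap_median,
                 sigma_sdlog = sigma_sdlog,
                 platform_noise_sd = platform_noise_sd,
                 adc_bits = adc_bits, duration = duration, fs = fs,
                 smoothness = smoothness, max_offset = max_offset,
                 geom = geom, circuit = circuit, dynamics = dynamics,
                 include_crosstalk = include_crosstalk,
                 master_seed = as.integer(master_seed)),
            class = "cohort_config")
}

#' Simulate a full cohort of mat + platform recordings
#'
#' Draws per-subject parameters (weight, sway targets) from the heterogeneity
#' distributions, then simulates every subject x trial through
#' [simulate_trial()]. Fully reproducible: each trial gets a seed derived from
#' `master_seed`, so regeneration is byte-identical.
#'
#' @param config a [cohort_config()]
#' @return an object of class `cohort_dataset`: list with `config`, `subjects`
#'   (data.frame of drawn parameters), and `recordings` (list indexed by
#'   subject of lists indexed by trial label)
#' @export
simulate_cohort <- function(config = cohort_config()) {
  set.seed(config$master_seed)
  ns <- config$n_subjects
  weight <- pmin(pmax(stats::rnorm(ns, 74.3, 16.34), 45), 120)
  sig_ml <- stats::rlnorm(ns, log(config$sigma_ml_median), config$sigma_sdlog)
  sig_ap <- stats::rlnorm(ns, log(config$sigma_ap_median), config$sigma_sdlog)
  trial_seeds <- matrix(sample.int(.Machine$integer.max - 1L,
                                   ns * length(config$trials)),
                        nrow = ns)
  subjects <- data.frame(subject = seq_len(ns), weight_kg = weight,
                         sigma_ml_target = sig_ml, sigma_ap_target = sig_ap)

  recordings <- vector("list", ns)
  for (s in seq_len(ns)) {
    rec <- list()
    for (ti in seq_along(config$trials)) {
      sw <- sway_model(sig_ml[s], sig_ap[s], config$smoothness,
                       config$duration, config$fs,
                       seed = trial_seeds[s, ti])
      ft <- foot_model(load = weight[s] * 9.81)
      rec[[config$trials[ti]]] <-
        simulate_trial(sw, ft, config$geom, config$circuit, config$dynamics,
                       adc_bits = config$adc_bits,
                       platform_noise_sd = config$platform_noise_sd,
                       max_offset = config$max_offset,
                       include_crosstalk = config$include_crosstalk)
    }
    recordings[[s]] <- rec
  }
  structure(list(config = config, subjects = subjects, recordings = recordings),
            class = "cohort_dataset")
}

#' @export
print.cohort_dataset <- function(x, ...) {
  cat(sprintf("Synthetic cohort: %d subjects x %d trials (%g s at %g Hz, %d x %d mat)\n",
              x$config$n_subjects, length(x$config$trials),
              x$config$duration, x$config$fs,
              x$config$geom$n_rows, x$config$geom$n_cols))
  invisible(x)
}
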