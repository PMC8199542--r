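#' Write a frame sequence to delimited text
#'
#' Plain, inspectable format: `#`-prefixed header lines carrying `n_rows`,
#' `n_cols`, `pitch_cm`, `fs_hz`, `units` (and `v_cc` for voltage frames),
#' then one record per sample — the timestamp followed by the
#' `n_rows * n_cols` cell values in row-major order. Values are written with
#' 17 significant digits, so a write/read round trip reproduces the payload
#' exactly.
#'
#' @param seq a [pressure_sequence()]
#' @param path output file
#' @export
write_frames <- function(seq, path) {
  geom <- seq$geometry
  fs <- if (length(seq$timestamps) > 1) 1 / stats::median(diff(seq$timestamps)) else 0
  hdr <- c(sprintf("# n_rows %d", geom$n_rows),
           sprintf("# n_cols %d", geom$n_cols),
           sprintf("# pitch_cm %.17g", geom$pitch),
           sprintf("# fs_hz %.17g", fs),
           sprintf("# units %s", seq$units))
  if (seq$units == "volts") hdr <- c(hdr, sprintf("# v_cc %.17g", seq$v_cc))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(hdr, con)
  nf <- length(seq$timestamps)
  for (k in seq_len(nf)) {
    vals <- as.vector(t(seq$frames[, , k]))    # row-major
    writeLines(paste(sprintf("%.17g", c(seq$timestamps[k], vals)),
                     collapse = " "), con)
  }
  invisible(path)
}

#' Read a frame sequence written by [write_frames()]
#'
#' Validates record lengths and strictly increasing timestamps, reporting the
#' offending record index on failure.
#'
#' @param path input file
#' @return a [pressure_sequence()]
#' @export
read_frames <- function(path) {
  lines <- readLines(path)
  is_hdr <- startsWith(lines, "#")
  hdr <- lines[is_hdr]
  body <- lines[!is_hdr & nzchar(lines)]
  get <- function(key, required = TRUE) {
    hit <- grep(paste0("^#\\s*", key, "\\s"), hdr, value = TRUE)
    if (length(hit) == 0) {
      if (required) stop(sprintf("missing header field '%s' in %s", key, path))
      return(NULL)
    }
    sub(paste0("^#\\s*", key, "\\s+"), "", hit[1])
  }
  n_rows <- as.integer(get("n_rows")); n_cols <- as.integer(get("n_cols"))
  pitch <- as.numeric(get("pitch_cm"))
  units <- get("units")
  v_cc <- get("v_cc", required = FALSE)
  if (!is.null(v_cc)) v_cc <- as.numeric(v_cc)

  nv <- n_rows * n_cols
  nf <- length(body)
  timestamps <- numeric(nf)
  frames <- array(0, dim = c(n_rows, n_cols, nf))
  for (k in seq_len(nf)) {
    vals <- as.numeric(strsplit(trimws(body[k]), "\\s+")[[1]])
    if (length(vals) != 1 + nv)
      stop(sprintf("record %d has %d values, expected %d (in %s)",
                   k, length(vals), 1 + nv, path))
    timestamps[k] <- vals[1]
    frames[, , k] <- matrix(vals[-1], nrow = n_rows, byrow = TRUE)
  }
  if (nf > 1 && any(diff(timestamps) <= 0))
    stop(sprintf("timestamps not strictly increasing at record %d (in %s)",
                 which(diff(timestamps) <= 0)[1] + 1, path))
  pressure_sequence(timestamps, frames,
                    mat_geometry(n_rows, n_cols, pitch),
                    units = units, v_cc = v_cc)
}

#' Write / read a CoP trajectory as 3-column delimited text
#'
#' Columns: time (s), `x_ml` (cm), `y_ap` (cm); one `#` header line.
#'
#' @param traj a [cop_trajectory()]
#' @param path file path
#' @export
write_cop <- function(traj, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("# t_s x_ml_cm y_ap_cm", con)
  writeLines(sprintf("%.17g %.17g %.17g", traj$t, traj$x_ml, traj$y_ap), con)
  invisible(path)
}

#' @rdname write_cop
#' @return [read_cop()] returns a [cop_trajectory()]
#' @export
read_cop <- function(path) {
  d <- utils::read.table(path, comment.char = "#",
                         col.names = c("t", "x_ml", "y_ap"))
  cop_trajectory(d$t, d$x_ml, d$y_ap)
}

#' Write / read a variant report as a tidy delimited table
#'
#' Columns `variant`, `trial`, `metric`, `icc`, `mae`, `n` — one row per cell
#' of the variant x trial x metric grid.
#'
#' @param report a `variant_report` (see [run_variant_comparison()])
#' @param path file path
#' @export
write_report <- function(report, path) {
  utils::write.table(as.data.frame(report), path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_report
#' @export
read_report <- function(path) {
  utils::read.table(path, sep = "\t", header = TRUE)
}

#' Load and validate a run configuration
#'
#' A single YAML file drives simulation and processing. Recognized keys (all
#' optional, shown with defaults): `circuit` (`v_cc` 3.3, `r_0` 2200, `r_mux`
#' 145, `r_adc` 123000), `geometry` (`n_rows` 16, `n_cols` 16, `pitch` 2),
#' `dynamics` (`tau` 0.25, `ts` 0.1), `inversion` (`max_iter` 100, `tol` 1e-9,
#' `damping` 1), `noise_floor` 0.01, `cohort` (`n_subjects` 42, `duration` 60,
#' `fs` 10, `sigma_sdlog` 0.3, `platform_noise_sd` 0.02, `adc_bits` 12,
#' `master_seed` 1), `variants`, `max_lag` 25.
#'
#' @param path YAML file, or NULL for pure defaults
#' @return a validated list of class `run_config` of constructed model objects
#' @export
run_config <- function(path = NULL) {
  raw <- if (is.null(path)) list() else yaml::read_yaml(path)
  pick <- function(section, key, default) {
    v <- raw[[section]][[key]]
    if (is.null(v)) default else v
  }
  top <- function(key, default) if (is.null(raw[[key]])) default else raw[[key]]

  circuit <- readout_circuit(pick("circuit", "v_cc", 3.3),
                             pick("circuit", "r_0", 2200),
                             pick("circuit", "r_mux", 145),
                             pick("circuit", "r_adc", 123000))
  geom <- mat_geometry(pick("geometry", "n_rows", 16),
                       pick("geometry", "n_cols", 16),
                       pick("geometry", "pitch", 2.0))
  fs <- pick("cohort", "fs", 10)
  dynamics <- dynamics_model(pick("dynamics", "tau", 0.25),
                             pick("dynamics", "ts", 1 / fs))
  inversion <- inversion_settings(pick("inversion", "max_iter", 100),
                                  pick("inversion", "tol", 1e-9),
                                  pick("inversion", "damping", 1.0))
  cohort <- cohort_config(n_subjects = pick("cohort", "n_subjects", 42),
                          sigma_sdlog = pick("cohort", "sigma_sdlog", 0.3),
                          platform_noise_sd = pick("cohort", "platform_noise_sd", 0.02),
                          adc_bits = pick("cohort", "adc_bits", 12),
                          duration = pick("cohort", "duration", 60),
                          fs = fs,
                          master_seed = pick("cohort", "master_seed", 1),
                          geom = geom, circuit = circuit, dynamics = dynamics)
  structure(list(circuit = circuit, geometry = geom, dynamics = dynamics,
                 inversion = inversion,
                 noise_floor = top("noise_floor", 0.01),
                 max_lag = top("max_lag", 25),
                 variants = top("variants", c("raw", "base", "first_order",
                                              "eight_by_eight")),
                 cohort = cohort),
            class = "run_config")
}
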