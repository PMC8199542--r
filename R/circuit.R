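#' Readout circuit of a scanned mat cell
#'
#' The scanning electronics connect the selected row line to the supply through
#' an offset resistor `r_0` and the selected column line to ground, forming a
#' voltage divider with the cell under test. Two non-idealities matter when
#' recovering the cell resistance from the measured voltage: the series
#' resistance of the analog multiplexers (`r_mux`, lumped row + column) and the
#' finite input impedance of the ADC (`r_adc`) which loads the divider.
#'
#' Defaults are the calibrated values of the prototype mat: `r_0` = 2.2 kOhm,
#' `r_mux` = 145 Ohm, `r_adc` = 123 kOhm. The supply is 3.3 V (typical of the
#' microcontroller family used); only the ratio `v_x / v_cc` enters the
#' inversion, so its exact value is immaterial for resistance recovery.
#'
#' @param v_cc supply voltage, volts (> 0)
#' @param r_0 offset resistance, ohms (> 0)
#' @param r_mux lumped multiplexer series resistance, ohms (>= 0)
#' @param r_adc ADC input impedance, ohms (> 0)
#' @return an object of class `readout_circuit`
#' @export
readout_circuit <- function(v_cc = 3.3, r_0 = 2200, r_mux = 145, r_adc = 123000) {
  stopifnot(is.numeric(v_cc), length(v_cc) == 1L, v_cc > 0,
            is.numeric(r_0), r_0 > 0,
            is.numeric(r_mux), r_mux >= 0,
            is.numeric(r_adc), r_adc > 0)
  structure(list(v_cc = v_cc, r_0 = r_0, r_mux = r_mux, r_adc = r_adc),
            class = "readout_circuit")
}

#' @export
print.readout_circuit <- function(x, ...) {
  cat(sprintf("Readout circuit: Vcc = %g V, R0 = %g Ohm, Rmux = %g Ohm, Radc = %g Ohm\n",
              x$v_cc, x$r_0, x$r_mux, x$r_adc))
  cat(sprintf("  open-circuit voltage bound: %.6g V\n", open_circuit_voltage(x)))
  invisible(x)
}

#' Open-circuit voltage bound of the readout divider
#'
#' The voltage measured for an unpressed (open) cell: as the cell resistance
#' grows, the divider saturates at `v_cc * r_adc / (r_0 + r_adc)`.
#'
#' @param circuit a [readout_circuit()]
#' @return volts
#' @export
open_circuit_voltage <- function(circuit) {
  circuit$v_cc * circuit$r_adc / (circuit$r_0 + circuit$r_adc)
}

#' Divider voltage for a given cell resistance
#'
#' Forward model of the scanned-cell circuit:
#' `V_x = V_cc * Z / (R_0 + Z)` with `Z = R_adc || (R_mux + R_x)`.
#' Monotonically increasing in `r_x`; tends to the open-circuit bound as
#' `r_x -> Inf` (`Inf` is accepted and maps to that bound exactly).
#'
#' @param r_x cell resistance(s), ohms, >= 0 (vectorized)
#' @param circuit a [readout_circuit()]
#' @return measured voltage(s), volts
#' @export
voltage_from_resistance <- function(r_x, circuit) {
  stopifnot(all(r_x >= 0))
  s <- circuit$r_mux + r_x
  z <- ifelse(is.infinite(s), circuit$r_adc,
              circuit$r_adc * s / (circuit$r_adc + s))
  circuit$v_cc * z / (circuit$r_0 + z)
}

#' Cell resistance from the measured divider voltage
#'
#' Exact algebraic inverse of [voltage_from_resistance()]:
#' `R_x = v_x / ((V_cc - v_x)/R_0 - v_x/R_adc) - R_mux`, clamped below at 0.
#' Voltages at or above the open-circuit bound denote an unpressed cell and
#' return `Inf` (the caller maps it to zero conductance); non-positive voltages
#' are invalid readings and raise an error.
#'
#' @param v_x measured voltage(s), volts (vectorized)
#' @param circuit a [readout_circuit()]
#' @return cell resistance(s), ohms (`Inf` for open circuit)
#' @export
resistance_from_voltage <- function(v_x, circuit) {
  if (any(v_x <= 0)) stop("invalid reading: voltage must be positive")
  den <- (circuit$v_cc - v_x) / circuit$r_0 - v_x / circuit$r_adc
  r <- ifelse(den <= 0, Inf, v_x / den - circuit$r_mux)
  pmax(r, 0)
}
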