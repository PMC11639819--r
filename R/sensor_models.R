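# Deterministic forward models for the three raw sensors of the portable
# analyzer: a strain-gauge load cell read through a 24-bit ADC, a 970-nm
# near-infrared photosensor, and a swept-frequency impedance converter.
# All quantities are plain numerics in SI-ish field units (kg, V, A, ohm).

#' Two-point load-cell calibration
#'
#' Fits the linear ADC-count-to-weight calibration from two reference
#' readings: the ADC value at zero load and the ADC value under a known
#' load. The slope is \code{known_load_kg / (known_load_counts -
#' zero_load_counts)} and the offset is defined as \code{slope *
#' zero_load_counts}, so that the zero-load reading maps exactly to 0 kg.
#'
#' @param zero_load_counts ADC counts recorded with nothing on the platform.
#' @param known_load_kg Known calibration load in kg; must be positive.
#' @param known_load_counts ADC counts recorded under the known load.
#' @return An object of class `load_cell_calibration`: a list with
#'   `slope_m` (kg per ADC count), `offset_c` (kg), and the three
#'   reference readings.
#' @examples
#' calib <- fit_load_cell_calibration(100000, 30, 400000)
#' calib$slope_m  # 1e-4 kg/count
#' adc_to_weight(400000, calib)  # 30 kg
#' @seealso [adc_to_weight()]
#' @export
fit_load_cell_calibration <- function(zero_load_counts, known_load_kg,
                                      known_load_counts) {
  pbc_check_numeric(zero_load_counts, "zero_load_counts")
  pbc_check_numeric(known_load_counts, "known_load_counts")
  if (!is.numeric(known_load_kg) || !is.finite(known_load_kg) ||
      known_load_kg <= 0) {
    pbc_domain_error("'known_load_kg' must be a positive finite number")
  }
  if (known_load_counts == zero_load_counts) {
    pbc_stop(
      "degenerate calibration: zero-load and known-load ADC counts are equal",
      class = c("pedibca_degenerate_calibration", "pedibca_domain_error")
    )
  }
  slope <- known_load_kg / (known_load_counts - zero_load_counts)
  structure(
    list(
      slope_m = slope,
      offset_c = slope * zero_load_counts,
      ref_zero_load_counts = zero_load_counts,
      ref_load_kg = known_load_kg,
      ref_load_counts = known_load_counts
    ),
    class = "load_cell_calibration"
  )
}

#' @export
print.load_cell_calibration <- function(x, ...) {
  cat("Load-cell calibration\n")
  cat(sprintf("  slope:  %.6g kg/count\n", x$slope_m))
  cat(sprintf("  offset: %.6g kg (zero load at %.6g counts)\n",
              x$offset_c, x$ref_zero_load_counts))
  invisible(x)
}

#' Convert an ADC reading to weight
#'
#' Applies a fitted load-cell calibration: `weight = counts * slope -
#' offset`. A result more negative than `-tol` signals a sensor or
#' calibration fault and raises an invalid-reading error rather than being
#' clamped to zero.
#'
#' @param adc_counts Numeric vector of ADC readings.
#' @param calib A [fit_load_cell_calibration()] object.
#' @param tol Tolerance below zero before a reading is declared invalid.
#' @return Weight(s) in kg.
#' @export
adc_to_weight <- function(adc_counts, calib, tol = 1e-9) {
  stopifnot(inherits(calib, "load_cell_calibration"))
  pbc_check_numeric(adc_counts, "adc_counts")
  w <- adc_counts * calib$slope_m - calib$offset_c
  if (any(w < -tol)) {
    pbc_stop(
      sprintf(
        "invalid load-cell reading: computed weight %.4g kg is negative",
        min(w)
      ),
      class = c("pedibca_invalid_reading", "pedibca_domain_error")
    )
  }
  w
}

#' Optical density of the transmitted near-infrared signal
#'
#' `OD = -log10(V / V0)`, where `V` is the detected photosensor voltage and
#' `V0` the initial (unattenuated) converted voltage. At 970 nm the
#' attenuation is dominated by water absorption, which is what the
#' total-body-water estimate keys on.
#'
#' @param v_volts Detected voltage (V), positive.
#' @param v0_volts Initial voltage (V), positive.
#' @return Optical density (dimensionless).
#' @examples
#' optical_density(0.05, 0.5)  # 1
#' @export
optical_density <- function(v_volts, v0_volts) {
  pbc_check_numeric(v_volts, "v_volts", positive = TRUE)
  pbc_check_numeric(v0_volts, "v0_volts", positive = TRUE)
  -log10(v_volts / v0_volts)
}

#' Transmission factor from optical density
#'
#' `T = 10^(-OD)`; the fraction of incident light transmitted.
#'
#' @param od Optical density (dimensionless, finite).
#' @return Transmission factor in (0, 1] for `od >= 0`.
#' @examples
#' transmission(1)  # 0.1
#' @export
transmission <- function(od) {
  pbc_check_numeric(od, "od")
  10^(-od)
}

#' Reconstruct the detected voltage from V0 and transmission
#'
#' `V = V0 * T`; the self-consistency ("verification") step of the optical
#' chain. Applying it to `transmission(optical_density(v, v0))` recovers
#' `v` exactly.
#'
#' @param v0_volts Initial voltage (V), positive.
#' @param transmission_t Transmission factor in (0, 1].
#' @return Voltage in V.
#' @export
reconstruct_voltage <- function(v0_volts, transmission_t) {
  pbc_check_numeric(v0_volts, "v0_volts", positive = TRUE)
  pbc_check_numeric(transmission_t, "transmission_t")
  if (any(transmission_t <= 0) || any(transmission_t > 1)) {
    pbc_domain_error("'transmission_t' must lie in (0, 1]")
  }
  v0_volts * transmission_t
}

#' Photosensor optical current
#'
#' `I_OC = responsivity * V`, evaluated numerically exactly as the device
#' firmware does (the detected voltage is the operand; with the default
#' responsivity 0.42 a detected 0.05 V yields 0.021 A, i.e. 21 mA).
#'
#' @param v_volts Detected voltage (V), non-negative.
#' @param responsivity Photodetector responsivity; datasheet value 0.42
#'   for the 970-nm sensor.
#' @return Optical current in A.
#' @examples
#' optical_current(0.05)  # 0.021 A
#' @export
optical_current <- function(v_volts, responsivity = 0.42) {
  pbc_check_numeric(v_volts, "v_volts", nonnegative = TRUE)
  pbc_check_numeric(responsivity, "responsivity", positive = TRUE)
  responsivity * v_volts
}

#' Impedance magnitude from a frequency-sweep measurement
#'
#' The impedance converter excites the body with a fixed alternating
#' current (default 0.25 mA at 50 kHz) and reports output/input voltages.
#' The device relation is printed as `1/Z = (Vout - Vin) / Iload`; its
#' literal solution (`mode = "printed"`, the default) is
#' `Z = Iload / (Vout - Vin)`. The conventional Ohm's-law reading
#' `Z = (Vout - Vin) / Iload` is available as `mode = "conventional"` and
#' is the form whose ohm-scale outputs (hundreds of ohms at 0.25 mA) feed
#' the fat-free-mass and muscle-mass equations. The mode used is recorded
#' as an attribute of the result.
#'
#' @param v_out Measured output voltage (V).
#' @param v_in Input-stage voltage (V); must differ from `v_out`.
#' @param i_load_a Excitation current (A), positive; default 0.25 mA.
#' @param mode `"printed"` or `"conventional"` (see Details).
#' @return Impedance magnitude in ohms, with attribute `"mode"`.
#' @examples
#' impedance_from_sweep(1.15385, 1.0, 0.25e-3, mode = "conventional")
#' @export
impedance_from_sweep <- function(v_out, v_in, i_load_a = 0.25e-3,
                                 mode = c("printed", "conventional")) {
  mode <- match.arg(mode)
  pbc_check_numeric(v_out, "v_out")
  pbc_check_numeric(v_in, "v_in")
  pbc_check_numeric(i_load_a, "i_load_a", positive = TRUE)
  dv <- v_out - v_in
  if (any(dv == 0)) {
    pbc_stop(
      "infinite impedance: v_out equals v_in",
      class = c("pedibca_infinite_impedance", "pedibca_domain_error")
    )
  }
  z <- switch(mode,
    printed = i_load_a / abs(dv),
    conventional = abs(dv) / i_load_a
  )
  attr(z, "mode") <- mode
  z
}
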