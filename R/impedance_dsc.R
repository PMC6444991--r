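# lumped electrical model, EIS depth rule, DSC specific heat, AUC descriptor

EPS0 <- 8.8541878128e-12 # vacuum permittivity, F/m

#' Lumped-element skin impedance
#'
#' Single-dispersion quasi-static surrogate for the concentric-electrode
#' measurement: a conductance `G = sigma / kappa` in parallel with a
#' capacitance `C = eps_r * eps0 / kappa`, where `kappa` is the electrode cell
#' constant (m^-1). `Z(f) = 1 / (G + i 2 pi f C)`; `|Z|` decreases strictly
#' with frequency and hydration (higher permittivity and conductivity) lowers
#' it at every frequency. This is deliberately a lumped surrogate for the
#' full-field electrode simulation, not a reproduction of it.
#'
#' @param state [skin_electrical_state()].
#' @param cell_constant Electrode cell constant, m^-1, > 0.
#' @param f Frequency(ies), Hz, > 0.
#' @return Complex impedance, Ohm, one value per frequency.
#' @examples
#' st <- eis_reference_states()
#' Mod(lumped_impedance(st$hydrated, 100, 1e5)) <
#'   Mod(lumped_impedance(st$dehydrated, 100, 1e5))
#' @export
lumped_impedance <- function(state, cell_constant, f) {
  stopifnot(inherits(state, "skin_electrical_state"))
  check_scalar(cell_constant, "cell_constant")
  if (!is.numeric(f) || any(f <= 0)) invalid_parameter("`f` must be > 0")
  G <- state$conductivity / cell_constant
  C <- state$permittivity * EPS0 / cell_constant
  1 / complex(real = G, imaginary = 2 * pi * f * C)
}

#' Measurement depth of a concentric impedance electrode
#'
#' The probing depth of a concentric-ring electrode pair is roughly half the
#' radial spacing between the outer edge of the inner disc and the inner edge
#' of the outer ring. For electrodes quoted by inner-disc diameter (ID) and
#' outer-ring inner diameter (OD), that spacing is `(OD - ID) / 2`; use
#' [electrode_gap()] to derive it.
#'
#' @param gap Radial electrode spacing, um, > 0.
#' @return Measurement depth, um.
#' @export
eis_measurement_depth <- function(gap) {
  check_scalar(gap, "gap")
  gap / 2
}

#' Radial gap of a concentric electrode pair
#'
#' @param id Inner-disc diameter, um.
#' @param od Inner diameter of the outer ring, um.
#' @return Radial gap `(od - id) / 2`, um.
#' @export
electrode_gap <- function(id, od) {
  check_scalar(id, "id")
  check_scalar(od, "od")
  if (od <= id) invalid_parameter("`od` must exceed `id`")
  (od - id) / 2
}

#' Calibrate the DSC instrument factor on a reference material
#'
#' Rearranges `Cp = h / (B * beta)` for the calibration factor:
#' `B = h_ref / (cp_ref * beta)`. Sapphire is the conventional reference; the
#' protocol heating rate is 5 K/min.
#'
#' @param h_ref Heat-flow deviation measured on the reference, W.
#' @param beta Heating rate, K min^-1, > 0.
#' @param cp_ref Known specific heat of the reference, J kg^-1 K^-1, > 0.
#' @return Calibration factor `B`.
#' @export
dsc_calibrate <- function(h_ref, beta, cp_ref) {
  check_scalar(h_ref, "h_ref")
  check_scalar(beta, "beta")
  check_scalar(cp_ref, "cp_ref")
  h_ref / (cp_ref * beta)
}

#' Specific heat from a DSC heat-flow deviation
#'
#' `Cp = h / (B * beta)`; linear in the deviation `h`.
#'
#' @param h Heat-flow deviation(s), W.
#' @param B Calibration factor from [dsc_calibrate()], > 0.
#' @param beta Heating rate, K min^-1, > 0.
#' @return Specific heat, J kg^-1 K^-1.
#' @export
dsc_specific_heat <- function(h, B, beta) {
  if (!is.numeric(h) || any(!is.finite(h))) invalid_parameter("`h` must be finite numeric")
  check_scalar(B, "B")
  check_scalar(beta, "beta")
  h / (B * beta)
}

#' Area under the curve relative to baseline
#'
#' Trapezoidal integral of `(values - baseline)` over time; the summary
#' statistic used to reduce a per-subject time profile to a single number.
#' Exact for piecewise-linear profiles and additive over contiguous time
#' partitions.
#'
#' @param times Measurement times, ascending, >= 2 points (minutes by
#'   convention).
#' @param values Measured quantity at each time.
#' @param baseline Reference level subtracted before integration.
#' @return AUC in value-units times time-units.
#' @export
auc_descriptor <- function(times, values, baseline = 0) {
  if (length(times) != length(values)) {
    invalid_parameter("`times` and `values` must have the same length")
  }
  if (length(times) < 2) invalid_parameter("need at least 2 points")
  if (any(diff(times) <= 0)) invalid_parameter("`times` must be ascending")
  y <- values - baseline
  sum(0.5 * (y[-1] + y[-length(y)]) * diff(times))
}
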