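# domain containers: plain validated S3 records, in the style of survival/ape

#' Thermal properties of a medium
#'
#' Bundle of thermal conductivity and diffusivity, with the volumetric heat
#' capacity derived from their ratio (`rho_cp = k / alpha` after converting
#' `alpha` to SI). These are the three quantities an ETPS fit recovers.
#'
#' @param k Thermal conductivity, W m^-1 K^-1. Must be > 0.
#' @param alpha Thermal diffusivity, mm^2 s^-1. Must be > 0.
#' @return An object of class `thermal_properties` with fields `k`, `alpha`
#'   and derived `rho_cp` (J m^-3 K^-1).
#' @examples
#' water <- thermal_properties(k = 0.6, alpha = 0.1434)
#' water$rho_cp # ~4.18e6 J m^-3 K^-1
#' @export
thermal_properties <- function(k, alpha) {
  check_scalar(k, "k")
  check_scalar(alpha, "alpha")
  out <- list(k = k, alpha = alpha, rho_cp = k / (alpha * 1e-6))
  class(out) <- "thermal_properties"
  out
}

#' @export
print.thermal_properties <- function(x, ...) {
  cat(sprintf(
    "thermal_properties: k = %.4g W/m/K, alpha = %.4g mm^2/s, rho*Cp = %.4g J/m^3/K\n",
    x$k, x$alpha, x$rho_cp
  ))
  invisible(x)
}

#' Sensor geometry and actuation settings
#'
#' Describes the measurement: the physical radius of the disc-shaped resistive
#' element, the calibrated effective radius used in the analytical model, the
#' total actuation power and its duration. When `power` is omitted it is
#' computed from the areal power density over the true sensor area,
#' `power = power_density * pi * true_radius^2`.
#'
#' Defaults follow the skin-measurement protocol: a 0.5 mm radius element
#' driven at 7 mW mm^-2 for 2 s, with a calibrated effective radius of
#' 0.254 mm (roughly half the true radius; see the methods vignette).
#'
#' @param true_radius Physical element radius, mm.
#' @param effective_radius Calibrated model radius, mm; must be in
#'   (0, `true_radius`].
#' @param power Total applied power, W. Optional if `power_density` given.
#' @param power_density Areal power density, W mm^-2. Optional if `power`
#'   given.
#' @param duration Actuation time, s.
#' @return An object of class `sensor_config`.
#' @export
sensor_config <- function(true_radius = 0.5, effective_radius = 0.254,
                          power = NULL, power_density = 7e-3, duration = 2) {
  check_scalar(true_radius, "true_radius")
  check_scalar(effective_radius, "effective_radius")
  check_scalar(duration, "duration")
  if (effective_radius > true_radius) {
    invalid_parameter("`effective_radius` must not exceed `true_radius`")
  }
  if (is.null(power)) {
    if (is.null(power_density)) {
      invalid_parameter("supply `power` or `power_density`")
    }
    check_scalar(power_density, "power_density")
    power <- power_density * pi * true_radius^2
  } else {
    check_scalar(power, "power")
    power_density <- power / (pi * true_radius^2)
  }
  out <- list(
    true_radius = true_radius, effective_radius = effective_radius,
    power = power, power_density = power_density, duration = duration
  )
  class(out) <- "sensor_config"
  out
}

#' @export
print.sensor_config <- function(x, ...) {
  cat(sprintf(
    "sensor_config: a_true = %.3g mm, a_eff = %.3g mm, P0 = %.4g mW, %.3g s\n",
    x$true_radius, x$effective_radius, 1e3 * x$power, x$duration
  ))
  invisible(x)
}

#' Sampled transient temperature-rise curve
#'
#' @param times Sample times, s; strictly increasing, starting at >= 0.
#' @param delta_T Temperature rise above baseline, K; same length as `times`.
#' @param T_inf Baseline (ambient/skin) temperature, K.
#' @return An object of class `transient_curve`.
#' @export
transient_curve <- function(times, delta_T, T_inf = 306.15) {
  if (length(times) != length(delta_T)) {
    invalid_parameter("`times` and `delta_T` must have the same length")
  }
  if (!all(is.finite(times)) || !all(is.finite(delta_T))) {
    invalid_parameter("transient curve must contain finite values only")
  }
  if (length(times) > 0 && times[1] < 0) {
    invalid_parameter("`times` must start at >= 0")
  }
  if (any(diff(times) <= 0)) {
    bad <- which(diff(times) <= 0)[1] + 1L
    schema_error(sprintf("`times` must be strictly increasing (violated at row %d)", bad))
  }
  check_scalar(T_inf, "T_inf")
  out <- list(times = as.numeric(times), delta_T = as.numeric(delta_T), T_inf = T_inf)
  class(out) <- "transient_curve"
  out
}

#' @export
print.transient_curve <- function(x, ...) {
  n <- length(x$times)
  cat(sprintf(
    "transient_curve: %d samples over [%.3g, %.3g] s, peak rise %.3g K (T_inf = %.2f K)\n",
    n, if (n) x$times[1] else NA, if (n) x$times[n] else NA,
    if (n) max(x$delta_T) else NA, x$T_inf
  ))
  invisible(x)
}

#' Constants of the simplified erfc fitting model
#'
#' `A1` is a dimensionless scale and `A2` an effective length (mm); together
#' they absorb the layered device construction, edge effects, convection and
#' the temperature distribution across the element.
#'
#' @param A1 Dimensionless scale, > 0.
#' @param A2 Effective length, mm, > 0.
#' @return An object of class `simplified_fit_constants`.
#' @export
simplified_fit_constants <- function(A1, A2) {
  check_scalar(A1, "A1")
  check_scalar(A2, "A2")
  structure(list(A1 = A1, A2 = A2), class = "simplified_fit_constants")
}

#' Two-phase material: dry-skin matrix with water inclusions
#'
#' Phase constants for the effective-medium model. Defaults are the dry skin /
#' water values used throughout the hydration analysis: densities 900 and
#' 1000 kg m^-3, specific heats 1500 and 4200 J kg^-1 K^-1, conductivities
#' 0.2 and 0.6 W m^-1 K^-1.
#'
#' @param matrix Named list with `rho` (kg m^-3), `cp` (J kg^-1 K^-1),
#'   `k` (W m^-1 K^-1) for the matrix (dry skin).
#' @param inclusion Same triple for the inclusion phase (water).
#' @return An object of class `phase_pair`.
#' @export
phase_pair <- function(matrix = list(rho = 900, cp = 1500, k = 0.2),
                       inclusion = list(rho = 1000, cp = 4200, k = 0.6)) {
  for (ph in list(matrix = matrix, inclusion = inclusion)) {
    for (f in c("rho", "cp", "k")) check_scalar(ph[[f]], f)
  }
  structure(list(matrix = matrix, inclusion = inclusion), class = "phase_pair")
}

#' Periodic two-phase unit cell
#'
#' A square (2D) or cubic (3D) cell of side `d_cell` containing a water
#' inclusion occupying volume fraction `x_cell`: a cylinder for the 2D
#' geometry (maximum fill pi/4), a sphere for 3D (maximum fill pi/6).
#'
#' @param x_cell Water volume fraction, in `[0, max_fill(geometry)]`.
#' @param geometry `"cylinder-2D"` or `"sphere-3D"`.
#' @param d_cell Cell side length, mm. Results for `k` and `rho*Cp` are
#'   scale-invariant in `d_cell`.
#' @param grid_n Finite-volume resolution per axis, >= 16.
#' @return An object of class `unit_cell`.
#' @export
unit_cell <- function(x_cell, geometry = c("cylinder-2D", "sphere-3D"),
                      d_cell = 1, grid_n = NULL) {
  geometry <- match.arg(geometry)
  check_scalar(x_cell, "x_cell", positive = FALSE, nonneg = TRUE)
  if (is.null(grid_n)) grid_n <- if (geometry == "cylinder-2D") 64L else 32L
  check_scalar(grid_n, "grid_n")
  if (grid_n < 16) invalid_parameter("`grid_n` must be >= 16")
  check_scalar(d_cell, "d_cell")
  mf <- max_fill(geometry)
  if (x_cell > mf) {
    invalid_parameter(sprintf(
      "`x_cell` = %.3g exceeds the maximum geometric fill %.3g for %s",
      x_cell, mf, geometry
    ))
  }
  structure(list(
    x_cell = x_cell, geometry = geometry,
    d_cell = d_cell, grid_n = as.integer(grid_n)
  ), class = "unit_cell")
}

#' Frequency-indexed complex impedance record
#'
#' @param frequencies Frequencies, Hz, ascending.
#' @param impedance Complex impedance, Ohm, one value per frequency.
#' @param drive_voltage Drive amplitude, V peak-to-peak.
#' @param instrument Logical; if `TRUE` the spectrum is validated against the
#'   acquisition band of the instrument (10 kHz to 1.2 MHz).
#' @return An object of class `impedance_spectrum`.
#' @export
impedance_spectrum <- function(frequencies, impedance, drive_voltage = 2,
                               instrument = FALSE) {
  if (length(frequencies) != length(impedance)) {
    invalid_parameter("`frequencies` and `impedance` must have the same length")
  }
  if (any(diff(frequencies) <= 0)) schema_error("`frequencies` must be ascending")
  if (any(Mod(impedance) <= 0)) invalid_parameter("|Z| must be > 0 at all frequencies")
  if (instrument && (any(frequencies < 10e3) || any(frequencies > 1.2e6))) {
    schema_error("instrument spectra must lie within [10 kHz, 1.2 MHz]")
  }
  structure(list(
    frequencies = as.numeric(frequencies),
    impedance = as.complex(impedance),
    drive_voltage = drive_voltage, instrument = instrument
  ), class = "impedance_spectrum")
}

#' Electrical state of skin for the lumped impedance model
#'
#' Relative permittivity and conductivity of the probed tissue. The reference
#' states used in the field simulations are available from
#' [eis_reference_states()]: dehydrated skin (eps_r = 1133.6,
#' sigma = 2.04e-4 S/m) and hydrated skin (eps_r = 29010, sigma = 2.93e-3 S/m).
#'
#' @param permittivity Relative permittivity, dimensionless, > 0.
#' @param conductivity Conductivity, S m^-1, > 0.
#' @return An object of class `skin_electrical_state`.
#' @export
skin_electrical_state <- function(permittivity, conductivity) {
  check_scalar(permittivity, "permittivity")
  check_scalar(conductivity, "conductivity")
  structure(list(permittivity = permittivity, conductivity = conductivity),
    class = "skin_electrical_state"
  )
}

#' Reference electrical states for dehydrated and hydrated skin
#'
#' @return Named list with `dehydrated` and `hydrated`
#'   [skin_electrical_state()] objects.
#' @export
eis_reference_states <- function() {
  list(
    dehydrated = skin_electrical_state(1133.6, 2.04e-4),
    hydrated = skin_electrical_state(29010, 2.93e-3)
  )
}

#' Differential scanning calorimetry record
#'
#' Carries the baseline-referenced heat-flow deviation `h`, the heating rate
#' `beta` and the sapphire-derived calibration factor `B` of the relation
#' `Cp = h / (B * beta)`. Baseline subtraction and pan-mass normalisation are
#' assumed done upstream.
#'
#' @param h Heat-flow deviation, W.
#' @param beta Heating rate, K min^-1, > 0.
#' @param B Calibration factor, > 0.
#' @return An object of class `dsc_record`.
#' @export
dsc_record <- function(h, beta = 5, B = 1) {
  if (!is.numeric(h) || !all(is.finite(h))) invalid_parameter("`h` must be finite numeric")
  check_scalar(beta, "beta")
  check_scalar(B, "B")
  structure(list(h = h, beta = beta, B = B), class = "dsc_record")
}
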