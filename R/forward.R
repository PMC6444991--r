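# forward models of the ETPS measurement

#' Dimensionless time of a plane-source measurement
#'
#' `tau = t * alpha / a^2`, the time variable of the shape function.
#'
#' @param t Time(s), s, >= 0.
#' @param alpha Thermal diffusivity, mm^2 s^-1, > 0.
#' @param a Source radius, mm, > 0.
#' @return Dimensionless `tau`, same length as `t`.
#' @examples
#' dimensionless_time(2, alpha = 0.1, a = 0.254) # ~3.100
#' @export
dimensionless_time <- function(t, alpha, a) {
  if (!is.numeric(t) || any(!is.finite(t)) || any(t < 0)) {
    invalid_parameter("`t` must be finite and >= 0")
  }
  check_scalar(alpha, "alpha")
  check_scalar(a, "a")
  t * alpha / a^2 # mm^2/s and mm^2 cancel
}

#' Mean temperature rise of a disc plane source
#'
#' The spatially averaged temperature rise of a disc-shaped resistive element
#' of effective radius `a` driven at constant power `P0` on a thermally
#' semi-infinite medium:
#' `dT(t) = P0 * pi^(-3/2) / (a * k) * D(t * alpha / a^2)`.
#' The rise is proportional to `P0` and inversely proportional to `k` at fixed
#' dimensionless time.
#'
#' @param props [thermal_properties()] of the medium.
#' @param cfg [sensor_config()]; the effective radius and power are used.
#' @param times Sample times, s, within `[0, cfg$duration]`.
#' @param method Shape-function evaluation method, see [tps_shape_function()].
#' @return Temperature rise in K at each time.
#' @examples
#' cfg <- sensor_config()
#' mean_temperature_rise(thermal_properties(0.6, 0.1434), cfg, c(0.5, 1, 2))
#' @export
mean_temperature_rise <- function(props, cfg, times, method = "interpolate") {
  stopifnot(inherits(props, "thermal_properties"), inherits(cfg, "sensor_config"))
  if (any(times < 0) || any(times > cfg$duration + 1e-9)) {
    invalid_parameter("`times` must lie within [0, cfg$duration]")
  }
  a <- cfg$effective_radius * 1e-3 # m
  alpha <- props$alpha * 1e-6 # m^2/s
  tau <- times * alpha / a^2
  cfg$power / (pi^1.5 * a * props$k) * tps_shape_function(tau, method = method)
}

#' Characteristic thermal diffusion length
#'
#' `Lambda = Pi * sqrt(alpha * t)`, the depth probed by a transient of
#' duration `t` in a medium of diffusivity `alpha`; `Pi` is a dimensionless
#' factor of order unity. For `alpha = 0.1` mm^2/s and `t = 2` s the probing
#' depth is ~450 um, several times the epidermal thickness.
#'
#' @param alpha Thermal diffusivity, mm^2 s^-1, >= 0.
#' @param t Time, s, >= 0.
#' @param Pi Dimensionless prefactor, default 1.
#' @return Diffusion length in um.
#' @export
diffusion_length <- function(alpha, t, Pi = 1) {
  if (!is.numeric(alpha) || any(alpha < 0)) invalid_parameter("`alpha` must be >= 0")
  if (!is.numeric(t) || any(t < 0)) invalid_parameter("`t` must be >= 0")
  check_scalar(Pi, "Pi")
  1000 * Pi * sqrt(alpha * t) # mm -> um
}

erfc <- function(x) 2 * pnorm(x * sqrt(2), lower.tail = FALSE)

#' Simplified erfc model of the transient rise
#'
#' A two-constant closed form used for rapid batch fitting:
#' `T(t) = T_inf + A1 * P0 / (2 * pi * A2 * k) * erfc(A2 / (2 * sqrt(alpha * t)))`,
#' the point-source half-space solution evaluated at an effective distance
#' `A2`, scaled by `A1`. The constants absorb the layered device construction,
#' edge effects and convection, and are calibrated against materials of known
#' properties (see [fit_simplified_constants()]). The model runs from
#' `T_inf` at `t -> 0` to `T_inf + A1*P0/(2*pi*A2*k)` as `t -> Inf` and is
#' monotone increasing in `t`.
#'
#' @param t Time(s), s, >= 0; `t = 0` returns the `T_inf` limit.
#' @param consts [simplified_fit_constants()].
#' @param k Thermal conductivity, W m^-1 K^-1.
#' @param alpha Thermal diffusivity, mm^2 s^-1.
#' @param P0 Total power, W.
#' @param T_inf Baseline temperature, K (default 0 gives the rise itself).
#' @return Temperature (or rise, for `T_inf = 0`) in K.
#' @export
simplified_rise <- function(t, consts, k, alpha, P0, T_inf = 0) {
  stopifnot(inherits(consts, "simplified_fit_constants"))
  check_scalar(k, "k")
  check_scalar(alpha, "alpha")
  check_scalar(P0, "P0")
  if (any(t < 0)) invalid_parameter("`t` must be >= 0")
  A2 <- consts$A2 * 1e-3 # m
  alpha_si <- alpha * 1e-6
  amp <- consts$A1 * P0 / (2 * pi * A2 * k)
  out <- rep(T_inf, length(t))
  pos <- t > 0
  out[pos] <- T_inf + amp * erfc(A2 / (2 * sqrt(alpha_si * t[pos])))
  out
}

#' Calibrate the simplified-model constants against a reference curve
#'
#' Least-squares fit of `A1` and `A2` so that the erfc model reproduces a
#' transient generated (or measured) at known `k` and `alpha`. Used to anchor
#' the fast fitting path to the exact plane-source model.
#'
#' @param curve [transient_curve()] to match.
#' @param props Known [thermal_properties()] of the reference medium.
#' @param cfg [sensor_config()].
#' @param init Starting values, `c(A1, A2_mm)`.
#' @return [simplified_fit_constants()] with an `sse` attribute.
#' @export
fit_simplified_constants <- function(curve, props, cfg, init = c(1, 0.5)) {
  stopifnot(inherits(curve, "transient_curve"))
  pos <- curve$times > 0
  tt <- curve$times[pos]
  yy <- curve$delta_T[pos]
  resid <- function(p) {
    simplified_rise(tt, simplified_fit_constants(p[1], p[2]),
      k = props$k, alpha = props$alpha, P0 = cfg$power
    ) - yy
  }
  fit <- minpack.lm::nls.lm(
    par = init, fn = resid,
    lower = c(1e-6, 1e-4), upper = c(1e3, 50),
    control = minpack.lm::nls.lm.control(ftol = 1e-12, ptol = 1e-10, maxiter = 500)
  )
  out <- simplified_fit_constants(fit$par[1], fit$par[2])
  attr(out, "sse") <- sum(fit$fvec^2)
  out
}
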