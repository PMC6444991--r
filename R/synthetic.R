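# seeded generators of synthetic measurement data: TPS transients, porcine-style
# hydration sweeps, impedance spectra, and clinical-protocol time series

#' Additive Gaussian noise model
#'
#' @param sigma Standard deviation of additive noise. For transients this is
#'   in K; `NULL` (the default) resolves to 1% of the peak rise of the curve
#'   being generated, a typical thermistor-class precision. Use `0` for
#'   noiseless output. For spectra the same field is interpreted as a relative
#'   standard deviation.
#' @param seed Integer seed; generation is bit-reproducible given the seed and
#'   leaves the global RNG state untouched.
#' @return An object of class `noise_model`.
#' @export
noise_model <- function(sigma = NULL, seed = NULL) {
  if (!is.null(sigma)) check_scalar(sigma, "sigma", positive = FALSE, nonneg = TRUE)
  if (!is.null(seed)) check_scalar(seed, "seed", positive = FALSE)
  structure(list(sigma = sigma, seed = seed), class = "noise_model")
}

# run code under a local RNG state
with_seed <- function(seed, code) {
  if (is.null(seed)) {
    return(code)
  }
  if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())), add = TRUE)
  }
  set.seed(as.integer(seed))
  code
}

#' Generate a synthetic ETPS transient
#'
#' Forward plane-source model sampled at `sampling` Hz over the actuation
#' window, plus additive Gaussian noise. With `sigma = 0` the curve equals the
#' forward model exactly; with a seed, repeated calls are identical.
#'
#' @param props [thermal_properties()] of the simulated medium.
#' @param cfg [sensor_config()] (default: 7 mW mm^-2 for 2 s).
#' @param sampling Sampling rate, Hz (default 100).
#' @param noise [noise_model()].
#' @param T_inf Baseline temperature, K.
#' @return [transient_curve()] with attribute `truth` holding `props`.
#' @export
generate_transient <- function(props, cfg = sensor_config(), sampling = 100,
                               noise = noise_model(), T_inf = 306.15) {
  check_scalar(sampling, "sampling")
  times <- seq(1 / sampling, cfg$duration, by = 1 / sampling)
  clean <- mean_temperature_rise(props, cfg, times)
  sigma <- if (is.null(noise$sigma)) 0.01 * max(clean) else noise$sigma
  dT <- if (sigma > 0) {
    with_seed(noise$seed, clean + rnorm(length(clean), 0, sigma))
  } else {
    clean
  }
  out <- transient_curve(times, dT, T_inf = T_inf)
  attr(out, "truth") <- props
  attr(out, "sigma") <- sigma
  out
}

#' Generate a hydration sweep of synthetic transients
#'
#' Emulates the soaked-tissue experiment: for each water fraction the
#' effective-medium model supplies the bulk properties (2D unit-cell
#' conductivity; volume-mixture heat capacity), and a transient is generated
#' from them. Conductivity rises with hydration, so the peak temperature rise
#' falls monotonically across the sweep.
#'
#' @param x_values Water fractions, each within the cylinder fill limit.
#' @param phases [phase_pair()].
#' @param cfg [sensor_config()].
#' @param noise [noise_model()]; curve `i` is seeded with `seed + i`.
#' @param sampling Sampling rate, Hz.
#' @param grid_n Unit-cell resolution for the conductivity solves.
#' @return List with `properties` (a `data.frame` of `x`, `k`, `rho_cp`,
#'   `alpha`) and `curves` (a list of [transient_curve()]s named by `x`).
#' @export
generate_hydration_sweep <- function(x_values, phases = phase_pair(),
                                     cfg = sensor_config(), noise = noise_model(),
                                     sampling = 100, grid_n = 64) {
  if (any(x_values > max_fill("cylinder-2D"))) {
    invalid_parameter("`x_values` must not exceed the cylinder fill limit")
  }
  props_tab <- do.call(rbind, lapply(x_values, function(x) {
    cell <- unit_cell(x, "cylinder-2D", grid_n = grid_n)
    k <- unit_cell_k(cell, phases)
    rc <- as.numeric(unit_cell_rho_cp(cell, phases))
    data.frame(x = x, k = k, rho_cp = rc, alpha = 1e6 * k / rc)
  }))
  curves <- lapply(seq_along(x_values), function(i) {
    nm <- if (is.null(noise$seed)) noise else noise_model(noise$sigma, noise$seed + i)
    generate_transient(
      thermal_properties(props_tab$k[i], props_tab$alpha[i]),
      cfg,
      sampling = sampling, noise = nm
    )
  })
  names(curves) <- sprintf("x=%g", x_values)
  list(properties = props_tab, curves = curves)
}

#' Clinical protocol timeline
#'
#' Measurement times (minutes relative to treatment application) and study
#' arms of the forearm protocol: a baseline reading 15 min before application,
#' one immediately after, follow-ups at 30, 60 and 270 min, and a final
#' reading at 300 min taken after cleaning off the compound.
#'
#' @param times Measurement times, min, ascending.
#' @param arms Study arms; subset of `"patch"`, `"glycerin_0"`,
#'   `"glycerin_15"`, `"glycerin_30"`.
#' @return An object of class `protocol_timeline`.
#' @export
protocol_timeline <- function(times = c(-15, 0, 30, 60, 270, 300),
                              arms = c("patch", "glycerin_0", "glycerin_15", "glycerin_30")) {
  if (any(diff(times) <= 0)) invalid_parameter("`times` must be ascending")
  allowed <- c("patch", "glycerin_0", "glycerin_15", "glycerin_30")
  if (!all(arms %in% allowed)) {
    invalid_parameter(paste("arms must be among:", paste(allowed, collapse = ", ")))
  }
  structure(list(times = times, arms = arms), class = "protocol_timeline")
}

# time-weight profile of each arm: 0 at baseline, 1 at full effect
arm_weight <- function(arm, times, patch_duration = 15) {
  vapply(times, function(t) {
    if (t < 0) {
      return(0)
    }
    switch(arm,
      patch = exp(-t / (patch_duration / 2)), # back to baseline within ~30 min
      glycerin_0 = if (t <= 270) 1 else 0.1, # removal returns near baseline
      glycerin_15 = if (t <= 270) 1 else 0.6, # persistent after removal
      glycerin_30 = if (t <= 270) 1 else 0.6,
      invalid_parameter(sprintf("unknown arm '%s'", arm))
    )
  }, numeric(1))
}

#' Generate a clinical-style multimodal time series
#'
#' Seeded emulation of one protocol arm: each measured quantity follows
#' `baseline + effect * w(t) + noise`, where the weight profile `w` encodes
#' the arm behaviour. The occlusive-patch effect decays back to baseline
#' within ~30 min of application; glycerin-containing compounds hold their
#' effect through the 270 min reading, and after removal at 300 min the
#' thermal conductivity stays above baseline while the glycerin-free compound
#' returns close to it.
#'
#' @param timeline [protocol_timeline()].
#' @param arm One arm name from the timeline.
#' @param effect_sizes Named list of full-effect deltas:
#'   `k` (W m^-1 K^-1), `alpha` (mm^2 s^-1), `impedance` (fractional change
#'   of `|Z|`), `corneometer` (instrument units). Defaults are
#'   hydration-like: `k` up, `alpha` down, `|Z|` down, corneometer up.
#' @param noise [noise_model()]; `sigma` scales each quantity's own noise
#'   floor fractionally (default `NULL` means 1%).
#' @param baseline Named list of baseline values.
#' @param patch_duration Occlusion time, min (quoted values differ between
#'   protocol descriptions; 15 or 30).
#' @return `data.frame` with columns `time`, `arm`, `k`, `alpha`,
#'   `impedance_mod`, `corneometer`.
#' @export
generate_trial_series <- function(timeline = protocol_timeline(), arm,
                                  effect_sizes = list(
                                    k = 0.05, alpha = -0.02,
                                    impedance = -0.30, corneometer = 15
                                  ),
                                  noise = noise_model(),
                                  baseline = list(
                                    k = 0.30, alpha = 0.12,
                                    impedance = 50e3, corneometer = 35
                                  ),
                                  patch_duration = 15) {
  stopifnot(inherits(timeline, "protocol_timeline"))
  if (!arm %in% timeline$arms) invalid_parameter(sprintf("unknown arm '%s'", arm))
  w <- arm_weight(arm, timeline$times, patch_duration)
  frac <- if (is.null(noise$sigma)) 0.01 else noise$sigma
  n <- length(timeline$times)
  with_seed(noise$seed, {
    mknoise <- function(scale) if (frac > 0) rnorm(n, 0, frac * abs(scale)) else numeric(n)
    data.frame(
      time = timeline$times,
      arm = arm,
      k = baseline$k + effect_sizes$k * w + mknoise(baseline$k),
      alpha = baseline$alpha + effect_sizes$alpha * w + mknoise(baseline$alpha),
      impedance_mod = baseline$impedance * (1 + effect_sizes$impedance * w) +
        mknoise(baseline$impedance),
      corneometer = baseline$corneometer + effect_sizes$corneometer * w +
        mknoise(baseline$corneometer)
    )
  })
}

#' Generate a synthetic impedance spectrum
#'
#' Lumped-model spectrum for a given electrical state with optional
#' multiplicative Gaussian noise on the complex impedance.
#'
#' @param state [skin_electrical_state()].
#' @param cell_constant Electrode cell constant, m^-1.
#' @param frequencies Frequencies, Hz (default 60 log-spaced points over the
#'   instrument band, 10 kHz to 1.2 MHz).
#' @param noise [noise_model()]; `sigma` is the relative noise level
#'   (`NULL` means 1%).
#' @return [impedance_spectrum()].
#' @export
generate_spectrum <- function(state, cell_constant = 100,
                              frequencies = exp(seq(log(10e3), log(1.2e6), length.out = 60)),
                              noise = noise_model()) {
  z <- lumped_impedance(state, cell_constant, frequencies)
  frac <- if (is.null(noise$sigma)) 0.01 else noise$sigma
  if (frac > 0) {
    z <- with_seed(
      noise$seed,
      z * (1 + complex(
        real = rnorm(length(z), 0, frac),
        imaginary = rnorm(length(z), 0, frac)
      ))
    )
  }
  impedance_spectrum(frequencies, z, instrument = TRUE)
}
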