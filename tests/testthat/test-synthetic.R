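test_that("noiseless generation reproduces the forward model exactly", {
  props <- thermal_properties(0.35, 0.11)
  cfg <- sensor_config()
  cur <- generate_transient(props, cfg, noise = noise_model(0))
  expect_identical(cur$delta_T, mean_temperature_rise(props, cfg, cur$times))
  expect_equal(length(cur$times), 200) # 100 Hz over 2 s
})

test_that("generation is bit-reproducible under a fixed seed", {
  props <- thermal_properties(0.35, 0.11)
  a <- generate_transient(props, noise = noise_model(0.05, seed = 42))
  b <- generate_transient(props, noise = noise_model(0.05, seed = 42))
  d <- generate_transient(props, noise = noise_model(0.05, seed = 43))
  expect_identical(a$delta_T, b$delta_T)
  expect_false(identical(a$delta_T, d$delta_T))
  # the generator does not disturb the global RNG stream
  set.seed(7)
  r1 <- runif(1)
  set.seed(7)
  invisible(generate_transient(props, noise = noise_model(0.05, seed = 1)))
  r2 <- runif(1)
  expect_identical(r1, r2)
})

test_that("hydration sweep: conductivity rises, peak temperature falls", {
  sweep <- generate_hydration_sweep(c(0.1, 0.3, 0.5),
    noise = noise_model(0, seed = 1), grid_n = 32
  )
  expect_true(all(diff(sweep$properties$k) > 0))
  peaks <- vapply(sweep$curves, function(cu) max(cu$delta_T), numeric(1))
  expect_true(all(diff(peaks) < 0))
  # endpoint: a dry cell reproduces the dry-skin conductivity
  dry <- generate_hydration_sweep(0, noise = noise_model(0), grid_n = 32)
  expect_equal(dry$properties$k, 0.2, tolerance = 1e-6)
  expect_equal(dry$properties$rho_cp, 900 * 1500, tolerance = 1e-9)
  # fitted conductivities recover the sweep ordering
  cfg <- sensor_config()
  k_hat <- vapply(sweep$curves, function(cu) fit_tps(cu, cfg)$props$k, numeric(1))
  expect_true(all(diff(k_hat) > 0))
  expect_equal(unname(k_hat), sweep$properties$k, tolerance = 0.01)
})

test_that("trial series encode the arm-specific recovery behaviour", {
  tl <- protocol_timeline()
  zero <- list(k = 0, alpha = 0, impedance = 0, corneometer = 0)
  flat <- generate_trial_series(tl, "patch", effect_sizes = zero, noise = noise_model(0))
  expect_true(all(flat$k == 0.30))
  expect_true(all(flat$impedance_mod == 50e3))
  expect_equal(auc_descriptor(flat$time, flat$k, baseline = 0.30), 0)

  patch <- generate_trial_series(tl, "patch", noise = noise_model(0))
  base_k <- patch$k[patch$time == -15]
  expect_gt(patch$k[patch$time == 0], base_k) # effect right after removal
  expect_lt(patch$k[patch$time == 30] - base_k, 0.1 * (patch$k[patch$time == 0] - base_k))

  gly <- generate_trial_series(tl, "glycerin_15", noise = noise_model(0))
  expect_gt(gly$k[gly$time == 300], base_k) # persists after removal
  expect_lt(gly$impedance_mod[gly$time == 60], gly$impedance_mod[gly$time == -15])

  gly0 <- generate_trial_series(tl, "glycerin_0", noise = noise_model(0))
  expect_lt(
    gly0$k[gly0$time == 300] - base_k,
    0.5 * (gly$k[gly$time == 300] - base_k)
  )
  expect_error(
    generate_trial_series(tl, "vaseline", noise = noise_model(0)),
    class = "etps_invalid_parameter"
  )
})

test_that("synthetic spectra live in the instrument band and respond to hydration", {
  st <- eis_reference_states()
  sp_dry <- generate_spectrum(st$dehydrated, noise = noise_model(0.01, seed = 5))
  sp_wet <- generate_spectrum(st$hydrated, noise = noise_model(0.01, seed = 5))
  expect_s3_class(sp_dry, "impedance_spectrum")
  expect_true(all(sp_dry$frequencies >= 10e3 & sp_dry$frequencies <= 1.2e6))
  expect_true(mean(Mod(sp_wet$impedance) < Mod(sp_dry$impedance)) > 0.95)
  again <- generate_spectrum(st$dehydrated, noise = noise_model(0.01, seed = 5))
  expect_identical(sp_dry$impedance, again$impedance)
})
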