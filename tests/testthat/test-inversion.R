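test_that("noiseless synthetic transients round-trip through the fit", {
  cfg <- ref_cfg()
  fit <- fit_tps(ref_curve(), cfg)
  expect_true(fit$converged)
  expect_lt(abs(fit$props$k - 0.4) / 0.4, 0.01)
  expect_lt(abs(fit$props$alpha - 0.10) / 0.10, 0.05)
  expect_lt(fit$sse, 1e-10)
})

test_that("degenerate and undersized curves are rejected", {
  cfg <- ref_cfg()
  zeros <- transient_curve(seq(0.01, 2, by = 0.01), rep(0, 200))
  expect_error(fit_tps(zeros, cfg), class = "etps_degenerate_input")
  short <- transient_curve(seq(0.1, 2, by = 0.5), rep(1, 4))
  expect_error(fit_tps(short, cfg), class = "etps_invalid_parameter")
})

test_that("noisy round-trips recover k tightly and alpha loosely", {
  cfg <- ref_cfg()
  truth <- ref_truth()
  errs <- t(vapply(1:8, function(s) {
    cur <- generate_transient(truth, cfg, noise = noise_model(seed = s)) # 1% of peak
    f <- fit_tps(cur, cfg)
    c(
      k = abs(f$props$k - truth$k) / truth$k,
      alpha = abs(f$props$alpha - truth$alpha) / truth$alpha
    )
  }, c(k = 0, alpha = 0)))
  expect_lt(median(errs[, "k"]), 0.02)
  expect_lt(median(errs[, "alpha"]), 0.10)
})

test_that("fit is invariant to doubling the sampling density", {
  cfg <- ref_cfg()
  truth <- thermal_properties(0.32, 0.13)
  f1 <- fit_tps(generate_transient(truth, cfg, sampling = 100, noise = noise_model(0)), cfg)
  f2 <- fit_tps(generate_transient(truth, cfg, sampling = 200, noise = noise_model(0)), cfg)
  expect_lt(abs(f1$props$k - f2$props$k) / f1$props$k, 0.005)
  expect_lt(abs(f1$props$alpha - f2$props$alpha) / f1$props$alpha, 0.005)
})

test_that("effective radius calibrates back from reference materials", {
  cfg <- ref_cfg() # generated with a_eff = 0.254 mm
  refs <- list(
    list( # water
      curve = generate_transient(thermal_properties(0.6, 0.1434), cfg, noise = noise_model(0)),
      props = thermal_properties(0.6, 0.1434)
    ),
    list( # ethylene glycol
      curve = generate_transient(thermal_properties(0.254, 0.094), cfg, noise = noise_model(0)),
      props = thermal_properties(0.254, 0.094)
    )
  )
  a_hat <- calibrate_effective_radius(refs, cfg)
  expect_lt(abs(a_hat - 0.254) / 0.254, 0.02)
  # for this sensor class the calibrated radius is about half the true radius
  expect_gt(a_hat / cfg$true_radius, 0.35)
  expect_lt(a_hat / cfg$true_radius, 0.65)
  # single exact reference: the optimum is an essentially perfect fit
  one <- calibrate_effective_radius(refs[1], cfg)
  c2 <- cfg
  c2$effective_radius <- one
  resid <- mean_temperature_rise(refs[[1]]$props, c2, refs[[1]]$curve$times) -
    refs[[1]]$curve$delta_T
  expect_lt(sum(resid^2), 1e-8)
})

test_that("volumetric heat capacity is the SI ratio k/alpha", {
  water <- thermal_properties(0.6, 0.1434)
  expect_equal(volumetric_heat_capacity(water), 4.18e6, tolerance = 2e-3)
  expect_equal(volumetric_heat_capacity(0, alpha = 0.1), 0)
  expect_error(volumetric_heat_capacity(0.4, alpha = 0), class = "etps_invalid_parameter")
  # scaling both k and alpha leaves the ratio unchanged
  expect_equal(
    volumetric_heat_capacity(thermal_properties(0.8, 0.2)),
    volumetric_heat_capacity(thermal_properties(0.4, 0.1))
  )
})

test_that("sensitivity scan is antisymmetric and identity at zero perturbation", {
  cfg <- ref_cfg()
  cur <- ref_curve()
  fit <- fit_tps(cur, cfg)
  tab <- sensitivity_scan(cur, cfg, fit, which = "alpha", perturbations = c(-0.05, 0, 0.05))
  expect_equal(tab$shift[tab$perturbation == 0], 0)
  expect_true(all(tab$converged))
  s_neg <- tab$shift[tab$perturbation == -0.05]
  s_pos <- tab$shift[tab$perturbation == 0.05]
  expect_lt(s_neg, 0)
  expect_gt(s_pos, 0)
})

test_that("error surface minimum sits at the best fit with k-dominated growth", {
  cfg <- ref_cfg()
  cur <- ref_curve()
  fit <- fit_tps(cur, cfg)
  surf <- error_surface(cur, cfg, fit, span = 0.15, n_per_axis = 31)
  expect_equal(dim(surf$sse), c(31, 31))
  expect_true(all(surf$sse >= 0))
  # global grid minimum at the central (best-fit) cell
  expect_equal(unname(surf$minimum_index), c(16L, 16L))
  # SSE climbs far faster along k than along alpha at the +/-15% edges
  ctr <- 16L
  growth_k <- surf$sse[c(1, 31), ctr]
  growth_a <- surf$sse[ctr, c(1, 31)]
  expect_gt(min(growth_k) / max(growth_a), 5)
})
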