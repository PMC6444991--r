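test_that("mixture density and specific heat interpolate the phase constants", {
  expect_equal(mixture_density(c(0, 0.5, 1)), c(900, 950, 1000))
  expect_equal(mixture_specific_heat(c(0, 0.5, 1)), c(1500, 2850, 4200))
  expect_error(mixture_density(1.2), class = "etps_invalid_parameter")
  expect_error(mixture_specific_heat(-0.1), class = "etps_invalid_parameter")
})

test_that("volumetric heat capacity slope splits into density and Cp terms", {
  # density term = (drho/dx) * Cp(x); Cp term = (dCp/dx) * rho(x)
  s0 <- rho_cp_slope(0)
  expect_equal(s0$density_term, 100 * 1500) # 1.5e5
  expect_equal(s0$cp_term, 2700 * 900) # 2.43e6
  s1 <- rho_cp_slope(1)
  expect_equal(s1$density_term, 100 * 4200) # 4.2e5
  expect_equal(s1$cp_term, 2700 * 1000) # 2.7e6
  # the Cp contribution dominates at both endpoints
  expect_gt(s0$cp_term / s0$density_term, 10)
  expect_gt(s1$cp_term / s1$density_term, 1)
  expect_equal(s0$total, s0$density_term + s0$cp_term)
  # consistency with a numerical derivative of rho(x) * Cp(x)
  h <- 1e-6
  num_d <- (mixture_density(0.3 + h) * mixture_specific_heat(0.3 + h) -
    mixture_density(0.3 - h) * mixture_specific_heat(0.3 - h)) / (2 * h)
  expect_equal(rho_cp_slope(0.3)$total, num_d, tolerance = 1e-6)
})

test_that("arithmetic and harmonic mixtures bound the conductivity", {
  b <- k_mixture_bounds(c(0, 0.5, 1))
  expect_equal(b[1, ], c(lower = 0.2, upper = 0.2))
  expect_equal(b[3, ], c(lower = 0.6, upper = 0.6))
  expect_equal(unname(b[2, "lower"]), 0.3) # 2 / (1/0.2 + 1/0.6)
  expect_equal(unname(b[2, "upper"]), 0.4)
  expect_true(all(b[, "lower"] <= b[, "upper"]))
})

test_that("geometric fill limits are pi/4 (cylinder) and pi/6 (sphere)", {
  expect_equal(max_fill("cylinder-2D"), pi / 4)
  expect_equal(max_fill("sphere-3D"), pi / 6)
  # agrees with the quoted 78% at its printed precision
  expect_lt(abs(100 * max_fill("cylinder-2D") - 78), 1)
  expect_identical(floor(100 * max_fill("cylinder-2D")), 78)
  expect_error(unit_cell(0.8, "cylinder-2D"), class = "etps_invalid_parameter")
  expect_error(unit_cell(0.55, "sphere-3D"), class = "etps_invalid_parameter")
  expect_error(unit_cell(0.3, grid_n = 8), class = "etps_invalid_parameter")
})

test_that("homogeneous cells return the matrix conductivity", {
  expect_equal(unit_cell_k(unit_cell(0, "cylinder-2D", grid_n = 32)), 0.2, tolerance = 5e-3)
  expect_equal(unit_cell_k(unit_cell(0, "sphere-3D", grid_n = 16)), 0.2, tolerance = 5e-3)
})

test_that("unit-cell conductivity is bracketed by the mixture bounds and monotone", {
  sw <- em_sweep()
  b <- k_mixture_bounds(sw$x)
  expect_true(all(sw$k >= b[, "lower"] - 1e-9))
  expect_true(all(sw$k <= b[, "upper"] + 1e-9))
  expect_true(all(diff(sw$k) > 0))
  # 3D spot checks
  x3 <- c(0.2, 0.4)
  k3 <- vapply(x3, function(x) unit_cell_k(unit_cell(x, "sphere-3D", grid_n = 20)), numeric(1))
  b3 <- k_mixture_bounds(x3)
  expect_true(all(k3 >= b3[, "lower"] & k3 <= b3[, "upper"]))
})

test_that("unit-cell heat capacity matches the volumetric rule of mixtures", {
  ph <- phase_pair()
  rom <- function(x) x * 1000 * 4200 + (1 - x) * 900 * 1500
  for (x in c(0.1, 0.3, 0.5)) {
    rc2 <- unit_cell_rho_cp(unit_cell(x, "cylinder-2D", grid_n = 64), ph)
    rc3 <- unit_cell_rho_cp(unit_cell(x, "sphere-3D", grid_n = 32), ph)
    expect_equal(as.numeric(rc2), rom(x), tolerance = 0.01)
    expect_equal(as.numeric(rc3), rom(x), tolerance = 0.01)
    # 2D and 3D agree at equal water fraction
    expect_equal(as.numeric(rc2), as.numeric(rc3), tolerance = 0.01)
  }
})

test_that("adiabatic cell response is linear in injected heat at fixed rho*Cp", {
  cell <- unit_cell(0.3, "cylinder-2D", grid_n = 32)
  r1 <- unit_cell_rho_cp(cell, Q_cell = 1e-3)
  r2 <- unit_cell_rho_cp(cell, Q_cell = 2e-3)
  expect_equal(as.numeric(r1), as.numeric(r2))
  expect_equal(attr(r2, "delta_T"), 2 * attr(r1, "delta_T"))
})

test_that("unit-cell results are scale-invariant in the cell size", {
  k_a <- unit_cell_k(unit_cell(0.3, "cylinder-2D", d_cell = 1, grid_n = 32))
  k_b <- unit_cell_k(unit_cell(0.3, "cylinder-2D", d_cell = 2.5, grid_n = 32))
  expect_equal(k_a, k_b)
  r_a <- unit_cell_rho_cp(unit_cell(0.3, "sphere-3D", d_cell = 1, grid_n = 16))
  r_b <- unit_cell_rho_cp(unit_cell(0.3, "sphere-3D", d_cell = 2, grid_n = 16))
  expect_equal(as.numeric(r_a), as.numeric(r_b))
})

test_that("grid refinement changes the conductivity by less than 1%", {
  k32 <- unit_cell_k(unit_cell(0.4, "cylinder-2D", grid_n = 32))
  k64 <- unit_cell_k(unit_cell(0.4, "cylinder-2D", grid_n = 64))
  expect_lt(abs(k64 - k32) / k32, 0.01)
  k16 <- unit_cell_k(unit_cell(0.3, "sphere-3D", grid_n = 16))
  k32_3d <- unit_cell_k(unit_cell(0.3, "sphere-3D", grid_n = 32))
  expect_lt(abs(k32_3d - k16) / k16, 0.01)
})

test_that("diffusivity dips near half filling only with the unit-cell k", {
  sw <- em_sweep()
  # with the linear (arithmetic-mixture) conductivity the curve is nearly flat
  # and its minimum sits at the edge of the range
  a_rom <- diffusivity_curve(sw$x, k_of_x = k_mixture_bounds(sw$x)[, "upper"])
  expect_equal(which.min(a_rom), length(a_rom)) # boundary, not interior
  expect_lt(diff(range(a_rom)) / max(a_rom), 0.05)
  # the unit-cell conductivity produces a pronounced interior minimum near 0.5
  a_fv <- diffusivity_curve(sw$x, k_of_x = sw$k)
  i_min <- which.min(a_fv)
  expect_gt(i_min, 1)
  expect_lt(i_min, length(a_fv))
  expect_lt(abs(sw$x[i_min] - 0.5), 0.15)
  expect_gt(diff(range(a_fv)) / max(a_fv), 0.05)
  # endpoint substitutions
  expect_equal(diffusivity_curve(0, k_of_x = 0.2), 1e6 * 0.2 / (900 * 1500))
  expect_equal(diffusivity_curve(1, k_of_x = 0.6), 1e6 * 0.6 / (1000 * 4200))
})

test_that("constant-density slope captures the sign structure of the derivative", {
  # the rho-bar form is a qualitative tool: it reproduces the sign of
  # d(alpha)/dx wherever the slope is strong, though its magnitude drifts
  # because the numerator is a near-cancellation (documented in the vignette)
  sw <- em_sweep()
  xs <- sw$x[2:8]
  ks <- sw$k[2:8]
  dk <- (sw$k[3:9] - sw$k[1:7]) / (sw$x[3:9] - sw$x[1:7])
  rho <- mixture_density(xs)
  cp <- mixture_specific_heat(xs)
  exact <- 1e6 * (dk * rho * cp - ks * (100 * cp + 2700 * rho)) / (rho * cp)^2
  approx_slope <- vapply(
    seq_along(xs),
    function(i) diffusivity_slope(xs[i], k = ks[i], dk_dx = dk[i])$slope,
    numeric(1)
  )
  strong <- abs(exact) > 0.5 * max(abs(exact))
  expect_equal(sign(approx_slope[strong]), sign(exact[strong]))
  # negative slope whenever heat capacity outruns conduction, and vice versa
  expect_lt(diffusivity_slope(0.2, k = 0.5, dk_dx = 0.1)$slope, 0)
  expect_gt(diffusivity_slope(0.2, k = 0.1, dk_dx = 1.0)$slope, 0)
  # balance point: dk/dx = k dCp/dx / Cp gives zero slope
  bal <- diffusivity_slope(0.5, k = 0.3, dk_dx = 0.3 * 2700 / 2850)
  expect_equal(bal$slope, 0, tolerance = 1e-12)
})
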