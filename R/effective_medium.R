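# two-phase effective medium: rule-of-mixtures algebra and finite-volume
# unit-cell solutions mapping water volume fraction to bulk thermal properties

#' Rule-of-mixtures density of hydrated skin
#'
#' Linear volume mixture `rho(x) = rho_dry + (rho_water - rho_dry) * x`;
#' with the default phases, `900 + 100 x` kg m^-3.
#'
#' @param x Water volume fraction(s) in `[0, 1]`.
#' @param phases [phase_pair()].
#' @return Density, kg m^-3.
#' @export
mixture_density <- function(x, phases = phase_pair()) {
  check_fraction(x)
  phases$matrix$rho + (phases$inclusion$rho - phases$matrix$rho) * x
}

#' Rule-of-mixtures specific heat of hydrated skin
#'
#' `Cp(x) = Cp_dry + (Cp_water - Cp_dry) * x`; with the default phases,
#' `1500 + 2700 x` J kg^-1 K^-1.
#'
#' @inheritParams mixture_density
#' @return Specific heat, J kg^-1 K^-1.
#' @export
mixture_specific_heat <- function(x, phases = phase_pair()) {
  check_fraction(x)
  phases$matrix$cp + (phases$inclusion$cp - phases$matrix$cp) * x
}

check_fraction <- function(x) {
  if (!is.numeric(x) || any(!is.finite(x)) || any(x < 0) || any(x > 1)) {
    invalid_parameter("water fraction `x` must lie in [0, 1]")
  }
  invisible(x)
}

#' Derivative of volumetric heat capacity with respect to water fraction
#'
#' Product rule on `rho(x) * Cp(x)`:
#' `d(rho Cp)/dx = (drho/dx) Cp(x) + (dCp/dx) rho(x)`. The two terms are
#' returned separately; with the default phases the `Cp` term dominates the
#' density term by two orders of magnitude at `x = 0` (1.5e4 vs 2.43e6) and
#' one order at `x = 1` (4.2e5 vs 2.7e6), which is why changes in `rho*Cp`
#' with hydration are essentially changes in `Cp`.
#'
#' @inheritParams mixture_density
#' @return `data.frame` with columns `x`, `density_term`, `cp_term`, `total`
#'   (J m^-3 K^-1 per unit water fraction).
#' @export
rho_cp_slope <- function(x, phases = phase_pair()) {
  check_fraction(x)
  drho <- phases$inclusion$rho - phases$matrix$rho
  dcp <- phases$inclusion$cp - phases$matrix$cp
  density_term <- drho * mixture_specific_heat(x, phases)
  cp_term <- dcp * mixture_density(x, phases)
  data.frame(x = x, density_term = density_term, cp_term = cp_term, total = density_term + cp_term)
}

#' Wiener bounds on the mixture conductivity
#'
#' The arithmetic (parallel slabs; rule of mixtures) and harmonic (series
#' slabs; inverse rule of mixtures) volume averages of the phase
#' conductivities. Any isotropic two-phase arrangement, including the
#' unit-cell solutions, lies between them.
#'
#' @inheritParams mixture_density
#' @return Matrix with columns `lower` (harmonic) and `upper` (arithmetic),
#'   W m^-1 K^-1.
#' @export
k_mixture_bounds <- function(x, phases = phase_pair()) {
  check_fraction(x)
  km <- phases$matrix$k
  ki <- phases$inclusion$k
  cbind(
    lower = 1 / ((1 - x) / km + x / ki),
    upper = (1 - x) * km + x * ki
  )
}

#' Maximum geometric fill factor of the unit-cell inclusion
#'
#' The largest water fraction the inclusion can occupy before touching the
#' cell boundary: `pi/4` (~78%) for a cylinder in a square cell, `pi/6`
#' (~52%) for a sphere in a cubic cell.
#'
#' @param geometry `"cylinder-2D"` or `"sphere-3D"`.
#' @return Fill fraction.
#' @export
max_fill <- function(geometry = c("cylinder-2D", "sphere-3D")) {
  geometry <- match.arg(geometry)
  if (geometry == "cylinder-2D") pi / 4 else pi / 6
}

# --- finite-volume machinery ------------------------------------------------

# Water membership on the lattice: the round(x*N) cell centres nearest the
# cell midpoint. Equivalent to a cell-centre-in-radius test with the radius
# chosen so the discretised fill equals the requested fraction to 1/N;
# deterministic tie-breaking by lattice index.
water_membership <- function(dims, x) {
  N <- prod(dims)
  m <- round(x * N)
  if (m == 0) {
    return(logical(N))
  }
  centers <- lapply(dims, function(nn) (seq_len(nn) - 0.5) / nn)
  g <- as.matrix(do.call(expand.grid, centers))
  d2 <- rowSums((g - 0.5)^2)
  ord <- do.call(order, c(list(d2), lapply(seq_len(ncol(g)), function(j) g[, j])))
  msk <- logical(N)
  msk[ord[seq_len(m)]] <- TRUE
  msk
}

cell_conductivities <- function(cell, phases) {
  dims <- rep(cell$grid_n, if (cell$geometry == "cylinder-2D") 2L else 3L)
  msk <- water_membership(dims, cell$x_cell)
  list(dims = dims, mask = msk, k = ifelse(msk, phases$inclusion$k, phases$matrix$k))
}

# steady conduction across the cell: Dirichlet on the two faces normal to the
# first axis, adiabatic elsewhere; harmonic-mean face conductivities. Returns
# the effective conductivity directly (dimensionless formulation; the cell
# size cancels, so the result is scale-invariant in d_cell).
solve_cell_conduction <- function(kc, dims, T1 = 0, T2 = 1) {
  nd <- length(dims)
  N <- prod(dims)
  idx <- array(seq_len(N), dims)
  strides <- c(1, cumprod(dims))
  ii <- integer(0)
  jj <- integer(0)
  vv <- numeric(0)
  diagv <- numeric(N)
  rhs <- numeric(N)
  for (d in seq_len(nd)) {
    a <- which(slice.index(idx, d) < dims[d])
    b <- a + strides[d]
    g <- 2 * kc[a] * kc[b] / (kc[a] + kc[b])
    ii <- c(ii, a, b)
    jj <- c(jj, b, a)
    vv <- c(vv, -g, -g)
    add <- numeric(N)
    add[a] <- g
    diagv <- diagv + add
    add <- numeric(N)
    add[b] <- g
    diagv <- diagv + add
  }
  lo <- which(slice.index(idx, 1) == 1)
  hi <- which(slice.index(idx, 1) == dims[1])
  diagv[lo] <- diagv[lo] + 2 * kc[lo]
  rhs[lo] <- rhs[lo] + 2 * kc[lo] * T1
  diagv[hi] <- diagv[hi] + 2 * kc[hi]
  rhs[hi] <- rhs[hi] + 2 * kc[hi] * T2
  A <- Matrix::sparseMatrix(
    i = c(ii, seq_len(N)), j = c(jj, seq_len(N)),
    x = c(vv, diagv), dims = c(N, N)
  )
  Tv <- tryCatch(
    as.numeric(Matrix::solve(Matrix::Cholesky(Matrix::forceSymmetric(A)), rhs)),
    error = function(e) {
      numerical_error(sprintf(
        "unit-cell conduction solve failed on a %s grid: %s",
        paste(dims, collapse = "x"), conditionMessage(e)
      ))
    }
  )
  h <- 1 / dims[1]
  Q <- sum(2 * kc[lo] * (Tv[lo] - T1)) * h^(nd - 2)
  abs(Q) / (T2 - T1)
}

#' Effective conductivity of the two-phase unit cell
#'
#' Solves steady conduction across the cell with the two faces normal to the
#' flow held at fixed temperatures (0 K and 1 K) and all other faces
#' adiabatic, using a regular-grid finite-volume discretisation with
#' harmonic-mean face conductivities, and returns the effective conductivity
#' from the area-normalised heat flux (Fourier's law rearranged,
#' `k_cell = Qdot * d / (T2 - T1)`). The result always lies within
#' [k_mixture_bounds()].
#'
#' @param cell [unit_cell()].
#' @param phases [phase_pair()].
#' @return Effective conductivity, W m^-1 K^-1.
#' @examples
#' unit_cell_k(unit_cell(0.3, "cylinder-2D", grid_n = 32))
#' @export
unit_cell_k <- function(cell, phases = phase_pair()) {
  stopifnot(inherits(cell, "unit_cell"))
  cc <- cell_conductivities(cell, phases)
  solve_cell_conduction(cc$k, cc$dims)
}

#' Volumetric heat capacity of the unit cell by energy bookkeeping
#'
#' Injects heat `Q_cell` into the cell with all boundaries adiabatic and reads
#' the equilibrium temperature rise; `(rho Cp)_cell = Q / (dT * V)`. At
#' equilibrium the rise is exactly `Q / sum(rho_i Cp_i V_i)`, so the result is
#' the volume-weighted mean of the phase heat capacities, independent of the
#' magnitude of `Q_cell` and identical between the 2D and 3D geometries at
#' equal water fraction.
#'
#' @param cell [unit_cell()].
#' @param phases [phase_pair()].
#' @param Q_cell Injected heat, J, > 0 (the result does not depend on it).
#' @return Volumetric heat capacity, J m^-3 K^-1, with attribute `delta_T`
#'   (the equilibrium rise in K for the given `Q_cell` and `d_cell`).
#' @export
unit_cell_rho_cp <- function(cell, phases = phase_pair(), Q_cell = 1e-3) {
  stopifnot(inherits(cell, "unit_cell"))
  check_scalar(Q_cell, "Q_cell")
  cc <- cell_conductivities(cell, phases)
  rc <- ifelse(
    cc$mask, phases$inclusion$rho * phases$inclusion$cp,
    phases$matrix$rho * phases$matrix$cp
  )
  nd <- length(cc$dims)
  V <- (cell$d_cell * 1e-3)^nd # m^2 (per unit depth) or m^3
  dT <- Q_cell / (mean(rc) * V)
  structure(mean(rc), delta_T = dT)
}

#' Thermal diffusivity across a hydration sweep
#'
#' `alpha(x) = k(x) / (rho(x) * Cp(x))` with the mixture forms for density and
#' specific heat. With rule-of-mixtures conductivity the curve is monotone;
#' with the unit-cell `k(x)` it develops an interior minimum near `x = 0.5`,
#' because below that point the heat-capacity growth outruns the conductivity
#' growth.
#'
#' @param x_values Water fractions.
#' @param phases [phase_pair()].
#' @param k_of_x Conductivity at each `x` (same length), W m^-1 K^-1.
#' @return Diffusivity, mm^2 s^-1, per `x`.
#' @export
diffusivity_curve <- function(x_values, phases = phase_pair(), k_of_x) {
  if (length(x_values) != length(k_of_x)) {
    invalid_parameter("`x_values` and `k_of_x` must have the same length")
  }
  check_fraction(x_values)
  1e6 * k_of_x / (mixture_density(x_values, phases) * mixture_specific_heat(x_values, phases))
}

#' Sign and magnitude of the diffusivity slope (constant-density form)
#'
#' Quotient rule on `alpha = k / (rho_bar * Cp)` holding the density at a
#' constant averaged value `rho_bar`:
#' `d(alpha)/dx = (rho_bar Cp dk/dx - k rho_bar dCp/dx) / (rho_bar Cp)^2`.
#' The slope is negative whenever `k * dCp/dx > Cp * dk/dx` (heat capacity
#' outrunning conduction) and positive in the opposite regime.
#'
#' @param x Water fraction.
#' @param phases [phase_pair()].
#' @param k Conductivity at `x`, W m^-1 K^-1.
#' @param dk_dx Local slope of `k(x)`, W m^-1 K^-1 per unit fraction.
#' @param rho_bar Averaged density, kg m^-3 (default 950).
#' @return List with `slope` (mm^2 s^-1 per unit fraction) and `sign`.
#' @export
diffusivity_slope <- function(x, phases = phase_pair(), k, dk_dx, rho_bar = 950) {
  check_fraction(x)
  check_scalar(k, "k")
  check_scalar(rho_bar, "rho_bar")
  cp <- mixture_specific_heat(x, phases)
  dcp <- phases$inclusion$cp - phases$matrix$cp
  num <- rho_bar * cp * dk_dx - k * rho_bar * dcp
  slope <- 1e6 * num / (rho_bar * cp)^2
  list(slope = slope, sign = sign(slope))
}

#' Tabulate effective-medium properties over a hydration grid
#'
#' Convenience sweep for reporting and for the `emm` command-line verb:
#' mixture density, specific heat and volumetric heat capacity, unit-cell
#' conductivities for both geometries (where the fraction is geometrically
#' reachable), and the derived diffusivities.
#'
#' @param x_values Water fractions.
#' @param phases [phase_pair()].
#' @param grid_n_2d,grid_n_3d Finite-volume resolutions.
#' @return `data.frame` with one row per `x`.
#' @export
effective_medium_table <- function(x_values, phases = phase_pair(),
                                   grid_n_2d = 64, grid_n_3d = 24) {
  check_fraction(x_values)
  rows <- lapply(x_values, function(x) {
    k2 <- if (x <= max_fill("cylinder-2D")) {
      unit_cell_k(unit_cell(x, "cylinder-2D", grid_n = grid_n_2d), phases)
    } else {
      NA_real_
    }
    k3 <- if (x <= max_fill("sphere-3D")) {
      unit_cell_k(unit_cell(x, "sphere-3D", grid_n = grid_n_3d), phases)
    } else {
      NA_real_
    }
    rho <- mixture_density(x, phases)
    cp <- mixture_specific_heat(x, phases)
    data.frame(
      x = x, rho = rho, cp = cp, rho_cp = rho * cp,
      k_2d = k2, k_3d = k3,
      alpha_2d = 1e6 * k2 / (rho * cp), alpha_3d = 1e6 * k3 / (rho * cp)
    )
  })
  do.call(rbind, rows)
}
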