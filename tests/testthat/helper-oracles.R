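# Independent brute-force oracle for the plane-source shape function.
# Deliberately a different scheme from the package path (midpoint inner
# quadrature and direct trapezoidal outer integration on its own grids, no
# table, no spline), sharing only the mathematical definition of the kernel.

oracle_i0e <- function(x) {
  out <- numeric(length(x))
  lo <- x <= 30
  out[lo] <- besselI(x[lo], 0, expon.scaled = TRUE)
  if (any(!lo)) {
    xx <- x[!lo]
    # asymptotic series, six terms: coefficients ((2k-1)!!)^2 / (k! 8^k)
    ck <- c(1, 1 / 8, 9 / 128, 225 / 3072, 11025 / 98304, 893025 / 3932160)
    acc <- 0
    for (k in rev(seq_along(ck))) acc <- acc / xx + ck[k]
    out[!lo] <- acc / sqrt(2 * pi * xx)
  }
  out
}

oracle_inner <- function(sigma, n_u = 200, n_v = 200) {
  u <- (seq_len(n_u) - 0.5) / n_u
  if (sigma >= 0.3) {
    v <- (seq_len(n_v) - 0.5) / n_v
    U <- outer(u, rep(1, n_v))
    V <- outer(rep(1, n_u), v)
    K <- U * V * exp(-(U - V)^2 / (4 * sigma^2)) * oracle_i0e(U * V / (2 * sigma^2))
    return(sum(K) / (n_u * n_v))
  }
  half <- 14 * sigma
  lo <- pmax(0, u - half)
  hi <- pmin(1, u + half)
  zz <- (seq_len(n_v) - 0.5) / n_v
  V <- outer(lo, rep(1, n_v)) + outer(hi - lo, zz)
  U <- matrix(u, n_u, n_v)
  K <- U * V * exp(-(U - V)^2 / (4 * sigma^2)) * oracle_i0e(U * V / (2 * sigma^2))
  sum(K * (hi - lo) / n_v) / n_u
}

# D(tau) by direct nested quadrature; head below smin contributes smin + O(smin^2)
# because the outer integrand tends to 1 as sigma -> 0.
oracle_shape <- function(tau, n_u = 200, n_v = 200, n_s = 600, smin = 1e-4) {
  sg <- exp(seq(log(smin), log(tau), length.out = n_s))
  g <- vapply(sg, function(s) oracle_inner(s, n_u, n_v) / s^2, numeric(1))
  smin + sum(0.5 * (g[-1] + g[-n_s]) * diff(sg))
}

# forward mean-rise curve built on the oracle shape function (SI internally)
oracle_rise <- function(times, k, alpha_mm2, a_mm, P0, ...) {
  a <- a_mm * 1e-3
  alpha <- alpha_mm2 * 1e-6
  vapply(times, function(t) {
    if (t == 0) 0 else P0 / (pi^1.5 * a * k) * oracle_shape(t * alpha / a^2, ...)
  }, numeric(1))
}

# shared noiseless reference transient used across inversion tests
ref_cfg <- function() sensor_config() # 0.5 mm element, a_eff 0.254 mm, 7 mW/mm^2, 2 s
ref_truth <- function() thermal_properties(k = 0.4, alpha = 0.10)
ref_curve <- function() generate_transient(ref_truth(), ref_cfg(), noise = noise_model(0))

# shared 2D unit-cell conductivity sweep, computed once per test run
em_sweep <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      xs <- c(0.05, 0.1, 0.2, 0.3, 0.4, 0.5, 0.6, 0.7, 0.75)
      k2 <- vapply(
        xs, function(x) unit_cell_k(unit_cell(x, "cylinder-2D", grid_n = 64)),
        numeric(1)
      )
      cache <<- list(x = xs, k = k2)
    }
    cache
  }
})
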