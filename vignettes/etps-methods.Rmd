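---
title: "Models and numerical methods behind the etps package"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and numerical methods behind the etps package}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(etps)
```

## The measurement and what it recovers

An epidermal transient plane source (ETPS) element is a thin, disc-shaped
resistive film mounted conformally on skin. Driving it at constant power for a
couple of seconds simultaneously heats the tissue and, through the temperature
coefficient of resistance, records the spatially averaged temperature rise of
the element. Because water conducts and stores heat very differently from the
dry tissue matrix, the shape of that transient encodes the hydration state of
the epidermis.

The forward model is the classical plane-source solution. For an element of
effective radius $a$ on a homogeneous medium of conductivity $k$ and
diffusivity $\alpha$, the mean rise is

$$\overline{\Delta T}(\tau) = \frac{P_0}{\pi^{3/2} a k}\, D(\tau),
\qquad \tau = \frac{t\,\alpha}{a^2},$$

with the dimensionless shape function

$$D(\tau) = \int_0^{\tau} \frac{d\sigma}{\sigma^2}
 \int_0^1 u\,du \int_0^1 v\,dv\;
 e^{-(u^2+v^2)/4\sigma^2}\, I_0\!\left(\frac{uv}{2\sigma^2}\right),$$

where $I_0$ is the modified Bessel function of the first kind, order zero.
Fitting the measured transient for $(k, \alpha)$ also yields the volumetric
heat capacity as the ratio $\rho C_p = k/\alpha$. The probing depth is the
diffusion length $\Lambda = \Pi\sqrt{\alpha t}$ with $\Pi$ of order one; at
$\alpha = 0.1\ \mathrm{mm^2\,s^{-1}}$ and $t = 2$ s it is about 450 µm, so the
50 µm device stack rides along as part of one effective medium and the
measurement senses the epidermis well below the stratum corneum.

## Evaluating the shape function

Two numerical points matter.

**An overflow-safe kernel.** The integrand couples a Gaussian that underflows
with an $I_0$ that overflows as $\sigma \to 0$. We evaluate the product in the
exponentially scaled form
$e^{-(u-v)^2/4\sigma^2}\,\big[e^{-x} I_0(x)\big]$, $x = uv/2\sigma^2$,
which is bounded by 1. Base R's scaled `besselI` itself degrades above
$x \approx 10^5$ (and its running time grows linearly in $x$), so for $x > 40$
we switch to the standard large-argument asymptotic series for
$e^{-x} I_0(x)$; at the switch point the two agree to within $3\times10^{-9}$
relative.

**Tabulation with controlled endpoints.** The outer integrand
$g(\sigma) = \sigma^{-2} \iint(\cdot)$ tends to exactly 1 as $\sigma \to 0$
(the inner integral collapses onto the diagonal $u = v$) and decays as
$1/(4\sigma^2)$ for large $\sigma$. `tps_shape_function()` therefore
integrates $g$ cumulatively over a 500-point geometric grid on
$[10^{-3}, 200]$, adds the analytic head ($\approx \sigma_{\min}$) and tail
($\tfrac14(1/\tau_{\max} - 1/\tau)$), and interpolates with a monotone
(Hyman) spline in $\log\tau$. The table is built lazily once per session
(well under a second) and a direct adaptive-quadrature path
(`method = "quadrature"`) remains available; the test suite additionally
checks both against an independent brute-force nested midpoint/trapezoid
quadrature on its own grids, agreeing to better than 0.1%.

**The large-$\tau$ limit.** The integral saturates at
$D(\infty) = 4/(3\sqrt{\pi}) \approx 0.7523$, which makes the forward model's
steady state equal the mean temperature of a uniformly powered disc embedded
in an *unbounded* medium, $4P_0/(3\pi^2 a k)$ — the classic hot-disc
configuration in which the sensor is clamped between two halves of the
sample. A sensor resting on a one-sided half-space sees twice that rise. The
analysis keeps the equation as stated and lets the calibration absorb the
geometry: doubling the rise is equivalent to halving $a$ in the prefactor,
which is precisely why the calibrated effective radius (~254 µm) comes out at
about half the physical radius (500 µm). `calibrate_effective_radius()`
reproduces this behaviour on synthetic reference materials.

## Inverse fitting and identifiability

`fit_tps()` minimises the sum of squared residuals over $(k, \alpha)$ with
bounded Levenberg–Marquardt (relative SSE tolerance $10^{-10}$, parameter
step tolerance $10^{-8}$). Defaults reflect the physiological envelope:
start at $k = 0.3\ \mathrm{W\,m^{-1}K^{-1}}$,
$\alpha = 0.1\ \mathrm{mm^2\,s^{-1}}$ (healthy skin sits around
$k \approx 0.3$–$0.5$; the representative porcine best fit is
$\alpha = 0.10$), bounds $k \in [0.05, 1.5]$, $\alpha \in [0.01, 0.5]$.
An option excludes the first few percent of the curve from the fit, mirroring
a common robustness check against early-time contact artefacts; the default
keeps every sample. Non-convergence is flagged, not thrown; constant or
all-zero curves are rejected as degenerate.

The two parameters are very unequally constrained. $k$ sets the overall
amplitude, while $\alpha$ only warps the curve along the (saturating) shape
function, so broad ranges of $\alpha$ trade off against small changes in
$k$. `sensitivity_scan()` quantifies this by fixing one parameter at
$(1+\delta)$ times its best-fit value and refitting the other: on the
package's reference synthetic transient ($k = 0.4$, $\alpha = 0.10$,
$a = 0.254$ mm, noiseless, 2 s at 100 Hz), fixing $\alpha$ 5% high moves
$k$ by about 1.2%, whereas fixing $k$ 5% high moves $\alpha$ by about 16%.
`error_surface()` shows the same anisotropy as a strongly elliptical SSE
valley elongated along $\alpha$ (31 x 31 grid over ±15% by default, ties at
the minimum broken deterministically toward smaller $k$, then smaller
$\alpha$). Consequently $k$ is the quantity of choice for tracking hydration,
and $\alpha$ earns its keep mainly through the ratio $k/\alpha$.

## Effective-medium model of hydrated tissue

To connect water volume fraction $x$ to the measured properties, the epidermis
is idealised as a periodic array of square (or cubic) cells of dry-skin matrix
containing a water inclusion: a cylinder in 2D (maximum fill $\pi/4 \approx
78\%$) or a sphere in 3D (maximum fill $\pi/6 \approx 52\%$; the inscribed
sphere allows 52.4% even though the figure is often quoted as 50%). Phase
constants default to $\rho = 900/1000\ \mathrm{kg\,m^{-3}}$,
$C_p = 1500/4200\ \mathrm{J\,kg^{-1}K^{-1}}$ and
$k = 0.2/0.6\ \mathrm{W\,m^{-1}K^{-1}}$ for dry skin/water.

Volumetric heat capacity composes exactly: injecting heat into an adiabatic
cell and reading the equilibrium rise gives the volume-weighted mean of the
phase $\rho C_p$, identical in 2D and 3D and in agreement with the linear
mixtures $\rho(x) = 900 + 100x$ and $C_p(x) = 1500 + 2700x$. Differentiating
the product splits the slope into a density term and a heat-capacity term,
$100\,C_p(x) + 2700\,\rho(x)$; the $C_p$ term dominates by two orders of
magnitude at $x=0$ ($1.5\times10^4$ vs $2.43\times10^6$) and one at $x=1$
($4.2\times10^5$ vs $2.7\times10^6$), so hydration changes in $\rho C_p$ are
essentially changes in $C_p$, and a constant averaged density
$\bar\rho = 950\ \mathrm{kg\,m^{-3}}$ is an adequate approximation.

Conductivity requires a field solution. `unit_cell_k()` discretises the cell
on a regular grid (finite volumes, harmonic-mean face conductivities — the
standard choice for discontinuous coefficients because it preserves flux
continuity), fixes the two faces normal to the flow at 0 K and 1 K with all
other faces adiabatic, solves the sparse SPD system by Cholesky
factorisation, and returns the effective conductivity from the
area-normalised boundary flux. Water membership on the grid is assigned by a
quantile rule: the $\mathrm{round}(xN)$ cell centres nearest the cell
midpoint. This is a cell-centre-in-radius test with the radius chosen so that
the discretised fill matches the requested fraction to $1/N$; a fixed
geometric radius would carry an $O(1/n)$ fill bias that visibly pollutes the
rule-of-mixtures comparisons at the default resolutions. The defaults
(`grid_n = 64` in 2D, 32 in 3D) put self-convergence under grid doubling
below 1% (asserted in the test suite; in practice well below that), and
every solution is bracketed by the arithmetic/harmonic (parallel/series)
mixture bounds. Results are scale-invariant in the cell size `d_cell`
(asserted in the tests), so the 1 mm default is purely conventional.

The derived diffusivity $\alpha(x) = k(x)/\big(\rho(x)C_p(x)\big)$ is the
interesting curve: with the unit-cell $k(x)$ it *dips*, reaching a minimum
near half filling, because below $x \approx 0.5$ the heat-capacity growth
outpaces conduction ($k\,dC_p/dx > C_p\,dk/dx$) while the superlinear rise of
$k$ near close packing reverses the sign above. A strictly linear $k(x)$
produces an almost flat $\alpha(x)$ instead (its residual interior extremum
is below 1%, a detail the test suite pins down), so observing the dip is a
signature of the inclusion geometry.

## Electrical impedance and calorimetry companions

The concentric-electrode impedance channel is represented by a deliberately
simple lumped surrogate: a parallel conductance/capacitance element,
$Z = 1/(G + i\,2\pi f C)$ with $G = \sigma/\kappa$ and
$C = \varepsilon_r \varepsilon_0 / \kappa$ for a cell constant $\kappa$.
Parameterised by the reference states (dehydrated skin
$\varepsilon_r = 1133.6$, $\sigma = 2.04\times10^{-4}$ S/m; hydrated
$\varepsilon_r = 29010$, $\sigma = 2.93\times10^{-3}$ S/m) it reproduces the
qualitative facts the analysis needs — $|Z|$ falls with both frequency and
hydration, phase stays in the capacitive quadrant — but it is a surrogate for
the full field problem, not a reproduction of it; single-dispersion lumping,
no electrode polarisation, no multi-layer dispersion. The probing depth of a
concentric pair is taken as half the radial gap between the inner disc's
outer edge and the outer ring's inner edge (`electrode_gap()` maps quoted
ID/OD diameters to that gap), confining the electrical measurement to the
stratum corneum, in contrast to the much deeper thermal channel.

For calorimetry, a DSC trace at constant heating rate $\beta$ gives
$C_p = h/(B\beta)$ from the baseline-referenced heat-flow deviation $h$;
`dsc_calibrate()` recovers $B$ from a sapphire (or other reference) run as
$B = h_{\mathrm{ref}}/(C_{p,\mathrm{ref}}\,\beta)$, making
calibration-then-extraction an exact algebraic identity. Baseline subtraction
and pan-mass normalisation are assumed done upstream. Time-series profiles
from repeated measurements are reduced by `auc_descriptor()`, a trapezoidal
area relative to baseline — exact for piecewise-linear profiles and additive
over contiguous time windows.

## Synthetic data: what it emulates and what it does not

All fixtures are generated in code, seeded, and bit-reproducible
(`generate_transient()`, `generate_hydration_sweep()`,
`generate_spectrum()`, `generate_trial_series()`); generators leave the
global RNG stream untouched.

* **Transients**: forward model plus additive i.i.d. Gaussian noise. No noise
  model is published for the instrument, so the default standard deviation is
  1% of the peak rise — thermistor-class precision. Sampling defaults to
  100 Hz over the 2 s actuation (200 points); the acquisition rate is
  likewise not published and the fits are insensitive to it (asserted).
  The default actuation is 7 mW mm^-2 over a 0.5 mm radius element for 2 s.
* **Hydration sweeps** mirror the soaked-porcine-tissue experiment: the
  effective-medium model supplies $(k, \rho C_p)$ per water fraction, the
  forward model the curves. Fitted conductivity rises and the 2 s peak
  temperature falls monotonically across the sweep.
* **Trial series** emulate the four-arm forearm protocol (occlusive patch;
  lotions at 0/15/30% glycerin) at the protocol's measurement times
  (-15, 0, 30, 60, 270, 300 min). Arm profiles are shaped weights: the patch
  effect decays to baseline within ~30 min; glycerin-containing arms hold
  their effect through 270 min and keep conductivity above baseline after
  removal at 300 min, while the glycerin-free arm returns close to baseline.
  The quoted occlusion time differs between protocol descriptions (15 vs
  30 min), so it is a parameter (default 15 min).

These generators reproduce the *structure* of the real data, not its
physiology: no subject-level covariates, no glycerin pharmacokinetics, no
contact-quality artefacts, no layered stratum-corneum gradients. A passing
test suite therefore demonstrates that the estimators are correct and stable
on data obeying the stated models, not that skin obeys them.

## Problem sizes and numerical defaults

The test and acceptance workloads are sized for a single CPU: 200-point
curves, 50 noisy refits for the recovery statistics, a 31 x 31 error surface
(961 forward evaluations), 2D cells at $n = 64$ (refinement check at 128),
3D cells at $n = 32$ (refinement check from 16; a single 3D solve is a
~33k-unknown sparse Cholesky, around ten seconds). Optimizer tolerances are
stated above; quadrature targets are ~$10^{-4}$ relative for the tabulated
shape function and 0.1% for every oracle comparison. Degenerate inputs
(constant curves, zero radii, fractions outside geometric fill limits) raise
typed conditions (`etps_invalid_parameter`, `etps_degenerate_input`,
`etps_schema_error`) rather than producing numbers.

## Known limitations

* The forward model treats the device-plus-tissue stack as one effective
  semi-infinite medium; multilayer analytical solutions and explicit
  convection are out of scope (the erfc model's $A_1, A_2$ absorb them
  empirically). The erfc model's argument is taken as
  $A_2/(2\sqrt{\alpha t})$, the point-source form with the correct limits.
* $\alpha$ is weakly identified by design of the physics; downstream users
  should treat per-curve $\alpha$ with the error-surface context in mind.
* The impedance element is a lumped surrogate (see above).
* Effective-medium constants are fixed, temperature-independent phase
  properties; no bound-water dispersion.
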