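# etps — transient plane source analysis for epidermal hydration sensing

Skin-mounted sensing platforms measure epidermal hydration through intrinsic
tissue properties rather than contact capacitance. A disc-shaped resistive
element (an epidermal transient plane source, ETPS) heats the skin at constant
power for ~2 s while recording its own spatially averaged temperature rise;
companion concentric electrodes record AC impedance spectra. Because water
conducts and stores heat very differently from dry tissue, the transient
encodes the thermal conductivity *k*, thermal diffusivity *α*, and — through
their ratio — the volumetric heat capacity *ρC*<sub>p</sub> of the epidermis,
all of which track water content.

This package is the analysis stack for such measurements, for instrument
developers and for analysts processing transient files:

* **Forward model** — the plane-source solution
  ΔT̄(τ) = P₀ π^(−3/2) (a k)^(−1) D(τ), τ = tα/a², with the Bessel-kernel
  shape function D evaluated by overflow-safe quadrature and a monotone
  interpolation table; the simplified erfc fitting model
  T = T∞ + A₁P₀/(2πA₂k) · erfc(A₂/(2√(αt))); and the probing-depth rule
  Λ = Π√(αt).
* **Inversion** — bounded least-squares recovery of (k, α) from measured
  transients (`fit_tps`), effective-radius calibration on reference
  materials (`calibrate_effective_radius`), perturb-and-refit sensitivity
  scans and (k, α) error surfaces quantifying the strong k / weak α
  identifiability asymmetry.
* **Effective medium** — a two-phase (dry skin + water) unit-cell model:
  rule-of-mixtures density/heat-capacity algebra and sparse finite-volume
  solutions for the effective conductivity of cylindrical (2D) and spherical
  (3D) water inclusions, mapping water volume fraction to every measured
  property.
* **Impedance & calorimetry** — a lumped parallel-RC skin impedance
  surrogate, the electrode-gap measurement-depth rule, DSC specific-heat
  extraction with reference calibration, and the AUC time-series descriptor.
* **Synthetic data** — seeded, bit-reproducible generators for noisy
  transients, hydration sweeps, impedance spectra, and clinical-protocol
  time series, so the whole stack is testable without instrument data.

See `vignettes/etps-methods.Rmd` for the models, numerical choices, and
limitations.

## Worked example

Simulate a skin-like measurement (k = 0.35 W m⁻¹K⁻¹, α = 0.11 mm² s⁻¹,
7 mW mm⁻² for 2 s, 1% noise), fit it, and probe the identifiability:

```r
library(etps)
cfg   <- sensor_config()     # 0.5 mm element, calibrated a_eff = 0.254 mm
skin  <- thermal_properties(k = 0.35, alpha = 0.11)
curve <- generate_transient(skin, cfg, noise = noise_model(seed = 42))

(fit <- fit_tps(curve, cfg))
#> fit_result: k = 0.3502 W/m/K, alpha = 0.11 mm^2/s, rho*Cp = 3.185e+06 J/m^3/K
#>   SSE = 1.075 K^2 over 200 samples (converged)

sensitivity_scan(curve, cfg, fit, which = "k", perturbations = c(-0.05, 0.05))
#>   perturbation fixed_value refit_value      shift converged
#> 1        -0.05   0.3326600  0.09358548 -0.1489082      TRUE
#> 2         0.05   0.3676768  0.12885446  0.1718375      TRUE

diffusion_length(fit$props$alpha, t = 2)
#> [1] 469 (um)
```

The fit recovers k to 0.1% and α exactly to the display precision; the scan
shows the characteristic asymmetry — forcing k off by 5% drags the refitted α
by 15–17%, whereas (run `which = "alpha"`) forcing α off by 5% moves k by only
~1%. The 2 s actuation probes ~470 µm of tissue, i.e. the epidermis well below
the stratum corneum.

The effective-medium table connects water fraction to the measured properties
(2D/3D unit-cell conductivity, mixture heat capacity, derived diffusivity):

```r
effective_medium_table(c(0, 0.2, 0.4))
#>     x rho   cp  rho_cp   k_2d   k_3d alpha_2d alpha_3d
#> 1 0.0 900 1500 1350000 0.2000 0.2000   0.1481   0.1481
#> 2 0.2 920 2040 1876800 0.2443 0.2517   0.1302   0.1341
#> 3 0.4 940 2580 2425200 0.3001 0.3150   0.1238   0.1299
```

Conductivity rises with hydration while diffusivity falls below half filling —
the signature that makes k the hydration readout of choice.

A command-line interface wraps the same functions for batch use
(`simulate`, `fit`, `scan`, `surface`, `emm`, `report`):

```sh
Rscript inst/cli/etps simulate --out fixtures --seed 7
Rscript inst/cli/etps report fixtures/curve_*.csv --out report
```

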