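Package: etps
Title: Transient Plane Source Analysis for Epidermal Hydration Sensing
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Forward modelling and inverse fitting for epidermal transient
    plane source (ETPS) thermal measurements of skin hydration. Implements the
    exact mean-temperature-rise solution for a disc-shaped plane source
    (Bessel-kernel triple integral), a simplified erfc fitting model, bounded
    least-squares recovery of thermal conductivity and diffusivity with
    effective-radius calibration, perturb-and-refit sensitivity scans and
    sum-of-squares error surfaces, a two-phase (dry skin plus water)
    effective-medium unit-cell model solved by sparse finite volumes, lumped
    electrical-impedance and differential scanning calorimetry helpers, and
    seeded synthetic-data generators for transients, hydration sweeps,
    impedance spectra and clinical-protocol time series.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Matrix,
    minpack.lm,
    pracma,
    jsonlite,
    optparse,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
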