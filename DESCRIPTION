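Package: trapvol
Title: Trapezoidal Volume Estimation from Non-Equidistant Planar Sections
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Cavalieri-type stereological volume estimation when the planar
    sections are not exactly equidistant. Implements the unbiased trapezoidal
    volume estimator, which weights each cross-sectional area by the mean of
    its two adjacent slice thicknesses, together with covariogram-based
    estimators of its variance: a model-free estimator valid under dropouts,
    and model-specific estimators for the perturbed (independently displaced
    equidistant cuts) and cumulative (independent identically distributed
    gaps) sampling models. Includes simulators for the three sampling models
    with optional section dropout, a synthetic generator of lobe-like area
    profiles estimated by point counting, and a Monte Carlo study engine that
    measures empirical variance decrease rates, extension-term constants and
    coefficients of error of the variance estimators.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports: stats, utils
Suggests: testthat (>= 3.0.0), pracma, withr, jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
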