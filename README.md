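# trapvol

Stereological volume estimation from parallel planar sections when the
slices are **not exactly equidistant** — thick slabs cut by hand or machine,
or section series with dropouts.

## The problem

The classical Cavalieri estimator infers the volume `Q` of an object from
the areas of its cross-sections on equidistant parallel planes a distance
`T` apart:

    Q̂ = T · Σₖ Area(Sₖ)

It is unbiased with a uniformly random start, and its variance falls fast as
`T` shrinks. But real slabs are rarely cut at exactly equal thickness, and
applying the Cavalieri form with the *average* spacing (the generalized
Cavalieri estimator) can inflate the variance dramatically. For a smooth
object the variance of the Cavalieri estimator under independently
perturbed cut positions decays only like `T³` (and like `T` when the cut
errors accumulate), instead of the equidistant `T⁴`.

The **trapezoidal estimator** repairs this using the observed slice
thicknesses `hₖ = xₖ − xₖ₋₁`:

    Q̂₁ = Σₖ (hₖ + hₖ₊₁)/2 · Area(Sₖ)

i.e. the trapezoid-rule integral of the observed area profile. It is
unbiased under any stationary sampling mechanism — including after section
dropouts — and its variance behaves essentially like the equidistant case:
`var(Q̂₁) = c·T^(2m+2) + Z(T) + r(T)`, where `m` is the smoothness of the
area function (`m = 1` for smooth convex objects, `m = 0` when a flat face
is parallel to the sections), `Z` is an oscillating *Zitterbewegung* term
and `r` is negligible.

The package provides:

* the Cavalieri, generalized Cavalieri and trapezoidal estimators;
* covariogram-based estimators of `var(Q̂₁)`: a **model-free** estimator
  (valid under dropouts) and **model-specific** estimators for the
  *perturbed* (independently displaced equidistant cuts) and *cumulative*
  (iid gaps) sampling models, with exact reduction to the classical
  equidistant formulas for constant gaps and an optional ×2 conservative
  bound covering the Zitterbewegung of 1-oriented objects;
* simulators for the three sampling models with calibrated
  truncated-normal dispersion and independent section thinning;
* a synthetic generator of lobe-like section tables (point-counted areas,
  nominal 2.5 mm slabs, area per point 2.29 mm²);
* a Monte Carlo study engine measuring empirical variance decrease rates,
  extension-term constants, variance-estimator bias and coefficients of
  error, and the section count at which perturbed sampling doubles the
  Cavalieri variance.

## Worked example

Estimate a volume from a section table (positions in mm, areas in mm²):

```r
library(trapvol)

# a synthetic parietal-lobe-like specimen: 13 slabs of nominal 2.5 mm,
# areas estimated by point counting (a = 2.29 mm^2 per point)
lobe <- synthesize_lobe_profile(seed = 42)
head(lobe$table, 4)
#>   position_mm points area_mm2
#> 1   0.1695659      0     0.00
#> 2   2.4374437      0     0.00
#> 3   5.1058970      7    16.03
#> 4   7.5402268     42    96.18

series <- section_series(lobe$table$position_mm, lobe$table$area_mm2)
estimate_volume(series, method = "perturbed", m = 1)
#> Trapezoidal volume estimate: 4015.32 mm^3 (14 sections, mean gap 2.486 mm)
#> Variance (perturbed, m = 1): 768.523 mm^6  |  CE = 0.006904
```

The reported variance is the estimated extension term of the *sectioning*
variance of `Q̂₁` (it does not include the point-counting error in the areas;
the generating profile here has true volume 3692.6 mm³ and the ~9%
deviation of the estimate is dominated by counting noise). `CE` is
`sqrt(variance) / volume`. Adding `conservative = TRUE` doubles the
variance to cover the Zitterbewegung of a 1-oriented object:

```r
estimate_volume(series, method = "perturbed", m = 1, conservative = TRUE)
#> Variance (perturbed, m = 1, conservative): 1537.05 mm^6  |  CE = 0.009764
```

A tiny table with unequal gaps, with the model-free variance estimator for
a 0-oriented object:

```r
s <- section_series(c(0, 1, 2, 4), c(0, 2, 3, 0))
estimate_volume(s, method = "model_free", m = 0)
#> Trapezoidal volume estimate: 6.5 mm^3 (4 sections, mean gap 1.333 mm)
#> Variance (model_free, m = 0): 3.125 mm^6  |  CE = 0.272
```

A command-line wrapper with `estimate`, `simulate`, `synth` and
`doubling-point` commands is installed at `inst/cli/trapvol.R`:

```sh
Rscript "$(Rscript -e 'cat(system.file("cli/trapvol.R", package="trapvol"))')" estimate table.csv --m 1
```

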