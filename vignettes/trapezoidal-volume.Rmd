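---
title: "Trapezoidal volume estimation from non-equidistant sections: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Trapezoidal volume estimation from non-equidistant sections: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(trapvol)
```

## The estimation problem

A bounded object sectioned by parallel planes orthogonal to a sampling axis
induces an *area function* $f(x)$: the cross-sectional area at axial
position $x$. The volume is $Q = \int f(x)\,dx$, so volume estimation from
sections is numerical integration of $f$ from its values at random plane
positions $x_0 < \dots < x_N$, where the object lies strictly between the
end planes ($f(x_0) = f(x_N) = 0$).

With equidistant planes a distance $T$ apart and a uniform random start,
the classical Cavalieri estimator $\hat Q = T\sum_k \mathrm{Area}(S_k)$ is
unbiased. When the slice thicknesses $h_k = x_k - x_{k-1}$ vary — hand-cut
slabs, knife drift, lost sections — the Cavalieri form becomes a crude
weighted sum, and its variance inflates. The *trapezoidal estimator*

$$\hat Q_1 = \sum_{k=1}^{N} \frac{h_k + h_{k+1}}{2}\,\mathrm{Area}(S_k)$$

is the trapezoid-rule integral of the observed $(x_k, \mathrm{Area}(S_k))$
profile. It is unbiased whenever the section positions form a stationary
(translation-invariant) point process, and it adapts to unequal gaps.
(Because $\mathrm{Area}(S_N) = 0$, the $k = N$ term vanishes; the
implementation sums $k = 1..N-1$, which is algebraically identical.)

## Smoothness, orientation and variance orders

The decisive quantity for the variance is the smoothness index $m$ of the
area function along the chosen axis: $m = 1$ if $f$ is continuous with a
derivative that jumps at finitely many points (smooth convex objects;
always true for ellipsoids), $m = 0$ if $f$ itself jumps (a flat face
parallel to the sections — to be avoided by choice of axis where possible,
and chosen deliberately via the `m` argument otherwise; the package default
is `m = 1`). The variance decomposes as

$$\mathrm{var}(\hat Q_1) = c\,T^{2m+2} + Z(T) + r(T),$$

with a leading *extension term* $c\,T^{2m+2}$, an oscillating
*Zitterbewegung* $Z(T)$ of at most the same order (present only when the
$m$-th derivative of $f$ jumps at two or more points), and a negligible
remainder. Under the cumulative sampling model $Z$ decays faster and can be
ignored. By contrast, the Cavalieri estimator under perturbed sampling
decays like $T^2$ ($m=0$) or $T^3$ ($m=1$), and only like $T$ under the
cumulative model, for either $m$ — the simulation engine reproduces all of
these orders.

The constant $c$ depends on derivatives of $f$ and is not computed
analytically here; `fit_extension_term()` estimates it by least squares
against $T^{2m+2}$. One useful analytic cross-check exists for the
equidistant Cavalieri estimator of an object whose first derivative jumps:
the phase-average of $\mathrm{var}/T^4$ equals
$\frac{1}{720}\sum (\Delta f')^2$; for the unit ball this is
$\pi^2/90 \approx 0.1097$, which the quadrature-based
variance in `doubling_point()` matches to three digits — a check exercised
implicitly by the decrease-rate tests.

## Sampling models

* **Equidistant**: lattice $\{U + jT\}$, $U$ uniform on $[0, T)$.
* **Perturbed**: each lattice point is displaced by an independent
  zero-mean normal truncated to $(-T/2, T/2)$ — the largest symmetric bound
  that guarantees ordered positions. Degenerate (zero) perturbations
  recover the equidistant model exactly, seed for seed.
* **Cumulative**: slice thicknesses are iid; the package uses a normal with
  mean $T$ truncated to $(T/2, 3T/2)$, started from a uniform offset below
  the estimation window. This start is uniform rather than the
  equilibrium (inspection-paradox-corrected) renewal start; for the
  variance-order studies conducted here the distinction is immaterial, and
  the stationarity test in the suite (uniformity of the start phase)
  covers the models the estimators' unbiasedness actually relies on.

Dispersion is parameterised by the *average relative thickness deviation*
$E|h - T|/T$ (default 0.05, i.e. 5%). `calibrate_dispersion()` solves for
the truncated-normal scale achieving it — in closed form for the
cumulative model, via the identity $E|X - X'| = 2\int F(1-F)$ and
numerical root-finding for the perturbed model. Both calibrations scale
linearly in $T$ and are cached per `rel_dev`. Targets beyond the
truncation-imposed suprema ($1/3$ and $1/4$ of $T$) fail loudly.

**Dropouts** are independent thinning: every section is lost with the same
probability. The simulation engine thins the full plane process *before*
trimming to the estimation-ready window, which preserves stationarity and
hence unbiasedness exactly. The series-level helper `apply_dropout()`
necessarily spares the two terminal zero-area planes (a trimmed series has
no planes beyond them); this mildly under-weights boundary sections, so
simulation studies always use the engine's pre-trim thinning.

## Variance estimation

All estimators are built from the empirical covariogram
$\hat g(k) = \sum_j \mathrm{Area}(S_j)\mathrm{Area}(S_{k+j})$ (only lags
0–2 enter) combined with moment estimates of the thickness distribution:

* **Model-free** (`varest_model_free()`): uses the empirical
  $\hat\gamma_{i,j}$ moments of the observed gaps; valid under any
  stationary sampling and after dropouts (`varest_after_dropout()`
  delegates here).
* **Perturbed model** (`varest_perturbed()`): uses $\hat T$,
  $\hat\theta_2$, $\hat\theta_4$ (mean, variance, fourth centred moment of
  the thickness). Not valid after dropouts; thinned series are refused.
* **Cumulative model** (`varest_cumulative()`): uses the raw moments
  $\hat\nu_1..\hat\nu_5$. Same dropout restriction.

With constant gaps all three reduce *exactly* (to $10^{-12}$ relative
error in the tests) to the classical equidistant estimates
$\frac{T^2}{12}(3\hat g(0) - 4\hat g(1) + \hat g(2))$ ($m=0$) and
$\frac{T^2}{240}(\cdot)$ ($m=1$). These reductions, together with the
closed-form moment substitutions of the two sampling models, pin down the
exact algebraic form of the $m=1$ formulas.

Numerical choices:

* Negative values of the covariogram combination (possible on pathological
  inputs) are clamped to zero with a warning — a variance report must be
  nonnegative, and the event is diagnostic.
* The *refined* moment corrections
  ($\hat\theta_2 N^2/(N^2-1)$ and $\hat T^2 - \hat\theta_2/(N^2-1)$) are
  exposed behind `refined = TRUE` and apply only to the perturbed $m = 0$
  formula, the only case for which the corrections are available; they are
  practically indistinguishable from the plain estimates except at very
  small $N$, and the plain estimators are the recommended default.
* The estimators approximate the variance by its extension term. For
  1-oriented objects the Zitterbewegung can reach the extension term (the
  ball attains the bound), so `conservative_bound()` doubles the estimate
  to cover it; the bound is not stated for $m = 0$ and such inputs are
  refused.

## The synthetic lobe generator

`synthesize_lobe_profile()` emulates the summary characteristics of
agar-embedded primate parietal lobes: 12–15 slabs of nominal 2.5 mm cut in
the perturbed model, cut-surface areas estimated by point counting with
area per point 2.29 mm², and an expected total of 645 counted points per
specimen. The generating profile is a smooth asymmetric unimodal bump
$u(1-u)(1+0.6u)$ (scaled), chosen so the profile has *nonzero slopes at
its support boundary* — two first-derivative jumps, exactly the structure
a cubic-spline profile through zero end-areas has, making the object
genuinely 1-oriented with a visible Zitterbewegung. Its integral is
calibrated to `total_points * area_per_point * nominal_gap`, and the
profile is placed with a uniform random shift relative to the cut lattice,
which makes the expected total count *exactly* 645. Poisson counting noise
stands in for the bench's systematic uniform grid (slightly
over-dispersed relative to a real grid); the spline profile rebuilt from
the noisy table is what an analysis sees, while the noise-free truth is
returned alongside for simulation studies.

What the generator does **not** emulate: real lobe shapes (no specimen
data are reconstructible from summary statistics), slab compression or
photograph-based measurement error of cut positions, or the
within-section subsampling error of the areas. Passing tests therefore
validate the estimators under the stated sampling models, not the full
measurement chain of a laboratory study.

## Simulation studies: design choices

* **Grids.** Decrease-rate studies use dyadic grids of mean section counts
  $n = L/T$ (length-5, $n = 6, 12, \dots, 96$, matching the range where
  such studies are read off log-log plots). Integer counts are used
  deliberately: for objects whose $m$-th derivative jumps at the two
  support endpoints (ball, lobe) the Zitterbewegung has period 1 in $n$,
  so integer counts lock its phase and the fitted log-log slope measures
  the true order instead of the oscillation. The oscillation-free
  0-oriented object needs no such care but uses the same grid. One
  exception: the cumulative-model study of the 0-oriented object scans
  deeper ($n = 16..256$) because its jump-driven $T^2$ extension term
  masks the asymptotic order-$T$ accumulation term at coarse spacing
  (measured local slopes fall from ~1.5 at $n \approx 10$ to ~1.05 at
  $n \approx 300$).
* **Replicates.** 5000 per grid point for variance curves; $10^5$ per
  scanned spacing for the doubling point, where a ratio of variances is
  the target; $10^4$ for unbiasedness checks. Empirical variances are
  measured as mean squared deviation from the true volume, which equals
  the estimator variance (the estimators are unbiased) without
  mean-estimation noise.
* **Estimator variants.** The engine reports the trapezoidal, the fixed-$T$
  Cavalieri and the mean-gap (generalized) Cavalieri estimators. Under the
  perturbed model the $T^3$ decrease concerns the *fixed-$T$* Cavalieri
  estimator; the generalized variant carries an additional $T^2$
  contribution from endpoint noise in the mean gap and measures a slope
  near 2 over this range — both are reported so the distinction is visible.
* **Doubling point.** For the ball, both the equidistant and the perturbed
  Cavalieri variances oscillate with period 1 in $n$, and the pointwise
  variance ratio swings between roughly 1.3 and 10 within every period —
  it has no single well-defined crossing of 2. `doubling_point()`
  therefore compares the *smooth components*: both curves are de-trended
  by $T^{2m+2}$, averaged over a moving one-period window, monotonised
  (isotonic regression), and the crossing through 2 is located by linear
  interpolation. The equidistant curve is computed essentially exactly by
  quadrature over the start offset, the perturbed one by Monte Carlo.
  Under truncated-normal perturbations at 5% average relative deviation
  this measures $n^* \approx 4.8$ for the unit ball. The value is
  sensitive to the perturbation law: reducing the perturbation scale by
  ~5% moves it to ≈5.3, so readings obtained with a different (or
  unreported) perturbation family can differ by about 10%.
* **Variance-estimator diagnostics.** The coefficient of error of a
  variance estimator is its empirical SD divided by the extension term —
  variability of the *variance* estimate, not the volume estimate. The
  mean-vs-actual-variance comparison ("the estimators overestimate, with
  vanishing bias as $T$ shrinks") is made on the 0-oriented object, whose
  variance has no oscillation, so the comparison is phase-free; for the
  ball the same comparison is made between one-period phase averages,
  since pointwise the actual variance sits up to a factor ~2 above or ~20
  below the extension term depending on phase — which is precisely why the
  ×2 conservative bound exists.

## Known limitations

* Higher-order ($m \ge 2$) Newton–Cotes estimators and fractional
  smoothness are out of scope; for $f$ smoother than $m = 1$ the
  trapezoidal estimator does not adapt further.
* Area-measurement error (point counting, subsampling within sections) is
  not propagated into the variance estimates; the reported CE covers the
  sectioning variance only.
* Model-specific variance estimation adapted to dropouts is not provided;
  after dropouts the model-free estimator is the supported route.
* `estimate_volume()` trusts the caller's declaration of the sampling
  model and of dropout status; it refuses model-specific estimators for
  series flagged as thinned, but cannot detect undeclared dropouts.
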