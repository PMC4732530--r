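---
title: "Methods: cumulative surface beta-ray dose from deposition surveys"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: cumulative surface beta-ray dose from deposition surveys}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(betadose)
options(betadose.verbose = FALSE)
```

## The problem

After a large reactor release, short-lived beta emitters deposited on the
ground dominate the early skin-level dose at the soil surface — the
operational quantity is the 70 µm dose equivalent, the dose assessed at
0.07 mm tissue depth. Gamma-dose maps are routine; beta doses matter for
skin exposure and, more importantly, for organisms that live on the
surface (insects, plant leaves). This package estimates the cumulative
one-year surface beta dose at surveyed locations and interpolates it into
maps, given a soil-sampling campaign that reports per-location deposition
densities of I-131, Cs-137 and Te-129m.

## The dose model

Seven radionuclides carry essentially all of the surface beta dose:
Te-129m, Te-129, I-131, Te-132, I-132, Cs-134 and Cs-137. Each contributes
an initial surface dose rate $\dot D_{i0}$ (µSv/h per 1000 kBq/m² of its
own deposition) that decays exponentially, so the dose rate per
1000 kBq/m² of Cs-137 deposition is

$$\dot D(r_I, r_T, t) \;=\; \sum_i f_i \, \dot D_{i0}\,
  2^{-t/T_i},$$

where $T_i$ is the nuclide's half-life and $f_i$ its activity relative to
Cs-137 at deposition. Two of the seven ratios are free parameters — $r_I$
(I-131/Cs-137) and $r_T$ (Te-129m/Cs-137) — because they genuinely varied
across the contaminated area; the rest are tied to them:
$f = (r_T,\; 0.7\,r_T,\; r_I,\; 8.3\,r_T,\; 8.3\,r_T,\; 1,\; 1)$.
The short-lived daughters Te-129 (70 min) and I-132 (2.3 h) are in
activity equilibrium with their parents Te-129m and Te-132; sustaining a
fixed activity ratio to a longer-lived parent implies exactly that, so the
package decays them with the parent half-life (`decay_parent` in
[`nuclide_set()`]).

The cumulative dose over a horizon $H$ integrates in closed form,

$$D(r_I, r_T) = \frac{1}{1000}\sum_i f_i\,\dot D_{i0}\,
  \frac{T_i}{\ln 2}\left(1 - 2^{-H/T_i}\right)
  \quad [\mathrm{mSv\ per\ 1000\ kBq/m^2}],$$

and, decisively, is *exactly linear* in $(r_I, r_T)$: every $f_i$ is
affine in the two parameters. The full model therefore collapses to

$$D(r_I, r_T) = a\,r_I + b_s\,r_T + b_0,$$

with three coefficients. The package's reference calibration is
$a = 1.1165$, $b_s = 31.032$, $b_0 = 50.009$ (mSv per 1000 kBq/m² over
one year). The absolute dose at a location scales with its Cs-137
deposition density $A$ (kBq/m²): $D_A = D(r_I, r_T)\cdot A/1000$.

### Assumptions

* Sources are fresh fallout on the soil surface; the per-nuclide
  coefficients absorb the source geometry (a thin surface soil layer) and
  the Gy→Sv conversion for beta rays, taken as 1.
* No weathering, migration or run-off: activity changes only by decay.
  Over one year this overstates the late caesium term somewhat.
* Occupancy is continuous: the mapped dose is the dose an organism fixed
  at that spot would accumulate.
* The dose rate is a pure sum of decaying exponentials, hence monotone
  non-increasing. Real time-series can show small late-time structure
  (e.g. from ingrowth or redistribution); no such mechanism is modelled.

## Calibration and its identifiability

`beta_dose_model()` inverts the linear surface back to per-nuclide
coefficients. With $I(T) = (T/\ln 2)(1 - 2^{-H/T})$:

* $\dot D_{I131,0} = 1000\,a / I(T_{I131})$ — uniquely determined
  (≈ 4.02 µSv/h per 1000 kBq/m²);
* the $r_T$ slope constrains only two *group composites*: the 33.6-d
  group $\dot D_{Te129m,0} + 0.7\,\dot D_{Te129,0}$ and the 3.204-d group
  $8.3(\dot D_{Te132,0} + \dot D_{I132,0})$. `te_split` (default 0.5)
  apportions $b_s$ between the groups, and within each group the two
  members share equally;
* `cs_split` (default 0.5) likewise apportions $b_0$ between Cs-134 and
  Cs-137.

The splits are not identifiable from the one-year surface alone — only
from per-nuclide transport calculations, which are out of scope here. The
package guarantees this does not matter downstream: whatever the splits,
the calibrated model reproduces the target surface exactly at the
calibration horizon (tested to 1e-9 relative on a 20 × 20 parameter
grid), because the inversion preserves the three identifiable
combinations. Dose-rate *curves* at intermediate times do depend mildly on
`te_split`; they are qualitative output.

Re-deriving the surface from the forward model (`scan_fit()` per-$r_T$
OLS in $r_I$, then `fit_b_line()` OLS of the intercepts on $r_T$) is the
round-trip used in tests; OLS is unweighted throughout. The default scan
grids are $r_I \in \{5, 9.2, 20, 40, 100, 200\}$ and
$r_T \in \{0.1, 0.5, 1, 5, 10, 50\}$, the parameter families used for the
reference dose-rate curves.

## Conventions and units

* One year = 365.25 d = 8766 h (`hours_per_year()`); versus 365 d this
  changes the caesium term by < 0.1 %. Any horizon can be passed
  explicitly.
* Cs-134 half-life 2.0652 y and Cs-137 30.07 y from standard nuclear
  data; Te-129m 33.6 d, I-131 8.021 d, Te-132 3.204 d. All configurable
  through `nuclide_set()`.
* Dates carry day resolution; decay intervals are whole days converted to
  hours. Survey tables that were themselves referenced to a common date
  (as the bundled 72-location table was, to 2011-06-14) reproduce their
  printed corrected ratios under this convention.
* `d0` is in µSv/h; cumulative doses in mSv (explicit 1/1000 in the
  integral); deposition densities in kBq/m².

### Deposition timing

Doses are scaled by the Cs-137 deposition density *as reported* by
default (`cs137_at = "sample"`), matching the usual survey convention;
Cs-137 decays only ~0.7 % over a three-month survey delay, below the
precision of reported tables. `cs137_at = "reference"` decay-corrects the
deposition to the deposition date first — the exact estimator of the
deposition-date dose, and the mode used when validating against synthetic
ground truth (where truth is defined at deposition).

## Multilevel B-spline interpolation

Where Te-129m was not measured, its ratio field must be interpolated from
the locations that have it. The package implements multilevel B-spline
approximation on uniform cubic tensor-product lattices:

1. **BA update** (`ba_fit()`): each data point distributes a candidate
   coefficient $w z / \sum w^2$ over its 4 × 4 control-point
   neighbourhood; each control point takes the $w^2$-weighted average of
   its candidates. A single point is reproduced exactly (algebraic
   identity); untouched control points stay at zero.
2. **Multilevel refinement** (`mbs_fit()`): the coarsest lattice (4 × 4
   cells by default) fits the data; each of the following levels (6 by
   default, halving the spacing each time, so the finest cell is ~1/128
   of the domain) fits the residuals at the data points; the surface is
   the sum over levels.

Residuals at the data contract by roughly 4× per level until the lattice
resolves the point separation, after which isolated points are fitted
exactly; for ~50 uniformly scattered points a constant field is
reproduced to 1e-6 of its value at 7 levels. Fitting in geographic
coordinates first scales longitude by $\cos(\text{mean latitude})$ so the
implicit smoothing metric is locally planar — at 37° N a degree of
longitude is only ~0.8 of a degree of latitude on the ground.

Numerical choices: evaluation clamps queries to the unit square and flags
them as extrapolated (values still returned; far from the data the
surface decays smoothly to zero because untouched coefficients are zero);
interpolated ratios below zero are clamped to zero with a logged count,
and measured values are never altered; evaluation order is deterministic
and independent of data ordering. Rasters use the plain-text ESRI ASCII
grid dialect with sentinel −9999.

## The survey pipeline

`run_pipeline()` chains: decay correction of per-record ratios → $r_T$
filling by interpolation → $D(r_I, r_T)$ (linear surface, or the
closed-form integral; they agree by the round-trip) → $D_A$ → a dose
raster from the per-location $D_A$ values. Records without an I-131
measurement keep their row in the output with `NA` dose and a logged
count — the iodine ratio field is too rough (orders-of-magnitude range,
sharp south–north contrast) to interpolate routinely, so filling $r_I$ is
an explicit opt-in (`interpolate_r_i = TRUE`). When a record has no
sampling date, a configurable global date (default 2011-07-01, the middle
of a June–August campaign) is used and logged.

## The synthetic survey generator

`plume_config()` / `generate_truth()` / `sample_survey()` emulate a
2-km-mesh deposition survey with known ground truth:

* Cs-137 deposition: exponential plume kernels (a principal north-west
  trace plus a weaker southern lobe, decay lengths ~30 km along / ~7 km
  across, peak 15 000 kBq/m²) times lognormal spatial noise (GSD 1.3).
* $r_I$: base 9.2 at the source latitude with a southward linear increase
  and Gaussian noise, floored at 0 — mimicking the observed south–north
  contrast of the iodine ratio.
* $r_T$: base 1.2 plus a smooth sinusoidal spatial term (amplitude 0.4,
  wavelength 0.6°) and noise, floored at 0.
* Sampling: one record per mesh cell (0.02° spacing), a uniform random
  date in June–August 2011, activities decayed to that date, lognormal
  measurement noise (GSD 1.15; multiplicative, chosen for positivity),
  then detection-limit censoring of I-131 at 0.3 kBq/m² — reproducing the
  characteristic situation where iodine is detectable at only a minority
  of locations three months after deposition (~13–19 % under the
  defaults).

Truth grids satisfy $d_A = D \cdot A/1000$ exactly, and all draws come
from R's Mersenne-Twister stream under the configured seed, so bundles
are reproducible across platforms.

**What passing synthetic tests do and do not show.** The generator's
ratio fields are smooth by construction, which flatters interpolation:
real deposition-ratio fields have discontinuities and unresolved
small-scale variance, so the ~5 % RMSE recovery seen on masked synthetic
fields is a best case, not a field-accuracy claim. Likewise no
atmospheric-dispersion physics is modelled — the plume is a statistical
stand-in with roughly the right ranges and spatial scales.

## Validation problem sizes

The shipped tests and the acceptance script run: the calibration round
trip on a 20 × 20 parameter grid; quadrature cross-checks with
`stats::integrate` at 1e-12 relative tolerance; interpolation recovery on
300 scattered points with 30 % masked; and end-to-end synthetic runs on
~440-cell (0.05°) and ~680-cell (0.04°) meshes — sizes chosen so the full
suite completes in well under a minute while leaving every statistical
conclusion unchanged at finer meshes.

## Known limitations

* Absolute per-nuclide coefficients are only group-identifiable (above);
  published per-nuclide transport results would pin them down.
* The model is monotone in time by construction; measured dose-rate
  series with late-time bumps are outside its family.
* No weathering/migration, no uncertainty propagation on the fitted
  coefficients (the source analysis reports none), no reprojection beyond
  the cosine metric correction, and no kriging/IDW alternatives for
  comparison.
* Published map figures produced with GIS tooling are reproducible only
  qualitatively: the original interpolation settings (level count, base
  resolution) are not documented, and the underlying full survey dataset
  is not bundled — only the 72-location table is.
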