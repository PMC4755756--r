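---
title: "Quantifying site-specific Se occupancies from anomalous difference maps"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying site-specific Se occupancies from anomalous difference maps}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(selenotrace)
```

## The measurement model

An anomalous difference Fourier map collected at the Se K edge
(12,662 eV) shows peaks at anomalous scatterers whose integrated density
is proportional to occupancy × f''. At that energy f''(Se) = 3.84 e,
f''(Fe) = 1.50 e and f''(S) = 0.24 e, so selenium is 2.56 times brighter
than iron and sulfur contributes a 6.3% residual of the selenium signal.
Because the map's absolute scale is arbitrary, occupancies are obtained by
*internal calibration*: the asymmetric unit contains 30 iron atoms (7 per
cofactor copy, 8 per P-cluster copy) that are all at full occupancy, and
their mean integrated density defines what "one full-occupancy scatterer
of unit f''" looks like in map units.

For a belt-chalcogen site modeled as a Se fraction $p$ and an S fraction
$1-p$ sharing one center, the normalized density
$D_\mathrm{norm} = D_\mathrm{site}/\bar{D}_\mathrm{Fe}$ satisfies
$D_\mathrm{norm} = p\,r_\mathrm{Se} + (1-p)\,r_\mathrm{S}$ with
$r_X = f''(X)/f''(\mathrm{Fe})$, giving

$$p = \frac{D_\mathrm{norm} - r_\mathrm{S}}{r_\mathrm{Se} - r_\mathrm{S}}.$$

This *mixed-chalcogen* form is the residual-sulfur correction: without it
a pure-S site would read 6.3% spurious Se. A site with no complementary
sulfur (e.g. the remote low-occupancy Se site) uses the *free* form
$p = D_\mathrm{norm}/r_\mathrm{Se}$. The two-component form assumes the
chalcogen fractions sum to one; where total chalcogen is lost (late
turnover points) the missing density is reported as an unexplained
deficit rather than attempting to split one scalar into two unknowns,
which would be underdetermined.

### Assumptions

* all reference irons are at full occupancy and share, with the chalcogen
  sites, a similar B-factor regime (9.0 ± 0.4 Å² for Fe/S, 9.9 ± 0.5 Å²
  for Se);
* the anomalous difference map is zero-mean away from scatterers, so no
  baseline is subtracted inside the integration sphere;
* map noise is characterized by its RMS alone.

## Tunable parameters

| parameter | default | units | rationale |
|---|---|---|---|
| integration radius | 1.0 | Å | captures ~76% of a B≈19 Å² peak while excluding neighbors ≥2.2 Å away; ratios cancel the constant aperture factor |
| sampling rule | voxel-sum | — | grid-native, deterministic; discretization bias cancels between query and reference sites |
| B-factor cutoff | off | Å² | reference and query B-factors are similar, so no exclusion is needed |
| map resolution (blur proxy) | 1.6 | Å | nominal data resolution |
| grid spacing | resolution/3 | Å | standard crystallographic map sampling |
| noise RMS | 2% of the full-occupancy Se peak | map units | the stated map-noise statistic; fixes the 0.02 detection floor |
| aperture correction | on | — | see below |

### Calibration quality, uncertainty and the detection floor

The coefficient of variation across the 30 iron densities is the
calibration quality statistic. It is computed with the population
standard deviation (the irons are the complete reference set, not a
sample); a CV above 4% warns, above 15% errors. A site's uncertainty is
the calibration CV propagated to its occupancy, combined in quadrature
with the detection floor — the occupancy whose expected peak height
equals the map RMS, i.e. floor = RMS/peak(Se, full occupancy), which is
0.02 at the default noise and scales linearly with RMS. The two
crystallographically independent cofactor copies provide an empirical
cross-check: their per-site occupancy deviation (typically ≤ 5 points)
is recorded by `cross_copy_check()` and propagated into series
uncertainties when copies are averaged.

Estimates outside [0, 1] by at most twice their uncertainty are clamped
with a `clamped` flag; further out they keep their value and are flagged
`inconsistent` — out-of-range magnitudes are diagnostic, so they are
never silently truncated.

### The aperture correction

A 1.0 Å sphere captures a *B-dependent* fraction of a peak (the Maxwell
CDF of the Gaussian peak model, `aperture_fraction()`). Se sites are
slightly stiffer-smeared (B ≈ 9.9 Å²) than the iron references
(≈ 9.0 Å²), which biases uncorrected full-occupancy estimates low by
~2–3%. With `aperture_correction = TRUE` (default) each ratio $r_X$ is
rescaled by the captured fraction computed from the per-site B and the
resolution blur; with similar B values the correction is small, and
turning it off reproduces the plain-ratio convention of treating all B
factors as equal.

## What the synthetic scenes emulate — and what they do not

`build_fixture()` places a *generic* geometry: only the facts that matter
to the estimator are faithful — 30 reference irons in four clusters, three
belt sites per cofactor copy mutually 5.7 Å apart with Fe contacts at
2.2 Å, copies ≥ 25 Å apart, everything ≥ 10 Å from cell edges, B-factors
drawn from the stated distributions. The two copies are related by a
translation that is an exact multiple of the voxel spacing, an idealized
non-crystallographic symmetry under which both copies sample the grid
identically; the copy-to-copy deviation is then a pure noise statistic
(real NCS adds a small sampling component on top).

`render_map()` renders each component as an isotropic Gaussian,
$\rho(r) = \mathrm{occ}\,f''\,(4\pi/B_\mathrm{eff})^{3/2}
e^{-4\pi^2 r^2/B_\mathrm{eff}}$ with
$B_\mathrm{eff} = B + B_\mathrm{blur}$,
$B_\mathrm{blur} = (\mathrm{res}/1.6)^2 \times 9$ Å², so the analytic
volume integral of a full-occupancy peak equals f'' in electrons. Noise
is i.i.d. Gaussian per voxel. Values are quantized to float32 once at
render time, making CCP4 mode-2 file round trips bit-exact.

Not emulated: structure-factor-space simulation and Friedel statistics,
correlated (resolution-shaped) noise, solvent, space-group symmetry
(all maps are P1), anisotropic displacement, and the true cofactor
coordinates. Passing recovery tests therefore demonstrate the estimator's
correctness under the stated noise model, not robustness to refinement
artifacts in real data.

The default seven-point migration trajectory
(`default_timecourse_truth()`) is likewise an invented, plausible
emulation — monotone Se loss from 2B, transient 5A > 3A population, near
total loss by turnover #5361 — used as planted truth for recovery
testing, not as measured values.

## Numerical choices

* **Sphere sampling.** Voxel-sum uses the voxel-center inclusion rule
  (center distance ≤ radius) with full voxel-volume weighting and
  periodic wrap; fewer than 7 voxels in the sphere is an error. Its
  per-site boundary-voxel scatter (~1–2%) cancels between query and
  reference sites at equal spacing. The `subgrid-trilinear` rule smooths
  the sphere cutoff but flattens sharp peaks by several percent — again
  cancelling in ratios. The `fourier` rule integrates the map's
  trigonometric interpolant over the sphere exactly (FFT × analytic
  sphere form factor) and is accurate to the map's band limit; it is the
  reference path used against the brute-force quadrature oracle in the
  tests, and the slowest.
* **Recovery accuracy.** Noiseless planted occupancies are recovered
  within 0.01 using subgrid-trilinear sampling with the aperture
  correction; at default noise the mean absolute error is ~0.01 over 100
  replicates.
* **Dixon aggregation.** With more than two substrate levels the
  intersection point is overdetermined; the abscissa is aggregated as the
  median of all pairwise line intersections (mean available), with MAD as
  dispersion, and near-parallel pairs (relative slope difference < 1e-6)
  excluded with a warning.
* **Lag phase.** The steady-state segment is the longest suffix attaining
  the best R² (ties favor longer suffixes); the lag is that line's
  x-intercept floored at zero, and non-positive slopes yield zero lag.
* **Dose optimum ties** break toward the lower concentration with a
  warning; a maximum at the highest tested concentration is flagged as
  having no interior optimum.
* **Rounding for display** is half-up (`round_half_up()`), matching the
  tabulated convention (6.25% displays as 6.3%); computations keep full
  precision.
* **Seed fan-out.** One top-level seed derives per-stage seeds through a
  fixed integer hash (`derive_seed()`, always < 2³¹), so a single number
  reproduces fixture geometry, B-factor draws and every noise stream.

## Open design decisions taken

* **Generator noise for the assay emulations.** The assay tables are
  synthetic emulations parameterized by the published summary statistics
  (K\_i = 410 µM and 12.7 mM, the 65%/38% relative H₂ activities, the
  1 mM CH₄ optimum, the 2350 nmol·min⁻¹·mg⁻¹ specific activity and the
  printed concentration grids). Replicate velocity noise is set to 1% CV
  for the Dixon layouts — calibrated once so the propagated K\_i
  dispersion is of the same order as, and within, the printed ± bands
  (the thiocyanate layout extrapolates ~3× beyond its inhibitor grid and
  amplifies noise accordingly) — and 3–5% for the titration assays.
* **Active-site molarity.** Turnover normalization needs the tetramer
  molar mass, which is a configuration input: default 230 kDa with two
  active sites per (αβ)₂ tetramer.
* **Copy averaging** uses equal weights; half the absolute copy
  difference enters the series uncertainty in quadrature.
* **No kinetic model** is fit to the migration traces: the ordered-vs-
  random character of the migration is not identifiable from these data,
  so the series module reports traces and conservation diagnostics only.

## Problem sizes used by the tests

The default fixture is a 72 × 51.2 × 37.3 Å orthorhombic P1 cell sampled
at 8/15 Å (135 × 96 × 70 ≈ 0.9 M voxels, ~0.2 s to render and fit).
Monte-Carlo statements (Fe reference CV, copy-to-copy deviation, noisy
recovery) use 100 seeded replicates; Dixon noise properties use 200
replicates; the noiseless recovery grid covers planted fractions
{0, 0.1, 0.25, 0.5, 0.75, 1}.

## Known limitations

* Only P1 maps with X,Y,Z axis order and zero origin are read/written;
  mmCIF, symmetry expansion and anisotropic B-factors are out of scope.
* The estimator quantifies at *given* site centers; there is no peak
  search, and positional errors translate directly into density loss.
* The mixed-chalcogen form cannot separate Se loss from total chalcogen
  loss at a single site; the total-occupancy deficit is reported as
  unexplained.
* Real-map features absent from the noise model (Fourier ripple,
  series-termination effects, model bias) are untested by construction.
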