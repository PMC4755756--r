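# selenotrace

Site-specific selenium occupancies in a nitrogenase-like metallocluster,
quantified from anomalous difference Fourier maps — with the synthetic
crystallographic fixtures and enzyme-kinetics routines needed to exercise
the whole analysis without deposited diffraction data.

## The problem

Selenium can be incorporated from selenocyanate into the S2B belt-sulfur
position of the nitrogenase FeMo-cofactor and then migrates, during
catalytic turnover, through the other two belt positions (S5A, S3A) until
it is lost. Tracking that migration means asking, for every freeze-quenched
crystal structure: *what fraction of each belt site is selenium?*

At the Se K edge (12,662 eV) the imaginary anomalous scattering factors are

| element | f'' (e) |
|---------|---------|
| Se      | 3.84    |
| Fe      | 1.50    |
| S       | 0.24    |

and anomalous difference map peaks scale with occupancy × f''. The
estimator this package implements:

1. integrate the anomalous density in a 1.0 Å sphere around every site
   (voxel sum with periodic wrap; trilinear-subgrid and exact spectral
   sampling are available);
2. calibrate the map scale internally on the 30 full-occupancy iron atoms
   of the asymmetric unit (2×7 cofactor Fe + 2×8 P-cluster Fe); their
   coefficient of variation (≤ 4% in practice) is the calibration quality
   statistic;
3. convert each belt-site density to a Se fraction with the
   residual-sulfur correction. Writing `D_norm = D_site / D̄_Fe` and
   `r_X = f''(X)/f''(Fe)`, a mixed Se/S site with Se fraction `p` obeys
   `D_norm = p·r_Se + (1−p)·r_S`, so

   `p = (D_norm − r_S) / (r_Se − r_S)`   (r_S/r_Se = 6.3%);

   an isolated Se site uses the free-mode form `p = D_norm / r_Se`;
4. attach uncertainties from the Fe calibration scatter and the map-noise
   detection floor (the occupancy whose expected peak equals the map RMS;
   0.02 at the typical noise level), and cross-check the two
   crystallographically independent cofactor copies against each other.

A synthetic-scene generator renders B-factor-smeared Gaussian peaks with
*planted* occupancies onto a P1 grid (CCP4/MRC mode-2 files), so the whole
pipeline is testable end to end: planted truth in, estimates out. The
kinetics module covers the surrounding assay arithmetic: Dixon-plot
inhibition constants from unrestrained line intersections, specific
activities, lag phases, relative activities, and dose optima.

## Worked example

Quantify a resting-state scene (Se fully on the 2B site) at the default
map noise (RMS = 2% of the full-occupancy Se peak):

```r
library(selenotrace)
scene <- build_scene(fixture_spec(seed = 7))
fit <- fit_occupancy(scene)
summary(fit)
#> Se occupancy fit (internal Fe calibration)
#>   Fe reference: n = 30, CV = 3.39%; detection floor = 0.021
#>   x2B     copy 1:  99.0% +/- 3.9%
#>   x5A     copy 1:   0.0% +/- 2.1% (below detection)
#>   x3A     copy 1:   0.1% +/- 2.1% (below detection)
#>   x2B     copy 2: 100.0% +/- 4.0%
#>   x5A     copy 2:   0.4% +/- 2.1% (below detection)
#>   x3A     copy 2:   0.0% +/- 2.1% (below detection)
#>   copy-to-copy max deviation: 1.0 occupancy points
```

The planted occupancy (100% Se on 2B, none elsewhere) is recovered within
the calibration uncertainty; the empty sites sit below the 2% detection
floor. A full seven-point migration series is one call:

```r
scenes <- simulate_timecourse_scenes(default_timecourse_truth(),
                                     fixture_spec(seed = 11))
series <- quantify_timecourse(scenes)
conservation_diagnostics(series)   # total-Se non-increasing, x5A leads x3A
plot(series)
```

and an inhibition constant from a Dixon layout:

```r
kse <- dixon_ki(simulate_dixon_assay(compound = "KSeCN", seed = 1))
kse
#> Dixon fit: K_i = 414.8 (MAD 3.54) from 6 lines, 15 intersections
```

`run_pipeline(run_config(seed = 1))` executes simulate → quantify →
timecourse, writing maps, PDBs, the series CSV and a provenance record
with checksums; re-running from the same config reproduces every output
bit-exactly.

Small example CSVs mirroring the assay layouts (all synthetic, generated
by the `simulate_*` functions) are installed under `inst/extdata/`.

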