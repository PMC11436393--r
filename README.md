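# mgscaffold

Synthetic micro-CT analysis of bioresorbable magnesium-alloy coronary
scaffolds.

Bioresorbable Mg scaffolds (BRS) restore vessel patency and then corrode
away over roughly two years. Preclinical micro-CT follow-up quantifies that
process with three serial measurements: the **remaining scaffold volume
ratio** (estimated from the grayscale histogram by peak fitting), the
**strut discontinuity ratio** (fraction of designed strut segments whose
endpoints are no longer bridged by scaffold material), and the **scaffold
inner area** on cross-sections at ~3 mm intervals. Because the underlying
animal scans of such studies are not public, this package provides the full
analysis chain *plus* a voxel phantom generator that emulates the imaging
physics, so every estimator can be validated against programmed ground
truth.

It is aimed at researchers developing or validating quantitative micro-CT
pipelines for resorbable implants.

## The degradation model

A strut of rectangular cross-section `w x h` (110 µm square here) corrodes
by uniform recession of every exposed face at rate `k` (mm/month). Length
loss at the strut ends is negligible, so the remaining volume fraction
equals the remaining cross-sectional area fraction

```
f(t) = (1 - 2kt/w)(1 - 2kt/h),        clamped at 0
```

For the square strut `f(t) = (1 - t/T)^2` with complete degradation period
`T = w/(2k)` and 50% degradation period `t50 = T (1 - 1/sqrt(2))`.
Scenario curves are parameterized by the percent area loss at one month
(`k = s(1 - sqrt(1 - loss/100))/2` for side `s`), and `fit_T()` recovers
`T` from observed remaining-volume ratios by bounded least squares.

With the fitted complete degradation period of 23.5 months, `t50 = 6.88`,
i.e. ~7 months; and among the 5% / 7.5% / 10% loss-at-1-month scenarios the
7.5% curve is the closest (least squares at t = 1, 6, 12, 18 months) to the
T = 23.5 reference — these two numbers are the package's acceptance
targets.

## Worked example

A four-timepoint synthetic study of a short (2-ring) device, eroded at the
rate implied by a 23.5-month complete degradation period, imaged with a
1-voxel PSF and SNR 10, and quantified by histogram peak fitting:

```r
library(mgscaffold)
design <- scaffold_design(nominal_diameter = 3, n_rings = 2)
graph  <- build_design(design)
print(graph)
#> design_graph: 24 nodes, 26 segments, total length 30.40 mm

cfg <- validate_config(list(
  design = list(n_rings = 2),
  degradation = list(T_complete = 23.5, substitution_fraction_dense = 0,
                     substitution_fraction_lucent = 0),
  schedule = lapply(c(1, 6, 12, 18), function(t) list(time = t)),
  rendering = list(spacing = 0.02, psf_sigma = 1, noise_sd = 10),
  seed = 1))
rep <- run_timecourse(cfg)
print(rep)
#> study_report:
#>  time erosion_depth n_cut mg_volume_mm3 remaining_ratio discontinuity_ratio
#>     1   0.002340426     0      0.337792    0.9182214150                   0
#>     6   0.014042553     0      0.207344    0.5636240677                   0
#>    12   0.028085106     0      0.046784    0.1271731441                 100
#>    18   0.042127660     0      0.000144    0.0003914358                 100
#>  n_fragments mean_inner_area_mm2 failed
#>            1                  NA  FALSE
#>            1              3.5932  FALSE
#>            0                  NA  FALSE
#>            0                  NA  FALSE
#> degradation model fit: T_complete = 20.61 months, t50 = 6.04 (~6) months
#>   implied loss at 1 month: 9.47%; residual SS 0.00639
```

Reading: the programmed `(1 - t/23.5)^2` law gives (0.917, 0.555, 0.239,
0.055); the estimates match closely at 1 and 6 months but under-detect the
sub-resolution remnant (< 3 voxels across) at 12–18 months. Refitting the
estimates still recovers `T = 20.6` months, within 13% of the programmed
23.5 despite blur and noise. Once the peak detector loses the alloy, the
grayscale mask empties — discontinuity reports 100% and the inner area
becomes unmeasurable, mirroring late in-vivo follow-up where such
measurements also became impossible. The noiseless label-volume path
(`use_labels: true`) recovers `T` within ~1%.

The CLI exposes each stage (`simulate-phantom`, `estimate-volume`,
`integrity`, `inner-area`, `fit-model`, `run-timecourse`):

```sh
CLI=$(Rscript -e 'cat(system.file("cli/mgscaffold", package="mgscaffold"))')
CFG=$(Rscript -e 'cat(system.file("extdata/example_study.yaml", package="mgscaffold"))')
Rscript $CLI simulate-phantom --config $CFG --out ph --time 6
Rscript $CLI integrity --labels ph/labels_t6.mhd --config $CFG --out integ.csv
#> discontinuity 46.15% (8 fragments)
```

## Layout

- `R/`, `src/` — implementation (geometry, phantom, volume I/O, histogram
  peak fitting, integrity, degradation model, pipeline).
- `vignettes/mgscaffold-methods.Rmd` — the methods vignette: model
  assumptions, estimator design, numerical choices, limitations.
- `tests/testthat/` — unit, property, and acceptance tests; fixtures are
  generated in code.
- `inst/cli/mgscaffold`, `inst/extdata/example_study.yaml` — CLI and
  example study configuration.
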