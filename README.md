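# vertemorph

Automated quantitative morphometry (QM) of thoracolumbar vertebral bodies in
lateral spine radiographs, for researchers building or validating vertebral
deformity screening pipelines (osteoporotic fracture assessment, T4–L5).

## What it computes

The pipeline has two stages:

1. **Detection.** Vertebral bodies are segmented into instance masks (a
   pluggable backend; the built-in reference backend is an intensity
   threshold + connected-component labeler). Each mask is reduced to its
   center of gravity, and a polynomial spinal curve *x = f(y)* (degree ≤ 4)
   is fitted to all centers with RANSAC. Centers deviating significantly
   from the curve — rib, diaphragm or airway edges picked up as false
   detections — are discarded, and a fixed-size crop (default 224 × 224 px)
   is extracted around each retained center.
2. **Morphometry.** On each crop, six landmarks are placed (pluggable
   backend; a truth-oracle backend with configurable Gaussian noise is
   provided for phantom studies): anterior-upper/lower (AU, AL),
   central-upper/lower (CU, CL), posterior-upper/lower (PU, PL). From these,
   the anterior, central and posterior heights

   A = ‖AU − AL‖,  C = ‖CU − CL‖,  P = ‖PU − PL‖

   give the height ratios **C/A, C/P, A/P**, a collapse percent
   100·(1 − min(A/P, C/P)), and a QM status bin (<20 %, 20–25 %, 25–40 %,
   >40 %, half-open on the left).

An evaluation suite implements the observer-agreement statistics used to
validate such pipelines: detection sensitivity / precision / false positives
per image, landmark errors normalised by vertebral width and height,
Shapiro–Wilk-gated Pearson/Spearman correlation, and Bland–Altman analysis
(mean difference, limits of agreement MD ± 1.96 SD, per-QM-bin coverage of
the global LOA, and proportional-bias regression of differences on pair
means). A review flag marks vertebrae whose ratios differ by ≥ 0.2 between
two measurements.

Because clinical radiographs cannot ship with a package, a synthetic spine
**phantom generator** produces radiograph-like images with exact ground
truth (masks, landmarks, per-level wedge/biconcave/crush deformities with
controlled severity, and optional diaphragm/airway/rib confuser structures),
so every stage is testable end to end.

## Worked example

```r
library(vertemorph)

spec <- phantom_spec(
  noise_sd = 0, confusers = "diaphragm",
  deformities = tibble::tibble(level = "T8", type = "wedge", severity = 0.45)
)
case <- generate_phantom(spec)

det <- detect_vertebrae(case$image)
det
#> <vm_detection> 15 center(s) detected, 14 retained on the spinal curve

res <- measure_radiograph(case$image, landmark_backend_oracle(case))
res <- label_by_nearest(res, case$truth_landmarks)
dplyr::select(res, level, A, C, P, ratio_CA, ratio_CP, ratio_AP,
              collapse_pct, qm_status)
#> # A tibble: 14 × 9
#>   level     A     C     P ratio_CA ratio_CP ratio_AP collapse_pct qm_status
#>   <chr> <dbl> <dbl> <dbl>    <dbl>    <dbl>    <dbl>        <dbl> <fct>
#> 1 T4     22    22    22       1       1        1              0   <20
#> 2 T5     22.7  22.7  22.7     1       1        1              0   <20
#> 3 T6     23.3  23.3  23.3     1       1        1              0   <20
#> 4 T7     24.0  24.0  24.0     1       1        1              0   <20
#> 5 T8     13.6  19.2  24.8     1.41    0.775    0.550         45.0 >40
#> 6 T9     25.5  25.5  25.5     1       1        1              0   <20
#> # ...
```

The bright diaphragm-like arc is detected as a 15th instance but rejected by
the spinal-curve filter (its centroid sits ~100 px off the fitted curve).
The wedged T8 recovers its constructed deformity exactly: A/P = 0.55, i.e.
45 % anterior collapse, QM bin ">40". Comparing against ground truth:

```r
rep <- evaluate_pipeline(res, case$truth_landmarks)
rep
#> <qm_report>
#>   detection: sensitivity 100.0%, precision 100.0%, 0.000 FP/image (1 images)
#>   ratio_CA: spearman r = 1.000 | MD = 0.0000, LOA [0.0000, 0.0000]
#>   ratio_CP: spearman r = 1.000 | MD = 0.0000, LOA [0.0000, 0.0000]
#>   ratio_AP: spearman r = 1.000 | MD = 0.0000, LOA [0.0000, 0.0000]
#>   discrepancies >= threshold: 0 of 14 vertebrae
```

`tidy()`, `glance()` and `autoplot()` methods are provided for the fitted
spinal curve, Bland–Altman results, correlations and full reports. A thin
command-line wrapper with `simulate`, `detect`, `measure`, `evaluate` and
`end2end` subcommands is installed at `inst/cli/vertemorph.R`.

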