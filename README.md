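# heqr — homology-based emphysema quantification from lung CT slices

`heqr` quantifies pulmonary emphysema on 2-D CT slices and predicts the
radiologist's ordinal visual score (0 = no emphysema … 5 = very severe) from
the quantification alone. It is aimed at chest-imaging researchers who want a
spatially aware alternative to the classical low-attenuation area percentage
(LAA%).

## The idea

At an HU threshold *t*, the low-attenuation lung set
`{p ∈ lung : HU(p) < t}` is a binary image. Besides its area,

    LAA%(t) = 100 · #{p ∈ lung : HU(p) < t} / #lung,

the package computes the set's Betti numbers: **b₀**, the number of connected
low-attenuation regions, and **b₁**, the number of normal-lung islands those
regions fully enclose — normalized by lung area to **nb₀** and **nb₁**.
Sweeping *t* from −1000 to −700 HU in 5 HU steps (60 levels, half-open range)
yields a threshold filtration whose profile captures how lesions appear, grow
and merge. Concatenated per-slice profiles form feature vectors — length 60
for the LAA% classifier, 120 (nb₀ block then nb₁ block) for the topological
one — for a Random Forest evaluated by leave-one-patient-out (LOPO)
cross-validation, with Spearman correlation, quadratic-weighted kappa and the
exact McNemar test as the surrounding statistics. A synthetic phantom module
generates scored cohorts with ground-truth lesion topology so the entire
pipeline is testable without clinical data.

## Worked example

```r
library(heqr)

# a scored synthetic cohort: 8 patients x 2 slices, known lesion topology
cohort <- make_cohort(cohort_spec(n_patients = 8, slices_per_patient = 2,
                                  seed = 7))
curves <- quantify_cohort(cohort, threshold_grid(-1000, -700))
dplyr::filter(curves, slice_id == "P001_S1", threshold_hu %in% c(-950, -875))
#> # A tibble: 2 × 10
#>   threshold_hu laa_pct    b0    b1     nb0      nb1 lung_pixels slice_id
#>          <int>   <dbl> <int> <int>   <dbl>    <dbl>       <int> <chr>
#> 1         -950    19.7    29    65 0.00156 0.00350        18556 P001_S1
#> 2         -875    20.2    29     4 0.00156 0.000216       18556 P001_S1
#> # ℹ 2 more variables: patient_id <chr>, score <int>

features <- build_features(curves, threshold_grid(-1000, -700), "heq")
search <- grid_search(features, rf_grid(), seed = 7)
search$best
#> Leave-one-patient-out CV (heq features): accuracy 62.5% on 16 slices
#>   trees = 10, feature fraction = 0.1, keep fraction = 1.0
glance(search$best)[, 1:4]
#> # A tibble: 1 × 4
#>   accuracy weighted_kappa n_slices n_patients
#>      <dbl>          <dbl>    <int>      <int>
#> 1    0.625          0.948       16          8
```

This slice carries visual score 5: at −950 HU its low-attenuation set covers
19.7% of the lung in 29 separate regions (`b0`), with 65 normal-lung islands
still enclosed (`b1`); by −875 HU most islands have been absorbed into the
growing lesions (`b1 = 4`) while the area has barely changed — exactly the
kind of spatial evolution LAA% alone cannot see. On this deliberately small
cohort the LOPO accuracy is 62.5%; the near-perfect kappa (0.948) reflects
that misclassifications land on neighbouring scores. The grid search picks
the Random-Forest
configuration with the best LOPO accuracy (ties go to the smaller forest);
`glance()` adds the quadratic-weighted kappa of its confusion table.
`autoplot(curves)`, `autoplot(search$best)` and `plot_range_sweep()` draw the
filtration profiles, the confusion matrix and the 21-cell threshold-range
accuracy table. `inst/exec/heq` exposes the same stages as shell subcommands
(`synth`, `quantify`, `features`, `cv`, `stats`, `compare`, `run`).

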