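---
title: "Homology-based emphysema quantification: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Homology-based emphysema quantification: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(heqr)
```

## The problem

Pulmonary emphysema destroys lung parenchyma, which lowers its X-ray
attenuation. On CT the classical quantitative measure is the percentage of
low-attenuation lung area,

$$\mathrm{LAA\%}(t) \;=\; 100 \times
\frac{\#\{\,p \in \mathrm{lung} : \mathrm{HU}(p) < t\,\}}
     {\#\,\mathrm{lung}},$$

at some Hounsfield-unit threshold $t$ (conventionally $-950$ or $-910$ HU).
LAA% ignores *how* the low-attenuation tissue is arranged, yet radiologists'
ordinal visual scores (0 = no emphysema ... 5 = very severe) are known to
respond to the spatial pattern of destruction, not just its total area.

This package quantifies that pattern topologically. At each threshold $t$
the low-attenuation set is a binary image; its Betti numbers are

* $b_0$ — the number of connected low-attenuation regions, and
* $b_1$ — the number of normal-lung islands completely surrounded by
  low-attenuation tissue,

normalized by lung area to $nb_0 = b_0 / \#\mathrm{lung}$ and
$nb_1 = b_1 / \#\mathrm{lung}$ so that slices of different sizes are
comparable. Sweeping $t$ from $-1000$ to $-700$ HU in 5 HU steps produces a
threshold *filtration*: a nested family of low-attenuation sets whose
evolving topology summarizes lesion number, growth and coalescence. The
per-slice profiles $(nb_0(t), nb_1(t))$ — and, for the reference method,
$\mathrm{LAA\%}(t)$ — are concatenated into feature vectors for a Random
Forest that predicts the visual score; accuracy is estimated by
leave-one-patient-out (LOPO) cross-validation and compared between the two
feature families with the exact McNemar test.

## Pipeline and parameters

1. **Lung segmentation** (`segment_lungs()`): candidate pixels are those
   strictly below $-500$ HU; 8-connected components touching the image
   border (outside-patient air) are removed, as are components below
   `min_area` = 50 px (airways, noise). The default threshold separates
   aerated lung (about $-900$ to $-700$ HU) from soft tissue (about
   $0$-$100$ HU) with a wide margin; the procedure is deterministic and
   needs no seed point. It makes no attempt to separate left and right
   lungs, and a mask produced elsewhere can be supplied instead
   (`load_mask()`).

2. **Binarization and topology** (`binarize()`, `betti_numbers()`):
   a lung pixel is low-attenuation iff HU is *strictly* below the
   threshold. $b_0$ counts 8-connected foreground components; $b_1$ counts
   4-connected complement components that touch no image border. The 8/4
   dual pairing is the standard choice that avoids the connectivity
   paradoxes of same-connectivity foreground and background, and it makes
   the identity $\chi = b_0 - b_1$ exact, where $\chi$ is the Euler
   characteristic of the pixel set viewed as a union of closed unit squares
   (`euler_characteristic()`, computed independently as
   vertices $-$ edges $+$ faces and used as a cross-check throughout the
   tests). Defining holes as border-free complement components means a
   degenerate low-attenuation ring that encircles *non-lung* tissue would
   also count; on chest slices the non-lung complement is border-connected,
   so in practice the counted holes are exactly the surrounded normal-lung
   islands.

3. **Threshold grid** (`threshold_grid()`): half-open, $[\ell, u)$ in 5 HU
   steps. The full range $[-1000, -700)$ therefore has exactly 60 levels,
   which fixes the canonical feature lengths: 60 for the LAA% classifier
   and 120 for the topological one. (An inclusive range would give 61
   levels and inconsistent vector lengths; the half-open convention is the
   one that reproduces the canonical lengths.)

4. **Feature vectors** (`build_features()`): for the topological classifier
   the vector is the $nb_0$ block followed by the $nb_1$ block, each in
   ascending threshold order. The block order follows the column
   concatenation of the filtration profile; within-block ascending order is
   a reproducibility convention — Random Forests are invariant to feature
   order. No scaling is applied (trees are scale-invariant). The 21
   sub-ranges evaluated by `range_sweep()` cross lower limits
   $\{-1000, \dots, -750\}$ with upper limits $\{-950, \dots, -700\}$ in
   50 HU steps.

5. **Prediction** (`lopo_cv()`, `grid_search()`): a Random Forest
   classifier over the six score classes, hyperparameter grid = number of
   trees $\{10, 100, 1000\}$ $\times$ per-split feature fraction
   $\{0.1, 0.3, 0.5, 0.7, 0.9\}$ (per-split count
   $\max(1, \mathrm{round}(f \cdot p))$, half-up rounding). Folds are
   patients, so within-patient similarity can never leak into a patient's
   own prediction. The best configuration is chosen on the same
   cross-validation that is reported; that selection is optimistically
   biased, and is retained deliberately because the reported headline
   accuracies are defined by that protocol. Training folds may lack the
   rare severe scores entirely; the forest then simply cannot predict the
   absent classes in that fold, which mirrors the scarcity of severe cases
   in screening-type cohorts. Optional importance-based feature selection
   (`select_features()`, keep fractions 0.9/0.7/0.5) ranks features by
   Gini impurity decrease *within each training partition only*.

6. **Statistics** (`spearman()`, `accuracy()`, `weighted_kappa()`,
   `mcnemar_exact()`): Spearman correlation between quantification and
   score; accuracy as trace over total of the $6\times6$ contingency
   table; quadratic-weighted kappa
   $\kappa = 1 - \sum_{ij}(i-j)^2 O_{ij} \,/\, \sum_{ij}(i-j)^2 E_{ij}$
   with categories fixed at 0-5 even when some scores are absent, so the
   weights always use the full ordinal scale; and the central exact
   McNemar p-value $p = \min(1,\, 2\,P(X \le \min(b,c)))$,
   $X \sim \mathrm{Bin}(b+c, 1/2)$ — the doubled-one-tail convention, the
   default behaviour of the standard exact-test implementations. Spearman
   p-values and kappa confidence intervals are not computed.

## The synthetic phantom cohort

Real scored CT databases cannot ship with a package, so every stage is
exercised on synthetic phantoms with *known* topology
(`make_phantom()`, `make_cohort()`):

* geometry: two elliptical lung fields inside a body ellipse on an air
  background (256 px square by default); body $+40$ HU, lung $-780$ HU,
  air $-1000$ HU;
* lesions: solid disks at $-980$ HU (one $b_0$ component each) and annuli
  enclosing normal lung (one component *plus* one hole each), placed by
  rejection sampling with a 1000-attempt cap, pairwise separated so
  components never merge; placement is deterministic given the seed;
* ground truth: for any threshold strictly between lesion and lung HU on a
  noise-free phantom, the low-attenuation set is exactly the lesion set, so
  LAA pixel count, $b_0$ and $b_1$ are known by construction — this is the
  package's strongest correctness oracle;
* cohort structure: 39 patients $\times$ 3 slices by default. Each patient
  draws one score from a skewed distribution (weights 61, 26, 11, 12, 3, 2
  — most slices show no or minimal emphysema, as in screening cohorts);
  lesion burden per score rises monotonically (disks 0, 3, 7, 12, 18, 25;
  rings 0, 0, 1, 2, 3, 4), with a per-slice jitter of one disk so slices of
  a patient are similar but not identical. The burden bands of adjacent
  scores stay disjoint under the jitter, so burden is monotone in score by
  construction. Slices carry 15 HU of additive Gaussian noise by default so
  segmentation and binarization are exercised away from the piecewise
  constant case.

What the phantoms do *not* emulate: anatomically realistic lung shapes,
airway trees, scanner reconstruction kernels, partial-volume effects,
correlated noise, or the continuum of real emphysema morphologies. Passing
the end-to-end tests therefore demonstrates that the pipeline recovers
scores when the score-to-morphology mapping is as assumed — not that it
reaches any particular accuracy on clinical data.

## Numerical conventions and edge cases

* Strict `<` at every threshold (a pixel exactly at the threshold is not
  low-attenuation), consistently in segmentation, binarization and LAA%.
* Thresholds outside $[-1024, 500]$ HU are rejected as implausible.
* Empty low-attenuation set: $(b_0, b_1) = (0, 0)$; an all-air slice fails
  segmentation with an explicit "no lung found" error because border
  air is excluded.
* Grid-search ties are broken toward fewer trees, then a smaller feature
  fraction (the cheaper, less variable model).
* `b + c = 0` discordant pairs yield a McNemar p of 1 with a warning;
  zero rank variance makes Spearman `NA` with a warning; a one-cell
  contingency table makes kappa `NA` with a warning.
* All randomness (phantom placement, noise, forest fitting) descends from
  explicit integer seeds; cohorts and cross-validation results are pure
  functions of their seeds.

## Problem sizes used in the tests

The exhaustive topology check compares the compiled Betti implementation
against an independent pure-R flood-fill oracle on all $2^{16}$ binary
$4\times4$ grids and verifies $b_0 - b_1 = \chi$ on 1000 random
$32\times32$ grids. End-to-end experiments run on the default synthetic
cohort (39 patients, 117 slices of $256^2$ px, 60 thresholds) with the full
15-configuration grid; the label-permutation baseline uses 20 balanced
relabelling repeats at 100 trees. These sizes keep the whole suite
comfortably reproducible on a single CPU while leaving the study-scale
structure (cohort size, threshold count, hyperparameter grid) intact.

## Known limitations

* 2-D only; volumes are handled slice-by-slice via the manifest.
* Segmentation equivalence with any particular clinical region-growing
  implementation is not claimed; supplied masks bypass it.
* The score classes are treated as nominal by the forest; no
  ordinal-specific loss is used.
* Persistent-homology barcodes and derived kernels are out of scope; the
  feature vector is the plain concatenation of per-threshold quantities.
* DICOM input is not implemented; convert to NIfTI first.
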