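---
title: "Fractal and intensity histomorphometry with prognostic evaluation: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Fractal and intensity histomorphometry with prognostic evaluation: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(histofract)
```

## What the package computes

`histofract` quantifies single-stain histology images — one immunostain
channel, already decomposed upstream — and evaluates the resulting image
features against right-censored time-to-metastasis outcomes. Breast-tumor
sections immunostained for pan-cytokeratin show malignant epithelial cell
clusters as dark structures on a light background; the working hypothesis is
that the spatial arrangement, contour shapes and staining intensity of these
clusters carry prognostic information beyond standard clinicopathological
variables.

Each image yields 34 features:

* **2 staining-intensity features.** Mean pixel intensity over the whole
  8-bit image (graylevels; low = dark = heavily stained) and total stained
  area of the thresholded mask (pixel count, also reported in µm² using the
  pixel size, 0.145 µm by default).
* **6 monofractal features.** Box-counting fractal dimension of the
  thresholded mask (`bin_fd`), of its contour (`bin_fd_outline`), and binary
  lacunarity (`bin_lac`); plus the grayscale counterparts by differential
  box counting (`gray_fd`, `gray_fd_outline`, `gray_lac`).
* **26 multifractal features.** For each modality, the spectrum values
  `D_Q`, `alpha(Q)`, `f(alpha)(Q)` pinned at `Q = 0` plus ten derived
  scalars (extrema of the singularity spectrum, the `alpha` positions of
  those extrema, `max D_Q`, slopes of the three curves against `Q`, a
  restricted `D_Q` slope over `Q` in `[-1, 3]`, and `f(alpha)` summed over
  positive `Q`).

## Image preprocessing contract

The preprocessing reproduces a widely used interactive-analysis contract so
that features are comparable with values produced that way:

* **Grayscale conversion** of RGB inputs uses the unweighted channel mean,
  rounded half-up — not luminance weighting.
* **Binarization** uses the IsoData iterative-intermeans threshold on the
  256-bin histogram: starting from the image mean, `T` is replaced by the
  floor of the average of the mean intensity at or below `T` and the mean
  above `T`, until stable. Foreground is `intensity <= T`: immunostain
  absorbs light, so stained structures are the dark ones. A constant image
  yields an empty mask rather than an error.
* **Outlines** are foreground pixels with at least one 4-connected
  background neighbour (the image border counts as background). This gives
  closed, 8-connected, 1-pixel contours that are always subsets of the
  foreground.

All grids are row-major with the origin at the top-left pixel.

## Box counting and scale grid

For a binary mask, the image is tiled by a non-overlapping, origin-anchored
grid of `eps x eps` boxes; `N(eps)` counts boxes containing at least one
foreground pixel, and the fractal dimension is the OLS slope of
`log N(eps)` against `log(1/eps)`. Design choices:

* **Scale grid**: powers of two from 2 up to 45% of the shorter image side,
  requiring at least three scales (so images must be at least 18 px on the
  short side). `make_scales()` also accepts another geometric base; base 3
  is natural for base-3 constructs such as the Sierpinski carpet, where the
  aligned grid recovers `log 8 / log 3` exactly.
* **Partial edge boxes are included.** Power-of-two scales rarely divide
  arbitrary crops; excluding partial boxes biases `N(eps)` low.
* **Single grid origin.** A deterministic single-origin grid is used rather
  than multi-origin averaging; this keeps every count reproducible and
  testable against a brute-force oracle.

**Lacunarity** is the scale-averaged squared coefficient of variation of
per-box mass, with moments taken over *all* grid boxes, empty ones
included; a translation-uniform mass gives 0, and a scale at which half the
boxes are full and half empty contributes exactly 1.

**Differential box counting (DBC)** extends the count to grayscale images:
intensity is treated as surface height, the intensity axis is divided into
cells of height `h = eps * 256 / min(rows, cols)`, and each box contributes
`floor((max - min)/h) + 1` cells. A flat image gives exactly one cell per
box and dimension 2; rough surfaces approach 3. The grayscale "outline"
variant applies DBC to the image with all non-outline pixels set to zero —
the choice of how to take an outline on grayscale data is genuinely open,
and this masked-DBC construction is this package's convention.

## Multifractal spectra

Spectra are estimated by the direct (Chhabra–Jensen) method rather than by
Legendre-transforming a fitted `tau(Q)`: for each moment order `Q` the
Q-normalized box measures `mu_i(Q, eps) = mu_i^Q / sum_j mu_j^Q` are formed
over occupied boxes, and `alpha(Q)`, `f(Q)` and `tau(Q)` are OLS slopes
over the scale grid. `D_Q = tau(Q)/(Q - 1)` with the entropy limit at
`Q = 1`. The direct method avoids numerically differentiating a fitted
curve; the Legendre relation `f(alpha(Q)) = Q alpha(Q) - tau(Q)` is kept as
a cross-check property in the test suite.

Numerical choices:

* The `Q` grid is the half-open 200-point grid `-10.0, -9.9, ..., +9.9`.
  A closed `[-10, 10]` grid at 0.1 steps would have 201 points; the
  half-open grid is the one consistent with a 200-point count, and it
  contains both `Q = 0` and `Q = 1` exactly.
* All internal sums use log-sum-exp, so `|Q| = 10` does not overflow even
  with tens of thousands of boxes; scales with a single occupied box are
  well defined at negative `Q` because only occupied boxes carry measure.
* Binary masks use foreground pixel counts as box masses. Grayscale images
  use summed *inverted* intensity (`255 - I`) so that stain carries mass —
  a measure must be non-negative, and dark (stained) regions should be
  mass-heavy.
* The scalar "base" features are the spectrum values at `Q = 0`; the
  restricted `D_Q` slope uses `Q` in `[-1, 3]` with inclusive endpoints;
  `max D_Q` is taken over the grid (for a monotone spectrum this coincides
  with the value at the most negative `Q`).

**A caution on monotonicity.** For measures with exact scale invariance
(multiplicative cascades, uniform measures) the estimated `D_Q` and
`alpha(Q)` are non-increasing in `Q` to machine precision, and the cascade
spectrum matches the closed form `D_Q = log2(sum p_i^Q)/(1 - Q)`. For
images *without* exact scaling the fitted spectrum has no such guarantee:
the Rényi-entropy monotonicity theorem binds at each fixed scale, not the
regression slope across scales. Binary cluster masks analyzed over a coarse
scale window can even produce a `D_Q` that rises with `Q` (dense boxes hold
mass proportional to `eps^2` while isolated pixels hold constant mass, so
the dense set dominates positive moments with the *larger* local exponent).
Spectra of real binary histology images should therefore be read as
descriptive fit summaries, not as certified Rényi dimensions.

## Prognostic evaluation

Per feature, on the continuous values:

* **ROC AUC** by the Mann–Whitney statistic (midranks for ties), with the
  tie-corrected normal approximation for the p-value. AUC is oriented as
  the probability that an event case exceeds a non-event case, so
  `AUC < 0.5` means higher values mark the event-free (low-risk) class.
  The nonparametric case-resampling bootstrap (default 1,000 resamples)
  gives a percentile interval and a bias-corrected point estimate.

After outcome-based categorization:

* **Optimal cutpoint** by exhaustive scan of all midpoints between
  consecutive distinct values that leave at least 10% of the cohort on each
  side, maximizing the two-group log-rank statistic, ties broken toward the
  more balanced split. The scan is deterministic and is its own oracle at
  small n. Because the cutpoint maximizes outcome separation, the naive
  log-rank p is optimistic: the report always shows it side by side with a
  resampling-corrected p obtained by permuting the feature against the
  (time, event) pairs and re-running the entire scan. Simulations in the
  test suite confirm that the uncorrected type-I error exceeds the nominal
  level while the corrected one does not.
* **Cox proportional hazards** on the dichotomized groups with Efron tie
  handling; the bootstrap (case resampling stratified by group, default
  1,000) yields a bias-corrected percentile CI for the hazard ratio.
  Monotone likelihood (complete separation) is flagged, not raised.
  The proportional-hazards assumption is checked by correlating scaled
  Schoenfeld residuals with event time (identity time transform).
* **Multivariate selection**: candidates pass a univariate screen at
  `P < 0.20`, then backward elimination removes the worst Wald p until all
  remaining satisfy `P < 0.05`. Exactly collinear candidates are dropped
  and flagged; an empty final model is a legitimate result, not an error.
* **Kaplan–Meier** curves with censoring marks and the two-sided log-rank
  test summarize the categorized groups; **Spearman** rank correlations
  (average ranks for ties) describe feature–feature association, with
  constant columns reported as missing and flagged.

Two-sided tests and a 0.05 reporting threshold are used throughout; every
stochastic routine takes an explicit seed, which is recorded in the report.

## Synthetic data: what it does and does not emulate

The generators provide every input with known ground truth:

* **Analytic masks** — filled square (dimension 2), axis-aligned line (1),
  Sierpinski triangle (`log 3/log 2`), Sierpinski carpet (`log 8/log 3`),
  and random carpets with per-cell retention `p` at each 2×2 subdivision
  (expected cascade dimension `log2(4p)`, clipped to `[0, 2]`).
* **Fractional Brownian surfaces** by spectral synthesis: white noise
  filtered with amplitude `|k|^-(H+1)` and rescaled to `[0, 255]`;
  theoretical surface dimension `3 - H`. Synthesis runs on a 4× finer grid
  and is decimated, because direct synthesis at the target resolution is
  spuriously smooth below a few pixels (the spectrum is truncated at the
  Nyquist frequency); decimation restores the correct increment scaling at
  pixel lags.
* **Blob-cluster stain mimics** — unions of correlated discs grown until a
  target coverage is reached (so realized coverage matches the target to
  within one disc area), with darker textured intensities inside blobs so
  that mean intensity falls as coverage rises. These emulate the geometry
  of malignant cell clusters, not the color statistics of real stains or
  scanner noise.
* **Survival cohorts** matching the validated study frame: 73 patients at a
  25% target event rate. A latent high-risk group (half the cohort by
  default) has hazard ratio `exp(group_log_hr)` (default 3, a moderate
  planted effect) against the low-risk group; event times are exponential
  and censoring is uniform over a 77–165 month follow-up window, the
  observed censoring range of the study frame. The baseline rate is solved
  numerically so the expected event fraction equals the target exactly.
  Planted features are drawn from per-group normals: mean pixel intensity
  244.5 ± 3.1 (high risk) vs 234.4 ± 9.1 (low risk) and binary fractal
  dimension 1.640 ± 0.10 vs 1.722 ± 0.09 — higher fractal dimension and
  darker staining mark the *low*-risk group. With this geometry the binary
  fractal dimension yields AUC below 0.5 while mean pixel intensity yields
  AUC above 0.5 (events are the lighter-stained tumors).

Passing tests on these generators show that the estimators recover known
dimensions, spectra and hazards under clean conditions; they do not show
robustness to stain variability, tissue artifacts, or field-of-view
selection effects present in real slides.

## Known limitations

* **DBC range compression.** The classic differential box count with cell
  height `eps * 256 / min(rows, cols)` cannot track very rough surfaces:
  the 256-graylevel budget caps per-box relief relative to `h` across the
  scale range, so estimated surface dimensions compress toward the middle
  of `[2, 3]`. On synthesized fractional Brownian surfaces the estimator
  reads about 2.46 at `H = 0.2` (theory 2.8) and about 2.28 at `H = 0.5`
  (theory 2.5), while `H = 0.8` (theory 2.2) is recovered within 0.15.
  This is a property of the estimator, widely reported for it, and is left
  visible in the validation suite rather than patched by rescaling tricks.
  Comparisons *between* images with the same geometry remain ordered
  correctly (rougher in, larger out), which is what the prognostic use
  requires.
* **Fitted spectra are not certified dimensions** on non-scaling images
  (see the monotonicity caution above).
* The IsoData variant used by interactive tools at the version pinned by
  the contract is not documented; plain iterative intermeans is
  implemented, and the brute-force fixed-point scan in the tests defines
  the behaviour exactly.
* Whole-image mean intensity assumes the field of view is representative;
  no selection or tiling logic is provided.

## Validation problem sizes

The validation suite exercises: 512×512 analytic masks (line, filled
square, depth-7 Sierpinski triangle), the 243×243 depth-5 carpet, 256×256
fractional Brownian surfaces at `H` in {0.2, 0.5, 0.8}, a depth-6 binomial
cascade with weights (0.4, 0.3, 0.2, 0.1) checked against its closed form
over `Q` in `[-5, 5]`, brute-force oracle equivalence on images up to
64×64, and cohort calibrations with 1,000 null-AUC replicates, 500
null-hazard replicates, 100 planted-effect recovery replicates and 200
event-rate replicates at n = 73. These sizes make every check reproducible
on a laptop in well under an hour.

## A worked example

```{r example, eval = FALSE}
library(histofract)

# one synthetic "stained section" and its features
img <- gen_clusters(image_spec("blob_clusters", 256, density = 0.35, seed = 1))
features <- extract_features(img$gray)
features[c("mean_intensity", "total_area_px", "bin_fd", "bin_lac")]

# a cohort with the default planted effects, evaluated end to end
cohort <- gen_cohort(cohort_spec(seed = 1))
report <- prognostic_report(cohort, c("mean_intensity", "bin_fd"),
  n_boot = 1000, n_perm = 200, seed = 1
)
tidy(report)
autoplot(report)
```
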