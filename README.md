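# histofract

Fractal and staining-intensity histomorphometry of single-stain histology
images, with survival-based prognostic evaluation.

## The problem

Breast tumors immunostained for pan-cytokeratin show malignant epithelial
cell clusters as dark structures on a light background. The spatial
arrangement, contour shapes, texture and staining intensity of these
clusters carry prognostic information about distant metastasis that routine
microscopic grading does not quantify. `histofract` is for researchers who
want to extract that information reproducibly: it turns each single-channel
8-bit image into a fixed 34-feature record and evaluates any feature table
against right-censored time-to-event outcomes.

## The methods at its core

* **Box-counting fractal dimension.** For box sizes ε (powers of two up to
  45% of the short image side), N(ε) counts grid boxes containing
  foreground; FD is the OLS slope of log N(ε) vs log (1/ε). A line has
  FD = 1, a filled square FD = 2. Computed for the thresholded mask, its
  contour (FD_outline), and — via Sarkar–Chaudhuri differential box
  counting, which treats intensity as surface height — for the grayscale
  image (FD in [2, 3]).
* **Lacunarity.** Λ = mean over scales of (σ/μ)² of per-box mass; measures
  gappiness (0 for translation-uniform mass).
* **Multifractal spectra** by the direct Chhabra–Jensen method: Q-weighted
  box measures μᵢ(Q, ε) = μᵢ^Q / Σμⱼ^Q over 200 moment orders
  Q = −10.0, −9.9, …, +9.9 give α(Q), f(α)(Q) and τ(Q) as log–log slopes,
  with D_Q = τ(Q)/(Q−1) and the entropy limit at Q = 1. Thirteen scalar
  features per modality (binary and grayscale) summarize each spectrum.
* **Prognostic evaluation.** Mann–Whitney ROC AUC on continuous values
  (AUC < 0.5 ⇒ higher values mark low risk) with bootstrap validation;
  outcome-based optimal cutpoint by exhaustive log-rank scan (uncorrected
  and permutation-corrected p reported side by side); univariate Cox
  regression with Efron ties and bootstrap bias-corrected CIs; Schoenfeld
  proportional-hazards check; forward-entry (P < 0.20) / backward-stay
  (P < 0.05) multivariate Cox selection; Kaplan–Meier summaries; Spearman
  correlation matrices.
* **Synthetic ground truth.** Generators for analytic fractal masks
  (Sierpinski triangle/carpet, random carpets), fractional Brownian
  surfaces (FD = 3 − H), blob-cluster stain mimics, and survival cohorts
  with planted feature effects (n = 73 at a 25% event rate by default).

## A worked example

```r
library(histofract)

# a synthetic stained section: blob clusters at 35% coverage
img <- gen_clusters(image_spec("blob_clusters", 256, density = 0.35, seed = 1))
extract_features(img$gray)[c(
  "mean_intensity", "total_area_px", "bin_fd", "bin_fd_outline", "bin_lac", "gray_fd"
)]
#>   mean_intensity total_area_px bin_fd bin_fd_outline bin_lac gray_fd
#> 1          212.9         21046  1.693          1.635   1.032    2.44
```

The mask covers 21,046 of 65,536 pixels; its box-counting dimension 1.69
sits between a line (1) and a filled plane (2), the contour dimension is
slightly lower, and the grayscale surface dimension 2.44 reflects the
blob texture.

```r
# a 73-patient synthetic cohort with the default planted effects
cohort <- gen_cohort(cohort_spec(seed = 1))   # 17 events of 73
report <- prognostic_report(cohort, c("mean_intensity", "bin_fd"),
  n_boot = 1000, n_perm = 200, seed = 1
)
tidy(report)[c("feature", "auc", "auc_lo", "auc_hi", "cutpoint", "hr", "hr_p", "direction")]
#>          feature   auc auc_lo auc_hi cutpoint    hr   hr_p direction
#> 1 mean_intensity 0.509  0.341  0.677   232.11 0.538 0.2790 high_risk
#> 2         bin_fd 0.367  0.226  0.523     1.55 0.223 0.0109  low_risk
```

Here the planted binary fractal dimension effect is recovered: AUC = 0.37
(< 0.5, higher FD marks the low-risk group) and the dichotomized hazard
ratio 0.22 is significant (p = 0.011), while this seed's mean-intensity
draw stays near chance. `autoplot(report)` draws the AUC forest plot and
`autoplot(km_summary(...))` the Kaplan–Meier curves.

## Layout

* `R/` — image prep, intensity, monofractal, multifractal, prognostics,
  synthetic generators, pipeline orchestration (`run_extract`,
  `run_prognosis`).
* `inst/cli/histofract.R` — thin command-line wrapper
  (`extract`, `prognosis`, `simulate`, `cohort`).
* `vignettes/histofract-methods.Rmd` — the full methods account:
  estimator definitions, parameter choices, generator design, numerical
  details and known limitations.
* `tests/testthat/` — unit, property and validation suites with
  brute-force oracles.
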