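Package: histofract
Title: Fractal and Staining-Intensity Histomorphometry with Survival-Based
    Prognostic Evaluation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantifies single-stain (immunostain channel) histology images by
    staining intensity (mean pixel intensity, total stained area), monofractal
    features (box-counting and differential box-counting fractal dimensions,
    outline dimension, lacunarity) and multifractal spectra (generalized
    dimensions D_Q, Holder exponents alpha(Q) and singularity spectrum f(alpha)
    by the direct Chhabra-Jensen method), and evaluates the resulting features
    against right-censored time-to-event outcomes with ROC AUC, outcome-based
    cutpoint selection, Cox proportional-hazards regression with bootstrap
    internal validation, Kaplan-Meier summaries and Spearman correlations.
    Includes synthetic generators (analytic fractal masks, multiplicative
    cascades, fractional Brownian surfaces, blob-cluster stain mimics, and
    survival cohorts with planted effects) that provide ground truth for
    end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    png,
    purrr,
    rlang,
    stats,
    survival,
    tibble,
    tidyr,
    tiff,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
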