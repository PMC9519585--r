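Package: connectopy
Title: Connectopic Mapping of Topographic Gradients from Connectivity
    Fingerprints
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Reconstructs two-dimensional functional gradients (connectopic
    maps) within a region of interest from timeseries-correlation
    connectivity fingerprints, benchmarks a suite of linear and non-linear
    dimensionality-reduction algorithms (spectral embedding with five graph
    variants, PCA, ICA, kernel PCA, modified locally linear embedding, local
    tangent space alignment, Isomap, diffusion maps, and t-SNE) against
    ground-truth topographic maps, and provides the accompanying statistical
    framework: one-sample and paired t-tests with Holm-Bonferroni
    correction, repeated-measures ANOVA with Greenhouse-Geisser correction
    and partial/generalized eta-squared, Tukey contrasts, and power
    analyses. Includes a seeded synthetic-data generator that embeds a known
    retinotopy-like topography in the correlation structure of multi-run
    timeseries, so every pipeline stage is testable without imaging data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    car,
    dplyr,
    generics,
    ggplot2,
    igraph,
    jsonlite,
    lhs,
    purrr,
    rlang,
    Rtsne,
    stats,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    kernlab,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
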