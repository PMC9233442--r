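Package: varconn
Title: Interindividual Variability Mapping of Seed-Based Resting-State
    Functional Connectivity
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for studying how much seed-based resting-state
    functional connectivity (RSFC) differs across individuals, and whether
    two groups differ in that interindividual variability.  The package
    covers the full pipeline: simulation of multi-cohort 4D BOLD studies
    with planted group means, group variances, subject subgroups and
    covariate effects; per-subject seed GLM connectivity mapping with
    bandpass filtering, nuisance regression and spatial smoothing;
    voxelwise two-way ANOVA, Brown-Forsythe variance-homogeneity maps and
    variance-ratio maps; Monte Carlo cluster-extent correction with data
    smoothness estimation; Lin's concordance correlation coefficient with
    a spatial-autocorrelation-preserving permutation null and a cross-seed
    specificity analysis; and connectivity-fingerprint hierarchical
    clustering with group dissimilarity comparison and covariate
    correlation mapping.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    RNifti,
    stats,
    utils,
    yaml
Suggests:
    car,
    jsonlite,
    mclust,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
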