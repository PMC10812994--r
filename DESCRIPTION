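Package: neurotx
Title: Imaging-Transcriptomics Association Analysis for Resting-State and
    Structural Brain MRI
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An end-to-end, testable pipeline linking group differences in
    brain imaging to spatial gene expression. Computes amplitude of
    low-frequency fluctuations (ALFF) maps from 4D resting-state time
    series, fits mass-univariate two-group general linear models with
    nuisance covariates on ALFF and gray-matter-volume maps, performs
    cluster-level correction by Gaussian random field theory and by
    Monte-Carlo cluster-extent simulation, refines donor-tagged
    probe-level expression samples into a genes-by-samples matrix
    (reannotation, intensity filtering, probe selection by differential
    stability, sample-to-voxel matching, normalization, stability
    filtering), correlates gene expression profiles with group-difference
    t-maps under a Bonferroni-plus-effect-size dual criterion, intersects
    gene lists across modalities, and runs hypergeometric
    over-representation analysis with false-discovery-rate control.
    Ships a synthetic-data generator with known ground truth so the whole
    chain is verifiable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    RNifti,
    jsonlite,
    yaml,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
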