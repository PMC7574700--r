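Package: osteoquant
Title: Multiscale Bone-Quality Analysis for Diabetic Rodent Studies
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tested, reusable pipeline for multiscale characterization of
    rodent cortical and trabecular bone quality in diabetic versus control
    cohorts. Analyzes raw instrument traces (three-point bending
    load-displacement curves with 0.2 percent offset yield and post-yield
    displacement; cyclic reference-point indentation; Oliver-Pharr
    nanoindentation), vibrational and diffraction spectra (FTIR compositional
    ratios with amide I Gaussian sub-band deconvolution for the non-enzymatic
    cross-link ratio; XRD Scherrer crystallite sizing), fluorescent advanced
    glycation end-product plate assays normalized to collagen, and voxel
    morphometry of cortical and trabecular volumes. A forward-modelling
    synthetic-cohort generator with known latent truth feeds every stage, and
    a statistics layer reproduces the two-group comparison workflow
    (2-SD outlier screen, normality/variance-guided test selection, Pearson
    correlation, forward stepwise regression).
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    stats,
    utils,
    jsonlite,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
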