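Package: glycge
Title: Processing and Annotation of xCGE-LIF N-Glycan Electropherograms
Version: 0.1.0
Authors@R:
    person("Package", "Maintainer", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for multiplexed capillary gel electrophoresis with
    laser-induced fluorescence (xCGE-LIF) N-glycomics. Reads ABIF (.fsa/.ab1)
    trace files, calibrates the migration axis against a co-injected
    oligonucleotide size standard, excises and preprocesses the glycomic
    region (Gaussian denoising, ARPLS baseline correction), detects and
    quantifies glycan peaks (height/prominence gating, Gaussian-fit
    boundaries, Simpson integration), transfers structural annotations from a
    reference peak list by dynamic time warping, and summarises technical
    replicate reproducibility (pairwise Pearson correlation, cross-correlation
    lag, per-peak coefficients of variation). Includes a ground-truthed
    synthetic electropherogram simulator for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Matrix,
    jsonlite,
    Rcpp,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
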