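Package: rubusmet
Title: Untargeted LC-Q/TOF Metabolomics Workflow for Raspberry Polyphenol Profiling
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Reusable implementation of an untargeted LC-Q/TOF metabolomics
    data-processing pipeline for (poly)phenolic profiling of Rubus fruit
    extracts: molecular-formula mass and adduct arithmetic with isotope-pattern
    modelling and charge inference; a built-in 68-compound polyphenol knowledge
    base with neutral-loss and diagnostic-ion rules; replicate feature
    alignment under ppm / retention-time / isotope-ratio / MS2-purity criteria;
    nonparametric feature selection (CV-versus-QC filter, Kruskal-Wallis
    screen, Dwass-Steel-Critchlow-Fligner post hoc); rule-based MS2 annotation
    with MSI confidence levels I-IV; genotype chemometrics (autoscaled PCA with
    pooled-QC diagnostics, Pearson correlation against pomological traits); and
    a ground-truth-known synthetic cohort generator for validating every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports: stats, utils
Suggests: testthat (>= 3.0.0), jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
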