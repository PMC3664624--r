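Package: modlink
Title: MOD-Score Linkage Analysis for Multiplex Disease Pedigrees
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Parametric multipoint linkage analysis of disease pedigrees with
    MOD scores, i.e. LOD scores maximized over trait-model parameters
    (disease-allele frequency and penetrances, optionally split by parental
    origin to model genomic imprinting). Implements a Lander-Green
    inheritance-vector hidden Markov model with founder-symmetry reduction, an
    exhaustive small-pedigree likelihood oracle, pedigree and genotype quality
    control (relationship checks, Mendelian genotype elimination,
    unlikely-genotype detection, marker filters, founder allele-frequency
    estimation), Excoffier-Slatkin EM haplotype-frequency r-squared pruning,
    gene-dropping Monte-Carlo empirical significance for MOD scores, a
    transmission disequilibrium test for family-based association in linked
    regions, monotone genetic-map interpolation, and a synthetic study
    generator emulating a multiplex congenital-heart-defect pedigree design.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    Rcpp,
    S4Vectors,
    SummarizedExperiment,
    jsonlite
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    knitr,
    rmarkdown
Config/testthat/edition: 3
RoxygenNote: 7.3.3
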