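Package: germdiv
Title: Germplasm Diversity Analysis with DUS Traits and SSR Markers
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Two-arm characterization of crop germplasm collections.
    The morphological arm handles graded DUS (distinctness, uniformity,
    stability) trait tables: LSD-based grading of quantitative traits,
    descriptive statistics, Shannon-Weaver diversity, trait correlation,
    principal component analysis with an eigenvalue-weighted composite
    score, and stepwise selection of a core trait set.  The molecular arm
    handles codominant SSR genotypes: per-locus diversity statistics
    (Na, Ne, Ho, He, Nei's gene diversity, Shannon's I, PIC),
    Hardy-Weinberg tests, allele-sharing distances with UPGMA clustering
    and Newick export, synonym/homonym detection, hierarchical AMOVA with
    Phi-statistics and gene flow, and Bayesian admixture inference with
    Evanno delta-K model choice.  A seeded simulator generates genotype
    and trait data with planted population structure, clones, homonyms
    and low-rank trait factors for validation and benchmarking.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    yaml,
    stats,
    utils,
    tools
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    ape
Config/testthat/edition: 3
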