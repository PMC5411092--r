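Package: phenoprio
Title: Phenotype-Driven Prioritization of Causative Genomic Variants
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Ranks variants in a patient VCF by the probability that they are
    causative for the patient's phenotypes. Builds a cross-species phenotype
    ontology by rewriting entity-quality (EQ) axioms into the phene pattern and
    inferring the subsumption hierarchy with a restricted reasoner; computes
    Resnik/best-matching-average semantic similarity between patient phenotype
    profiles and gene-phenotype associations; and trains random-forest
    classifiers over a 60-feature variant representation combining
    pathogenicity scores, zygosity, mode of inheritance, high-level phenotype
    flags and phenotype similarity. Includes a synthetic spike-in cohort
    generator and rank-recovery evaluation utilities.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    digest,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    randomForest,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    vcfR,
    yaml
Suggests:
    igraph,
    optparse,
    pROC,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
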