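Package: corediv
Title: Core Collection Selection and Leaf-Trait GWAS from GBS SNP Panels
Version: 0.1.0
Authors@R:
    person("Core", "Diversity Maintainers", email = "maintainers@corediv.org",
           role = c("aut", "cre"))
Description: Tools for genetic-diversity analysis of genotyping-by-sequencing
    (GBS) SNP panels in germplasm collections: hard and population-level SNP
    filtering with sliding-window LD pruning, polymorphism information content
    and heterozygosity statistics, identity-by-state genetic distances,
    neighbor-joining trees with bootstrap support, stepwise maximum-length-
    subtree core-collection selection with sphericity-index stopping and
    synonym detection, core-set diversity-retention evaluation, derivation of
    mature-leaf size traits, and mixed-linear-model (Q+K / P+K) genome-wide
    association. Includes a Balding-Nichols panel and trait simulator so every
    stage is testable without external data, plus end-to-end pipeline drivers
    and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    ape,
    jsonlite,
    stats,
    SummarizedExperiment,
    tools,
    utils,
    VariantAnnotation
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
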