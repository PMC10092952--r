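Package: pedseg
Title: High-Risk Pedigree Analysis of Rare Cancer-Predisposition Variants
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Pedigree-based discovery of rare cancer-predisposition variants in
    founder-population genealogies. Provides a pedigree graph data model with
    relationship computations (ancestors, descendants, cousin classification,
    relationship degree, founding common ancestors, relatedness clustering),
    birth-cohort-stratified baseline cancer rates with expected case counts for
    arbitrary descendant sets, a one-sided exact Poisson excess-of-cancer test
    for high-risk pedigree flagging, rare-variant filtering (population
    frequency, functional class, RegulomeDB range, cousin-pair sharing, assay
    performance classes), genealogy-based segregation clustering of related
    heterozygous carriers, carrier case/control association with
    nearest-neighbour principal-component matching and Bonferroni correction,
    and a genealogy/genotype/phenotype simulator with Mendelian gene dropping
    and planted risk variants for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    tools,
    igraph,
    jsonlite,
    yaml,
    vcfR
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
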