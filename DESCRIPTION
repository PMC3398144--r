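Package: paralogMLPA
Title: Paralog-Aware MLPA Dosage Analysis at Duplicated Loci
Version: 0.99.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Interpretation of multiplex ligation-dependent probe
    amplification (MLPA) dosage data at loci shadowed by a highly similar
    pseudogene, modelled on the PMS2/PMS2CL segmental duplication on 7p22.
    Provides reference-sample qualification against the 2:2
    gene:pseudogene criterion, integer copy-number calling from relative
    probe signals, combinatorial enumeration of diploid hybrid-allele
    genotypes consistent with a dosage profile, paralogous sequence
    variant (PSV) based recombination-breakpoint mapping with
    crossover/gene-conversion classification, in-silico allele-specific
    PCR, array-probe deletion bounding, and a synthetic-cohort generator
    emulating the population of nondeleterious hybrid alleles together
    with the whole-gene-deletion, single-exon-deletion and intron-10
    crossover patient archetypes.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    knitr,
    rmarkdown
Config/testthat/edition: 3
RoxygenNote: 7.3.3
biocViews: CopyNumberVariation, GeneticVariability, Software
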