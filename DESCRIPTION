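Package: airrstat
Title: Multi-Chain Immune Receptor Repertoire Statistics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Feature construction and association testing for adaptive immune
    receptor repertoire (AIRR) sequencing data across the seven receptor
    chains (TRA, TRB, TRD, TRG, IGH, IGK, IGL). Builds clone, meta-clone,
    k-mer and gene-segment feature matrices from AIRR rearrangement tables;
    computes repertoire diversity, chain/segment usage, isotype and somatic
    hypermutation measures; tests features for phenotype association with a
    two-part hurdle model adjusted for the clone detection rate (CDR), plus
    baseline and longitudinal mixed-effect regressions; characterizes CDR3
    sets through similarity networks, permutation tests and biochemical
    enrichment scores; and trains a leave-one-out cross-validated random
    forest repertoire classifier. Includes a seeded synthetic multi-chain
    cohort generator with planted effects for power and calibration studies.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    MASS,
    Matrix,
    igraph,
    lme4,
    lmerTest,
    ranger,
    pROC,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
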