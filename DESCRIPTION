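Package: protarget
Title: Proteogenomic Discovery of Overexpressed Protein Targets in Paired Tumor Cohorts
Version: 0.1.0
Authors@R:
    person("protarget", "developers", email = "protarget@example.org", role = c("aut", "cre"))
Description: Detects differentially expressed and outlier-overexpressed
    proteins in paired tumor/normal proteomic cohorts, contrasts
    protein-level events with somatic-mutation and mRNA overexpression
    rates, intersects hits with druggable-gene lists, and tests
    expression-driven drug dependency in cell-line viability screens.
    Includes a seeded synthetic-cohort generator with planted ground
    truth, a moderated paired differential-expression engine, an
    outlier-overexpression detector based on weighted k-nearest-neighbor
    background inference with a within-sample permutation null, and a
    command-line pipeline orchestrator.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    optparse
Suggests:
    testthat (>= 3.0.0),
    limma,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
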