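Package: clonocall
Title: Automated Clonality Calling for NGS-Based B- and T-Cell Receptor
    Rearrangement Assays
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Rule-based classification of B- and T-cell clonality from
    amplicon next-generation sequencing clonotype frequency tables
    (IGH FR1/FR2/FR3, IGK, TRG, TRB). Implements the Roswell Park
    decision-tree model together with the Invivoscribe, MSK/Arcila and
    Nollet-Schumaker rule sets, near-duplicate clonotype merging,
    run- and control-level quality gating, case-level aggregation,
    diagnostic-accuracy evaluation against gold-standard labels, and a
    seedable Dirichlet-multinomial clonotype simulator for end-to-end
    testing without clinical data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
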