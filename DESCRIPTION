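Package: AvatarScreen
Title: Patient Simulation Avatars and In Silico Drug Combination Screening
    on Signed Signaling Networks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Builds per-patient "simulation avatars" from genomic aberration
    calls (copy-number gains and losses, whole-chromosome events,
    translocation-driven amplifications, classified point mutations), maps
    them onto a curated signed signaling network of the malignant plasma
    cell, simulates normalized-Hill ordinary differential equation dynamics
    to a homeostatic steady state, and screens a drug library singly and in
    exhaustive pairwise combination. Regimens are ranked by percent
    reduction of a weighted tumor relative growth index; combinations are
    scored for synergy by Bliss independence and a highest-single-agent
    dominance rule, with inhibitory-concentration (ICxx) dose selection by
    bisection. Ships curated network, annotation, aberration and drug
    library fixtures for four patient case studies, and a synthetic
    scenario generator with planted driver lesions for benchmarking.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    tools,
    deSolve,
    jsonlite,
    igraph,
    GenomicRanges,
    IRanges,
    S4Vectors,
    yaml
Suggests:
    testthat (>= 3.0.0),
    optparse,
    knitr,
    rmarkdown
VignetteBuilder: knitr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
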