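Package: haplogeo
Title: Chloroplast Haplotype Phylogeography
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for intraspecific chloroplast DNA (cpDNA) phylogeography:
    haplotype calling from aligned non-coding regions with indels coded as
    single mutational events, gene and nucleotide diversity, the Pons & Petit
    decomposition with the GST/NST permutation test, AMOVA phi-statistics and
    a spatial (SAMOVA-style) group search, Mantel isolation-by-distance,
    neighbor-joining trees with bootstrap and midpoint rooting, statistical
    parsimony haplotype networks, mismatch-distribution analysis under the
    sudden-expansion model with parametric-bootstrap goodness of fit, and
    strict-clock lineage dating. Ships a worked dataset of 47 alpine
    populations of the aquatic herb Hippuris vulgaris together with coalescent
    simulators so every stage can be exercised on synthetic data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    ape,
    phangorn,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    vegan,
    geosphere
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
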