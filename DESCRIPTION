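Package: phylodiscord
Title: Decomposing Gene-Tree Discordance into Incomplete Lineage Sorting,
    Estimation Error, and Introgression
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com",
    role = c("aut", "cre"))
Description: Simulates multilocus sequence data under the multispecies
    coalescent with pulse introgression, and quantifies the sources of
    gene-tree heterogeneity across a reference species tree: per-branch
    gene concordance factors and quartet frequencies, coalescent-unit
    branch lengths and the theta (mutation/coalescent) ratio, tree
    estimation error by a simulate-and-reestimate bootstrap analogue,
    ABBA-BABA D statistics with block-jackknife Z scores, a reticulation
    index for discordant-topology asymmetry, a four-state (V0-V3)
    windowed genealogy scan with optional HMM smoothing, and an LMG
    relative-importance regression that partitions total discordance
    among the three factors.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    ape,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    phangorn,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
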