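Package: crosscomm
Title: Cross-Community Congruence Analysis for Paired Microbiomes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for asking whether two sample-matched microbial
    communities (for example the endophytes of a parasitic plant and the
    rhizosphere of its host) change in concert. Implements weighted UniFrac
    beta diversity, principal coordinates analysis, symmetric Procrustes
    superimposition with the t0 congruence statistic and PROTEST permutation
    significance, and a leave-one-out delta-t statistic that attributes
    congruence to individual taxonomic groups. Also provides alpha
    diversity (Chao1, Simpson, Pielou), rarefaction, co-occurrence network
    construction with bootstrap pseudo-p edge filtering, greedy modularity,
    Zi/Pi node roles and global network attributes, a microbe-metabolite
    Spearman + Z-test association screen, and a differential-metabolite
    threshold filter. A synthetic paired-community generator with known
    ground truth makes the whole pipeline testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Depends:
    R (>= 4.1)
Imports:
    ape,
    dplyr,
    generics,
    ggplot2,
    igraph,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    utils,
    vegan
Suggests:
    phangorn,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Roxygen: list(markdown = TRUE)
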