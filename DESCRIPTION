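Package: mhcsupertypes
Title: Host-Parasite Coevolution Dynamics and Population Genetics of MHC Supertypes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to probe whether balancing selection on MHC supertypes can
    explain trans-species polymorphism. Provides an individual-based model of
    host-parasite coevolution in a two-dimensional paratope space with scenario
    presets (mutation-rate and population-size variants, neutral parasites,
    suppressed parasite seeding, multiple parasite species), single-linkage
    supertype delimitation and lineage tracking through simulated trajectories,
    a population-genetic pipeline around Jost's D (observed versus
    label-randomized expectations, per-supertype jackknife, randomized-deletion
    controls, supertype-homozygosity summaries), a neighbour-joining /
    Jukes-Cantor phylogenetic stage with bootstrap support and a
    supertype-monophyly report, and seed-deterministic generators of synthetic
    alignments and multi-population genotype tables with known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ape,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    phangorn,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    igraph,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
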