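Package: phylosymr
Title: Phylosymbiosis Detection from Amplicon Feature Tables
Version: 1.0.0
Authors@R: person("Dana", "Kirby", email = "dana.kirby@example.org",
    role = c("aut", "cre"))
Description: A tested pipeline for comparing marker-gene microbiome profiles
    across mammalian hosts and detecting phylosymbiosis: feature-table
    processing (depth filtering, host collapsing, rarefaction, taxonomic
    collapsing), Bray-Curtis and UniFrac beta diversity, UPGMA dendrograms
    with rarefaction-bootstrap support, a Robinson-Foulds congruence test
    against uniform random topologies, Procrustes/PROTEST ordination
    concordance, reference-database curation with a naive-Bayes k-mer
    taxonomy classifier, and a synthetic-data generator with a tunable
    phylosymbiosis signal so the whole workflow is testable without any
    sequence downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ape,
    phangorn,
    jsonlite,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    vegan,
    withr
Config/testthat/edition: 3
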