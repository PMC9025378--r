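Package: phyllocore
Title: Community Ecology and Network Analysis of Phyllosphere Mycobiomes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Downstream community-ecology and complex-network analysis for
    fungal metabarcoding OTU tables: Hellinger transformation, Bray-Curtis
    and Jensen-Shannon dissimilarities, principal coordinates ordination,
    permutation tests of multivariate dispersion (PERMDISP), integer
    similarity-threshold network sweeps with critical-network selection and
    modularity partitioning, presence/absence co-occurrence networks,
    hierarchical strict-occupancy core-mycobiome extraction with a Spearman
    antagonism screen, trophic-mode/guild assignment from a local lookup
    table, and Venn-style set algebra. Ships a synthetic-community generator
    with planted, recoverable structure (cores, antagonist pairs, block
    similarity, stage-dependent dominance shifts) so the whole pipeline is
    testable without sequencing data.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    igraph,
    jsonlite,
    stats,
    tools,
    utils,
    vegan
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
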