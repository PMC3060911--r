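Package: lekscreen
Title: Screening Marker-Gene Surveys for Phylogenetically Novel Deep-Branching Lineages
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for discovering phylogenetically novel, deeply branching
    lineages in marker-gene surveys of environmental (metagenomic) sequence
    data. The package clusters protein superfamilies (e.g. the RecA and RpoB
    superfamilies) into subfamilies on a BLAST-style pairwise similarity graph
    using an agglomerative Lek clustering score, places small-subunit rRNA
    reads into a labelled reference alignment and tests whether they branch
    near the node separating Bacteria, Archaea and Eukaryota, calls
    environmental-only monophyletic subfamilies as candidate novel lineages,
    and attributes metagenome assemblies to a domain of life by majority vote
    over the phylogenetic assignments of neighbouring genes. A seeded
    synthetic-data generator produces three-domain phylogenies with planted
    divergent lineages, ancient paralogous subfamilies, and fragmentary
    environmental reads, so the whole screen can be exercised and validated
    end to end without external databases.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ape,
    Biostrings,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    phangorn,
    mclust,
    jsonlite,
    withr
Config/testthat/edition: 3
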