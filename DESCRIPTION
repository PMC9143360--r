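Package: aavgenotyper
Title: Recombination-Aware Genotype Classification of Adeno-Associated
    Viruses from Rep-Gene Distances
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for classifying adeno-associated virus (AAV) genomes into
    genotypes from nucleotide p-distances in the rep gene, and for locating the
    recombination-quiet genome region that makes such a classification robust.
    Implements pairwise p-distances with pairwise deletion, pairwise distance
    correspondence plots (PDCP) and pairwise distance deviation matrices (PDDM)
    for sliding-window recombination screening, Simplot-style similarity scans,
    single-linkage threshold clustering with separation diagnostics,
    nucleotide/amino-acid distance-cloud partitioning, neighbor-joining trees,
    and a seeded simulator of genotype-structured recombinant virus populations
    for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    ape,
    Biostrings,
    jsonlite,
    stats,
    utils,
    graphics,
    grDevices
Suggests:
    testthat (>= 3.0.0),
    igraph,
    mclust,
    phangorn
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
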