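Package: stalkscan
Title: Trait-Association Pan-Genome Analysis for Microbial Phenotype Gene Screens
Version: 0.1.0
Authors@R:
    person("Pan-Genome", "Maintainers", email = "maintainers@example.org", role = c("aut", "cre"))
Description: A tested, reusable pipeline for trait-based comparative genomics of
    bacterial isolate collections. Builds pan-genomes by greedy pre-clustering and
    Markov clustering (MCL) of an all-vs-all protein similarity graph at a sweep of
    percent-identity thresholds, screens for gene families uniquely shared by all
    trait-positive genomes and absent from all trait-negative genomes, detects
    contiguous syntenic cassettes of candidate genes, computes average amino-acid
    identity (AAI) from reciprocal best hits with Bray-Curtis/UPGMA clustering,
    fits Heaps-law pan-genome openness, scans proteins for short literal motifs
    (c-di-GMP binding and glycosyltransferase motifs), and tests COG category
    enrichment. Includes a synthetic-community generator with a machine-readable
    truth ledger so that every stage of the screen can be scored against planted
    ground truth.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    Biostrings,
    rtracklayer,
    GenomicRanges,
    igraph,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    ape
Config/testthat/edition: 3
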