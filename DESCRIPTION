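Package: tetrasig
Title: Polyploid-Origin Signatures from K-mer Profiles, Smudge Analysis and
    Variant Filtering
Version: 0.1.0
Authors@R:
    person("Tetrasig", "Developers", email = "tetrasig@example.org",
           role = c("aut", "cre"))
Description: Tools to diagnose the origin of a polyploid genome from
    haplotype-resolved assemblies and short reads. Implements canonical
    K-mer counting per chromosome, selection of chromosome-enriched K-mers,
    hierarchical clustering of chromosomes by enriched-K-mer abundance
    profiles with an auto- versus allo-polyploid verdict, heterozygous
    K-mer-pair ("smudge") analysis of read sets with ploidy-pattern
    assignment, a six-rule SNP hard-filter cascade with per-rule accounting,
    and a tandem gene-cluster caller. Includes simulators for polyploid
    genomes, short reads and variant call sets so every stage is testable
    without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    data.table,
    jsonlite,
    ape,
    vegan,
    optparse,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    Biostrings,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
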