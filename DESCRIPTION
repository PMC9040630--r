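Package: ogun
Title: Operational Genomic Units from Shotgun Metagenome Alignments
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Converts per-read sequence alignments against reference genomes
    (SAM, BLAST tabular, or plain query-to-subject maps, optionally compressed)
    into taxonomy-free feature tables of operational genomic units (OGUs),
    apportioning multi-mapped reads 1/k across their k hit genomes. Provides
    table operations (half-to-even rounding, per-sample relative-abundance and
    prevalence filtering, genome-size normalization, rarefaction that accounts
    for unaligned reads, merging, TSV I/O), taxonomy handling in three dialects
    (Greengenes-style lineages, NCBI taxdump, child-to-parent maps), rank
    collapsing of tables, conversion of taxonomies to constant-branch-length
    trees, monophyly-checked collapsing of genome phylogenies to taxonomic
    ranks, and phylogeny-aware community ecology statistics: Bray-Curtis,
    Jaccard, unweighted and weighted UniFrac, principal coordinates analysis,
    PERMANOVA, and a within- versus between-environment distance-ratio
    statistic. A deterministic synthetic-data generator produces alignments,
    taxonomies and phylogenies at desk scale for testing and method study.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    ape,
    dplyr,
    generics,
    ggplot2,
    purrr,
    readr,
    rlang,
    stats,
    stringr,
    tibble,
    tidyr,
    utils
Suggests:
    picante,
    testthat (>= 3.0.0),
    vegan,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
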