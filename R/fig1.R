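#' The conceptual three-community fixture
#'
#' A small frozen dataset for studying how feature resolution changes
#' beta-diversity conclusions: three communities (A, B, C) of 12 read hits
#' each over 10 reference genomes (OGUs O1–O10), classified into five
#' species, three genera and one family, with a genome phylogeny whose
#' placements deliberately disagree with the taxonomy in places (O4 and O5
#' are phylogenetic sisters yet sit in different genera; O1 and O2 are
#' closer to each other than either is to O3, which taxonomy cannot
#' express).
#'
#' The exact counts are a constraint-satisfying construction, frozen here:
#' per-sample totals are 12; species S1 has identical summed counts in all
#' three samples (6), carried by a different member OGU in each (O1 in A,
#' O2 in B, O3 in C); within species S3, O5 and O7 carry equal counts in
#' samples B and C; samples A and B share nonzero counts at O6 and O9.
#' On this table, genus-level Bray-Curtis places B and C spuriously close,
#' while OGU-level analysis separates them, and weighted UniFrac on the
#' phylogeny makes A and B the closest pair through shared OGUs and shared
#' long branches.
#'
#' @return A list with `table` (an [ogu_table], 10 OGUs x 3 samples),
#'   `taxonomy` (see [ogu_taxonomy()]) and `tree` (`ape::phylo` over the
#'   10 OGUs).
#' @examples
#' fx <- conceptual_fixture()
#' sample_sums(fx$table)
#' @export
conceptual_fixture <- function() {
  counts <- matrix(
    c(6, 0, 0,
      0, 6, 0,
      0, 0, 6,
      2, 0, 0,
      0, 2, 2,
      2, 1, 0,
      0, 2, 2,
      0, 0, 1,
      2, 1, 0,
      0, 0, 1),
    nrow = 10, byrow = TRUE,
    dimnames = list(paste0("O", 1:10), c("A", "B", "C")))
  table <- ogu_table_from_matrix(counts, value_kind = "rounded_int")
  species <- c(O1 = "S1", O2 = "S1", O3 = "S1", O4 = "S2", O5 = "S3",
               O6 = "S3", O7 = "S3", O8 = "S4", O9 = "S4", O10 = "S5")
  genus <- c(S1 = "G1", S2 = "G1", S3 = "G2", S4 = "G3", S5 = "G3")
  taxonomy <- ogu_taxonomy(bind_rows(
    tibble(node_id = names(species), parent_id = unname(species),
           rank = "none", name = names(species)),
    tibble(node_id = names(genus), parent_id = unname(genus),
           rank = "species", name = names(genus)),
    tibble(node_id = unique(unname(genus)), parent_id = "F1",
           rank = "genus", name = unique(unname(genus))),
    tibble(node_id = "F1", parent_id = NA_character_, rank = "family",
           name = "F1")))
  tree <- read_newick(paste0(
    "((((O1:0.1,O2:0.1):0.9,O3:1.0):0.5,(O4:0.2,O5:0.2):0.8):0.5,",
    "((O6:0.5,O7:0.5):0.5,((O8:0.3,O9:0.3):0.7,O10:1.0):0.3):0.5);"))
  list(table = table, taxonomy = taxonomy, tree = tree)
}

#' Write the conceptual fixture to disk
#'
#' @param dir Output directory (created if needed).
#' @return Invisibly, the paths written: the dense feature table
#'   (`table.tsv`), lineage-style taxonomy (`lineages.tsv`) and Newick
#'   tree (`tree.nwk`).
#' @export
write_conceptual_fixture <- function(dir) {
  fx <- conceptual_fixture()
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(table = file.path(dir, "table.tsv"),
             taxonomy = file.path(dir, "lineages.tsv"),
             tree = file.path(dir, "tree.nwk"))
  write_feature_table(fx$table, paths[["table"]])
  lineages <- vapply(paste0("O", 1:10), function(g) {
    sp <- ancestor_at_rank(fx$taxonomy, g, "species")
    ge <- ancestor_at_rank(fx$taxonomy, g, "genus")
    sprintf("%s\tk__K1; p__P1; c__C1; o__Or1; f__F1; g__%s; s__%s",
            g, ge, sp)
  }, "")
  writeLines(lineages, paths[["taxonomy"]])
  write_newick(fx$tree, paths[["tree"]])
  invisible(paths)
}
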