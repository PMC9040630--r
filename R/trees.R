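#' Read and write rooted trees in Newick format
#'
#' Thin, validated wrappers around `ape`'s Newick parser. Trees must have
#' unique tip labels; missing branch lengths are read as 0. A trifurcation
#' at the root is accepted and kept as a root with three children.
#'
#' @param x Path to a Newick file, or a Newick string (detected by the
#'   presence of `(` / `;`).
#' @param tree An `ape::phylo` object.
#' @param path Output file path; when `NULL`, the Newick string is
#'   returned.
#' @return `read_newick()` returns an `ape::phylo`; `write_newick()` writes
#'   (or returns) the Newick text.
#' @export
read_newick <- function(x) {
  tree <- if (length(x) == 1 && grepl("[(;]", x)) {
    tryCatch(ape::read.tree(text = x),
             error = function(e) NULL, warning = function(w) NULL)
  } else {
    if (!file.exists(x)) abort(paste0("cannot read tree file: ", x))
    tryCatch(ape::read.tree(x),
             error = function(e) NULL, warning = function(w) NULL)
  }
  if (is.null(tree) || !inherits(tree, "phylo")) {
    abort("malformed Newick input")
  }
  validate_phylogeny(tree)
}

#' @rdname read_newick
#' @export
write_newick <- function(tree, path = NULL) {
  validate_phylogeny(tree)
  txt <- ape::write.tree(tree)
  if (is.null(path)) return(txt)
  writeLines(txt, path)
  invisible(txt)
}

validate_phylogeny <- function(tree) {
  if (!inherits(tree, "phylo")) abort("not a phylo object")
  if (anyDuplicated(tree$tip.label)) {
    abort(paste0("duplicate tip label(s): ",
                 paste(unique(tree$tip.label[duplicated(tree$tip.label)]),
                       collapse = ", ")))
  }
  if (is.null(tree$edge.length)) {
    tree$edge.length <- rep(0, nrow(tree$edge))
  }
  if (any(tree$edge.length < 0)) abort("negative branch length")
  tree
}

# children lists indexed by node number
node_children <- function(tree) {
  nn <- ape::Ntip(tree) + tree$Nnode
  kids <- vector("list", nn)
  for (i in seq_len(nrow(tree$edge))) {
    p <- tree$edge[i, 1]
    kids[[p]] <- c(kids[[p]], tree$edge[i, 2])
  }
  kids
}

# tip labels descending from each node (list indexed by node number)
node_tip_sets <- function(tree) {
  ntip <- ape::Ntip(tree)
  po <- ape::reorder.phylo(tree, "postorder")
  sets <- vector("list", ntip + tree$Nnode)
  for (i in seq_len(ntip)) sets[[i]] <- tree$tip.label[i]
  for (i in seq_len(nrow(po$edge))) {
    p <- po$edge[i, 1]; ch <- po$edge[i, 2]
    sets[[p]] <- c(sets[[p]], sets[[ch]])
  }
  sets
}

#' Convert a taxonomy to a constant-branch-length tree
#'
#' Builds a rooted tree over the taxonomy restricted to the seven standard
#' ranks, in which every branch between adjacent ranks has length 1.0.
#' Lineages missing intermediate ranks are bridged, and lineages ending
#' above species level are padded down, with deterministic placeholder
#' nodes named `<child>__incertae_<rank>`; as a result every tip sits at
#' species depth and all tips have exactly the same tip-to-root path
#' length. The tree can replace a genome phylogeny in UniFrac analyses of
#' rank-collapsed tables.
#'
#' @param taxonomy A taxonomy tibble (see [ogu_taxonomy()]); nodes of rank
#'   `"none"` (e.g. genomes) are ignored.
#' @return An `ape::phylo` with all branch lengths 1.
#' @export
taxonomy_to_tree <- function(taxonomy) {
  tx <- filter(taxonomy, .data$rank %in% OGU_RANKS)
  if (nrow(tx) == 0) abort("taxonomy has no nodes at a standard rank")
  idx <- setNames(match(tx$rank, OGU_RANKS), tx$node_id)
  # nearest ranked ancestor (skip rank-none intermediates such as subkingdoms)
  parent_all <- setNames(taxonomy$parent_id, taxonomy$node_id)
  rank_all <- setNames(taxonomy$rank, taxonomy$node_id)
  ranked_parent <- vapply(tx$node_id, function(id) {
    node <- parent_all[[id]]
    while (!is.na(node) && !(rank_all[[node]] %in% OGU_RANKS)) {
      node <- parent_all[[node]]
    }
    if (is.na(node)) NA_character_ else node
  }, "")
  # bridge rank gaps with placeholders, then pad every leaf to species
  edges <- list()  # child -> parent, unit length each
  add_chain <- function(child, child_idx, parent, parent_idx) {
    # insert placeholders for ranks strictly between parent_idx and child_idx
    node <- child
    gap <- child_idx - parent_idx - 1L
    for (j in rev(seq_len(gap) + parent_idx)) {
      ph <- paste0(child, "__incertae_", OGU_RANKS[j])
      edges[[length(edges) + 1]] <<- c(node, ph)
      node <- ph
    }
    edges[[length(edges) + 1]] <<- c(node, parent)
  }
  for (i in seq_len(nrow(tx))) {
    id <- tx$node_id[i]
    p <- ranked_parent[[id]]
    if (is.na(p)) {
      if (idx[[id]] > 1) {
        add_chain(id, idx[[id]], "__root__", 0L)
      } else {
        edges[[length(edges) + 1]] <- c(id, "__root__")
      }
    } else {
      add_chain(id, idx[[id]], p, idx[[p]])
    }
  }
  emat <- do.call(rbind, edges)
  # pad non-species leaves down to species depth
  leaves <- setdiff(emat[, 1], emat[, 2])
  leaf_rank <- idx[leaves]
  for (leaf in leaves[!is.na(leaf_rank) & leaf_rank < length(OGU_RANKS)]) {
    node <- leaf
    for (j in seq(idx[[leaf]] + 1, length(OGU_RANKS))) {
      ph <- paste0(leaf, "__incertae_", OGU_RANKS[j])
      emat <- rbind(emat, c(ph, node))
      node <- ph
    }
  }
  tree_from_edges(emat, root = "__root__")
}

# build an ape::phylo from a child->parent matrix of unit-length edges
tree_from_edges <- function(emat, root) {
  kids <- split(emat[, 1], emat[, 2])
  build <- function(node) {
    ch <- kids[[node]]
    if (is.null(ch)) return(quote_label(node))
    paste0("(", paste(vapply(sort(ch), build, ""), collapse = ","), ")",
           quote_label(node))
  }
  # iterative depth guard not needed at desk scale; recursion is fine
  txt <- paste0(sub(paste0(quote_label(root), "$"), "", build(root)),
                ";")
  tree <- ape::read.tree(text = txt)
  tree$edge.length <- rep(1, nrow(tree$edge))
  tree
}

quote_label <- function(x) {
  ifelse(grepl("[ ():,;\\[\\]']", x), paste0("'", gsub("'", "''", x), "'"), x)
}

#' Collapse a genome phylogeny to taxonomic units at a rank
#'
#' Replaces the clade of every taxonomic unit at `rank` by a single tip
#' named for the unit. Tips not assigned to any unit at that rank are
#' pruned first; each unit must then be monophyletic (its members' MRCA
#' contains no member of another unit), otherwise an error names the unit
#' and the intruding tips. The collapsed tip keeps the clade's stem branch
#' length (the branch from the clade root to its parent); a unit whose
#' clade is the whole tree gets stem length 0.
#'
#' @param tree `ape::phylo` whose tips are genome ids.
#' @param taxonomy A taxonomy tibble mapping genomes (directly or through
#'   intermediate nodes) to units at `rank`.
#' @param rank One of the seven standard ranks.
#' @return An `ape::phylo` with one tip per taxonomic unit.
#' @export
collapse_phylogeny <- function(tree, taxonomy, rank) {
  tree <- validate_phylogeny(tree)
  rank <- match.arg(rank, OGU_RANKS)
  unit <- ancestor_at_rank(taxonomy, tree$tip.label, rank)
  covered <- tree$tip.label[!is.na(unit)]
  if (length(covered) < 2) {
    abort("fewer than two tips are covered by units at this rank")
  }
  pruned <- ape::keep.tip(tree, covered)
  unit <- setNames(ancestor_at_rank(taxonomy, pruned$tip.label, rank),
                   pruned$tip.label)
  units <- unique(unname(unit))
  tipsets <- node_tip_sets(pruned)
  ntip <- ape::Ntip(pruned)
  root <- ntip + 1L
  keep_tip <- character(length(units))
  stem_len <- numeric(length(units))
  for (i in seq_along(units)) {
    members <- names(unit)[unit == units[i]]
    if (length(members) == 1) {
      node <- match(members, pruned$tip.label)
    } else {
      node <- ape::getMRCA(pruned, members)
    }
    clade_tips <- tipsets[[node]]
    intruders <- setdiff(clade_tips, members)
    if (length(intruders) > 0) {
      abort(paste0("taxonomic unit '", units[i],
                   "' is not monophyletic; intruding tip(s): ",
                   paste(intruders, collapse = ", ")))
    }
    keep_tip[i] <- members[1]
    stem_len[i] <- if (node == root) 0 else {
      pruned$edge.length[which(pruned$edge[, 2] == node)]
    }
  }
  out <- ape::keep.tip(pruned, keep_tip)
  # representative tips carry the merged path length; restore the stem length
  pos <- match(keep_tip, out$tip.label)
  for (i in seq_along(units)) {
    eidx <- which(out$edge[, 2] == pos[i])
    out$edge.length[eidx] <- stem_len[i]
  }
  out$tip.label[pos] <- units
  validate_phylogeny(out)
}
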