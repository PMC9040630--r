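#' Taxonomy maps
#'
#' A taxonomy is a tibble with one row per node and columns `node_id`,
#' `parent_id` (`NA` at a root), `rank` (one of the seven standard ranks —
#' kingdom, phylum, class, order, family, genus, species — or `"none"`) and
#' `name`. Three input dialects produce the same structure:
#' [read_lineages()] (Greengenes-style lineage strings), [read_taxdump()]
#' (NCBI nodes.dmp/names.dmp) and [read_parent_map()] (plain child-to-parent
#' TSV).
#'
#' @param x A data frame with the columns above.
#' @return A validated taxonomy tibble.
#' @export
ogu_taxonomy <- function(x) {
  x <- as_tibble(x)
  req <- c("node_id", "parent_id", "rank", "name")
  if (!all(req %in% names(x))) {
    abort(paste0("taxonomy needs columns ", paste(req, collapse = ", ")))
  }
  x <- distinct(select(x, all_of(req)))
  if (anyDuplicated(x$node_id)) {
    dup <- x$node_id[duplicated(x$node_id)]
    abort(paste0("conflicting taxonomy rows for node(s): ",
                 paste(unique(dup), collapse = ", ")))
  }
  bad_rank <- setdiff(unique(x$rank), c(OGU_RANKS, "none"))
  if (length(bad_rank) > 0) {
    abort(paste0("unknown rank(s): ", paste(bad_rank, collapse = ", ")))
  }
  orphans <- setdiff(x$parent_id[!is.na(x$parent_id)], x$node_id)
  if (length(orphans) > 0) {
    abort(paste0("orphan parent id(s) absent from taxonomy: ",
                 paste(orphans, collapse = ", ")))
  }
  validate_acyclic(x)
  validate_rank_order(x)
  x
}

validate_acyclic <- function(x) {
  parent <- setNames(x$parent_id, x$node_id)
  state <- setNames(integer(nrow(x)), x$node_id)  # 0 new, 1 active, 2 done
  for (start in x$node_id) {
    node <- start
    chain <- character()
    while (!is.na(node) && state[[node]] == 0L) {
      state[[node]] <- 1L
      chain <- c(chain, node)
      node <- parent[[node]]
    }
    if (!is.na(node) && state[[node]] == 1L) {
      abort(paste0("taxonomy contains a parent cycle through node: ", node))
    }
    state[chain] <- 2L
  }
  invisible(x)
}

validate_rank_order <- function(x) {
  idx <- setNames(match(x$rank, OGU_RANKS), x$node_id)  # NA for "none"
  pidx <- idx[match(x$parent_id, x$node_id)]
  bad <- !is.na(idx) & !is.na(pidx) & pidx >= idx
  if (any(bad)) {
    abort(paste0("rank does not increase away from the root at node(s): ",
                 paste(x$node_id[bad], collapse = ", ")))
  }
  invisible(x)
}

lineage_prefixes <- c(k = "kingdom", p = "phylum", c = "class", o = "order",
                      f = "family", g = "genus", s = "species")

#' Read Greengenes-style lineage strings
#'
#' Each row is `genome_id<TAB>k__X; p__Y; ...` with rank prefixes `k__`,
#' `p__`, `c__`, `o__`, `f__`, `g__`, `s__`. One taxonomy node is created
#' per distinct prefixed label; empty labels (`s__`) create no node, and a
#' lineage with a nonempty label below an empty one is rejected as
#' malformed. Each genome attaches (rank `"none"`) to its deepest nonempty
#' label.
#'
#' @param path Lineage TSV path (or a character vector of lines via
#'   `lines`).
#' @param lines Optional character vector of lines instead of a file.
#' @return A taxonomy tibble (see [ogu_taxonomy()]).
#' @export
read_lineages <- function(path = NULL, lines = NULL) {
  lines <- lines %||% readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines)]
  rows <- strsplit(lines, "\t", fixed = TRUE)
  if (any(lengths(rows) != 2)) {
    abort(sprintf("lineage line %d is not 'genome<TAB>lineage'",
                  which(lengths(rows) != 2)[1]))
  }
  nodes <- list()
  genome_rows <- vector("list", length(rows))
  for (i in seq_along(rows)) {
    genome <- rows[[i]][1]
    labels <- stringr::str_trim(strsplit(rows[[i]][2], ";", fixed = TRUE)[[1]])
    labels <- labels[nzchar(labels)]
    prefixes <- sub("__.*$", "", labels)
    if (!all(prefixes %in% names(lineage_prefixes))) {
      abort(paste0("unknown rank prefix in lineage: ",
                   labels[!prefixes %in% names(lineage_prefixes)][1]))
    }
    values <- sub("^.__", "", labels)
    ranks <- unname(lineage_prefixes[prefixes])
    nonempty <- nzchar(values)
    if (any(nonempty & cumsum(!nonempty) > 0)) {
      abort(paste0("lineage for ", genome,
                   " has a nonempty rank below an empty one"))
    }
    labels <- labels[nonempty]
    ranks <- ranks[nonempty]
    if (length(labels) == 0) {
      abort(paste0("lineage for ", genome, " is entirely empty"))
    }
    parents <- c(NA_character_, head(labels, -1))
    nodes[[i]] <- tibble(node_id = labels, parent_id = parents, rank = ranks,
                         name = sub("^.__", "", labels))
    genome_rows[[i]] <- tibble(node_id = genome,
                               parent_id = tail(labels, 1),
                               rank = "none", name = genome)
  }
  ogu_taxonomy(bind_rows(bind_rows(nodes), bind_rows(genome_rows)))
}

split_dmp <- function(lines) {
  lines <- sub("\t\\|$", "", lines[nzchar(lines)])
  strsplit(lines, "\t|\t", fixed = TRUE)
}

#' Read an NCBI-style taxdump
#'
#' Parses the pipe-delimited `nodes.dmp` (tax_id, parent tax_id, rank) and
#' `names.dmp` (tax_id, name, unique name, name class; only
#' `scientific name` rows are used). The root is the node that is its own
#' parent. Ranks outside the seven standard ones map to `"none"`.
#'
#' @param nodes_path Path to `nodes.dmp`.
#' @param names_path Path to `names.dmp` (optional; node ids are used as
#'   names when absent).
#' @return A taxonomy tibble (see [ogu_taxonomy()]).
#' @export
read_taxdump <- function(nodes_path, names_path = NULL) {
  nodes <- split_dmp(readLines(nodes_path, warn = FALSE))
  if (any(lengths(nodes) < 3)) {
    abort("nodes.dmp rows need at least tax_id | parent | rank")
  }
  id <- vapply(nodes, `[[`, "", 1L)
  parent <- vapply(nodes, `[[`, "", 2L)
  rank <- vapply(nodes, `[[`, "", 3L)
  rank[!rank %in% OGU_RANKS] <- "none"
  parent[parent == id] <- NA_character_  # self-parent marks the root
  name <- id
  if (!is.null(names_path)) {
    nm <- split_dmp(readLines(names_path, warn = FALSE))
    if (any(lengths(nm) < 4)) {
      abort("names.dmp rows need tax_id | name | unique | class")
    }
    cls <- vapply(nm, `[[`, "", 4L)
    sci <- nm[cls == "scientific name"]
    nm_map <- setNames(vapply(sci, `[[`, "", 2L), vapply(sci, `[[`, "", 1L))
    hit <- id %in% names(nm_map)
    name[hit] <- nm_map[id[hit]]
  }
  ogu_taxonomy(tibble(node_id = id, parent_id = parent, rank = rank,
                      name = name))
}

#' Read plain child-to-parent maps
#'
#' Each file is a two-column TSV `child<TAB>parent`. Several files may be
#' supplied (e.g. one per rank, genome-to-species then species-to-genus);
#' `ranks` assigns the children of each file a rank (default `"none"`).
#' Nodes appearing only as parents in the last map become roots.
#'
#' @param paths Character vector of TSV paths.
#' @param ranks Optional character vector, recycled along `paths`: the rank
#'   of each file's child column.
#' @return A taxonomy tibble (see [ogu_taxonomy()]).
#' @export
read_parent_map <- function(paths, ranks = "none") {
  ranks <- rep_len(ranks, length(paths))
  rows <- purrr::map2(paths, ranks, function(p, r) {
    fields <- strsplit(readLines(p, warn = FALSE), "\t", fixed = TRUE)
    fields <- fields[lengths(fields) > 0]
    if (any(lengths(fields) != 2)) {
      abort(paste0("map file ", p, " is not two-column child<TAB>parent"))
    }
    tibble(node_id = vapply(fields, `[[`, "", 1L),
           parent_id = vapply(fields, `[[`, "", 2L),
           rank = r)
  })
  df <- bind_rows(rows)
  roots <- setdiff(df$parent_id, df$node_id)
  # a root never occurs as a child, so its rank is not in any file; infer
  # it as one rank above its children when they agree on a standard rank
  root_rank <- vapply(roots, function(r) {
    kid_ranks <- unique(df$rank[df$parent_id == r])
    idx <- match(kid_ranks, OGU_RANKS)
    if (length(idx) == 1 && !is.na(idx) && idx > 1) OGU_RANKS[idx - 1]
    else "none"
  }, "")
  df <- bind_rows(df, tibble(node_id = roots, parent_id = NA_character_,
                             rank = unname(root_rank)))
  df$name <- df$node_id
  ogu_taxonomy(df)
}

# ancestor of each id at the given rank, NA where the chain has none
ancestor_at_rank <- function(taxonomy, ids, rank) {
  parent <- setNames(taxonomy$parent_id, taxonomy$node_id)
  node_rank <- setNames(taxonomy$rank, taxonomy$node_id)
  vapply(ids, function(id) {
    node <- if (id %in% names(parent)) id else NA_character_
    while (!is.na(node)) {
      if (node_rank[[node]] == rank) return(node)
      node <- parent[[node]]
    }
    NA_character_
  }, "", USE.NAMES = FALSE)
}

#' Collapse a feature table to a taxonomic rank
#'
#' Adds each feature's counts to its taxonomy ancestor at `rank`. Features
#' lacking an ancestor at that rank — including features absent from the
#' taxonomy altogether, which trigger a warning — are pooled into the
#' reserved feature `"Unassigned"`. Per-sample totals are conserved exactly.
#'
#' @param x An [ogu_table].
#' @param taxonomy A taxonomy tibble (see [ogu_taxonomy()]).
#' @param rank One of the seven standard ranks.
#' @return The collapsed [ogu_table] (same value kind).
#' @export
collapse_table <- function(x, taxonomy, rank) {
  stopifnot(is_ogu_table(x))
  rank <- match.arg(rank, OGU_RANKS)
  feats <- table_features(x)
  unknown <- setdiff(feats, taxonomy$node_id)
  if (length(unknown) > 0) {
    warn(paste0(length(unknown), " feature(s) absent from the taxonomy ",
                "were pooled into 'Unassigned'"))
  }
  anc <- ancestor_at_rank(taxonomy, feats, rank)
  anc[is.na(anc)] <- "Unassigned"
  map <- setNames(anc, feats)
  y <- mutate(as_tibble(x), feature_id = unname(map[.data$feature_id]))
  tab <- ogu_table(y, samples = table_samples(x),
                   features = unique(unname(map)),
                   value_kind = value_kind(x))
  set_depth_ledger(drop_empty_features(tab), depth_ledger(x))
}
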