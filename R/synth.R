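#' Random rooted phylogeny with exponential branch lengths
#'
#' @param n_tips Number of tips (>= 2).
#' @param seed Integer seed; the same seed yields an identical tree.
#' @param tip_labels Optional tip labels (default `t1..tn`).
#' @return A rooted binary `ape::phylo`.
#' @export
random_phylogeny <- function(n_tips, seed, tip_labels = NULL) {
  if (n_tips < 2) abort("a phylogeny needs at least 2 tips")
  tree <- with_local_seed(seed, {
    tr <- ape::rtree(n_tips)
    tr$edge.length <- rexp(nrow(tr$edge))
    tr
  })
  tree$tip.label <- tip_labels %||% paste0("t", seq_len(n_tips))
  tree
}

#' Describe a synthetic metagenomic scenario
#'
#' Fixes, deterministically from `seed`, a community of reference genomes
#' with per-sample true relative abundances, a genome phylogeny, a full
#' seven-rank taxonomy, and a read-generation law: per sample, `n` reads of
#' which a fraction aligns, each aligned read hitting its true genome plus,
#' with probability governed by `k_probs`, its k − 1 nearest phylogenetic
#' neighbors — the multi-mapping ambiguity real aligners produce among
#' similar genomes.
#'
#' Abundances are log-normal: per-genome base log-abundance N(0, 1), plus
#' N(0, `sample_sd`) per-sample noise, plus `log(effect_size)` on a fraction
#' `effect_genomes` of genomes in every second group when `n_groups > 1`,
#' then softmax-normalized.
#'
#' @param n_samples,n_genomes Community dimensions.
#' @param reads_per_sample Total sequences n per sample.
#' @param aligned_fraction Fraction of reads that align, in (0, 1].
#' @param k_probs Named probability vector over k (hits per read), e.g.
#'   `c("1" = 0.8, "2" = 0.15, "4" = 0.05)`.
#' @param n_groups Number of sample groups (planted community difference).
#' @param effect_genomes Fraction of genomes carrying the group effect.
#' @param effect_size Fold-change on affected genomes.
#' @param sample_sd Per-sample log-abundance noise SD.
#' @param seed Integer seed.
#' @return An `ogu_scenario` list with elements `genomes`, `abundances`
#'   (genomes x samples matrix of true relative abundances), `tree`,
#'   `taxonomy`, `groups` (tibble `sample_id`, `group`), and the
#'   read-generation parameters.
#' @export
ogu_scenario <- function(n_samples = 6, n_genomes = 20,
                         reads_per_sample = 1000, aligned_fraction = 0.9,
                         k_probs = c("1" = 0.8, "2" = 0.15, "4" = 0.05),
                         n_groups = 1, effect_genomes = 0.25,
                         effect_size = 4, sample_sd = 0.5, seed = 1) {
  if (aligned_fraction <= 0 || aligned_fraction > 1) {
    abort("aligned_fraction must be in (0, 1]")
  }
  ks <- as.integer(names(k_probs))
  if (any(is.na(ks)) || any(ks < 1) || any(k_probs < 0) ||
      abs(sum(k_probs) - 1) > 1e-9) {
    abort("k_probs must be a probability vector named by integers k >= 1")
  }
  if (max(ks) >= n_genomes) abort("max k must be below n_genomes")
  genomes <- sprintf("G%02d", seq_len(n_genomes))
  samples <- sprintf("S%d", seq_len(n_samples))
  tree <- random_phylogeny(n_genomes, seed = seed + 1000L,
                           tip_labels = genomes)
  state <- with_local_seed(seed, {
    base <- rnorm(n_genomes)
    affected <- if (n_groups > 1) {
      sample(n_genomes, max(1, round(effect_genomes * n_genomes)))
    } else integer(0)
    group_of <- rep_len(seq_len(n_groups), n_samples)
    logab <- vapply(seq_len(n_samples), function(j) {
      la <- base + rnorm(n_genomes, sd = sample_sd)
      if (group_of[j] %% 2 == 0) {
        la[affected] <- la[affected] + log(effect_size)
      }
      la
    }, numeric(n_genomes))
    list(logab = logab, group_of = group_of)
  })
  abund <- apply(state$logab, 2, function(v) exp(v) / sum(exp(v)))
  dimnames(abund) <- list(genomes, samples)
  structure(list(
    genomes = genomes, samples = samples, abundances = abund, tree = tree,
    taxonomy = nested_taxonomy(genomes),
    groups = tibble(sample_id = samples,
                    group = paste0("grp", state$group_of)),
    reads_per_sample = reads_per_sample,
    aligned_fraction = aligned_fraction,
    k_probs = k_probs, seed = seed), class = "ogu_scenario")
}

# deterministic seven-rank taxonomy by index nesting: genomes pair into
# species, species into genera, and so on up to a single kingdom
nested_taxonomy <- function(genomes) {
  prefixes <- c(kingdom = "ki", phylum = "ph", class = "cl", order = "or",
                family = "fa", genus = "ge", species = "sp")
  out <- list()
  ids <- genomes
  child_rank <- "none"
  for (rank in rev(OGU_RANKS)) {
    parents <- sprintf("%s%02d", prefixes[[rank]],
                       (seq_along(ids) - 1) %/% 2 + 1)
    out[[rank]] <- tibble(node_id = ids, parent_id = parents,
                          rank = child_rank)
    ids <- unique(parents)
    child_rank <- rank
  }
  out$root <- tibble(node_id = ids, parent_id = NA_character_,
                     rank = "kingdom")
  df <- bind_rows(out)
  df$name <- df$node_id
  ogu_taxonomy(df)
}

#' Simulate reads and alignments for a scenario
#'
#' Draws each sample's aligned reads multinomially from the true
#' abundances, assigns each read k hit genomes (the true genome plus its
#' k − 1 nearest phylogenetic neighbors, k drawn from the scenario's
#' multi-mapping law), and returns the hits together with the ground truth.
#' Read ids embed sample and serial number (`S1_r000001`) so multiplexed
#' demultiplexing is exercised by default.
#'
#' @param scenario An [ogu_scenario()].
#' @return An `ogu_simulation` list: `hits` (tibble `sample_id`,
#'   `query_id`, `subject_id`), `truth` (an [ogu_table] of true per-genome
#'   read counts, with the full depth ledger n and m), `groups`, and the
#'   scenario itself.
#' @export
simulate_reads <- function(scenario) {
  stopifnot(inherits(scenario, "ogu_scenario"))
  n <- scenario$reads_per_sample
  genomes <- scenario$genomes
  # neighbor order by patristic distance, ties broken by genome id
  coph <- ape::cophenetic.phylo(scenario$tree)[genomes, genomes]
  neighbor <- apply(coph, 1, function(d) {
    genomes[order(d, genomes)]
  })  # genomes x genomes, column = focal genome, first entry = itself
  ks <- as.integer(names(scenario$k_probs))
  sim <- with_local_seed(scenario$seed + 2000L, {
    purrr::map(scenario$samples, function(s) {
      m <- round(scenario$aligned_fraction * n)
      true_counts <- as.vector(rmultinom(1, m, scenario$abundances[, s]))
      true_genome <- rep(genomes, true_counts)
      k <- if (length(ks) == 1) rep.int(ks, m) else {
        sample(ks, m, replace = TRUE, prob = scenario$k_probs)
      }
      qid <- sprintf("%s_r%06d", s, seq_len(m))
      subjects <- lapply(seq_len(m), function(i) {
        neighbor[seq_len(k[i]), true_genome[i]]
      })
      list(hits = tibble(sample_id = s,
                         query_id = rep(qid, lengths(subjects)),
                         subject_id = unlist(subjects)),
           truth = tibble(feature_id = genomes, sample_id = s,
                          count = as.double(true_counts)),
           m = m)
    })
  })
  truth <- ogu_table(bind_rows(purrr::map(sim, "truth")),
                     samples = scenario$samples, features = genomes,
                     value_kind = "rounded_int")
  truth <- set_depth_ledger(truth, tibble(
    sample_id = scenario$samples,
    m = vapply(sim, function(x) as.double(x$m), 0),
    n = as.double(n)))
  structure(list(hits = bind_rows(purrr::map(sim, "hits")),
                 truth = truth, groups = scenario$groups,
                 scenario = scenario),
            class = "ogu_simulation")
}

open_out <- function(path, compression) {
  switch(compression,
         none = file(path, "w"),
         gzip = gzfile(path, "w"),
         bzip2 = bzfile(path, "w"),
         lzma = xzfile(path, "w"))
}

compression_ext <- c(none = "", gzip = ".gz", bzip2 = ".bz2", lzma = ".xz")
format_ext <- c(sam = ".sam", blast6 = ".b6o", map = ".map")

format_alignment_lines <- function(hits, format, genomes) {
  switch(format,
    map = sprintf("%s\t%s", hits$query_id, hits$subject_id),
    blast6 = sprintf(
      "%s\t%s\t100.000\t100\t0\t0\t1\t100\t1\t100\t1e-50\t200",
      hits$query_id, hits$subject_id),
    sam = {
      secondary <- duplicated(hits$query_id)
      c("@HD\tVN:1.6\tSO:queryname",
        sprintf("@SQ\tSN:%s\tLN:1000000", genomes),
        sprintf("%s\t%d\t%s\t1\t42\t100M\t*\t0\t0\t*\t*",
                hits$query_id, ifelse(secondary, 256L, 0L),
                hits$subject_id))
    })
}

#' Write simulated alignments to disk
#'
#' Writes a simulation's hits in any of the three alignment formats,
#' optionally compressed, either as one multiplexed file (query ids keep
#' their sample prefix) or one file per sample (prefix stripped; the
#' filename stem names the sample).
#'
#' @param sim An `ogu_simulation` (or a hits tibble).
#' @param dir Output directory (created if needed).
#' @param format `"map"`, `"sam"` or `"blast6"`.
#' @param compression `"none"`, `"gzip"`, `"bzip2"` or `"lzma"`.
#' @param multiplexed Single multiplexed file (default) or per-sample files.
#' @return Character vector of the files written.
#' @export
write_alignments <- function(sim, dir, format = c("map", "sam", "blast6"),
                             compression = c("none", "gzip", "bzip2", "lzma"),
                             multiplexed = TRUE) {
  format <- match.arg(format)
  compression <- match.arg(compression)
  hits <- if (inherits(sim, "ogu_simulation")) sim$hits else as_tibble(sim)
  hits <- arrange(hits, .data$sample_id, .data$query_id)
  genomes <- sort(unique(hits$subject_id))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  ext <- paste0(format_ext[[format]], compression_ext[[compression]])
  if (multiplexed) {
    path <- file.path(dir, paste0("alignment", ext))
    con <- open_out(path, compression)
    writeLines(format_alignment_lines(hits, format, genomes), con)
    close(con)
    return(path)
  }
  vapply(unique(hits$sample_id), function(s) {
    sub <- filter(hits, .data$sample_id == s)
    sub$query_id <- sub("^[^_]*_", "", sub$query_id)
    path <- file.path(dir, paste0(s, ext))
    con <- open_out(path, compression)
    writeLines(format_alignment_lines(sub, format, genomes), con)
    close(con)
    path
  }, "")
}

#' Write a taxonomy in any of the three supported dialects
#'
#' `"lineage"` writes one Greengenes-style lineage string per genome
#' (rank-`none`` leaf); `"taxdump"` writes `nodes.dmp` and `names.dmp`;
#' `"map"` writes one child-to-parent TSV per child rank, named
#' `<rank>.map`.
#'
#' @param taxonomy A taxonomy tibble (see [ogu_taxonomy()]).
#' @param dir Output directory.
#' @param dialect `"lineage"`, `"taxdump"` or `"map"`.
#' @return Character vector of the files written.
#' @export
write_taxonomy <- function(taxonomy, dir,
                           dialect = c("lineage", "taxdump", "map")) {
  dialect <- match.arg(dialect)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  parent <- setNames(taxonomy$parent_id, taxonomy$node_id)
  rank <- setNames(taxonomy$rank, taxonomy$node_id)
  if (dialect == "lineage") {
    leaves <- taxonomy$node_id[taxonomy$rank == "none" &
                                 !taxonomy$node_id %in% taxonomy$parent_id]
    pref <- setNames(names(lineage_prefixes), unname(lineage_prefixes))
    lines <- vapply(leaves, function(g) {
      chain <- character()
      node <- parent[[g]]
      while (!is.na(node)) {
        if (rank[[node]] %in% OGU_RANKS) {
          chain <- c(paste0(pref[[rank[[node]]]], "__",
                            taxonomy$name[taxonomy$node_id == node]), chain)
        }
        node <- parent[[node]]
      }
      paste0(g, "\t", paste(chain, collapse = "; "))
    }, "")
    path <- file.path(dir, "lineages.tsv")
    writeLines(lines, path)
    return(path)
  }
  if (dialect == "taxdump") {
    pid <- ifelse(is.na(taxonomy$parent_id), taxonomy$node_id,
                  taxonomy$parent_id)
    rk <- ifelse(taxonomy$rank == "none", "no rank", taxonomy$rank)
    nodes_path <- file.path(dir, "nodes.dmp")
    names_path <- file.path(dir, "names.dmp")
    writeLines(sprintf("%s\t|\t%s\t|\t%s\t|", taxonomy$node_id, pid, rk),
               nodes_path)
    writeLines(sprintf("%s\t|\t%s\t|\t\t|\tscientific name\t|",
                       taxonomy$node_id, taxonomy$name), names_path)
    return(c(nodes_path, names_path))
  }
  # one child->parent map per child rank
  with_parent <- filter(taxonomy, !is.na(.data$parent_id))
  vapply(unique(with_parent$rank), function(r) {
    sub <- filter(with_parent, .data$rank == r)
    path <- file.path(dir, paste0(r, ".map"))
    writeLines(sprintf("%s\t%s", sub$node_id, sub$parent_id), path)
    path
  }, "")
}

#' Partition a tree's tips into monophyletic taxonomic units
#'
#' Splits the tree into `n_units` clades (repeatedly replacing the largest
#' clade by its children, deterministically) and returns a minimal taxonomy
#' that assigns every tip to a unit at `rank`. Because every unit is a
#' clade by construction, the result is always monophyletic — the setting
#' [collapse_phylogeny()] requires, as when a reference taxonomy has been
#' curated against its phylogeny.
#'
#' @param tree An `ape::phylo`.
#' @param n_units Number of units (2 .. number of tips).
#' @param rank Rank of the units (default `"species"`).
#' @return A taxonomy tibble mapping tips (rank `"none"`) to units named
#'   `U1..Un` at `rank`, under a single root at the next rank up.
#' @export
clade_taxonomy <- function(tree, n_units, rank = "species") {
  tree <- validate_phylogeny(tree)
  rank <- match.arg(rank, OGU_RANKS)
  ntip <- ape::Ntip(tree)
  if (n_units < 2 || n_units > ntip) {
    abort("n_units must be between 2 and the number of tips")
  }
  tipsets <- node_tip_sets(tree)
  kids <- node_children(tree)
  nodes <- ntip + 1L  # root
  while (length(nodes) < n_units) {
    sizes <- lengths(tipsets[nodes])
    splittable <- nodes[nodes > ntip]
    if (length(splittable) == 0) break
    target <- splittable[which.max(lengths(tipsets[splittable]))]
    nodes <- c(setdiff(nodes, target), kids[[target]])
  }
  units <- tipsets[nodes]
  parent_rank <- if (match(rank, OGU_RANKS) > 1) {
    OGU_RANKS[match(rank, OGU_RANKS) - 1]
  } else "kingdom"
  root_id <- "U_root"
  bind_units <- purrr::imap(units, function(tips, i) {
    tibble(node_id = tips, parent_id = paste0("U", i), rank = "none")
  })
  df <- bind_rows(
    bind_rows(bind_units),
    tibble(node_id = paste0("U", seq_along(units)), parent_id = root_id,
           rank = rank),
    tibble(node_id = root_id, parent_id = NA_character_,
           rank = if (rank == "kingdom") "none" else parent_rank))
  df$name <- df$node_id
  ogu_taxonomy(df)
}
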