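# Independent oracles used across the suite. These deliberately take naive
# routes (per-branch enumeration, hat-matrix algebra, full relabeling
# enumeration) so they share no code path with the package.

# descendant tip indices of a node, by repeated edge lookup
oracle_tips_below <- function(tree, node) {
  ntip <- ape::Ntip(tree)
  if (node <= ntip) return(tree$tip.label[node])
  kids <- tree$edge[tree$edge[, 1] == node, 2]
  unlist(lapply(kids, oracle_tips_below, tree = tree))
}

# brute-force UniFrac: iterate every branch, enumerate its tip set
oracle_unifrac <- function(tree, x, y, weighted, normalized = FALSE) {
  x <- x[tree$tip.label]
  y <- y[tree$tip.label]
  x[is.na(x)] <- 0
  y[is.na(y)] <- 0
  num <- 0
  den <- 0
  for (e in seq_len(nrow(tree$edge))) {
    tips <- oracle_tips_below(tree, tree$edge[e, 2])
    l <- tree$edge.length[e]
    if (weighted) {
      px <- sum(x[tips]) / sum(x)
      py <- sum(y[tips]) / sum(y)
      num <- num + l * abs(px - py)
      den <- den + l * (px + py)
    } else {
      ax <- sum(x[tips]) > 0
      ay <- sum(y[tips]) > 0
      if (xor(ax, ay)) num <- num + l
      if (ax || ay) den <- den + l
    }
  }
  if (weighted && !normalized) return(num)
  if (den == 0) return(0)
  num / den
}

# pseudo-F via Gower centering and projection algebra (McArdle-Anderson)
oracle_pseudo_f <- function(dm, groups) {
  m <- as.matrix(dm)
  n <- nrow(m)
  a <- length(unique(groups))
  A <- -0.5 * m^2
  C <- diag(n) - matrix(1 / n, n, n)
  G <- C %*% A %*% C
  X <- stats::model.matrix(~ factor(groups))
  H <- X %*% solve(t(X) %*% X) %*% t(X)
  ss_b <- sum(diag(H %*% G %*% H))
  ss_w <- sum(diag((diag(n) - H) %*% G %*% (diag(n) - H)))
  (ss_b / (a - 1)) / (ss_w / (n - a))
}

# every distinct relabeling of a grouping vector
oracle_relabelings <- function(groups) {
  n <- length(groups)
  perm_idx <- function(v) {
    if (length(v) == 1) return(list(v))
    out <- list()
    for (i in seq_along(v)) {
      for (rest in perm_idx(v[-i])) out[[length(out) + 1]] <- c(v[i], rest)
    }
    out
  }
  all_orders <- perm_idx(seq_len(n))
  labelings <- unique(lapply(all_orders, function(ix) groups[ix]))
  labelings
}

# random small integer table for property tests
random_table <- function(n_features, n_samples, seed, max_count = 20) {
  withr::with_seed(seed, {
    m <- matrix(rpois(n_features * n_samples, 3), n_features, n_samples)
    m[m > max_count] <- max_count
    dimnames(m) <- list(sprintf("F%03d", seq_len(n_features)),
                        sprintf("S%02d", seq_len(n_samples)))
    ogu_table_from_matrix(m, value_kind = "rounded_int")
  })
}

# random taxonomy with truncated lineages and rank gaps, for tree-contract
# properties: starts from the deterministic nested hierarchy, then deletes
# random internal nodes (children reattach to the grandparent) and random
# species (genomes reattach higher up)
random_gappy_taxonomy <- function(seed) {
  withr::with_seed(seed, {
    genomes <- sprintf("G%02d", seq_len(sample(8:24, 1)))
    tax <- ogun:::nested_taxonomy(genomes)
    for (i in seq_len(sample(0:4, 1))) {
      killable <- tax$node_id[tax$rank %in%
                                c("phylum", "class", "order", "family",
                                  "genus", "species")]
      victim <- sample(killable, 1)
      gp <- tax$parent_id[tax$node_id == victim]
      tax$parent_id[tax$parent_id == victim] <- gp
      tax <- tax[tax$node_id != victim, ]
    }
    ogu_taxonomy(tax)
  })
}
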