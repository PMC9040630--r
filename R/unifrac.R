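#' UniFrac distances between two communities
#'
#' Both variants walk every branch of a rooted tree with branch lengths and
#' compare what descends through it in the two communities.
#'
#' Unweighted UniFrac is the fraction of branch length unique to one
#' community: the summed length of branches whose subtree contains features
#' present in exactly one of the two samples, divided by the summed length
#' of branches with features present in at least one.
#'
#' Weighted UniFrac sums `l_b * |p_x(b) - p_y(b)|` over branches, where
#' `p_s(b)` is the fraction of sample s's total count descending through
#' branch b. The normalized variant divides by `sum l_b * (p_x(b) + p_y(b))`
#' and lies in `[0, 1]`; the unnormalized variant is the conventional
#' default.
#'
#' @param tree Rooted `ape::phylo` with branch lengths.
#' @param x,y Named nonnegative count vectors; names are tip labels. Every
#'   feature with a nonzero count must be a tip of the tree.
#' @param normalized Use the normalized weighted variant (default `FALSE`).
#' @return A single distance.
#' @examples
#' tr <- read_newick("(A:1,B:1);")
#' weighted_unifrac(tr, c(A = 1), c(B = 1))            # 2
#' weighted_unifrac(tr, c(A = 1), c(B = 1), normalized = TRUE)  # 1
#' unweighted_unifrac(tr, c(A = 1), c(B = 1))          # 1
#' @export
unweighted_unifrac <- function(tree, x, y) {
  P <- branch_fractions(tree, cbind(x = tip_counts(tree, x),
                                    y = tip_counts(tree, y)))
  lens <- P$lengths
  ax <- P$frac[, 1] > 0
  ay <- P$frac[, 2] > 0
  denom <- sum(lens[ax | ay])
  if (denom == 0) return(0)
  sum(lens[xor(ax, ay)]) / denom
}

#' @rdname unweighted_unifrac
#' @export
weighted_unifrac <- function(tree, x, y, normalized = FALSE) {
  P <- branch_fractions(tree, cbind(x = tip_counts(tree, x),
                                    y = tip_counts(tree, y)),
                        relative = TRUE)
  d <- sum(P$lengths * abs(P$frac[, 1] - P$frac[, 2]))
  if (!normalized) return(d)
  denom <- sum(P$lengths * (P$frac[, 1] + P$frac[, 2]))
  if (denom == 0) return(0)
  d / denom
}

# align a named count vector onto the tree's tips; error on nonzero
# features missing from the tree
tip_counts <- function(tree, x) {
  x <- x[x != 0]
  missing <- setdiff(names(x), tree$tip.label)
  if (length(missing) > 0) {
    abort(paste0("feature(s) with nonzero count absent from the tree: ",
                 paste(missing, collapse = ", ")))
  }
  v <- setNames(numeric(length(tree$tip.label)), tree$tip.label)
  v[names(x)] <- x
  v
}

# per-branch descendant totals for a tips-by-samples count matrix, by
# postorder accumulation; returns branch lengths and the matrix of
# per-branch totals (relative = fractions of each sample's total)
branch_fractions <- function(tree, counts, relative = FALSE) {
  tree <- validate_phylogeny(tree)
  ntip <- ape::Ntip(tree)
  stopifnot(nrow(counts) == ntip)
  po <- ape::reorder.phylo(tree, "postorder")
  nn <- ntip + tree$Nnode
  acc <- matrix(0, nrow = nn, ncol = ncol(counts))
  acc[seq_len(ntip), ] <- counts
  for (i in seq_len(nrow(po$edge))) {
    p <- po$edge[i, 1]; ch <- po$edge[i, 2]
    acc[p, ] <- acc[p, ] + acc[ch, ]
  }
  frac <- acc[po$edge[, 2], , drop = FALSE]
  if (relative) {
    tot <- colSums(counts)
    if (any(tot <= 0)) abort("weighted UniFrac needs nonzero sample totals")
    frac <- sweep(frac, 2, tot, "/")
  }
  list(lengths = po$edge.length, frac = frac)
}
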