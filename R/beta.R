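#' Bray-Curtis and Jaccard dissimilarities between two count vectors
#'
#' Bray-Curtis is `sum(|x - y|) / sum(x + y)`; Jaccard is computed on
#' presence/absence, `1 - |support(x) & support(y)| / |support(x) |
#' support(y)|`. Both lie in `[0, 1]`.
#'
#' @param x,y Equal-length nonnegative numeric vectors (aligned by position;
#'   both may be named identically). They must not both be all-zero.
#' @return A single dissimilarity in `[0, 1]`.
#' @export
bray_curtis <- function(x, y) {
  check_pair(x, y)
  sum(abs(x - y)) / sum(x + y)
}

#' @rdname bray_curtis
#' @export
jaccard <- function(x, y) {
  check_pair(x, y)
  px <- x > 0
  py <- y > 0
  1 - sum(px & py) / sum(px | py)
}

check_pair <- function(x, y) {
  if (length(x) != length(y)) abort("count vectors differ in length")
  if (any(x < 0) || any(y < 0)) abort("negative counts")
  if (sum(x) == 0 && sum(y) == 0) {
    abort("dissimilarity undefined for two all-zero vectors")
  }
  invisible(NULL)
}

#' Pairwise beta-diversity distance matrix for a feature table
#'
#' Computes all pairwise sample dissimilarities under one metric. UniFrac
#' metrics need `tree`; branch mass is accumulated once for all samples, so
#' the result matches the per-pair functions ([bray_curtis()],
#' [jaccard()], [unweighted_unifrac()], [weighted_unifrac()]) exactly.
#'
#' @param x An [ogu_table] with at least 2 samples.
#' @param metric One of `"braycurtis"`, `"jaccard"`, `"unweighted-unifrac"`,
#'   `"weighted-unifrac"`, `"weighted-unifrac-normalized"`.
#' @param tree Rooted `ape::phylo` (UniFrac metrics only).
#' @return An `ogu_dist`: a base [stats::dist] with the metric recorded in
#'   an attribute.
#' @export
beta_diversity <- function(x, metric = c("braycurtis", "jaccard",
                                         "unweighted-unifrac",
                                         "weighted-unifrac",
                                         "weighted-unifrac-normalized"),
                           tree = NULL) {
  stopifnot(is_ogu_table(x))
  metric <- match.arg(metric)
  m <- as.matrix(x)
  samples <- colnames(m)
  if (length(samples) < 2) abort("beta diversity needs at least 2 samples")
  unifrac <- grepl("unifrac", metric)
  if (unifrac) {
    if (is.null(tree)) abort(paste0(metric, " requires a tree"))
    counts <- vapply(samples, function(s) tip_counts(tree, m[, s]),
                     numeric(length(tree$tip.label)))
    P <- branch_fractions(tree, counts,
                          relative = metric != "unweighted-unifrac")
  }
  pair <- function(i, j) {
    switch(metric,
           "braycurtis" = bray_curtis(m[, i], m[, j]),
           "jaccard" = jaccard(m[, i], m[, j]),
           "unweighted-unifrac" = {
             ax <- P$frac[, i] > 0; ay <- P$frac[, j] > 0
             denom <- sum(P$lengths[ax | ay])
             if (denom == 0) 0 else sum(P$lengths[xor(ax, ay)]) / denom
           },
           "weighted-unifrac" =
             sum(P$lengths * abs(P$frac[, i] - P$frac[, j])),
           "weighted-unifrac-normalized" = {
             num <- sum(P$lengths * abs(P$frac[, i] - P$frac[, j]))
             den <- sum(P$lengths * (P$frac[, i] + P$frac[, j]))
             if (den == 0) 0 else num / den
           })
  }
  n <- length(samples)
  dm <- matrix(0, n, n, dimnames = list(samples, samples))
  for (i in seq_len(n - 1)) {
    for (j in seq(i + 1, n)) {
      d <- tryCatch(pair(i, j), error = function(e) {
        abort(paste0("metric failed for pair (", samples[i], ", ",
                     samples[j], "): ", conditionMessage(e)))
      })
      dm[i, j] <- d
      dm[j, i] <- d
    }
  }
  as_ogu_dist(dm, metric)
}

as_ogu_dist <- function(m, metric = NA_character_) {
  d <- stats::as.dist(m)
  attr(d, "metric") <- metric
  class(d) <- c("ogu_dist", class(d))
  d
}

#' @method tidy ogu_dist
#' @export
tidy.ogu_dist <- function(x, ...) {
  m <- as.matrix(x)
  idx <- which(upper.tri(m), arr.ind = TRUE)
  tibble(sample_1 = rownames(m)[idx[, 1]],
         sample_2 = colnames(m)[idx[, 2]],
         distance = m[idx])
}

#' Read and write square distance matrices as TSV
#'
#' The format is a square matrix with sample ids as both the header row and
#' the first column.
#'
#' @param d A `dist` (or `ogu_dist`) object.
#' @param path File path.
#' @return `read_distance_matrix()` returns an `ogu_dist`;
#'   `write_distance_matrix()` returns `d` invisibly.
#' @export
write_distance_matrix <- function(d, path) {
  m <- as.matrix(d)
  df <- as.data.frame(m)
  df <- cbind(tibble(`#SampleID` = rownames(m)), df)
  readr::write_tsv(df, path)
  invisible(d)
}

#' @rdname write_distance_matrix
#' @export
read_distance_matrix <- function(path) {
  df <- readr::read_tsv(path, show_col_types = FALSE)
  m <- as.matrix(df[, -1])
  rownames(m) <- df[[1]]
  if (!isTRUE(all.equal(m, t(m), tolerance = 1e-8))) {
    abort("distance matrix is not symmetric")
  }
  as_ogu_dist(m)
}
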