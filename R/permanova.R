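#' PERMANOVA: permutational multivariate analysis of variance
#'
#' Tests whether community structure differs between groups of samples in a
#' distance matrix, via the pseudo-F ratio
#' `F = (SS_between / (a - 1)) / (SS_within / (N - a))` with
#' `SS_total = (1/N) * sum_{i<j} d_ij^2`,
#' `SS_within = sum_g (1/n_g) * sum_{i<j in g} d_ij^2` and
#' `SS_between = SS_total - SS_within` (a groups, N samples). The p-value
#' is obtained by permuting group labels:
#' `p = (1 + #{F_perm >= F_obs}) / (1 + n_permutations)`, which can never
#' be 0. With `method = "exhaustive"` all distinct relabelings are
#' enumerated instead and `p = #{F >= F_obs} / #relabelings` (the identity
#' included).
#'
#' @param d A `dist`/`ogu_dist`.
#' @param groups Group labels: a vector along the samples of `d`, a named
#'   vector, or a tibble with `sample_id` and a grouping column.
#' @param permutations Number of label permutations (default 999, the
#'   conventional default; large studies often use far more).
#' @param seed Integer seed for the permutations (required for
#'   `method = "sampled"`).
#' @param method `"sampled"` (default) or `"exhaustive"` (small N only).
#' @return An `ogu_permanova` list: `pseudo_F`, `p_value`,
#'   `n_permutations`, `df_between`, `df_within`, and the sums of squares.
#' @export
permanova <- function(d, groups, permutations = 999, seed = NULL,
                      method = c("sampled", "exhaustive")) {
  method <- match.arg(method)
  m <- as.matrix(d)
  groups <- align_groups(groups, rownames(m))
  a <- length(unique(groups))
  n <- nrow(m)
  if (a < 2) abort("PERMANOVA needs at least 2 groups")
  if (any(table(groups) == n)) abort("a group spans all samples")
  if (method == "sampled" && is.null(seed)) {
    abort("permanova with sampled permutations requires a seed")
  }
  d2 <- m^2
  f_obs <- pseudo_f(d2, groups, a, n)
  if (method == "exhaustive") {
    perms <- multiset_permutations(groups)
    f_all <- vapply(perms, function(g) pseudo_f(d2, g, a, n), 0)
    p <- sum(f_all >= f_obs - 1e-12) / length(f_all)
    n_perm <- length(f_all)
  } else {
    if (permutations < 1) abort("need at least one permutation")
    ge <- with_local_seed(seed, {
      sum(vapply(seq_len(permutations), function(i) {
        pseudo_f(d2, sample(groups), a, n) >= f_obs - 1e-12
      }, TRUE))
    })
    p <- (1 + ge) / (1 + permutations)
    n_perm <- permutations
  }
  structure(list(pseudo_F = f_obs, p_value = p, n_permutations = n_perm,
                 df_between = a - 1, df_within = n - a,
                 ss_total = ss_total(d2, n),
                 ss_within = ss_within(d2, groups)),
            class = "ogu_permanova")
}

ss_total <- function(d2, n) sum(d2[upper.tri(d2)]) / n

ss_within <- function(d2, groups) {
  sum(vapply(unique(groups), function(g) {
    idx <- which(groups == g)
    sub <- d2[idx, idx, drop = FALSE]
    sum(sub[upper.tri(sub)]) / length(idx)
  }, 0))
}

pseudo_f <- function(d2, groups, a, n) {
  sst <- ss_total(d2, n)
  ssw <- ss_within(d2, groups)
  ((sst - ssw) / (a - 1)) / (ssw / (n - a))
}

# all distinct orderings of a label multiset
multiset_permutations <- function(labels) {
  rec <- function(counts, prefix) {
    if (sum(counts) == 0) return(list(prefix))
    out <- list()
    for (lab in names(counts)[counts > 0]) {
      counts2 <- counts
      counts2[lab] <- counts2[lab] - 1
      out <- c(out, rec(counts2, c(prefix, lab)))
    }
    out
  }
  rec(table(labels)[unique(labels)], character(0))
}

align_groups <- function(groups, sample_ids) {
  if (is.data.frame(groups)) {
    col <- setdiff(names(groups), "sample_id")[1]
    groups <- setNames(as.character(groups[[col]]), groups$sample_id)
  }
  if (!is.null(names(groups)) && all(sample_ids %in% names(groups))) {
    groups <- groups[sample_ids]
  } else if (length(groups) != length(sample_ids)) {
    abort("group labels do not match the samples of the distance matrix")
  }
  as.character(groups)
}

#' @export
print.ogu_permanova <- function(x, ...) {
  cat(sprintf(
    "# PERMANOVA: pseudo-F = %.4f (df %d, %d), p = %.4g (%d permutations)\n",
    x$pseudo_F, x$df_between, x$df_within, x$p_value, x$n_permutations))
  invisible(x)
}

#' @method tidy ogu_permanova
#' @export
tidy.ogu_permanova <- function(x, ...) {
  tibble(term = c("between groups", "within groups"),
         df = c(x$df_between, x$df_within),
         sum_of_squares = c(x$ss_total - x$ss_within, x$ss_within),
         pseudo_F = c(x$pseudo_F, NA),
         p_value = c(x$p_value, NA))
}

#' @method glance ogu_permanova
#' @export
glance.ogu_permanova <- function(x, ...) {
  tibble(pseudo_F = x$pseudo_F, p_value = x$p_value,
         n_permutations = x$n_permutations)
}
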