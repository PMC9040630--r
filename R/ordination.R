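#' Principal coordinates analysis (classical multidimensional scaling)
#'
#' Double-centers the squared distance matrix, eigendecomposes it, and
#' returns sample coordinates on the axes with positive eigenvalues, in
#' decreasing eigenvalue order. The proportion of variance explained by an
#' axis is its eigenvalue divided by the sum of positive eigenvalues.
#' Negative eigenvalues (a sign of a non-Euclidean distance matrix) are
#' reported untouched — no Cailliez or Lingoes correction is applied — but
#' contribute no axis.
#'
#' @param d A `dist`/`ogu_dist` over at least 2 samples.
#' @return An `ogu_pcoa` list: `coordinates` (tibble `sample_id`, `Axis.1`,
#'   ...), `eigenvalues` (all of them, decreasing), and
#'   `proportion_explained` (one entry per retained axis).
#' @export
pcoa_ordination <- function(d) {
  m <- as.matrix(d)
  n <- nrow(m)
  if (n < 2) abort("PCoA needs at least 2 samples")
  # cmdscale warns when fewer than k eigenvalues are positive; the axis
  # count is decided from the eigenvalues below, so the warning is moot
  sc <- suppressWarnings(cmdscale(stats::as.dist(m), k = n - 1, eig = TRUE))
  eig <- sc$eig
  pos <- which(eig > max(eig) * 1e-12 & eig > 0)
  coords <- sc$points[, seq_along(pos), drop = FALSE]
  colnames(coords) <- paste0("Axis.", seq_along(pos))
  out <- list(
    coordinates = bind_cols(tibble(sample_id = rownames(m)),
                            as_tibble(coords)),
    eigenvalues = eig,
    proportion_explained = eig[pos] / sum(eig[pos]))
  class(out) <- "ogu_pcoa"
  out
}

#' @export
print.ogu_pcoa <- function(x, ...) {
  cat(sprintf("# PCoA: %d samples, %d axes retained\n",
              nrow(x$coordinates), length(x$proportion_explained)))
  pe <- round(100 * x$proportion_explained[seq_len(
    min(3, length(x$proportion_explained)))], 1)
  cat("  variance explained by first axes (%):",
      paste(pe, collapse = ", "), "\n")
  invisible(x)
}

#' @method tidy ogu_pcoa
#' @export
tidy.ogu_pcoa <- function(x, ...) {
  x$coordinates
}

#' @method glance ogu_pcoa
#' @export
glance.ogu_pcoa <- function(x, ...) {
  tibble(n_samples = nrow(x$coordinates),
         n_axes = length(x$proportion_explained),
         n_negative_eigenvalues = sum(x$eigenvalues < 0),
         prop_axis1 = x$proportion_explained[1],
         prop_axis2 = if (length(x$proportion_explained) > 1)
           x$proportion_explained[2] else NA_real_)
}

#' Scatter plot of the first two principal coordinates
#'
#' @param object An `ogu_pcoa`.
#' @param metadata Optional tibble with `sample_id` plus grouping columns.
#' @param colour Optional name of a metadata column to colour by.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot ogu_pcoa
#' @export
autoplot.ogu_pcoa <- function(object, metadata = NULL, colour = NULL, ...) {
  df <- object$coordinates
  if (ncol(df) < 3) abort("fewer than 2 axes to plot")
  if (!is.null(metadata)) df <- left_join(df, metadata, by = "sample_id")
  pe <- round(100 * object$proportion_explained[1:2], 1)
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$Axis.1, y = .data$Axis.2))
  p <- if (is.null(colour)) p + ggplot2::geom_point() else
    p + ggplot2::geom_point(ggplot2::aes(colour = .data[[colour]]))
  p + ggplot2::labs(x = paste0("Axis 1 (", pe[1], "%)"),
                    y = paste0("Axis 2 (", pe[2], "%)"))
}
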