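#' Sparse feature tables of samples by features
#'
#' An `ogu_table` is a tibble in sparse "triplet" form — one row per nonzero
#' (feature, sample) cell with columns `feature_id`, `sample_id` and `count` —
#' carrying three attributes: the ordered sample axis (`samples`), the ordered
#' feature axis (`features`) and a `value_kind` flag recording what the values
#' mean:
#'
#' * `"raw_float"` — fractional read counts straight out of [tally_hits()]
#'   (1/k apportionment, not yet rounded);
#' * `"rounded_int"` — integer counts after [round_counts()];
#' * `"normalized_float"` — counts divided by genome size
#'   ([normalize_by_size()]).
#'
#' Keeping the axes as attributes lets a table remember samples whose column
#' became empty, so column order and column count survive filtering.
#'
#' @param x A data frame with columns `feature_id`, `sample_id`, `count`.
#' @param samples,features Ordered axis labels. Default: order of first
#'   appearance in `x`.
#' @param value_kind One of `"raw_float"`, `"rounded_int"`,
#'   `"normalized_float"`.
#' @return An `ogu_table` (a tibble subclass).
#' @examples
#' tab <- ogu_table(
#'   tibble::tibble(feature_id = c("G1", "G2"), sample_id = "S1",
#'                  count = c(3, 4)),
#'   value_kind = "rounded_int")
#' sample_sums(tab)
#' @export
ogu_table <- function(x, samples = NULL, features = NULL,
                      value_kind = c("raw_float", "rounded_int",
                                     "normalized_float")) {
  value_kind <- match.arg(value_kind)
  x <- as_tibble(x)
  req <- c("feature_id", "sample_id", "count")
  if (!all(req %in% names(x))) {
    abort(paste0("ogu_table needs columns ",
                 paste(req, collapse = ", ")))
  }
  x <- select(x, all_of(req))
  x$feature_id <- as.character(x$feature_id)
  x$sample_id <- as.character(x$sample_id)
  x$count <- as.double(x$count)
  if (any(is.na(x$count)) || any(x$count < 0)) {
    abort("feature table counts must be nonnegative and non-missing")
  }
  if (value_kind == "rounded_int" && any(x$count != trunc(x$count))) {
    abort("a rounded_int table may contain only integer counts")
  }
  samples <- as.character(samples %||% unique(x$sample_id))
  features <- as.character(features %||% unique(x$feature_id))
  if (anyDuplicated(samples)) abort("duplicate sample ids")
  if (anyDuplicated(features)) abort("duplicate feature ids")
  if (!all(x$sample_id %in% samples)) {
    abort("table contains sample ids outside the declared sample axis")
  }
  if (!all(x$feature_id %in% features)) {
    abort("table contains feature ids outside the declared feature axis")
  }
  # collapse duplicate cells, drop explicit zeros, fix a canonical row order
  x <- x |>
    group_by(.data$feature_id, .data$sample_id) |>
    summarise(count = sum(.data$count), .groups = "drop") |>
    filter(.data$count > 0)
  x <- x[order(match(x$feature_id, features),
               match(x$sample_id, samples)), ]
  structure(x,
            class = c("ogu_table", class(tibble())),
            samples = samples,
            features = features,
            value_kind = value_kind)
}

#' @rdname ogu_table
#' @export
is_ogu_table <- function(x) inherits(x, "ogu_table")

#' Axis and metadata accessors for `ogu_table`s
#'
#' @param x An [ogu_table].
#' @return `table_samples()` and `table_features()` return character vectors;
#'   `value_kind()` returns the value-kind string; `sample_sums()` returns a
#'   named numeric vector over all samples (zero for empty columns).
#' @export
table_samples <- function(x) attr(x, "samples")

#' @rdname table_samples
#' @export
table_features <- function(x) attr(x, "features")

#' @rdname table_samples
#' @export
value_kind <- function(x) attr(x, "value_kind")

#' @rdname table_samples
#' @export
sample_sums <- function(x) {
  stopifnot(is_ogu_table(x))
  s <- setNames(numeric(length(table_samples(x))), table_samples(x))
  agg <- tapply(x$count, x$sample_id, sum)
  s[names(agg)] <- agg
  s
}

#' Convert a feature table to a dense matrix
#'
#' @param x An [ogu_table].
#' @param ... Unused.
#' @return A dense numeric matrix, features in rows, samples in columns, in
#'   axis order; absent cells are 0.
#' @export
as.matrix.ogu_table <- function(x, ...) {
  m <- matrix(0, nrow = length(table_features(x)),
              ncol = length(table_samples(x)),
              dimnames = list(table_features(x), table_samples(x)))
  if (nrow(x) > 0) {
    m[cbind(x$feature_id, x$sample_id)] <- x$count
  }
  m
}

#' Build an `ogu_table` from a dense matrix
#'
#' @param m Numeric matrix, features in rows (rownames) and samples in
#'   columns (colnames).
#' @param value_kind See [ogu_table()].
#' @return An [ogu_table].
#' @export
ogu_table_from_matrix <- function(m, value_kind = "rounded_int") {
  stopifnot(is.matrix(m), !is.null(rownames(m)), !is.null(colnames(m)))
  idx <- which(m != 0, arr.ind = TRUE)
  ogu_table(tibble(feature_id = rownames(m)[idx[, 1]],
                   sample_id = colnames(m)[idx[, 2]],
                   count = m[idx]),
            samples = colnames(m), features = rownames(m),
            value_kind = value_kind)
}

#' Drop features whose row is entirely zero
#'
#' @param x An [ogu_table].
#' @return The table with unused feature labels removed from the axis.
#' @export
drop_empty_features <- function(x) {
  stopifnot(is_ogu_table(x))
  keep <- table_features(x)[table_features(x) %in% unique(x$feature_id)]
  new_ogu_table(x, features = keep)
}

# internal re-wrapper that preserves attributes unless overridden
new_ogu_table <- function(x, samples = NULL, features = NULL,
                          value_kind = NULL) {
  ogu_table(as_tibble(x)[c("feature_id", "sample_id", "count")],
            samples = samples %||% attr(x, "samples"),
            features = features %||% attr(x, "features"),
            value_kind = value_kind %||% attr(x, "value_kind"))
}

#' @export
print.ogu_table <- function(x, ...) {
  cat(sprintf("# OGU feature table: %d features x %d samples (%s), %d nonzero cells\n",
              length(table_features(x)), length(table_samples(x)),
              value_kind(x), nrow(x)))
  NextMethod()
}

#' @method tidy ogu_table
#' @export
tidy.ogu_table <- function(x, ...) {
  as_tibble(x)
}

#' @method glance ogu_table
#' @export
glance.ogu_table <- function(x, ...) {
  nf <- length(table_features(x))
  ns <- length(table_samples(x))
  tibble(n_features = nf, n_samples = ns, n_nonzero = nrow(x),
         density = if (nf * ns > 0) nrow(x) / (nf * ns) else NA_real_,
         total_count = sum(x$count), value_kind = value_kind(x))
}

#' Heat-map style plot of a feature table
#'
#' @param object An [ogu_table].
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot ogu_table
#' @export
autoplot.ogu_table <- function(object, ...) {
  df <- as_tibble(object)
  df$feature_id <- factor(df$feature_id, levels = rev(table_features(object)))
  df$sample_id <- factor(df$sample_id, levels = table_samples(object))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$sample_id, y = .data$feature_id,
                                   fill = .data$count)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_viridis_c() +
    ggplot2::labs(x = "sample", y = "feature", fill = "count")
}
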