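#' Tally hit groups into a fractional OGU table
#'
#' The core accounting step of the OGU method. Each query sequence that hit
#' k genomes contributes 1/k counts to each of those genomes in its sample's
#' column, so every query carries total weight exactly 1 and the pre-rounding
#' column sum equals the number of aligned queries in that sample. Counts are
#' summed over the whole alignment; rounding is a separate, later step
#' ([round_counts()]).
#'
#' @param hits Tibble of hits as returned by [read_alignment()]: columns
#'   `sample_id`, `query_id`, `subject_id`, duplicate-free per query.
#' @return An [ogu_table] of kind `raw_float`. The attached depth ledger
#'   (see [depth_ledger()]) records `m`, the number of aligned queries per
#'   sample.
#' @examples
#' hits <- tibble::tibble(sample_id = "S1", query_id = c("r1", "r1", "r2"),
#'                        subject_id = c("G1", "G2", "G1"))
#' tab <- tally_hits(hits)
#' as.matrix(tab)  # G1 = 1.5, G2 = 0.5; column sum = 2 queries
#' @export
tally_hits <- function(hits) {
  hits <- as_tibble(hits)
  req <- c("sample_id", "query_id", "subject_id")
  if (!all(req %in% names(hits))) {
    abort(paste0("hits need columns ", paste(req, collapse = ", ")))
  }
  hits <- distinct(hits, .data$sample_id, .data$query_id, .data$subject_id)
  if (nrow(hits) == 0) {
    tab <- ogu_table(tibble(feature_id = character(), sample_id = character(),
                            count = double()), value_kind = "raw_float")
    return(set_depth_ledger(tab, tibble(sample_id = character(),
                                        m = double(), n = double())))
  }
  weighted <- hits |>
    group_by(.data$sample_id, .data$query_id) |>
    mutate(weight = 1 / n()) |>
    ungroup()
  cells <- weighted |>
    group_by(feature_id = .data$subject_id, .data$sample_id) |>
    summarise(count = sum(.data$weight), .groups = "drop")
  ledger <- hits |>
    distinct(.data$sample_id, .data$query_id) |>
    count(.data$sample_id, name = "m") |>
    mutate(m = as.double(.data$m), n = NA_real_)
  tab <- ogu_table(cells,
                   samples = unique(hits$sample_id),
                   features = sort(unique(cells$feature_id)),
                   value_kind = "raw_float")
  set_depth_ledger(tab, ledger)
}

#' Per-sample sequencing depth ledger
#'
#' Subsampling needs to know, per sample, how many sequences the original
#' dataset held (`n`) and how many aligned (`m`, the pre-rounding column
#' sum). [tally_hits()] records `m`; `set_total_reads()` supplies `n`.
#'
#' @param x An [ogu_table].
#' @param ledger Tibble with columns `sample_id`, `m`, `n`.
#' @param n Named numeric vector (or tibble with `sample_id`, `n`) of total
#'   sequence counts per sample.
#' @return `depth_ledger()` returns the ledger tibble (computing `m` from
#'   column sums when none was recorded); the setters return the table.
#' @export
depth_ledger <- function(x) {
  stopifnot(is_ogu_table(x))
  led <- attr(x, "ledger")
  if (is.null(led)) {
    led <- tibble(sample_id = table_samples(x),
                  m = unname(sample_sums(x)), n = NA_real_)
  }
  led
}

#' @rdname depth_ledger
#' @export
set_depth_ledger <- function(x, ledger) {
  stopifnot(is_ogu_table(x))
  ledger <- as_tibble(ledger)
  bad <- !is.na(ledger$n) & ledger$n < ledger$m
  if (any(bad)) {
    abort(paste0("total reads n below aligned reads m for sample(s): ",
                 paste(ledger$sample_id[bad], collapse = ", ")))
  }
  attr(x, "ledger") <- ledger
  x
}

#' @rdname depth_ledger
#' @export
set_total_reads <- function(x, n) {
  led <- depth_ledger(x)
  if (is.data.frame(n)) n <- setNames(n$n, n$sample_id)
  missing <- setdiff(led$sample_id, names(n))
  if (length(missing) > 0) {
    abort(paste0("no total read count for sample(s): ",
                 paste(missing, collapse = ", ")))
  }
  led$n <- as.double(n[led$sample_id])
  set_depth_ledger(x, led)
}

#' Round a fractional table to integer counts
#'
#' Summed 1/k frequencies are rounded half-to-even (banker's rounding), so
#' the per-sample sum stays nearly — considering rounding — equal to the
#' number of aligned sequences. Entries that round to zero are dropped from
#' storage. `mode = "always_even"` instead snaps every value to the nearest
#' even integer (2·round(x/2)); it is provided for comparison only and
#' destroys near-conservation, so it is not the default.
#'
#' @param x An [ogu_table] of kind `raw_float`.
#' @param mode `"half_even"` (default) or `"always_even"`.
#' @return An [ogu_table] of kind `rounded_int`.
#' @export
round_counts <- function(x, mode = c("half_even", "always_even")) {
  stopifnot(is_ogu_table(x))
  mode <- match.arg(mode)
  if (value_kind(x) == "rounded_int") return(x)
  y <- as_tibble(x)
  y$count <- switch(mode,
                    half_even = round(y$count),
                    always_even = 2 * round(y$count / 2))
  tab <- ogu_table(filter(y, .data$count > 0),
                   samples = table_samples(x), features = table_features(x),
                   value_kind = "rounded_int")
  set_depth_ledger(drop_empty_features(tab), depth_ledger(x))
}

#' Filter features by per-sample relative abundance
#'
#' Within each sample, entries whose relative abundance (count divided by
#' that sample's column sum, computed before any removal) falls strictly
#' below `threshold` are zeroed in that sample only; entries exactly at the
#' threshold are kept. Features left with an all-zero row are dropped.
#' A threshold of 0 is the identity; samples with a zero column sum are
#' left untouched.
#'
#' @param x An [ogu_table].
#' @param threshold Fraction in `[0, 1)`; e.g. `1e-4` for the 0.01%
#'   per-sample cutoff commonly used on OGU tables.
#' @return The filtered [ogu_table].
#' @export
filter_rel_abund <- function(x, threshold) {
  stopifnot(is_ogu_table(x), threshold >= 0, threshold < 1)
  if (threshold == 0) return(x)
  tot <- sample_sums(x)
  y <- filter(as_tibble(x),
              .data$count / tot[.data$sample_id] >= threshold |
                tot[.data$sample_id] == 0)
  tab <- ogu_table(y, samples = table_samples(x),
                   features = table_features(x)[table_features(x) %in%
                                                  unique(y$feature_id)],
                   value_kind = value_kind(x))
  set_depth_ledger(tab, depth_ledger(x))
}

#' Filter features by prevalence
#'
#' Drops features detected (nonzero) in fewer than `min_samples` samples.
#'
#' @param x An [ogu_table].
#' @param min_samples Minimum number of samples a feature must appear in
#'   (>= 1); the common companion of the 0.01% abundance filter is 2.
#' @return The filtered [ogu_table].
#' @export
filter_prevalence <- function(x, min_samples) {
  stopifnot(is_ogu_table(x), min_samples >= 1)
  prev <- table(x$feature_id)
  keep <- names(prev)[prev >= min_samples]
  y <- filter(as_tibble(x), .data$feature_id %in% keep)
  tab <- ogu_table(y, samples = table_samples(x),
                   features = table_features(x)[table_features(x) %in% keep],
                   value_kind = value_kind(x))
  set_depth_ledger(tab, depth_ledger(x))
}

#' Normalize counts by reference genome size
#'
#' OGU frequencies are sequence abundances; dividing by genome length (and
#' multiplying by `scale`) converts them toward taxonomic abundances:
#' `count / size * scale`.
#'
#' @param x An [ogu_table].
#' @param sizes Genome sizes in bp: a named numeric vector or a data frame
#'   with columns `genome_id`, `length` (see [read_genome_sizes()]). Every
#'   feature present in the table must have a positive size.
#' @param scale Positive multiplier, default 1.
#' @param round_result Re-apply half-to-even rounding to the normalized
#'   values (default `FALSE`).
#' @return An [ogu_table] of kind `normalized_float` (or `rounded_int` when
#'   `round_result = TRUE`).
#' @export
normalize_by_size <- function(x, sizes, scale = 1, round_result = FALSE) {
  stopifnot(is_ogu_table(x), scale > 0)
  if (is.data.frame(sizes)) sizes <- setNames(sizes$length, sizes$genome_id)
  if (any(sizes <= 0)) abort("genome sizes must be positive")
  present <- unique(x$feature_id)
  missing <- setdiff(present, names(sizes))
  if (length(missing) > 0) {
    abort(paste0("no genome size for feature(s): ",
                 paste(missing, collapse = ", ")))
  }
  y <- mutate(as_tibble(x),
              count = .data$count / unname(sizes[.data$feature_id]) * scale)
  tab <- ogu_table(y, samples = table_samples(x),
                   features = table_features(x),
                   value_kind = "normalized_float")
  tab <- set_depth_ledger(tab, depth_ledger(x))
  if (round_result) round_counts(tab) else tab
}

#' Read a genome-size map
#'
#' @param path Two-column TSV: genome id, length in bp (no header, or a
#'   header line starting with `#`).
#' @return Tibble with columns `genome_id`, `length`.
#' @export
read_genome_sizes <- function(path) {
  df <- readr::read_tsv(path, col_names = c("genome_id", "length"),
                        comment = "#", show_col_types = FALSE)
  if (any(is.na(df$length)) || any(df$length <= 0)) {
    abort("genome sizes must be positive integers")
  }
  df
}

# run code under a given RNG seed, restoring the caller's RNG state
with_local_seed <- function(seed, code) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

#' Rarefy a table to a fixed sequencing depth, accounting for unaligned reads
#'
#' Mimics a shallower sequencing run: per sample, an extra reserved feature
#' `__UNALIGNED__` with frequency n − m (n total sequences, m aligned = the
#' column sum) is added, `depth` items are drawn without replacement from the
#' resulting n-item urn (a multivariate hypergeometric draw), and the
#' reserved feature is removed again. The draw is deterministic given
#' `seed`; the replicate convention in depth-robustness studies is seeds
#' 0 through 9.
#'
#' @param x An [ogu_table] of kind `rounded_int`, with integer counts.
#' @param depth Positive integer target depth; must not exceed n for any
#'   sample.
#' @param seed Integer random seed (required).
#' @param total_reads Optional per-sample n (named vector or tibble with
#'   `sample_id`, `n`); defaults to the ledger's `n`, and to m (everything
#'   aligned) where that is unrecorded.
#' @return A subsampled [ogu_table] of kind `rounded_int`. Column sums equal
#'   `depth` minus the number of unaligned draws for that sample.
#' @export
subsample_table <- function(x, depth, seed, total_reads = NULL) {
  stopifnot(is_ogu_table(x))
  if (value_kind(x) != "rounded_int") {
    abort("subsampling needs an integer (rounded_int) table")
  }
  if (length(depth) != 1 || is.na(depth) || depth < 1 ||
      depth != trunc(depth)) {
    abort("depth must be a positive integer")
  }
  if (missing(seed) || is.null(seed)) {
    abort("subsample_table requires an explicit seed")
  }
  if (UNALIGNED_ID %in% table_features(x)) {
    abort(paste0("reserved feature id ", UNALIGNED_ID,
                 " already present in the table"))
  }
  if (!is.null(total_reads)) x <- set_total_reads(x, total_reads)
  led <- depth_ledger(x)
  m <- sample_sums(x)
  n <- setNames(led$n, led$sample_id)[names(m)]
  n[is.na(n)] <- m[is.na(n)]
  if (any(n < m - 1e-9)) abort("total reads n below aligned reads m")
  if (any(depth > n)) {
    abort(paste0("depth ", depth, " exceeds total reads for sample(s): ",
                 paste(names(n)[depth > n], collapse = ", ")))
  }
  mat <- as.matrix(x)
  out <- with_local_seed(seed, {
    res <- matrix(0, nrow = nrow(mat), ncol = ncol(mat),
                  dimnames = dimnames(mat))
    for (s in colnames(mat)) {
      counts <- c(mat[, s], round(n[[s]] - m[[s]]))
      urn <- rep.int(seq_along(counts), counts)
      drawn <- urn[sample.int(length(urn), depth)]
      tab <- tabulate(drawn, nbins = length(counts))
      res[, s] <- tab[seq_len(nrow(mat))]  # last bin = unaligned, removed
    }
    res
  })
  tab <- ogu_table_from_matrix(out, value_kind = "rounded_int")
  tab <- drop_empty_features(tab)
  led$m <- unname(colSums(out)[led$sample_id])
  led$n <- rep(as.double(depth), nrow(led))
  set_depth_ledger(tab, led)
}

#' Merge feature tables
#'
#' Axes are unioned in order of appearance; counts of overlapping
#' (feature, sample) cells are summed. All tables must share a value kind.
#'
#' @param ... [ogu_table] objects, or a single list of them.
#' @return The merged [ogu_table].
#' @export
merge_tables <- function(...) {
  tabs <- list(...)
  if (length(tabs) == 1 && !is_ogu_table(tabs[[1]])) tabs <- tabs[[1]]
  stopifnot(length(tabs) >= 1, all(vapply(tabs, is_ogu_table, TRUE)))
  kinds <- unique(vapply(tabs, value_kind, ""))
  if (length(kinds) > 1) {
    abort(paste0("cannot merge tables of different value kinds: ",
                 paste(kinds, collapse = ", ")))
  }
  ogu_table(bind_rows(lapply(tabs, as_tibble)),
            samples = unique(unlist(lapply(tabs, table_samples))),
            features = unique(unlist(lapply(tabs, table_features))),
            value_kind = kinds)
}

#' Read and write feature tables as TSV
#'
#' The dense dialect has features as rows and samples as columns, with the
#' first header cell `#FeatureID`. The sparse dialect is a triplet file with
#' header `#FeatureID<TAB>SampleID<TAB>Count`. Integer tables round-trip
#' losslessly. Negative values and duplicate ids are rejected on read.
#'
#' @param x An [ogu_table].
#' @param path File path.
#' @param format `"dense"` (default) or `"sparse"`.
#' @param value_kind Value kind to stamp on the table read from disk;
#'   `NULL` (default) infers `rounded_int` when all values are integers.
#' @return `write_feature_table()` returns `x` invisibly;
#'   `read_feature_table()` returns an [ogu_table].
#' @export
write_feature_table <- function(x, path, format = c("dense", "sparse")) {
  stopifnot(is_ogu_table(x))
  format <- match.arg(format)
  fmt_num <- function(v) {
    if (value_kind(x) == "rounded_int") format(v, scientific = FALSE)
    else format(v, digits = 15, scientific = FALSE)
  }
  if (format == "dense") {
    m <- as.matrix(x)
    lines <- c(paste(c("#FeatureID", colnames(m)), collapse = "\t"),
               vapply(seq_len(nrow(m)), function(i) {
                 paste(c(rownames(m)[i], trimws(fmt_num(m[i, ]))),
                       collapse = "\t")
               }, ""))
  } else {
    lines <- c("#FeatureID\tSampleID\tCount",
               paste0("#Samples\t", paste(table_samples(x), collapse = "\t")),
               sprintf("%s\t%s\t%s", x$feature_id, x$sample_id,
                       trimws(fmt_num(x$count))))
  }
  writeLines(lines, path)
  invisible(x)
}

#' @rdname write_feature_table
#' @export
read_feature_table <- function(path, value_kind = NULL) {
  lines <- readLines(path, warn = FALSE)
  if (length(lines) == 0) abort(paste0("empty feature table file: ", path))
  header <- strsplit(lines[1], "\t", fixed = TRUE)[[1]]
  sparse <- identical(header, c("#FeatureID", "SampleID", "Count"))
  if (header[1] != "#FeatureID") {
    abort("feature table must start with a '#FeatureID' header")
  }
  if (sparse) {
    samples <- NULL
    body <- lines[-1]
    if (length(body) > 0 && startsWith(body[1], "#Samples\t")) {
      samples <- strsplit(body[1], "\t", fixed = TRUE)[[1]][-1]
      body <- body[-1]
    }
    cells <- strsplit(body, "\t", fixed = TRUE)
    df <- tibble(feature_id = vapply(cells, `[[`, "", 1L),
                 sample_id = vapply(cells, `[[`, "", 2L),
                 count = as.double(vapply(cells, `[[`, "", 3L)))
    if (any(is.na(df$count)) || any(df$count < 0)) {
      abort("negative or non-numeric count in feature table")
    }
    kind <- value_kind %||%
      if (all(df$count == trunc(df$count))) "rounded_int" else "raw_float"
    return(ogu_table(df, samples = samples %||% unique(df$sample_id),
                     features = unique(df$feature_id), value_kind = kind))
  }
  samples <- header[-1]
  if (anyDuplicated(samples)) abort("duplicate sample ids in header")
  rows <- strsplit(lines[-1], "\t", fixed = TRUE)
  feats <- vapply(rows, `[[`, "", 1L)
  if (anyDuplicated(feats)) abort("duplicate feature ids")
  m <- matrix(0, nrow = length(feats), ncol = length(samples),
              dimnames = list(feats, samples))
  for (i in seq_along(rows)) {
    vals <- suppressWarnings(as.double(rows[[i]][-1]))
    if (length(vals) != length(samples) || anyNA(vals)) {
      abort(sprintf("malformed row %d in feature table", i))
    }
    m[i, ] <- vals
  }
  if (any(m < 0)) abort("negative count in feature table")
  kind <- value_kind %||%
    if (all(m == trunc(m))) "rounded_int" else "raw_float"
  ogu_table_from_matrix(m, value_kind = kind)
}
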