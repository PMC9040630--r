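#' Open a possibly compressed alignment file as a text connection
#'
#' Compression is detected from the file's magic bytes (gzip `1f 8b`, bzip2
#' `BZh`, xz `fd 37 7a 58 5a`), falling back to the file extension
#' (`.gz`, `.bz2`, `.xz`/`.lzma`); plain text otherwise. The caller is
#' responsible for closing the connection.
#'
#' @param path Path to the file.
#' @param compression `"auto"` (default) or one of `"none"`, `"gzip"`,
#'   `"bzip2"`, `"lzma"` to force a codec.
#' @return An open read-only text connection.
#' @export
open_alignment <- function(path, compression = "auto") {
  if (!file.exists(path)) abort(paste0("cannot read alignment file: ", path))
  compression <- match.arg(compression,
                           c("auto", "none", "gzip", "bzip2", "lzma"))
  if (compression == "auto") compression <- sniff_compression(path)
  con <- switch(compression,
                none  = file(path, open = "rt"),
                gzip  = gzfile(path, open = "rt"),
                bzip2 = bzfile(path, open = "rt"),
                lzma  = xzfile(path, open = "rt"))
  con
}

sniff_compression <- function(path) {
  magic <- readBin(path, "raw", n = 6L)
  if (length(magic) >= 2 && magic[1] == as.raw(0x1f) && magic[2] == as.raw(0x8b)) {
    return("gzip")
  }
  if (length(magic) >= 3 && rawToChar(magic[1:3]) == "BZh") return("bzip2")
  if (length(magic) >= 6 && identical(magic[1:6],
      as.raw(c(0xfd, 0x37, 0x7a, 0x58, 0x5a, 0x00)))) {
    return("lzma")
  }
  ext <- tolower(tools::file_ext(path))
  switch(ext, gz = "gzip", bz2 = "bzip2", xz = "lzma", lzma = "lzma", "none")
}

# drain a binary connection; decoder warnings (e.g. a truncated xz
# stream) are treated as corruption
drain_connection <- function(opener, path) {
  con <- opener(path)
  on.exit(close(con))
  chunks <- list()
  withCallingHandlers(
    repeat {
      chunk <- readBin(con, "raw", 1048576L)
      if (length(chunk) == 0) break
      chunks[[length(chunks) + 1]] <- chunk
    },
    warning = function(w) {
      abort(paste0("corrupt or unreadable alignment file '", path, "': ",
                   conditionMessage(w)))
    })
  unlist(chunks) %||% raw()
}

read_alignment_lines <- function(path, compression = "auto") {
  if (!file.exists(path)) abort(paste0("cannot read alignment file: ", path))
  compression <- match.arg(compression,
                           c("auto", "none", "gzip", "bzip2", "lzma"))
  if (compression == "auto") compression <- sniff_compression(path)
  corrupt <- function(why) {
    abort(paste0("corrupt or unreadable alignment file '", path, "': ", why))
  }
  body <- switch(compression,
    none = readBin(path, "raw", n = file.size(path)),
    gzip = {
      # connections inflate a truncated gzip stream silently; the trailer's
      # ISIZE field (uncompressed size mod 2^32) exposes the damage
      if (file.size(path) < 18) corrupt("gzip stream shorter than its header")
      out <- drain_connection(function(p) gzfile(p, "rb"), path)
      trailer <- readBin(path, "raw", n = file.size(path))
      isize <- sum(as.double(trailer[length(trailer) - 3:0]) * 256^(0:3))
      if (length(out) %% 2^32 != isize) {
        corrupt("gzip stream truncated (length does not match its trailer)")
      }
      out
    },
    bzip2 = tryCatch(
      memDecompress(readBin(path, "raw", n = file.size(path)),
                    type = "bzip2"),
      error = function(e) corrupt(conditionMessage(e))),
    lzma = drain_connection(function(p) xzfile(p, "rb"), path))
  strsplit(rawToChar(body), "\n", fixed = TRUE)[[1]]
}

# FASTA-header convention: subject ids end at the first whitespace
trim_subject <- function(x) sub("[ \t].*$", "", x)

#' Parse SAM alignment records into query-to-subject hits
#'
#' Header lines (leading `@`) are skipped, as are unmapped records (FLAG bit
#' 0x4) and records with RNAME `*`. Paired mates share a QNAME in SAM; FLAG
#' bits 0x40/0x80 append `/1` or `/2` so each aligned mate is a distinct
#' query contributing its own unit of count. Subjects are deduplicated per
#' query (secondary/supplementary hits to the same genome count once).
#'
#' @param lines Character vector of SAM text lines.
#' @return A tibble with columns `query_id`, `subject_id`, one row per
#'   distinct (query, subject) pair.
#' @export
parse_sam <- function(lines) {
  body <- lines[!startsWith(lines, "@") & nzchar(lines)]
  if (length(body) == 0) return(tibble(query_id = character(),
                                       subject_id = character()))
  fields <- strsplit(body, "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf < 11)) {
    abort(sprintf("SAM record with fewer than 11 fields at data line %d",
                  which(nf < 11)[1]))
  }
  qname <- vapply(fields, `[[`, "", 1L)
  flag <- suppressWarnings(as.integer(vapply(fields, `[[`, "", 2L)))
  if (any(is.na(flag))) {
    abort(sprintf("non-numeric SAM FLAG at data line %d", which(is.na(flag))[1]))
  }
  rname <- vapply(fields, `[[`, "", 3L)
  mate <- ifelse(bitwAnd(flag, 0x40L) > 0L, "/1",
                 ifelse(bitwAnd(flag, 0x80L) > 0L, "/2", ""))
  keep <- bitwAnd(flag, 0x4L) == 0L & rname != "*"
  out <- tibble(query_id = paste0(qname, mate)[keep],
                subject_id = trim_subject(rname[keep]))
  distinct(out, .data$query_id, .data$subject_id)
}

#' Parse BLAST tabular (-outfmt 6) lines into query-to-subject hits
#'
#' Only the first two columns (query, subject) are used; percent identity,
#' e-value and the rest are ignored — the unit of evidence is the hit itself.
#'
#' @param lines Character vector of tab-separated lines.
#' @return A tibble with columns `query_id`, `subject_id` (deduplicated).
#' @export
parse_blast6 <- function(lines) {
  body <- lines[nzchar(lines)]
  if (length(body) == 0) return(tibble(query_id = character(),
                                       subject_id = character()))
  fields <- strsplit(body, "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf < 2)) {
    abort(sprintf("BLAST tabular line %d has fewer than 2 columns",
                  which(nf < 2)[1]))
  }
  out <- tibble(query_id = vapply(fields, `[[`, "", 1L),
                subject_id = trim_subject(vapply(fields, `[[`, "", 2L)))
  distinct(out, .data$query_id, .data$subject_id)
}

#' Parse a plain query-to-subject map into hits
#'
#' Each nonempty line is `query<TAB>subject`. Lines for one query need not
#' be adjacent; hits are accumulated over the whole input and deduplicated.
#'
#' @param lines Character vector of lines.
#' @return A tibble with columns `query_id`, `subject_id` (deduplicated).
#' @export
parse_map <- function(lines) {
  body <- lines[nzchar(lines)]
  if (length(body) == 0) return(tibble(query_id = character(),
                                       subject_id = character()))
  fields <- strsplit(body, "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf != 2)) {
    abort(sprintf("mapping line %d does not have exactly 2 fields",
                  which(nf != 2)[1]))
  }
  out <- tibble(query_id = vapply(fields, `[[`, "", 1L),
                subject_id = trim_subject(vapply(fields, `[[`, "", 2L)))
  distinct(out, .data$query_id, .data$subject_id)
}

#' Split multiplexed query ids into sample and per-sample query
#'
#' Multiplexed alignments prefix every query id with its sample:
#' `S1_r001` under delimiter `_` belongs to sample `S1` as read `r001`.
#' Only the first delimiter occurrence splits. Ids without the delimiter
#' get `NA` as sample (the caller substitutes the filename stem).
#'
#' @param query_id Character vector of query ids.
#' @param delimiter Nonempty delimiter string (default `"_"`).
#' @return Tibble with columns `sample_id`, `query_id`.
#' @export
demultiplex <- function(query_id, delimiter = "_") {
  if (!nzchar(delimiter)) abort("demultiplex delimiter must be nonempty")
  if (any(!nzchar(query_id))) abort("empty query id cannot be demultiplexed")
  pos <- regexpr(delimiter, query_id, fixed = TRUE)
  has <- pos > 0L
  tibble(
    sample_id = ifelse(has, substr(query_id, 1L, pos - 1L), NA_character_),
    query_id = ifelse(has, substr(query_id, pos + nchar(delimiter),
                                  nchar(query_id)), query_id))
}

# strip known alignment and compression extensions from a filename
sample_stem <- function(path) {
  stem <- basename(path)
  stem <- sub("\\.(gz|bz2|xz|lzma)$", "", stem, ignore.case = TRUE)
  sub("\\.(sam|b6o|blast6|m8|tsv|txt|map)$", "", stem, ignore.case = TRUE)
}

sniff_format <- function(path, lines) {
  ext <- tolower(tools::file_ext(sub("\\.(gz|bz2|xz|lzma)$", "", basename(path),
                                     ignore.case = TRUE)))
  if (ext == "sam") return("sam")
  if (ext %in% c("b6o", "blast6", "m8")) return("blast6")
  if (ext == "map") return("map")
  body <- lines[nzchar(lines)]
  if (length(body) == 0) return("map")
  if (any(startsWith(body, "@"))) return("sam")
  f1 <- strsplit(body[1], "\t", fixed = TRUE)[[1]]
  nf <- length(f1)
  # SAM without header: >= 11 fields with an integer FLAG in column 2;
  # BLAST6 column 2 is a subject id
  if (nf >= 11 && grepl("^[0-9]+$", f1[2])) "sam"
  else if (nf > 2) "blast6"
  else "map"
}

#' Read alignment files into per-sample hit groups
#'
#' The entry point of the profiling workflow: reads one or more alignment
#' files in SAM, BLAST tabular (-outfmt 6) or plain mapping format —
#' optionally gzip/bzip2/xz compressed — and returns one row per
#' (sample, query, subject genome) hit. A query hitting k genomes appears in
#' k rows; [tally_hits()] turns these into 1/k-apportioned counts.
#'
#' Sample assignment: with `demux = TRUE` query ids are split on
#' `delimiter` and the prefix is the sample; with `demux = FALSE` every
#' query in a file belongs to one sample named by `sample_id` (or the
#' filename stem). The default `demux = NULL` demultiplexes only when every
#' query id contains the delimiter.
#'
#' @param paths Character vector of alignment file paths.
#' @param format `"auto"` (default; sniffs extension then content) or one of
#'   `"sam"`, `"blast6"`, `"map"`.
#' @param compression Passed to [open_alignment()].
#' @param demux `TRUE`, `FALSE`, or `NULL` (auto).
#' @param delimiter Demultiplexing delimiter, default `"_"`.
#' @param sample_id Optional explicit sample names, recycled along `paths`;
#'   defaults to filename stems. Ignored for queries that demultiplex.
#' @return A tibble of hits: `sample_id`, `query_id`, `subject_id`.
#' @examples
#' f <- tempfile(fileext = ".map")
#' writeLines(c("S1_r1\tG1", "S1_r1\tG2", "S2_r1\tG1"), f)
#' read_alignment(f)
#' @export
read_alignment <- function(paths, format = "auto", compression = "auto",
                           demux = NULL, delimiter = "_", sample_id = NULL) {
  format <- match.arg(format, c("auto", "sam", "blast6", "map"))
  if (!is.null(sample_id)) sample_id <- rep_len(sample_id, length(paths))
  res <- Map(function(path, i) {
    lines <- read_alignment_lines(path, compression)
    fmt <- if (format == "auto") sniff_format(path, lines) else format
    hits <- switch(fmt,
                   sam = parse_sam(lines),
                   blast6 = parse_blast6(lines),
                   map = parse_map(lines))
    fallback <- if (is.null(sample_id)) sample_stem(path) else sample_id[i]
    assign_samples(hits, demux, delimiter, fallback)
  }, paths, seq_along(paths))
  bind_rows(res)
}

assign_samples <- function(hits, demux, delimiter, fallback) {
  if (nrow(hits) == 0) {
    return(tibble(sample_id = character(), query_id = character(),
                  subject_id = character()))
  }
  dm <- demultiplex(hits$query_id, delimiter)
  use_demux <- if (is.null(demux)) !anyNA(dm$sample_id) else isTRUE(demux)
  if (use_demux) {
    if (anyNA(dm$sample_id)) dm$sample_id[is.na(dm$sample_id)] <- fallback
    tibble(sample_id = dm$sample_id, query_id = dm$query_id,
           subject_id = hits$subject_id)
  } else {
    tibble(sample_id = fallback, query_id = hits$query_id,
           subject_id = hits$subject_id)
  }
}
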