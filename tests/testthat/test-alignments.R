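sam_record <- function(qname, flag, rname) {
  paste(qname, flag, rname, "1", "42", "100M", "*", "0", "0", "*", "*",
        sep = "\t")
}

test_that("SAM parsing skips headers and unmapped records and dedups hits", {
  lines <- c("@HD\tVN:1.6",
             "@SQ\tSN:G1\tLN:100",
             sam_record("r0", 4, "*"),
             sam_record("r1", 0, "G1"),
             sam_record("r1", 256, "G2"),
             sam_record("r1", 256, "G1"),
             sam_record("r2", 0, "G1"))
  hits <- parse_sam(lines)
  expect_equal(hits$query_id, c("r1", "r1", "r2"))
  expect_setequal(hits$subject_id[hits$query_id == "r1"], c("G1", "G2"))
  expect_equal(hits$subject_id[hits$query_id == "r2"], "G1")
})

test_that("SAM paired mates become distinct queries via flag bits", {
  lines <- c(sam_record("r1", 0x40 + 1, "G1"),
             sam_record("r1", 0x80 + 1, "G2"))
  hits <- parse_sam(lines)
  expect_setequal(hits$query_id, c("r1/1", "r1/2"))
  # each aligned mate contributes its own unit of count
  tab <- tally_hits(cbind(sample_id = "s", hits))
  expect_equal(unname(sample_sums(tab)), 2)
})

test_that("malformed SAM and BLAST6 records raise parse errors", {
  expect_error(parse_sam("r1\t0\tG1"), "fewer than 11 fields")
  expect_error(parse_blast6("justone"), "fewer than 2 columns")
  expect_error(parse_map("a\tb\tc"), "exactly 2 fields")
})

test_that("BLAST6 keeps only query and subject, deduplicated", {
  lines <- c("q1\tG1\t99.1\t100\t0\t0\t1\t100\t5\t105\t1e-30\t180",
             "q1\tG2\t98.0\t100\t0\t0\t1\t100\t5\t105\t1e-28\t175",
             "q1\tG1\t97.0\t50\t0\t0\t1\t50\t5\t55\t1e-10\t90",
             "q2\tG1\t99.9\t100\t0\t0\t1\t100\t5\t105\t1e-40\t190")
  hits <- parse_blast6(lines)
  expect_equal(nrow(hits), 3)
  expect_setequal(hits$subject_id[hits$query_id == "q1"], c("G1", "G2"))
})

test_that("map parsing aggregates non-adjacent lines per query", {
  # oracle: accumulate subject sets over the whole file in a named list
  lines <- c("q1\tG1", "q2\tG2", "q1\tG2", "q1\tG1")
  oracle <- list()
  for (l in lines) {
    f <- strsplit(l, "\t")[[1]]
    oracle[[f[1]]] <- union(oracle[[f[1]]], f[2])
  }
  hits <- parse_map(lines)
  got <- split(hits$subject_id, hits$query_id)
  expect_equal(lapply(got, sort), lapply(oracle, sort)[names(got)])
})

test_that("demultiplexing splits at the first delimiter only", {
  expect_equal(demultiplex("S1_r001"),
               tibble::tibble(sample_id = "S1", query_id = "r001"))
  expect_equal(demultiplex("S1_r_001")$query_id, "r_001")
  expect_true(is.na(demultiplex("r001")$sample_id))
  expect_error(demultiplex(""), "empty query id")
  expect_error(demultiplex("x", delimiter = ""), "nonempty")
})

test_that("queries without the delimiter fall back to the filename stem", {
  f <- file.path(tempdir(), "sampleA.map")
  writeLines(c("r001\tG1", "r002\tG2"), f)
  hits <- read_alignment(f)
  expect_equal(unique(hits$sample_id), "sampleA")
})

test_that("parsing is insensitive to compression, which is sniffed by magic bytes", {
  lines <- c("S1_r1\tG1", "S1_r2\tG2", "S2_r1\tG1")
  plain <- tempfile(fileext = ".map")
  writeLines(lines, plain)
  ref <- read_alignment(plain)
  for (comp in c("gzip", "bzip2", "lzma")) {
    # deliberately misleading extension: detection must use magic bytes
    path <- tempfile(fileext = ".map")
    con <- switch(comp, gzip = gzfile(path, "w"), bzip2 = bzfile(path, "w"),
                  lzma = xzfile(path, "w"))
    writeLines(lines, con)
    close(con)
    expect_equal(read_alignment(path), ref, ignore_attr = TRUE)
  }
})

test_that("a truncated gzip body is reported as corrupt", {
  good <- tempfile(fileext = ".gz")
  con <- gzfile(good, "wb")
  writeLines(rep("S1_r1\tG1", 2000), con)
  close(con)
  raw <- readBin(good, "raw", file.size(good))
  bad <- tempfile(fileext = ".gz")
  writeBin(raw[1:(length(raw) - 30)], bad)
  expect_error(read_alignment(bad), "corrupt|unreadable")
})

test_that("hit groups round-trip through all formats and compressions", {
  sim <- simulate_reads(ogu_scenario(n_samples = 2, n_genomes = 6,
                                     reads_per_sample = 40, seed = 5))
  # demultiplexing strips the sample prefix from query ids, so the
  # reference hit groups carry the trimmed ids too
  ref <- sim$hits
  ref$query_id <- sub("^[^_]*_", "", ref$query_id)
  ref <- dplyr::arrange(ref, sample_id, query_id, subject_id)
  for (fmt in c("map", "sam", "blast6")) {
    for (comp in c("none", "gzip")) {
      dir <- file.path(tempdir(), paste0("rt_", fmt, "_", comp))
      write_alignments(sim, dir, format = fmt, compression = comp)
      got <- read_alignment(list.files(dir, full.names = TRUE))
      got <- dplyr::arrange(got, sample_id, query_id, subject_id)
      expect_equal(got, ref, ignore_attr = TRUE)
    }
  }
  # per-sample files: sample from filename stem, same hit groups
  dir <- file.path(tempdir(), "rt_persample")
  write_alignments(sim, dir, format = "map", multiplexed = FALSE)
  got <- read_alignment(list.files(dir, full.names = TRUE))
  expect_equal(dplyr::arrange(got, sample_id, query_id, subject_id),
               ref, ignore_attr = TRUE)
})

test_that("for unpaired unique-hit SAM, hit groups equal mapped records", {
  lines <- c("@HD\tVN:1.6",
             vapply(1:25, function(i) {
               sam_record(paste0("r", i), 0, paste0("G", i %% 4 + 1))
             }, ""),
             sam_record("rX", 4, "*"))
  hits <- parse_sam(lines)
  expect_equal(nrow(hits), 25)
  expect_equal(length(unique(hits$query_id)), 25)
})
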