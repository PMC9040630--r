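hits_tbl <- function(...) {
  rows <- list(...)
  tibble::tibble(sample_id = vapply(rows, `[[`, "", 1),
                 query_id = vapply(rows, `[[`, "", 2),
                 subject_id = vapply(rows, `[[`, "", 3))
}

test_that("tally apportions each query 1/k across its k hit genomes", {
  # k = 1
  t1 <- tally_hits(hits_tbl(c("s", "q1", "G1")))
  expect_equal(as.matrix(t1)["G1", "s"], 1.0)
  # k = 2
  t2 <- tally_hits(hits_tbl(c("s", "q1", "G1"), c("s", "q1", "G2")))
  expect_equal(unname(as.matrix(t2)[c("G1", "G2"), "s"]), c(0.5, 0.5))
  # three queries all hitting the same trio: symmetry and conservation
  rows <- unlist(lapply(1:3, function(q) {
    lapply(paste0("G", 1:3), function(g) c("s", paste0("q", q), g))
  }), recursive = FALSE)
  t3 <- tally_hits(do.call(hits_tbl, rows))
  expect_equal(unname(as.matrix(t3)[, "s"]), rep(1, 3))
  expect_equal(unname(sample_sums(t3)), 3)
})

test_that("pre-rounding column sums equal aligned query counts for any k mix", {
  for (seed in 1:5) {
    sim <- simulate_reads(ogu_scenario(n_samples = 3, n_genomes = 10,
                                       reads_per_sample = 150, seed = seed))
    tab <- tally_hits(sim$hits)
    led <- depth_ledger(tab)
    expect_equal(unname(sample_sums(tab)[led$sample_id]), led$m,
                 tolerance = 1e-9)
  }
})

test_that("tally is order-independent", {
  sim <- simulate_reads(ogu_scenario(n_samples = 2, n_genomes = 8,
                                     reads_per_sample = 60, seed = 3))
  shuffled <- withr::with_seed(1, sim$hits[sample(nrow(sim$hits)), ])
  a <- as.matrix(tally_hits(sim$hits))
  b <- as.matrix(tally_hits(shuffled))  # axis order follows appearance
  expect_equal(b[rownames(a), colnames(a)], a)
})

test_that("rounding is half-to-even and drops zeros; always_even is different", {
  tab <- ogu_table(tibble::tibble(
    feature_id = c("a", "b", "c", "d"), sample_id = "s",
    count = c(2.5, 3.5, 0.25, 7)))
  r <- round_counts(tab)
  m <- as.matrix(r)
  expect_equal(m["a", "s"], 2)  # 2.5 rounds down to even
  expect_equal(m["b", "s"], 4)  # 3.5 rounds up to even
  expect_false("c" %in% rownames(m))  # rounds to 0, dropped from storage
  expect_equal(m["d", "s"], 7)  # integers unchanged
  ae <- as.matrix(round_counts(tab, mode = "always_even"))
  expect_equal(ae["b", "s"], 4)
  expect_equal(ae["d", "s"], 8)  # snapped to nearest even integer
  # an all-integer table is a fixed point
  expect_equal(as.matrix(round_counts(r)), m)
})

test_that("rounded sums stay within the per-sample rounding bound", {
  for (seed in 1:5) {
    sim <- simulate_reads(ogu_scenario(n_samples = 3, n_genomes = 12,
                                       reads_per_sample = 200, seed = seed))
    raw <- tally_hits(sim$hits)
    r <- round_counts(raw)
    led <- depth_ledger(r)
    nz <- table(factor(raw$sample_id, levels = led$sample_id))
    drift <- abs(sample_sums(r)[led$sample_id] - led$m)
    expect_true(all(drift <= 0.5 * as.numeric(nz)))
  }
})

test_that("relative-abundance filtering is per sample, strict, and idempotent", {
  m <- matrix(c(99, 1, 50, 50), 2, 2,
              dimnames = list(c("A", "B"), c("s1", "s2")))
  tab <- ogu_table_from_matrix(m)
  f <- filter_rel_abund(tab, 0.02)
  fm <- as.matrix(f)
  expect_equal(fm["B", "s1"], 0)   # 1% < 2%, removed in s1 only
  expect_equal(fm["B", "s2"], 50)  # untouched in s2
  # the conventional 0.01% per-sample cutoff
  tab2 <- ogu_table_from_matrix(matrix(c(19999, 1), 2, 1,
                                       dimnames = list(c("A", "B"), "s")))
  expect_false("B" %in% rownames(as.matrix(filter_rel_abund(tab2, 1e-4))))
  # exactly at threshold is kept
  tab3 <- ogu_table_from_matrix(matrix(c(98, 2), 2, 1,
                                       dimnames = list(c("A", "B"), "s")))
  expect_true("B" %in% rownames(as.matrix(filter_rel_abund(tab3, 0.02))))
  # threshold 0 is the identity; filtering twice changes nothing more
  expect_equal(as.matrix(filter_rel_abund(tab, 0)), m)
  expect_equal(as.matrix(filter_rel_abund(f, 0.02)), fm)
})

test_that("prevalence filtering drops features seen in too few samples", {
  m <- matrix(c(1, 0, 0,
                1, 1, 0,
                5, 5, 5), 3, 3, byrow = TRUE,
              dimnames = list(c("once", "twice", "thrice"),
                              paste0("s", 1:3)))
  tab <- ogu_table_from_matrix(m)
  expect_setequal(rownames(as.matrix(filter_prevalence(tab, 2))),
                  c("twice", "thrice"))
  expect_equal(as.matrix(filter_prevalence(tab, 1)), as.matrix(tab))
})

test_that("size normalization divides by genome length and scales", {
  m <- matrix(c(10, 10), 2, 1, dimnames = list(c("A", "B"), "s"))
  tab <- ogu_table_from_matrix(m)
  sizes <- c(A = 1e6, B = 2e6)
  norm <- normalize_by_size(tab, sizes, scale = 1e6)
  expect_equal(unname(as.matrix(norm)[, "s"]), c(10, 5))
  expect_equal(value_kind(norm), "normalized_float")
  # equal sizes with scale = size cancel out
  same <- normalize_by_size(tab, c(A = 500, B = 500), scale = 500)
  expect_equal(as.matrix(same), m)
  expect_error(normalize_by_size(tab, c(A = 1e6)), "B")
})

test_that("merging unions axes and sums overlapping cells", {
  t1 <- ogu_table_from_matrix(matrix(2, 1, 1, dimnames = list("A", "s1")))
  t2 <- ogu_table_from_matrix(matrix(3, 1, 1, dimnames = list("A", "s1")))
  t3 <- ogu_table_from_matrix(matrix(7, 1, 1, dimnames = list("B", "s2")))
  expect_equal(as.matrix(merge_tables(t1, t2))["A", "s1"], 5)
  merged <- as.matrix(merge_tables(t1, t3))
  expect_equal(dim(merged), c(2L, 2L))
  expect_equal(merged["B", "s1"], 0)
  raw <- ogu_table(tibble::tibble(feature_id = "A", sample_id = "s1",
                                  count = 0.5))
  expect_error(merge_tables(t1, raw), "value kinds")
})

test_that("tables round-trip through dense and sparse TSV", {
  for (seed in 1:3) {
    tab <- random_table(12, 4, seed)
    for (fmt in c("dense", "sparse")) {
      path <- tempfile(fileext = ".tsv")
      write_feature_table(tab, path, format = fmt)
      back <- read_feature_table(path)
      expect_equal(as.matrix(back), as.matrix(tab))
      expect_equal(value_kind(back), "rounded_int")
    }
  }
  # a raw float table survives dense round-trip within precision
  raw <- tally_hits(hits_tbl(c("s", "q1", "G1"), c("s", "q1", "G2"),
                             c("s", "q2", "G1"), c("s", "q2", "G3"),
                             c("s", "q2", "G4")))
  path <- tempfile(fileext = ".tsv")
  write_feature_table(raw, path)
  expect_equal(as.matrix(read_feature_table(path)), as.matrix(raw),
               tolerance = 1e-12)
})

test_that("table reading rejects negatives and duplicates", {
  path <- tempfile()
  writeLines(c("#FeatureID\ts1", "A\t-3"), path)
  expect_error(read_feature_table(path), "negative")
  writeLines(c("#FeatureID\ts1", "A\t3", "A\t4"), path)
  expect_error(read_feature_table(path), "duplicate")
  writeLines(c("#FeatureID\ts1\ts1", "A\t3\t4"), path)
  expect_error(read_feature_table(path), "duplicate")
})

test_that("an empty table writes a header-only file", {
  tab <- ogu_table(tibble::tibble(feature_id = character(),
                                  sample_id = character(), count = double()),
                   value_kind = "rounded_int")
  path <- tempfile()
  write_feature_table(tab, path)
  expect_equal(readLines(path), "#FeatureID")
})
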