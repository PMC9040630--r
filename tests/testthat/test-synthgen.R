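test_that("the conceptual fixture satisfies every printed constraint", {
  fx <- conceptual_fixture()
  m <- as.matrix(fx$table)
  expect_equal(unname(colSums(m)), c(12, 12, 12))
  expect_equal(dim(m), c(10L, 3L))
  expect_equal(sum(fx$taxonomy$rank == "species"), 5)
  expect_equal(sum(fx$taxonomy$rank == "genus"), 3)
  expect_equal(sum(fx$taxonomy$rank == "family"), 1)
  # species S1 has identical summed frequency in all three samples
  sp <- as.matrix(collapse_table(fx$table, fx$taxonomy, "species"))
  expect_equal(length(unique(sp["S1", ])), 1)
  # O5 and O7 (both in S3) carry equal counts within samples B and C
  expect_equal(ogun:::ancestor_at_rank(fx$taxonomy, c("O5", "O7"), "species"),
               c("S3", "S3"))
  expect_equal(m["O5", "B"], m["O7", "B"])
  expect_equal(m["O5", "C"], m["O7", "C"])
  # samples A and B share O6 and O9
  expect_true(all(m[c("O6", "O9"), c("A", "B")] > 0))
  # phylogeny: O1-O2 sisters with O3 next; O4-O5 sisters across genera
  coph <- ape::cophenetic.phylo(fx$tree)
  expect_lt(coph["O1", "O2"], coph["O1", "O3"])
  expect_lt(coph["O1", "O3"], min(coph["O1", c("O6", "O8", "O10")]))
  expect_lt(coph["O4", "O5"], min(coph["O4", c("O1", "O6", "O8")]))
  expect_false(ogun:::ancestor_at_rank(fx$taxonomy, "O4", "genus") ==
                 ogun:::ancestor_at_rank(fx$taxonomy, "O5", "genus"))
})

test_that("scenario generation and read simulation are seed-deterministic", {
  a <- simulate_reads(ogu_scenario(n_samples = 3, n_genomes = 10,
                                   reads_per_sample = 100, seed = 17))
  b <- simulate_reads(ogu_scenario(n_samples = 3, n_genomes = 10,
                                   reads_per_sample = 100, seed = 17))
  expect_identical(a$hits, b$hits)
  expect_identical(as.matrix(a$truth), as.matrix(b$truth))
  c <- simulate_reads(ogu_scenario(n_samples = 3, n_genomes = 10,
                                   reads_per_sample = 100, seed = 18))
  expect_false(identical(a$hits, c$hits))
  # and the written files are byte-identical
  d1 <- file.path(tempdir(), "det1")
  d2 <- file.path(tempdir(), "det2")
  f1 <- write_alignments(a, d1, format = "map")
  f2 <- write_alignments(b, d2, format = "map")
  expect_identical(readLines(f1), readLines(f2))
})

test_that("with every read aligned and unique hits, tallying recovers the truth", {
  sim <- simulate_reads(ogu_scenario(n_samples = 3, n_genomes = 12,
                                     reads_per_sample = 400,
                                     aligned_fraction = 1,
                                     k_probs = c("1" = 1), seed = 2))
  tab <- round_counts(tally_hits(sim$hits))
  truth <- as.matrix(sim$truth)
  expect_equal(as.matrix(tab)[rownames(truth), colnames(truth)], truth)
})

test_that("multi-mapped simulation conserves per-sample mass before rounding", {
  sim <- simulate_reads(ogu_scenario(n_samples = 2, n_genomes = 10,
                                     reads_per_sample = 300,
                                     aligned_fraction = 1,
                                     k_probs = c("2" = 1), seed = 6))
  tab <- tally_hits(sim$hits)
  led <- depth_ledger(tab)
  expect_equal(unname(sample_sums(tab)[led$sample_id]), led$m,
               tolerance = 1e-9)
  # every query hit exactly 2 genomes
  k <- table(table(sim$hits$query_id))
  expect_equal(names(k), "2")
})

test_that("recovery of true abundances improves with sequencing depth", {
  med_bc <- vapply(c(500, 5000, 50000), function(depth) {
    sc <- ogu_scenario(n_samples = 4, n_genomes = 30,
                       reads_per_sample = depth, aligned_fraction = 1,
                       k_probs = c("1" = 1), seed = 21)
    tab <- round_counts(tally_hits(simulate_reads(sc)$hits))
    m <- as.matrix(tab)
    median(vapply(sc$samples, function(s) {
      est <- m[, s] / sum(m[, s])
      truth <- sc$abundances[rownames(m), s]
      bray_curtis(est, truth)
    }, 0))
  }, 0)
  expect_lt(med_bc[3], 0.02)          # deep samples recover the community
  expect_true(all(diff(med_bc) < 0))  # monotone improvement with depth
})

test_that("abundance-weighted distances are robust to multi-mapping ambiguity", {
  sc1 <- ogu_scenario(n_samples = 8, n_genomes = 30,
                      reads_per_sample = 5000, aligned_fraction = 1,
                      k_probs = c("1" = 1), seed = 31)
  sck <- ogu_scenario(n_samples = 8, n_genomes = 30,
                      reads_per_sample = 5000, aligned_fraction = 1,
                      k_probs = c("1" = 0.8, "2" = 0.15, "4" = 0.05),
                      seed = 31)
  t1 <- round_counts(tally_hits(simulate_reads(sc1)$hits))
  tk <- round_counts(tally_hits(simulate_reads(sck)$hits))
  for (metric in c("weighted-unifrac", "braycurtis")) {
    d1 <- as.matrix(beta_diversity(t1, metric, tree = sc1$tree))
    dk <- as.matrix(beta_diversity(tk, metric, tree = sc1$tree))
    s <- rownames(d1)
    r <- stats::cor(d1[upper.tri(d1)], dk[s, s][upper.tri(d1)])
    expect_gt(r, 0.95)
  }
})

test_that("random phylogenies are reproducible rooted binary trees", {
  expect_error(random_phylogeny(1, seed = 1), "at least 2")
  cherry <- random_phylogeny(2, seed = 1)
  expect_equal(ape::Ntip(cherry), 2)
  t1 <- random_phylogeny(9, seed = 5)
  expect_equal(sort(t1$tip.label), sort(paste0("t", 1:9)))
  expect_identical(write_newick(t1), write_newick(random_phylogeny(9, seed = 5)))
  expect_true(all(t1$edge.length >= 0))
  expect_true(ape::is.rooted(t1))
  expect_true(ape::is.binary(t1))
})
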