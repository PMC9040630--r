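---
title: "Operational genomic units: model, parameters and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Operational genomic units: model, parameters and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ogun)
```

## The model

Reference-based shotgun metagenomics usually compresses read-to-genome
alignments into taxonomic profiles before any ecology is done. That step
throws information away twice: reads from distinct genomes of one species
become indistinguishable, and reads whose genome has no (or a wrong)
taxonomic assignment are misplaced. The operational genomic unit (OGU)
approach keeps the individual reference genome as the feature. Each aligned
read contributes one unit of evidence; when it aligns equally well to `k`
genomes, each genome receives `1/k`. Frequencies are summed over the whole
alignment and only then rounded half-to-even, so the per-sample sum of the
table stays equal to the number of aligned reads up to rounding. The table
is taxonomy-free, and community ecology proceeds directly on it — ideally
with phylogeny-aware metrics (UniFrac against a genome phylogeny), since at
genome resolution a phylogeny is what relates the features to one another.

Three properties make this worth the trouble, and all three are what the
test suite pins down:

* **Conservation.** Before rounding, each sample's column sum equals its
  aligned read count exactly (to floating-point tolerance); after
  half-to-even rounding the drift is bounded by half the number of nonzero
  entries. With unique hits only (`k = 1`) the rounded table is exact.
* **Resolution.** The bundled three-community example (`conceptual_fixture()`)
  shows genus-level Bray-Curtis declaring two samples similar that share no
  genome at all, while the OGU-level view separates them and weighted
  UniFrac on the phylogeny joins the pair that truly shares genomes and
  branches.
* **Depth robustness.** Because abundance-weighted metrics are dominated by
  common taxa, group separation (PERMANOVA pseudo-F) survives aggressive
  rarefaction; presence/absence metrics do not. The acceptance suite
  reproduces this contrast at desk scale.

## From alignments to a table

`read_alignment()` accepts SAM, BLAST tabular (`-outfmt 6`) and plain
two-column query-to-subject maps, plain or gzip/bzip2/xz-compressed.
Compression is detected from magic bytes with the file extension as
fallback. Decompression deliberately goes through whole-stream routes that
can detect truncation: a gzip stream is checked against its trailer's
ISIZE field, a bzip2 stream through `memDecompress()`, and an xz stream by
promoting the decoder's warnings to errors. A silently shortened alignment
file would bias every downstream count, so corruption is an error, never a
warning.

Decisions a SAM parser has to make, and the ones taken here:

* Paired mates share a QNAME; FLAG bits 0x40/0x80 are used to suffix
  `/1`/`/2` so each aligned mate counts once. This keeps the accounting
  per sequence; the convention is configurable in the sense that map and
  BLAST inputs are taken verbatim.
* Unmapped records (FLAG 0x4, or RNAME `*`) contribute nothing.
* CIGAR, MAPQ and alignment scores are ignored: the unit of evidence is
  the hit itself, and score-based filtering belongs to the aligner.
* Subject ids are truncated at the first whitespace (FASTA header
  convention).
* Multiplexed files are demultiplexed at the first occurrence of the
  delimiter (default `_`); per-sample files take the sample from the
  filename stem.

`tally_hits()` performs the `1/k` apportionment and records the per-sample
aligned count `m` in a depth ledger that travels with the table.
`round_counts()` applies half-to-even rounding — the reading of "nearest
even integer" under which near-conservation actually holds; the literal
always-to-even alternative (`mode = "always_even"`) is exposed for
comparison but would double-quantize every value and is not endorsed.
Rounding happens once, after the full alignment is processed, never per
read.

## Table operations

* `filter_rel_abund()` zeroes entries strictly below a per-sample
  relative-abundance threshold, computed from the column sum before any
  removal; entries exactly at the threshold stay. The conventional cutoff
  in this line of work is 0.01% (`1e-4`), typically combined with
  `filter_prevalence(min_samples = 2)`. Filtering is defined on the rounded
  table: the threshold is a post-hoc table operation, not part of the
  tally.
* `normalize_by_size()` divides by genome length and multiplies by `scale`
  (default 1), converting sequence abundance toward taxonomic abundance.
  The result is a float table and is not re-rounded unless asked.
* `subsample_table()` rarefies without replacement. Each sample's column is
  augmented with a reserved `__UNALIGNED__` feature of frequency `n - m`
  (total minus aligned reads), `depth` items are drawn from that n-item urn
  (multivariate hypergeometric), and the reserved feature is removed again.
  This mimics sequencing fewer reads rather than resampling the aligned
  fraction only. A name collision with the reserved feature is an error,
  not a silent rename. Draws are deterministic given `seed`; the replicate
  convention used in the depth-robustness analyses is seeds 0–9.

## Taxonomy and trees

Three taxonomy dialects are parsed into one child-to-parent structure:
Greengenes-style lineage strings, NCBI-style taxdump (`nodes.dmp` /
`names.dmp`, scientific names only), and plain child-to-parent maps (one
file per rank or a single file). Lineages with an empty middle rank below
which nonempty ranks appear are rejected: silently bridging such gaps would
create ambiguous nodes. In the map dialect the root never occurs as a
child, so its rank is inferred from its children's rank when they agree.

`collapse_table()` adds each feature's counts to its ancestor at the
requested rank; features without such an ancestor pool into `Unassigned`
(with a warning when the feature is missing from the taxonomy entirely),
and per-sample sums are conserved exactly at every rank.

`taxonomy_to_tree()` converts a taxonomy restricted to the seven standard
ranks into a rooted tree in which every branch between adjacent ranks has
length 1. Lineages that skip an intermediate rank, or end above species
level, are completed with deterministic placeholder nodes named
`<child>__incertae_<rank>`; the contract preserved is that all taxa of one
rank sit at one depth — in fact every tip is padded to species depth, so
all tip-to-root path lengths are equal. Such a tree drives UniFrac when no
genome phylogeny is available, at the cost of the resolution a real
phylogeny would add.

`collapse_phylogeny()` goes the other way: given a genome phylogeny and a
taxonomy whose units at the chosen rank are monophyletic, each unit's clade
is replaced by a single tip carrying the clade's stem branch length. Tips
not covered by any unit are pruned first; a non-monophyletic unit is an
error that names the unit and the intruding tips. The stem length was
chosen over alternatives (mean tip depth) to keep the operation purely
topological. A unit whose clade is the entire tree gets stem length 0.

## Diversity statistics

Bray-Curtis and Jaccard follow their textbook definitions. Both UniFrac
variants accumulate per-branch descendant mass in one postorder pass;
the unweighted variant compares presence of descendants, the weighted
variant sums `l_b |p_x(b) − p_y(b)|` over branches with `p_s(b)` the
fraction of sample `s`'s counts descending through `b`. The default
weighted UniFrac is the unnormalized variant — the quantity most tools
mean by that name; the normalized variant (divide by
`Σ l_b (p_x + p_y)`, range [0, 1]) is a flag. On a unit-branch star tree
the unnormalized variant equals the Manhattan distance of the
relative-abundance vectors, which the tests exploit as an algebraic
oracle alongside a naive per-branch brute force.

PCoA is classical scaling (double-centered squared distances,
eigendecomposition) via `stats::cmdscale`, with axes restricted to
positive eigenvalues and negative eigenvalues reported untouched — no
Cailliez or Lingoes correction, so a non-Euclidean matrix is visible to
the user rather than papered over.

PERMANOVA uses the pseudo-F from within/between sums of squared distances
and a label-permutation p-value with the +1 correction, so p is never 0
and never below `1/(permutations + 1)`. The default is 999 permutations —
the conventional default; published analyses sometimes use far more, and
the count is a parameter everywhere. An exhaustive mode enumerates all
distinct relabelings for small designs; the test suite checks it against
an independently coded projection-algebra oracle and against vegan's
`adonis2`.

`relative_distance_ratio()` implements the site-clustering statistic: for
each sample of a focal site, the mean distance to the other focal sites'
samples divided by the mean distance to non-focal samples, with the
sample's own site excluded from both means. The distribution of these
per-sample ratios is the result; values below 1 mean the focal sites
cluster against the background.

## The synthetic-data generator

`ogu_scenario()` fixes the study conditions; `simulate_reads()` realizes
them. The generator emulates exactly the features the method cares about
and nothing more:

* log-normal communities (per-genome base log-abundance N(0, 1), per-sample
  noise N(0, `sample_sd`), softmax-normalized), with an optional planted
  group effect (`effect_size`-fold change on a fraction `effect_genomes`
  of genomes);
* a random genome phylogeny (random topology, exponential branch lengths)
  and a deterministic seven-rank taxonomy nested by index;
* per sample, `n` reads of which `aligned_fraction` align; each aligned
  read hits its true genome plus its `k − 1` nearest phylogenetic
  neighbors, `k` drawn from `k_probs`. Drawing co-hits from phylogenetic
  neighbors — not uniformly — mimics how real aligners smear reads across
  similar genomes, which is the mechanism that makes `1/k` apportionment
  matter.

It does **not** simulate bases, quality scores, sequencing error or
aligner scoring, so passing tests say nothing about alignment quality
itself — only about everything downstream of the hits.

Defaults and the sizes used in tests were chosen once as desk-scale
analogs of a real study: 150 genomes and 5,000 reads/sample for the
depth-robustness study (12 samples, 2 groups, subsampled to depths
400–4,000 — one order of magnitude — with 5 replicate seeds); 500 to
50,000 reads for the depth-recovery curve; multi-mapping law
P(k=1)=0.8, P(k=2)=0.15, P(k=4)=0.05. The `sample_sd = 1` dispersion in
the robustness study gives the community a realistic rare tail, so that
presence/absence metrics have variation to lose — with a small, fully
saturated genome set every sample contains every genome and Jaccard
degenerates.

The Fig-1-style fixture is frozen rather than simulated: its exact counts
are a constraint-satisfying construction (per-sample totals of 12; species
S1 equal across samples via different member OGUs; equal O5/O7 counts
within S3 in samples B and C; O6/O9 shared by A and B; a phylogeny with
O1/O2 as sisters, O3 next, and O4/O5 as sisters despite sitting in
different genera). Tests assert only those constraints and the qualitative
distance orderings, never the arbitrary counts themselves.

## Numerical choices and degenerate inputs

* Half-to-even rounding uses R's IEEE `round()`; values that round to zero
  leave sparse storage, and features left without support leave the axis.
* Conservation is asserted to 1e-9 (additive float tolerance); UniFrac
  oracle equivalence to 1e-9; Newick round-trips to 1e-9 on branch
  lengths.
* Two all-zero count vectors have no defined dissimilarity — error, not 0.
* A sample with zero column sum passes through `filter_rel_abund()`
  untouched (no division by zero).
* Distance-matrix symmetry is validated on read (1e-8); the diagonal is
  exactly zero by construction.
* `permanova()` refuses a grouping that spans all samples, and requires an
  explicit seed whenever permutations are sampled — no silent
  nondeterminism anywhere in the package; the CLI enforces the same rule.
* Ties in the permutation test count as `F_perm ≥ F_obs` with a 1e-12
  guard, which keeps exhaustive and sampled estimates consistent.

## Command line

The installed `exec/ogu` script is a thin wrapper over `ogu_cli()`:
`classify`, `collapse`, `filter`, `normalize`, `subsample`, `beta`,
`pcoa`, `permanova`, `ratio`, `simulate` and `fixture` each delegate to
one documented function and read/write the TSV formats described in the
function documentation. Thresholds are given in percent on the command
line (`--threshold 0.01` means 0.01%), matching how such cutoffs are
quoted in practice. Exit codes: 0 success, 1 usage error, 2 data error.
Shelling the workflow is byte-identical to composing the functions in R,
which the test suite asserts.

## Known limitations

* Alpha diversity is out of scope, as is differential-abundance testing
  (Phylofactor/ANCOM-style) and any visualization beyond basic
  `autoplot()` methods.
* PERMANOVA supports a single grouping factor; no multi-factor
  `adonis`-style models, no strata.
* Taxonomic-abundance inference stops at genome-size normalization; no
  Bayesian read reassignment.
* BAM/CRAM/PAF require external conversion to SAM or a mapping file.
* `collapse_phylogeny()` requires monophyly; it will not repair a
  discordant taxonomy, by design — the error names the offending tips so
  the taxonomy can be curated.
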