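---
title: "Species-level amplicon profiling with rpodprofiler: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Species-level amplicon profiling with rpodprofiler: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rpodprofiler)
```

## The problem

The 16S rRNA gene is too conserved to separate species within *Pseudomonas*:
many species differ by under 1% across the V3-V4 region, so standard 16S
profiling stops at the genus. The single-copy housekeeping gene *rpoD*
(sigma-70 factor of RNA polymerase) carries enough variation for species-level
resolution. This package re-embodies an *rpoD* amplicon workflow built around
the degenerate primer pair PsEG30F (`ATYGAAATCGCCAARCG`) and PsEG790R
(`CGGTTGATKTCCTTGA`), which produce a ~736-nt product — too long for 2 x 300 nt
paired-end sequencing to cover: the mates leave an uncovered interior
(`sequencing_gap(760, 300)` = 160 nt for the full region), so merged-read
OTU/ASV pipelines do not apply and read pairs must be classified against a
reference database instead.

The toolkit has four computational stages, plus a synthetic-data generator
that stands in for sequencing data in all tests:

1. **in-silico PCR** — find degenerate primer sites and extract products;
2. **database construction** — primer-trimmed, taxonomy-labelled *rpoD*
   amplicons;
3. **classification** — concordant paired-end alignment with a uniqueness
   score;
4. **community statistics** — mock-community recovery, diversity, ordination,
   dispersion and qPCR-anchored absolute abundance.

## In-silico PCR

A primer site is accepted where the primer aligns with **at most one
substitution and at most one single-base indel, counted separately** (not an
edit distance of two: two substitutions are rejected). An IUPAC code in the
primer matches exactly the bases of its set; an ambiguity code in the
*template* (typically an N at a contig break) never matches — this stops
assembly gaps from fabricating sites. There is no 3'-anchoring: a mismatch at
the extension end is treated like any other.

Alignment details that required a decision:

* Template insertions are internal to the primer footprint only; a deletion
  may remove any primer base. Boundary insertions would merely shift the
  reported start by one and create duplicate hits.
* When several within-budget alignments share a start, the one with fewest
  total edits wins (ties: end closest to the gapless end, then leftmost).
* Overlapping hits at adjacent offsets — one physical site seen through its
  indel variants — are deduplicated by lowest edit count, then leftmost
  start. `scan_template(..., dedupe = FALSE)` exposes the raw set, which the
  test suite compares against a brute-force enumeration oracle (all
  expansions x all single-indel variants x all single-substitution variants,
  located by exhaustive substring search) on random templates up to 2 kb.

`amplify()` pairs each forward-primer site with the *nearest* compatible
downstream reverse-complemented reverse site (PCR's dominant short product);
`all_pairs = TRUE` switches to every compatible pairing for anomaly hunting.
Both template orientations are searched, and products are capped at
`max_len = 5000` nt — large enough to expose "much longer than expected"
off-target products while bounding runaway pairings. Product lengths are
reported **including both primer footprints**; the conventional 736-nt figure
for PsEG30F/PsEG790R is interpreted this way (so the trimmed interior is
736 − 17 − 16 = 703 nt).

## The reference database

`build_database()` amplifies every template, keeps the shortest product per
template (a single *rpoD* copy is expected; the rule only matters for
anomalous templates), trims both primer footprints, attaches taxonomy
(species, group, subgroup), and reports unamplifiable templates as rejects.
Records serialize to FASTA with `id|species|group|subgroup` headers — the
single cross-module contract the classifier reads back. Subspecies are not
collapsed: whatever species label the taxonomy table carries is what the
classifier reports, so callers control the granularity.

Discriminating power is quantified by greedy identity clustering
(`cluster_at_threshold()`, default 0.97 — the conventional species-level
cutoff): records are seeded in descending length order (ties broken
lexicographically by id, for reproducibility), and species sharing a cluster
are reported as mutually confusable, the analogue of near-identical pairs
such as *P. putida* KT2440 / *P. monteilii* DSM 14164. Identity is
matches / alignment columns under a unit-cost global alignment — gap columns
count in the denominator, which is the conservative choice.

## Classifying non-overlapping read pairs

Each mate is aligned in both orientations against every reference by a
seed-anchored banded local alignment (k-mer seeds, k = 15; band half-width 8
around the dominant seed diagonal; scores match +2, mismatch −3, gap open −5,
gap extend −2 — conventional short-read local-alignment weights, exposed as
configuration). Hits below 60% of the maximal attainable score are dropped.
Two engine choices matter for speed and are invisible to results:

* candidate references are pre-filtered by seed votes (at least 2 seeds and
  20% of the best candidate's votes, at most 16 candidates) — close
  neighbours share enough exact k-mers to survive, so the second-best
  reference needed by the uniqueness score is retained;
* when all seeds agree on one diagonal the score is computed by an exact
  ungapped maximal-segment scan on that diagonal; the gapped banded DP runs
  only when votes split across diagonals or the ungapped score is marginal.

A reference is **concordant** for a pair when the two mates hit it in
opposite orientations and the combined footprint spans 400–1,000 nt (a window
bracketing the 736-nt product). The pair's **uniqueness score** is

$$Q = \min(42,\; S_{best} - S_{second})$$

in combined alignment-score units, where the second-best concordant reference
stands in; with a single concordant reference the score floor substitutes.
Identical references tie, give Q = 0, and leave the pair unassigned. A pair
is assigned to the best reference's species iff **Q > 10, strictly** — the
source workflow states the threshold as "quality of >10" without fixing
strictness at exactly 10; we chose strict. One mismatch of separation between
two candidate references is worth 5 score units, so assignment needs the best
reference to be at least 3 mismatch-equivalents closer than the runner-up
within the sequenced windows.

Counts are conserved by construction: every pair ends in exactly one of
*assigned*, *ambiguous* (concordant but Q ≤ threshold), *discordant*, or
*no_hit*, and `tabulate_assignments()` gives each pair at most one count.

Abundance tables are normalized by **scaling** each sample row to exactly
100,000 reads (`normalize_to_depth()`) — fractional values are intended; a
seeded subsampling alternative (`subsample_to_depth()`) exists behind a flag
for workflows that require integer counts.

Quality control before classification: exact-prefix barcode demultiplexing
(no mismatch tolerance — barcodes are short, and a one-error rescue is more
likely to mis-assign than to recover) and 3' sliding-window trimming
(window 4, mean quality < 20 cut, then residual trailing bases below the
threshold; pairs with a mate under 100 nt are discarded). These are the
defaults of the common trimming-tool family and are all overridable.

## Community statistics

* **Observed/expected ratio** per mock member: `100 x observed / expected`
  (both in percent), summarised as mean ± SD across replicates.
* **Bray–Curtis**: `sum |x−y| / sum (x+y)`; the package's own one-line
  implementation is cross-checked against `vegan::vegdist` in the tests.
* **PCoA**: classical scaling via `stats::cmdscale`; when Bray–Curtis
  produces negative eigenvalues the additive (Cailliez) correction is applied
  and the constant reported.
* **Beta dispersion**: per-sample distance to the group's **spatial median**
  in principal-coordinate space (the referenced ecology package's default;
  `center = "centroid"` available), group dispersion = mean distance, and for
  two groups a two-sided Mann–Whitney U test on the per-sample distances.
  Singleton groups are rejected in comparisons.
* **Mann–Whitney U**: exact by full enumeration when `n*m <= 400` — via the
  closed-form rank-sum distribution without ties, or a permutation
  distribution over doubled midranks (dynamic programming) with ties, so that
  identical samples give exactly p = 1 — and a tie-corrected normal
  approximation with continuity correction otherwise. Two-sided throughout,
  as are all tests in the package.
* **NMDS**: `vegan::metaMDS` (iterative majorization) under a mandatory seed
  with 20 random restarts by default; fractional Kruskal stress-1 is
  reported.
* **Chao1**: the bias-corrected form `S_obs + F1(F1−1) / (2(F2+1))` — always
  finite, equal to `S_obs` when fewer than two singletons exist.
* **Rarefaction**: the analytic hypergeometric expectation
  `E[S(d)] = sum_i (1 − C(N−n_i, d)/C(N, d))` (via `vegan::rarefy`),
  verified against Monte-Carlo subsampling in the tests.
* **qPCR anchoring**: least squares `CT = slope·log10(q) + intercept`;
  efficiency `E = (10^(−1/slope) − 1)·100`; absolute taxon load =
  total CFU/g x relative abundance / 100.

## The synthetic-data generator

The generator's defaults *are* the study conditions the rest of the package
is validated under: a **166-entry** reference database; a **736-nt** amplicon
(interior 703 nt after trimming); **2 x 300 nt** non-overlapping mates (prefix
and reverse-complemented suffix of the record, leaving the interior
unsequenced); **0.5%** i.i.d. substitution errors; constant **Q37** qualities
with an optional linear 3' decay to exercise the trimmer; equimolar
**16-member** mock mixtures at **1,000 pairs per member**.

References evolve independently from one random ancestor by per-site
substitution at 1.7x the target minimum pairwise divergence (default target
3%). The factor puts the expected pairwise divergence (~10%) far enough above
the target that the minimum over all pairs clears it even in the tail; the
realised minimum is verified, the rate escalates on failure, and an
unreachable target is an error rather than a silent shortfall. Everything is
byte-reproducible from `(config, seed)`.

What the generator deliberately does **not** model: PCR amplification bias
(the real workflow underestimates poorly primed species — *P. libanensis*-like
cases), chimeras, indel sequencing errors, position-dependent error spectra,
and off-target/contaminant reads beyond simple random-sequence spike-ins in
tests. Passing the mock-recovery tests therefore demonstrates that the
*bioinformatic* pipeline is unbiased and well-calibrated on its own
assumptions, not that wet-lab biases are absent.

## Problem sizes and numerical choices

The test suite and the acceptance script run the full mock design (166
references, 16,000 pairs) in seconds thanks to the seeded aligner; unit tests
use smaller slices (tens to hundreds of pairs, 2–30 references) chosen to
keep each property sharp rather than to stress throughput. Determinism is
enforced everywhere: candidate references are iterated in sorted order, RNG
state is saved and restored around every seeded generator, and classification
results are independent of read order.

Known limitations:

* the uniqueness score is a best-vs-second-best margin, not a posterior; its
  scale (c = 1, cap 42) is conventional rather than calibrated;
* greedy identity clustering is order-dependent by design (the order rule is
  fixed and documented) and is a stand-in for phylogenetic analysis, not a
  replacement;
* equal-length global-alignment identity underestimates similarity for
  records with large terminal indels;
* the Mann–Whitney permutation path is exact but quadratic in the pooled
  rank-sum range; the `n*m <= 400` switch point keeps it instantaneous.
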