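---
title: "Models and design decisions in scafrag"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and design decisions in scafrag}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(scafrag)
```

`scafrag` processes tag-multiplexed single-cell ATAC-seq data at the
fragment level and computes coaccessibility and allele-specificity
statistics from it. This vignette explains the models, the parameters
that matter, the numerical choices, and the places where the design was
genuinely open and a decision had to be made.

## The fragment model

The atomic datum is a *fragment*: one Tn5-excised genomic interval
attributed to one cell, carried as a row
`(chrom, start, end, cell_id, read_count, r1_meta, r2_meta, allele)`.
Coordinates are 0-based and half-open (BED convention) everywhere,
including on the way in and out of files. The META pair — the transposon
end tags observed on the two mates — is part of a fragment's identity:
two fragments with identical coordinates but different tag pairs are
distinct molecules. That identity, the *FragmentKey*
`(chrom, start, end, r1_meta, r2_meta)`, drives both deduplication and
decontamination.

### Demultiplexing

Each mate begins with a cell barcode (4–7 nt) followed by a META tag
(11–13 nt). Both are matched against the scheme's whitelist by Hamming
distance, with tolerances of 1 (barcode) and 2 (META) substitutions by
default. Two decisions here:

- **Ambiguity goes to loss, not to a guess.** When two whitelist entries
  tie at the minimal distance, the read is left unassigned. Misassigning
  a read to a wrong cell corrupts two cells at once; dropping it costs
  one read.
- **Lengths are declared, not searched.** Real plates mix barcode
  lengths across wells; the scheme declares the length at each position
  and parsing uses it, rather than trying all lengths against all
  whitelists.

`example_scheme()` generates whitelists with minimum pairwise distance 3
(barcodes) and 5 (META tags), so a single substitution is always uniquely
correctable and a double substitution in a META tag still is. With such
spacing, reads carrying at most one barcode error are provably never
assigned to a wrong cell — the round-trip tests assert exactly that.

### Adapter trimming

Short inserts read through into the 19-bp Tn5 mosaic end: its reverse
complement appears as a 3' adapter and the sequence itself can precede
the insert at the 5' end. Trimming is semiglobal: full internal
occurrences and terminal partial matches of at least 3 nt are eligible,
a match is accepted when its per-base error rate is at most 0.22, and
the best-scoring occurrence (matches minus mismatches) is removed, with
qualities trimmed in lockstep.

### Tn5 centering, deduplication, decontamination

Aligned pairs become fragments as
`[plus-strand start + 4, minus-strand end − 5)` — the standard
correction placing both ends at the center of the 9-bp Tn5 duplication —
after discarding pairs with mapping quality below 30 or improper
orientation. Pairs whose corrected interval is empty or inverted are
discarded: such lengths are physically meaningless, and keeping them
would break the `start < end` invariant everywhere downstream.

Deduplication groups fragments by FragmentKey within a cell and keeps
one representative carrying the group's total read support; the total
read count is conserved and the operation is idempotent.

Decontamination addresses barcode switching and index hopping: a
FragmentKey observed in several cells is almost surely one molecule that
leaked. The copy in the cell with the *strictly* highest read count is
kept; all others are removed. **Frequency ties are removed from every
cell.** The alternative — keeping an arbitrary copy — would assign real
signal to a cell on a coin flip; the conservative rule only ever costs
sensitivity. Each cell's contamination rate is the fraction of its
unique fragments removed this way.

## QC metrics

- **Library complexity** inverts the Lander–Waterman relation
  `U = L (1 − e^{−T/L})` by bisection (relative tolerance 1e-6). `U = T`
  has no finite solution and reports `Inf`. Simulation shows the
  estimator recovers the true `L` within a few percent across duplication
  depths `T/L` from 0.5 to 2.
- **TSS enrichment** aggregates insertion events (both fragment ends) in
  a strand-aware ±2 kb window and divides the mean per-bp density of the
  central 101 bp by that of the two outermost 100-bp flanks. The metric
  is a named convention rather than a derived quantity; this geometry
  follows common practice in scATAC QC tooling. Zero flank insertions
  make the score undefined (`NA`), not infinite.
- **Promoter ratio** is the fraction of fragments overlapping TSS ± 2 kb
  — again a convention, stated here so the number is reproducible.
- **Species mixing** classifies each cell by its fraction of fragments
  on human chromosomes: strictly above 0.9 is human, strictly below 0.1
  is mouse, anything else — boundaries included — is a doublet. The
  strictness is deliberate: a cell sitting exactly at the threshold has
  not earned a species call.
- **DHS saturation** draws random cell subsets without replacement
  (seeded), calls peaks with an injected caller, and counts reference
  DHSs overlapped by at least one peak. The default is 10 replicates per
  cell number; 3 is a common published choice and is available via the
  argument. A deliberately simple coverage-threshold caller ships for
  tests; production peak calling is consumed, not produced.
- **Cell filtering** is entirely threshold-table driven with no hidden
  defaults: published per-dataset thresholds vary too much for any
  default to be honest.

## Coaccessibility

With `N` cells, marginals `M` and `n`, and co-occurrence `x`, the score
is `−log10 P(X ≥ x)` for hypergeometric `X`. Design points:

- **`N` is the full cell universe**, including cells where neither peak
  is open. The test conditions on both marginals within all assayed
  cells; dropping empty cells would inflate every score.
- **Log-space tails.** The survival function is evaluated with
  `log.p = TRUE`, so scores beyond 300 (tail probabilities under
  1e-300) are computed without underflow.
- The score is a valid upper-tail p-value on −log10 scale: on
  independent peaks, `P(score ≥ s) ≤ 10^{−s}` up to discreteness. The
  calibration tests check this at s = 1, 2, 3 with a discreteness
  allowance of 50%; the empirical tails in practice sit *below* the
  nominal bound because the hypergeometric is discrete and conservative.
- **Pair distance is midpoint-to-midpoint**, and the neighbor-pair
  enumeration includes pairs at exactly the maximum distance (closed
  bound). Any convention works; this one is symmetric under peak-width
  changes.
- **Clustering by coaccessibility** uses average-linkage hierarchical
  clustering on the distance `max(score) − score`, cut into `k` groups,
  with the higher mean within-group score labeled HIGH. Linkage and
  transform are conventions; they are fixed and documented so results
  are reproducible, with ties broken deterministically by `hclust`'s
  ordering.
- Precision–recall against validated pairs scores every labeled pair
  (missing scores count as 0) and integrates precision over recall by
  trapezoid.

## Allele-specific accessibility

Fragments are labeled from the SNP observations of their reads: no
observation → unphased; all observations matching one parent → that
parent; observations supporting both parents, or any base matching
neither genotype, → inconclusive. Unphased and inconclusive fragments
never enter allele-specific statistics.

Per-region counts default to **insertion mode**: each fragment
contributes its Tn5 insertion ends falling inside the region (up to
two). "Accessibility" at a region is insertion events, and a fragment
spanning a region boundary genuinely contributes one insertion, not
two. Fragment-mode counting (one per overlapping fragment) is available
because the choice between the two readings is a convention.

The specificity statistic is
`S = log10 P(K ≥ n) − log10 P(K ≥ m)`, `K ~ Binomial(n + m, 1/2)`,
with properly normalised binomial tails. An unnormalised variant that
places `(1/2)^k` inside the tail sum (instead of `(1/2)^{n+m}`
overall) appears in some write-ups; it does not satisfy `S(n, n) = 0`
and is not a tail of a probability distribution, so the normalised form
is used here. Significance for monoallelic calling uses the exact
two-sided binomial test (twice the smaller tail, capped at 1) with
Benjamini–Hochberg correction at FDR 0.05 by default — the test family
and FDR level are decisions, documented rather than implied.

**X-inactivation** is assigned per cell from the maternal fragment
ratio among SNP-informative chrX fragments. In F1 hybrids this ratio is
strongly bimodal near 0 and 1; the default thresholds (≤ 0.2 →
maternal X inactive, ≥ 0.8 → paternal X inactive) and the minimum of 10
informative fragments are conservative choices placed well inside the
antimodes. Cells between the thresholds or with too few informative
fragments stay unassigned. Pooling then routes each assigned cell's
maternal/paternal chrX fragments into active-X and inactive-X pools.

Parent-of-origin and strain effects cannot be separated without
reciprocal crosses; the package labels by parent only.

## RNA-side UMI handling

Reads are dropped when the UMI disagrees with the designed IUPAC
template at more than 3 positions or when the 5 bases downstream of the
UMI contain fewer than 4 Ts; cDNA reads additionally pass a post-polyA
length (≥ 40 bp), quality (strictly more than half of bases above
Q38) and N-content (strictly below 10%) filter. All boundary readings
are strict, exactly as stated.

UMI collapsing counts connected components of the Hamming-distance ≤ 1
graph: transitive chains merge, and the count is permutation-invariant.
This differs from count-weighted directional collapsing (as in
UMI-tools' `directional` method), which splits chains when a low-count
node separates two high-count nodes; component counting is the simpler
semantics and matches "UMIs within Hamming distance 1 are collapsed"
literally. At realistic error rates (1% per base, 8-nt UMIs) recovered
counts stay within 10% of truth for up to 50 molecules per gene.

## The synthetic-data generator

The generator produces what the other modules consume, with a ledger of
the planted truth. Its defaults are the package's standard study
conditions: 600 cells; 200 peaks of 501 bp evenly spaced on three 1-Mb
toy autosomes; per-peak baseline accessibility drawn uniformly from
[0.05, 0.5]; co-accessible modules with a shared per-cell latent
(activation 0.4, leak 0.05, latent probability 0.5); 1–3 fragments per
open (cell, peak) entry; 10% PCR duplication; 2% cross-cell
contamination, always at strictly lower read support than the owner; 1%
per-base barcode error in simulated reads; 30 chrX fragments per cell,
90% SNP-informative, with X-inactivation skew 0.98. The skew reflects
essentially complete inactivation — observed per-cell allelic ratios in
adult tissue peak tightly near 0 and 1 — while leaving a realistic
trickle of wrong-allele fragments from escapee regions and labeling
noise.

Key-uniqueness of the planted fragments is enforced at generation (rare
random coordinate collisions are nudged apart) so that the injected
duplication and contamination events are *exactly* the ones the ledger
lists, making the decontamination test an identity check rather than a
statistical one.

One seed drives all randomness through an isolated RNG scope
(`withr::with_seed`); identical configuration and seed give identical
output, and nothing touches the global random state.

What the generator does **not** emulate — and what passing tests on it
therefore do not show about real data: sequence-content biases (GC,
Tn5 insertion-site preference), fragment-size periodicity from
nucleosomes, doublets, per-cell depth variation beyond the binomial
model, mapping artifacts, or allele-specific mapping bias. Results on
real data depend on upstream alignment and peak calling, both of which
this package consumes rather than produces.

## Problem sizes and numerical notes

The test suite and the acceptance script exercise: exhaustive
hypergeometric enumeration for all feasible tuples at N ≤ 10 (996
cases, exact to 1e-9); a randomized law sweep of 10⁴ tuples at N up to
600; null calibration and planted-module recovery on 600-cell matrices
with 20 000 sampled pairs; binomial-oracle equivalence for all
n + m ≤ 25; allelic power at maternal fraction 0.9 (400 regions) and
calibration under the balanced null (2 000 regions); X-inactivation
accuracy on 200 cells; and a full read-to-fragment round trip at 500
cells × ~2 000 fragments per cell (about 10⁶ fragments, ~1.1 × 10⁶ read
pairs). These sizes were chosen as the smallest at which the asserted
properties are stable across seeds.

Degenerate inputs are defined, not guessed: FRiP and TSS enrichment on
empty input are `NA`; `S` at `n + m = 0` is `NA`; species calls with
zero fragments are `UNCLASSIFIED`; empty UMI sets count 0; empty
fragment files parse to empty tables.

## Known limitations

- Decontamination assumes the true owner has the highest read support;
  at very shallow sequencing, ties become common and the conservative
  tie rule then costs real fragments.
- The coaccessibility score tests marginal independence; it does not
  model cell-type structure, so pervasive covariates (depth, cell type)
  can inflate scores between unrelated peaks. Comparisons against
  matched controls (flanking pairs, distance bins) are provided for
  that reason.
- The binomial allele model treats insertion ends as independent
  Bernoulli trials; the two ends of one fragment share an allele, so
  insertion-mode counts are mildly overdispersed relative to the model.
  Fragment-mode counting avoids this at the cost of half the counts.
- The CLI is a thin wrapper for scripting convenience; the R functions
  are the primary, fully-tested interface.
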