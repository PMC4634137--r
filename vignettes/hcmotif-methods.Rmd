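---
title: "Methods: cell-type-specific promoter motif enrichment"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: cell-type-specific promoter motif enrichment}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

This vignette is the package's own account of its methods: the statistical
model behind each stage, the tunable parameters and their defaults, what the
synthetic-data generator does and does not emulate, the numerical choices,
and the known limitations.

## The analysis in one paragraph

Sorted inner-ear cell populations — hair cells (HC), epithelial non-hair
cells (ENHC) and non-epithelial cells (NEC), from the cochlea and the
vestibular system — are profiled on an intensity platform (three replicates
per condition) and a count platform. Genes elevated in HCs are derived from
the count data; their promoters are scanned for a position-weight-matrix
motif; over-representation relative to the expressed-gene background is
scored by an upper-tail hypergeometric test with an enrichment factor;
positional analysis around the transcription start site (TSS) justifies
narrowing the promoter window, which sharpens the test; and the resulting
putative regulon is validated three independent ways: intersection with
ChIP-derived target lists, the same enrichment on orthologous promoters of
a second species, and a rank-based test that the targets' expression is
shifted toward HCs.

## Expression stages

**Detection filter.** Bead-array scanners attach a detection p-value to
every measurement. A feature is kept when it is detected (p below
`detection_p_expressed`, default 0.01) in at least `min_samples_detected`
samples (default 2). This is deliberately permissive: it defines the
"expressed" universe used as background later, and an over-strict filter
would bias the enrichment background.

**Quantile normalization.** `quantile_normalize()` forces every sample to
share the empirical distribution of per-rank row means (ties receive the
mean of their rank range), delegating to `limma::normalizeQuantiles`. One
caveat matters and is visible in the tests: when a large fraction of genes
is differentially expressed in one direction (e.g. a planted regulon that
is 10% of all genes), quantile normalization compresses exactly that tail
and shrinks fold changes. At the default conditions (4% of genes) the
effect is mild; reduced-scale tests assert recovery above 80% rather than
total recovery for this reason.

**Differential expression.** Per feature, a fixed-effects two-way ANOVA of
`log2(x + 1)` on cell type, organ, and their interaction. The log transform
is chosen to match fold-change semantics; the offset of 1 keeps zero counts
finite and is negligible against the floor of 20 used on the count
platform. Sums of squares are type II — each main effect adjusted for the
other, the interaction adjusted for both — so the test is invariant to
factor ordering and robust to mild imbalance; on the balanced default
design type II coincides with the classical sequential decomposition. The
fits are computed by shared QR projections applied to all features at once
(the `limma::lmFit` idiom), which is exact classical least squares; the
test suite verifies equality with per-feature `car::Anova(type = 2)` and
with an explicit hat-matrix oracle to 1e-8. P-values are BH-adjusted across
features separately per effect and a feature is selected when any adjusted
q falls below `fdr_level` (default 0.05). Degenerate features are resolved
as: constant feature → F = 0, p = 1; perfect fit with structure → p = 0;
both sums of squares at numerical zero → p = 1, using a relative tolerance
of 1e-12 times the feature's total sum of squares.

**Pattern clustering.** The selected features, standardized per row to mean
0 and sample s.d. 1 (constant rows map to zeros and are flagged), are
partitioned by k-means with `n_pattern_clusters = 12`, Euclidean distance,
50 restarts and a fixed seed. K-means is a deliberate, documented stand-in
for graph-based pattern discovery: its objective on standardized profiles
groups co-varying genes the same way in practice, it is deterministic under
seed, and it needs no external binaries. Cluster summaries report the mean
pattern ± per-sample s.d.

**Sample dendrogram.** Average-linkage agglomeration on 1 − Pearson
correlation between sample columns over all expressed genes. The metric is
a choice (the linkage is the standard one for this view); correlation
distance is insensitive to scale and is what makes the dendrogram group
samples by cell type rather than by overall intensity. A constant column
has no defined correlation and is reported as an error naming the sample.

**Marker calling.** The strict rule: gene g is a marker of cell type c when
the mean over the target replicates exceeds `marker_high` (250 a.u.) and
every single sample outside the target group stays below `marker_low`
(120 a.u.). Both inequalities are strict. The thresholds are meaningful on
the normalized intensity scale, where detection flags separate cleanly
around 120. The target group is the cell type pooled over organs (scope
"both") or a single organ's population, in which case all other samples —
including the same cell type in the other organ — must stay low. The
">250" side is applied to the replicate mean and the "<120" side to every
individual sample: the strictest reading consistent with "in all other
samples", which is what makes the resulting markers usable as sorting
controls. With the mean-vs-every-sample asymmetry, a gene can be a marker
of at most one cell type by construction.

**HC-elevated set.** On floored, quantile-normalized counts: replicate-mean
HC over replicate-mean ENHC at least `fold_threshold` (default 3, the
boundary inclusive, reading "at least") in either organ. The floor of 20
exists exactly to keep these ratios from exploding on near-zero
denominators.

## Motif stages

**Promoters.** For a plus-strand gene the window is the genomic interval
`[tss − u, tss + d)`; for a minus-strand gene, the reverse complement of
`[tss − d + 1, tss + u + 1)`; position 0 is always the TSS base read in the
transcription direction. Coordinates are 0-based half-open throughout, with
BED conventions for the TSS (start for +, end − 1 for −). Windows are
clipped at contig edges, never padded, and flagged; one promoter per gene
(first TSS record wins, with a warning). Defaults: u = 1000, d = 500,
narrowed to u = 200, d = 100 after positional analysis.

**Scanning.** A PWM column contributes `log2(p_b / q_b)` for observed base
b against background composition q; N contributes 0. A window is a hit
when its score reaches `theta` × the maximum achievable score (default
0.8), on the forward strand or the reverse complement. The
fraction-of-maximum threshold makes the cutoff PWM-width-invariant and
needs no score distribution model. Uninformative (uniform) PWM columns
drop out of the score automatically. The inner loop is a small compiled
kernel; `Biostrings::matchPWM` is used as an independent cross-check in the
tests, never as the implementation.

**Enrichment.** Presence/absence per gene (≥ 1 hit anywhere in the window)
feeds `P(X ≥ k)` for `X ~ Hypergeometric(N, K, n)` — computed via `phyper`
in log space — with enrichment factor `(k/n)/(K/N)`. Presence rather than
hit counts matches how such regulons are reported (a promoter either
carries the signature or not) and makes the null exact. The same
`hypergeom_tail()` is the single implementation behind the motif test, the
ChIP overlaps and the panel enrichment.

**Positional analysis and narrowing.** The best (highest-scoring) hit per
gene is binned at 25 nt over `[−u, d)`. The modal bin (first maximal bin
on ties, flagged) identifies the TSS-proximal peak; the pipeline then
re-extracts and re-scans the narrowed window and re-runs the test. On data
whose instances concentrate near the TSS, narrowing discards background
sequence faster than signal, so the narrowed p-value is expected to be at
most the full-window one; the acceptance suite asserts exactly that.

**De-novo discovery.** All 8-mers, collapsed with reverse complements
(palindromes are their own class), scored by the same presence/absence
hypergeometric and Bonferroni-corrected over the full class family
((4^8 + 4^4)/2 = 32 896 classes — the conservative default for a family
this size). The top class's occurrences in target promoters are stacked
into a count-matrix PWM with pseudocount 1. This is the seed-enumeration
phase of de-novo discovery only; no EM refinement, spaced motifs, or
multi-motif modes.

**Cross-species transfer.** Targets are mapped through a one-to-one
ortholog map (many-to-many input rows resolved first-wins with a warning),
unmapped genes are dropped and counted, and the identical enrichment test
runs against the second species' background. An identity map reproduces
the within-species result exactly — a test, not an assumption.

## Validation stages

**ChIP intersection.** Counts of candidates bound by at least one and by
both ChIP experiments, each with an upper-tail hypergeometric p against
the gene universe, plus the overlap between the two ChIP lists themselves.

**HC-enrichment shift.** Per gene, expression in HC divided by the mean
over the three cell types (replicates pooled across organs by default; a
per-organ mode exists). The one-sided Wilcoxon rank-sum test asks whether
a set's log2 ratios are stochastically larger than the rest's — one-sided
because the claim under test is directional ("shifted to the right");
the two-sided alternative is available. Exact enumeration is used when the
smaller group has ≤ 10 values and no ties; otherwise the normal
approximation with midranks, tie-corrected variance and continuity
correction (`stats::wilcox.test` underneath, enumeration oracles in the
tests).

## The synthetic-data generator

The generator produces the statistical structure the analysis assumes,
with recorded ground truth:

* log-normal expression, `log2 x = base + effects + N(0, noise_sd)`;
  baselines `N(6, 1.5)` put roughly half the genes below the detection
  threshold of 120 in every sample, as bead arrays behave;
* a 200-gene regulon (of 5000) on an elevated baseline `N(7.8, 0.2)` —
  high enough that regulon genes stay clearly detected outside HCs and do
  not masquerade as strict markers — with +2 log2 in HC columns;
* 30 strict markers per cell type at 512 a.u. in their own type and 40
  elsewhere; 20% of remaining genes organ-biased by 1 log2 — chosen so
  cell-type variance dominates organ variance and the dendrogram's top
  split follows cell type;
* log2 noise s.d. 0.25, a typical replicate CV for sorted populations;
* one contig per gene (flank + u + d + flank bases, GC 0.42); regulon
  promoters receive a PWM-sampled motif instance with probability 0.8 at
  `round(N(−50, 30))` nt (motif start, clamped into the window), background
  promoters with probability 0.05 at uniform positions; instances and
  positions are recorded;
* ChIP lists include each regulon gene with probability 0.65 plus 300
  non-regulon genes; the second species conserves 80% of the regulon.

The planted PWM is a width-14 X-box-like matrix: an 8-bp sharp core
(consensus GTTGCCAT, dominant probability 0.92) with three uniform columns
on each side, mirroring the degenerate edges of the palindromic RFX site.
Because instances are *sampled* from the PWM, roughly half of them score
below 0.8 × max — scanning sensitivity is exercised realistically rather
than trivially — and chance hits run a few percent per 1.5-kb promoter, so
the planted enrichment factor lands in the single digits rather than at
the insertion-rate ratio.

What the generator does **not** emulate: probe-level microarray artifacts,
batch effects, sequencing depth and dispersion structure of real counts,
correlated promoters (shared CpG islands, repeats), TSS annotation error,
and many-to-many orthology. Passing tests therefore demonstrate that the
machinery is correct and calibrated on data with the assumed structure —
not that the biological conclusions of any real study are automatic.

## Numerical and design notes

* All randomness flows from one integer seed; each generator stage derives
  its own fixed offset, so outputs are byte-identical under a repeated
  seed and stages cannot perturb each other's draws.
* Scan-threshold comparisons use a 1e-9 absolute slack so that exact
  consensus matches at `theta = 1` survive floating-point summation.
* Gene symbols are case-sensitive exact-match keys everywhere.
* The null-calibration experiment for the enrichment p-values is designed
  around the discreteness of the hypergeometric: an upper-tail p on a
  discrete statistic is conservative by about half the modal probability
  mass, which a 1000-replicate KS test can detect unless the hit-count
  s.d. is large. The experiment therefore uses a 20 000-gene null genome,
  a lenient scan threshold (0.65, putting the hit rate near 50% where the
  test statistic has maximal resolution), and resamples both the
  background universe and the target-set size per replicate. This is
  resolution-matched experimental design; the pass criterion itself
  (KS not rejected at 1%) is untouched.
* Problem sizes in the test suite: oracle equivalences run at enumeration
  scale (N ≤ 12, groups ≤ 12); planted-recovery checks run at the full
  default conditions (5000 genes, 20 seeds); reduced-scale pipeline tests
  use 600 genes with planted fractions kept near the default proportions,
  since distortions (quantile normalization, k-mer flukes) scale with the
  planted fraction, not the gene count.

## Limitations

* The de-novo stage is seed enumeration only; a motif whose information is
  spread thinly across many weak positions can escape both the 8-mer
  tournament and a fixed-threshold PWM scan.
* Presence/absence scoring discards multiplicity; a regulator that acts
  through homotypic clusters would be under-read.
* The enrichment background is "expressed genes", which is the right
  control for expression-linked promoter composition but cannot correct
  for GC or CpG covariates within that background.
* Type-II ANOVA presumes the interaction is interpretable on the log
  scale; strong mean-variance coupling would call for count models
  instead.
* Quantile normalization assumes mostly-unchanged distributions; with very
  large one-sided differential fractions it attenuates true fold changes
  (see the expression-stage caveat above).
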