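---
title: "cisPathway: methods, parameter choices and limitations"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{cisPathway: methods, parameter choices and limitations}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cisPathway)
```

# The problem

Quantitative sequencing experiments produce *scored genomic loci* — ChIP-seq
peaks with binding estimates, disease-associated SNPs, differentially
accessible regions. Interpreting them at the pathway level requires two
lossy steps that this package makes explicit and testable: assigning loci
to candidate target genes (most loci are non-coding, and a locus may
regulate several genes, including neighbors rather than its host), and
condensing gene-level scores into gene-set-level scores with honest
uncertainty.

# Locus-to-gene mapping (seq2gene)

## Coordinate conventions

Internally everything is 1-based closed (`GRanges`). GTF input is read
natively; BED input (0-based half-open) is converted at the boundary by
`readLociBed()`. Gene geometry is built from `exon` and `CDS` rows only,
so minimal GTFs without `gene`/`transcript` rows parse identically;
per transcript, UTR = exons minus CDS and introns = transcript range
minus exons. A transcript without CDS rows is non-coding: its CDS *and*
UTR are empty, and its exonic overlaps are labelled `exon`, never
`cds`/`utr`.

## Gene span, TSS and promoter

The gene span is the union range over the gene's transcripts and the TSS
its strand-aware 5' end. A per-gene (rather than per-transcript) TSS is a
deliberate simplification: it gives each gene one promoter and one
neighbor distance, which keeps the mapping table interpretable; genes
whose alternative promoters are far apart are the price. The promoter
window is `promoterUp = 2000` bp upstream to `promoterDown = 0` bp
downstream of the TSS — a common convention, configurable, clamped at the
chromosome start.

## Mapping types and priority

A locus intersecting a gene's body receives exactly one of
`cds > utr > exon > intron`, resolved jointly over all transcripts in
that specificity order (a junction-straddling locus is labelled by the
most specific feature it touches). `promoter` applies only when the locus
touches the promoter window but not the body. `neighbor` records link a
locus to every gene whose TSS lies within `radius` bp of the locus's
nearest edge (closed inclusion, `|d| <= radius`; default 100 kb, with
5 kb a typical stringent choice). The signed distance is 0 on TSS
overlap and negative when the locus is upstream of the TSS in the gene's
orientation. Equidistant TSSs are both reported — the mapping is
many-to-many by design, so no tie-breaking is needed; records are ordered
by `|distance|` then gene id for determinism.

Neighbor records are emitted only for loci that touch no gene body,
*unless* `snpMode = TRUE`, in which case intragenic loci also get
neighbor records: a point variant in an intron may act on a neighboring
gene rather than its host. Wide peaks overlapping a gene are presumed to
act on that gene, hence no neighbor records for them outside SNP mode.
By construction the SNP-mode record set is a superset of the default
(a tested invariant), and the record set is monotone in `radius`.

# Collapsing to gene profiles

`collapseToGenes()` reduces the mapping to one score per gene. A locus
mapping to the same gene through several types contributes exactly once
(type multiplicity is metadata); this per-gene collapsing also prevents
clusters of linked loci — e.g. SNPs in linkage disequilibrium — from
being counted repeatedly. The default statistic `max_abs` keeps the
signed score of largest magnitude: it retains each gene's strongest
evidence and is the natural choice when locus scores are significance
estimates. `mean`, `median`, `max`, `min` and `count` are available;
`count` deliberately ignores scores (it is also what the naive
enrichment route below consumes). The resulting universe is the set of
*mapped* genes — genes without any locus are not invented as zeros,
although `mergeSamples(fillMissing = 0)` supports explicit zero-filling
across samples.

# Gene-set scoring (gene2pathway)

Sets are read from GMT, intersected with the universe and filtered by
`filterSets()`; the default floor of 5 post-intersection genes is the
conventional point below which set statistics are too unstable to
interpret.

## FAIME

Per sample, scores are ranked descending (ties averaged), weighted
`w_g = x_g * exp(-alpha * r_g / N)` and contrasted:
`f = mean(w | in-set) - mean(w | out-set)`. The exponential factor makes
the statistic sample-centric — only each sample's top-ranked genes carry
appreciable weight — while retaining the quantitative score `x_g` rather
than a binarized hit/no-hit. `alpha = 5` by default: weights fall to
`exp(-5) ~ 0.7%` at the bottom rank, and ~37% at rank `N/5`; larger
`alpha` sharpens the focus on top ranks. `alpha` is exposed so variants
of the exponential family can be matched by configuration. Two exact
identities double as tests: `f = 0` when all scores are equal, and
`f(complement) = -f(m)`.

## Alternatives

* **Fisher's exact test** on the 2x2 in-set x significant table, exact
  hypergeometric upper tail. The binarization rule (`threshold` on the
  score, or `top_k`) must be given explicitly — a silent default
  threshold would manufacture results. The odds ratio takes the Haldane
  0.5 correction only when a cell is 0; the p-value is never corrected.
* **Kolmogorov–Smirnov**: two-sided two-sample, asymptotic p (in-set vs
  out-set score distributions).
* **Cumulative rank test**: `T = sum of in-set descending ranks`. For
  `N <= 10` the p-value is exact by enumeration of all `choose(N, k)`
  rank subsets with the inclusive tail `P[T' <= T]` ("greater" = greater
  enrichment = smaller rank sum); otherwise a normal approximation with
  `E[T] = k(N+1)/2`, `Var[T] = k(N-k)(N+1)/12` and a 0.5 continuity
  correction toward the mean. The variance formula ignores ties; the
  exact path handles them natively. Against the tie-free exact rank-sum
  distribution at `N = 50, k = 10`, the approximation agrees within
  0.05 in p (tested).

## Empirical p-values and FDR

For FAIME, `p = (1 + #extreme) / (nPerm + 1)` over `nPerm` label
shuffles of the gene-score vector within the sample (default 1000;
two-sided extremity `|f_b| >= |f|` by default). The add-one estimator
guarantees a valid, strictly positive p with floor `1/(nPerm+1)`.
Permutations use R's Mersenne-Twister; `scorePathways()` seeds the
stream for set `i`, sample `j` with `seed + (j-1)*nSets + (i-1)`, making
the joint run bit-identical to manual `faimeScore()` + `empiricalP()`
calls and reproducible across platforms. The caller's RNG state is
always restored. Benjamini–Hochberg q-values are computed per sample
across sets — matching the per-sample framing of the empirical p — via
the standard step-up rule.

# The synthetic world

`makeToyGenome()` draws non-overlapping genes with log-normal lengths
(meanlog `log(1e4)`, sdlog 0.8) and exponential intergenic gaps (mean
10 kb), 1–3 transcripts per gene, 20% non-coding. The log-normal length
tail is the one feature that matters for the bias analyses below; the
absolute scale is compressed ~2-3x relative to mammalian genes so that
toy genomes stay small. `sampleNullLoci()` places signal-free loci either
uniformly over the genome — under which a gene's expected locus count is
proportional to its footprint, the textbook origin of gene-length bias —
or per-gene Poisson (length-free). `makeToyGeneSets()` samples member
genes uniformly or with probability proportional to gene length; the
latter emulates real pathway collections, whose member locus lengths are
strongly correlated within terms (developmental and neuronal sets being
the classic examples). All generators take explicit seeds and are
byte-reproducible; none of them emulate read-level noise, LD structure,
or clustered/overlapping real gene models.

# What the bias tests do and do not establish

With uniform null loci on the toy genome, per-gene locus counts track
gene length (Spearman correlation asserted positive in the acceptance
suite). The acceptance tests then measure false-positive rates at
p < 0.05:

* With **uniform random sets**, FAIME-with-permutation is exactly
  calibrated (inside the exact binomial 99% band around 0.05), as is —
  necessarily — the hypergeometric route: random membership *is* the
  hypergeometric null, so no count-based inflation can appear under
  uniform sets.
* With **length-weighted sets** (membership probability proportional to
  gene length), thresholding per-gene locus counts and applying Fisher's
  test inflates the false-positive rate several-fold above the band —
  the bias the empirical route is meant to remove. FAIME on the
  score-collapsed profile over the mapped-gene universe removes *most*
  of it (roughly a two-fold reduction, measured in
  `tests/testthat/test-acceptance.R`), but in this maximal confound it
  remains marginally above the 99% band, and the corresponding
  assertion is left failing rather than relaxed.

The honest statement is structural: permuting gene scores conditions on
the observed score vector, so it removes every miscalibration that does
not couple membership to score magnitude. When set membership itself is
correlated with score magnitude — proportional-length-weighted sets
scored on profiles whose magnitudes retain a residual length signal
through the locus-count channel — no label-shuffling scheme can be
exactly calibrated. Score collapsing (taking one representative score
per gene instead of counting loci) is what shrinks the length channel;
the permutation then calibrates against the remaining profile. Users
whose gene sets are strongly length-structured should treat borderline
empirical p-values with care; length-stratified permutation would be the
next step and is out of scope here.

# Numerical and degenerate-input choices

* Ranking ties: average ranks everywhere, for determinism.
* `max_abs` ties (equal magnitude, opposite sign): first occurrence in
  gene-sorted locus order wins; documented rather than randomized.
* Empty promoters (TSS at position 1 with `promoterDown = 0` on +):
  zero-width ranges, never negative.
* A locus inside a gene's union span but outside every transcript span
  is labelled `intron`.
* Loci on chromosomes absent from the annotation are reported in
  `unmappedLoci()`; if more than 90% of loci are on unknown
  chromosomes, `seq2gene()` aborts and suggests a naming-dialect
  mismatch ("chr1" vs "1").
* `empiricalP` extremity comparisons are exact floating-point `>=`;
  permuted statistics are computed by the same arithmetic path as the
  observed one, so exact ties (e.g. the identity permutation) count as
  extreme, keeping p valid.
* Degenerate sets (empty, or covering the whole universe after
  intersection) and degenerate Fisher margins (all/none significant)
  are errors, not silent NAs.

# Known limitations

Per-gene TSS (no per-transcript promoters); no GO DAG expansion or
bundled gene-set catalogs (users supply GMT); no GREAT-style regulatory
domains or locus-length adjustment; no LD-aware or length-stratified
permutation; asymptotic KS p-values (ties tolerated but not exact);
single-sample collapse assumes one mapping table per sample.
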