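---
title: "Evaluating chromatin loop calls: models, parameters, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Evaluating chromatin loop calls: models, parameters, and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(loopeval)
```

ChIA-PET and HiChIP detect chromatin loops — pairs of genomic anchors in
physical contact — by sequencing paired-end tags (PETs) from
proximity-ligated, immunoprecipitated chromatin. Because many loop
callers exist and disagree, `loopeval` scores a loop set from several
independent angles. This vignette explains each metric's model and
assumptions, the tunable parameters and their defaults, what the
synthetic-data generators do and do not emulate, and the numerical and
design choices made where the underlying definitions were open.

## The metric models

### UV Rate

A PET is *uniquely mapped and valid* when both ends map with
MAPQ ≥ `mapq_min` (default 30), it is not a PCR duplicate, and it is an
inter-ligation product. The UV Rate is the fraction of PETs passing all
three filters. Same-chromosome PETs spanning less than the
self-ligation cutoff are circularised fragments, not contacts; the
cutoff defaults to 8 kb and is meaningful between roughly 5 and 12 kb
(`classify_pets(self_ligation_cutoff =)`). PETs flagged invalid
upstream (for example chimeric ligations) keep that class.

### Peak co-occupancy (PC)

For peak-based callers, anchors should sit on ChIP-seq peaks. Anchors
are first merged at 90% reciprocal overlap (`merge_intervals`, see
below) so near-duplicate anchors are not double counted. Every anchor
with ≥ 1 bp of peak overlap enters the candidate set A; its best peak
is the one with the longest overlap (ties broken by leftmost peak
start, then input order), and it contributes
`max(L(o)/L(p), L(o)/L(a))` — the overlap length relative to whichever
of peak or anchor it explains best. Two summaries are offered because
the classical formula, `N_A * Σ term_i / N`, exceeds 1 whenever many
anchors match well (with all `N` anchors perfectly matched it equals
`N_A`). `mode = "literal"` reproduces that formula; the default
`mode = "normalized"` drops the `N_A` multiplier, giving `Σ term_i / N`
bounded in [0, 1], which is the natural co-occupancy fraction for
cross-method comparison. Note the formula scores 1 for a peak strictly
nested inside an anchor (the overlap equals the whole peak), so PC = 1
does not certify exact coincidence.

### Enrichment score (ES)

Cluster-based callers have no peaks to compare against, so ES asks
whether each loop is a local maximum of PET density. With anchor
coordinates `[s1, e1)` and `[s2, e2)` and mean anchor length
`l_m = (l_a + l_b)/2`, the four flanking windows are
`[s1 − l_m, s1)`, `[e1, e1 + l_m)`, `[s2 − l_m, s2)`, `[e2, e2 + l_m)`.
The neighbour count `P_n` is the smaller of the two per-anchor flank
sums, and `ES_i = C_i / P_n`. The assumption is that a genuine enriched
locus is surrounded by relatively depleted flanks; `ES_i < 1` marks a
loop whose neighbourhood out-enriches its anchors.

Numerical choices: flanking windows are clipped at position 0 and at
the chromosome end (loops near edges are kept with truncated flanks,
not discarded); a flank count of zero is replaced by a pseudocount of 1
so the ratio stays finite; a missing PET count is an error rather than
a silent zero.

The global ES corrects for uneven sequencing depth. Genome-wide PET
coverage is `C = L·N/G` (PET length × PET count / genome length) and
`C_j` is the same quantity per chromosome, so `α_j = C/C_j` boosts
under-covered chromosomes. Because `α_j` is chromosome-specific, the
global score is computed per chromosome as
`(Σ C_i / Σ max(P_n, 1)) · α_j` and aggregated across chromosomes with
PET-count weights `w_j = Σ_j C_i / Σ C_i`; a chromosome carrying loops
but no PETs is an error, since its coverage correction is undefined.

### Accuracy (ACC)

Detected loops are scored against a gold-standard "true" set and
(by default three) sampled "false" sets of the same size. Two loops
intersect when, after ordering anchors along the genome, anchor 1
overlaps anchor 1 and anchor 2 overlaps anchor 2 by at least 1 bp; a
reciprocal-fraction knob (`min_fraction`) tightens this when desired.
TP and FN come from the truth comparison; FP and TN are averaged over
the false-set replicates; `ACC = (TP + TN)/(TP + TN + FP + FN)`.

### Activation rate (AR)

Loops are pre-filtered for significance: PET count ≥ 3 (ChIA-PET) or
≥ 8 (HiChIP), and p ≤ 0.05 / FDR ≤ 0.05 where the calling method
reports them — missing values pass, since not every method emits
significance columns. Anchors are labelled E (enhancer-like overlap) or
P (promoter-like overlap); an anchor overlapping both takes the P
label, promoter annotations being the rarer and more specific signal,
and the loop class (E-E / E-P / P-P) is the pair of labels when both
anchors are annotated. Loops with neither anchor annotated are
excluded. Each retained loop's total anchor overlap with the coordinate
union of active-mark sets is compared against the union of
repressive-mark sets: strictly greater is active, strictly smaller
inactive, and equal-or-both-zero is "other". The union is the default
because the same base covered by two active datasets is one active
base; `per_mark = TRUE` sums per-dataset overlaps instead. AR is
active / (active + inactive + other).

### Resolution levels

The anchor distance `d` is measured midpoint to midpoint — the natural
symmetric choice when only "distance between anchors" is specified.
Intra-chromosomal loops are binned into `d ≤ 10 kb`,
`10 kb < d ≤ 100 kb`, `100 kb < d ≤ 1 Mb` (inclusive upper bounds);
loops beyond 1 Mb are excluded from all bins, and fractions are over
binned loops only.

### Score rescaling

For cross-method displays, ACC and AR are min-max rescaled per dataset:
`(x − min)/(max − min)`. When every method scores the same the
transformation is undefined; all methods are then mapped to 1 (equally
best), a deliberate convention so a degenerate dataset never penalises
anyone.

## Interval merging

`merge_intervals(x, f)` merges intervals overlapping by at least
fraction `f` of *each* member's length (reciprocal; a one-sided mode is
available since the underlying rule could be read either way). Each
round links every qualifying pair, replaces each linked group with its
union, and repeats to a fixpoint. This round-based closure is
idempotent and independent of input order, unlike greedy sequential
merging, which can give different results depending on which qualifying
pair is merged first. The cost is that two intervals joined through a
chain may themselves overlap by less than `f`.

## Gold-standard construction

Candidate loops are scored by *coverage*: the number of verified
contacts (eQTL variant–gene pairs with the variant expanded ± 5 kb,
CRISPR-validated enhancer–gene pairs, or Hi-C loops with
FDR ≤ 0.01 and counts ≥ 5) whose two regions overlap the loop's two
distinct anchors, in either orientation. "Significantly covered" needs
a null model, and none is prescribed by the coverage-counting framing
itself; a permutation null was chosen because it makes no parametric
assumption: the whole contact set is re-placed uniformly at random
(chromosome drawn by length, each contact keeping its region lengths
and inter-region distance) `n_perm` times (default 1000), and the
empirical p-value is `(1 + #{coverage ≥ observed})/(n_perm + 1)`.
P-values are Benjamini–Hochberg adjusted and loops pass at p < 0.05 and
FDR < 0.05 (strict, matching the stated thresholds). Zero-coverage
candidates are assigned p = 1 outright. All permutations are scored in
one vectorised interval join, so 1000 permutations over thousands of
contacts run in seconds.

Because coverage is a small integer, the permutation p-value is
discrete and conservative when mean null coverage is low; the
type-I-control test therefore uses a geometry (disjoint candidate
footprints, ~10 expected covering contacts per candidate under the
null) where the p-value distribution is close enough to uniform for
the nominal level to be meaningful.

False loop sets copy anchor lengths and anchor distances from randomly
drawn truth loops, so accuracy penalises *location*, not geometry
differences, and are placed by rejection sampling: neither anchor may
touch the exclusion mask (TSS and enhancer-like regions) and the loop
may intersect none of the excluded loop sets. Replicate `k` uses the
derived seed `seed + k`; a retry budget (default 1e5 per loop) turns an
over-dense mask into an explicit error rather than a hang.

## The simulators and fixture generator

`simulate_chiapet` segments chromosomes into 5 kb bins and draws
`n_ij ~ Poisson(a/(1 + δ))` for bin pairs at distance
`1 ≤ δ ≤ max_delta`. δ is measured in bin units: in base pairs the
intensity would be vanishingly small at any realistic distance,
contradicting the strong distance dependence the model is meant to
capture. Self-pairs (δ = 0, expectation `a`) appear in the companion
table but are not emitted as loops, and zero-count pairs are never
emitted, matching sparse BEDPE semantics. Each chromosome draws from a
substream seeded by the master seed and the chromosome name, so results
do not depend on chromosome order. The companion table (δ, λ, n) feeds
`estimate_a`, whose closed-form MLE `Σn / Σ 1/(1+δ)` validates that the
simulator draws from the distribution it advertises.

`simulate_hichip` emulates the ChIP-enrichment step: Hi-C anchor pairs
are scored by ChIP read count over both anchors and the
better-covered fraction is kept. The 50% threshold is read as a median
cut across candidate pairs (the cutoff is the `(⌊t·n⌋+1)`-th smallest
score, keeping `⌈(1−t)·n⌉` pairs up to ties; all pairs tie → all kept);
an absolute mode (covered-base fraction ≥ t) is available since the
denominator of "50%" could be read either way.

`make_fixture` writes a complete synthetic input bundle in which every
metric's expected value is planted by construction: an exact UV
fraction (each failing PET fails exactly one filter), gold loops
carrying verified contacts placed exactly on their anchors, ChIP peaks
coinciding with anchors (PC = 1), per-loop active/inactive/other
labels with exact overlap lengths, and a known distance profile.
Candidate loops occupy disjoint windows so no planted signal bleeds
between loops.

What the generators do *not* emulate: mappability and GC structure,
restriction-site biases, chromatin-domain correlation between nearby
contacts, duplicate-rate structure, or inter-chromosomal contacts.
Passing tests therefore demonstrate that the metrics compute their
definitions correctly and that the statistical machinery is calibrated
under its own model — not that any particular caller ranks correctly on
real data.

## Problem sizes and test design

Oracle agreement is checked on 100 randomized instances per metric at
small scale (tens of intervals, hundreds of PETs) against deliberately
naive reimplementations (explicit loops, linear scans). Simulator
moments use one 60 Mb chromosome (≥ 10⁴ draws per δ); parameter
recovery uses 5,000 pairs × 3 seeds for a ∈ {1, 5, 10}; type-I control
uses 1000 candidates × 1000 permutations × 10,000 contacts. These sizes
give stable statistics while the full suite runs in about a minute and
a half on one CPU.

## Known limitations

- Inter-chromosomal loops carry no distance and are excluded from
  resolution profiles; global ES currently requires intra-chromosomal
  loops.
- The PC literal mode can exceed 1 by design; comparisons across
  methods should use the normalized mode or rescaled scores.
- The permutation null re-places contacts uniformly, ignoring the
  accessibility landscape; on real genomes a masked or GC-matched
  placement would be more faithful.
- BEDPE extra columns are mapped positionally (`pet_count` = column 7
  by default); caller-specific layouts need an explicit column map.
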