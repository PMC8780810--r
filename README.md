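# loopeval

Benchmarking toolkit for chromatin loops called from targeted chromatin
conformation capture experiments (ChIA-PET and HiChIP).

Loop callers for these assays disagree wildly — in how they pre-process
paired-end tags (PETs), how they seed anchors, and which interactions
they deem significant — and there is no ground truth to compare them
against directly. `loopeval` implements a metric suite that scores a
loop set from several independent angles, plus the machinery to build
reference sets and simulate data with known truth:

- **UV Rate** — the fraction of PETs that are *u*niquely mapped
  (both ends MAPQ ≥ 30), non-duplicate, and *v*alid (inter-ligation):
  a joint measure of library quality and pre-processing stringency.
- **Peak co-occupancy (PC)** — for peak-based callers, how well merged
  loop anchors coincide with ChIP-seq peaks. Each anchor overlapping a
  peak contributes `max(L(o)/L(p), L(o)/L(a))` (overlap length over peak
  and anchor length); the bounded, normalized summary is the mean term
  over all `N` anchors, and the literal form multiplies by the candidate
  count `N_A`.
- **Enrichment score (ES)** — for cluster-based callers,
  `ES_i = C_i / P_n_i`: the loop's PET count over the smaller of its two
  anchors' flanking-window PET counts (flank width `l_m`, the mean
  anchor length). A true anchor should be a local maximum of PET
  density, so `ES_i < 1` flags an invalid loop. The global ES corrects
  each chromosome by `α_j = C / C_j` (genome-wide over per-chromosome
  PET coverage, `C = LN/G`).
- **Accuracy (ACC)** — `(TP + TN) / (TP + TN + FP + FN)` against a
  gold-standard "true" loop set and three sampled "false" loop sets of
  matched size and geometry (FP and TN averaged over replicates).
- **Activation rate (AR)** — among significant loops with
  enhancer/promoter-annotated anchors, the fraction whose anchors
  overlap active marks (H3K27ac, H3K4me1, H3K4me3) by more total length
  than repressive marks (H3K27me3).
- **Resolution levels** — the distribution of anchor distances over
  ≤ 10 kb, 10–100 kb, and 100 kb–1 Mb.

Around the metrics, the package provides the gold-standard construction
(coverage of candidate loops by verified contacts — eQTL variant–gene
pairs, CRISPR-validated enhancer–gene pairs, strong Hi-C loops — tested
against a permutation null), matched false-set sampling that avoids
regulatory regions, a distance-decay Poisson simulator of ChIA-PET
contacts (`n_ij ~ Pois(a / (1 + δ))` over 5 kb bins), a ChIP-coverage
HiChIP simulator, and a fixture generator that plants every expected
value for end-to-end testing.

Everything is a tibble in and a tibble out: BEDPE loop sets, BED peak
and annotation sets, and tabular PET records flow through `dplyr`-style
verbs and compose with the pipe.

## Worked example

Generate a synthetic bundle with planted truth and evaluate it as if it
were a caller's output:

```r
library(loopeval)

fx <- make_fixture("demo", seed = 1)   # plants UV 0.4, 20/100 gold loops, AR 0.6
report <- evaluate_loops(list(
  loops = fx$paths$loops, sizes = fx$paths$sizes, pets = fx$paths$pets,
  chip_peaks = fx$paths$chip_peaks, enhancers = fx$paths$enhancers,
  promoters = fx$paths$promoters, tss = fx$paths$tss,
  active_marks = fx$paths$active_marks,
  repressive_marks = fx$paths$repressive_marks,
  contacts = fx$paths$contacts,
  protocol = "chiapet", method_class = "peak",
  label = "demo_caller", seed = 1
))
dplyr::select(tibble::as_tibble(report),
              method, uv_rate, pc_normalized, acc, ar, res_le10k)
#> # A tibble: 1 × 6
#>   method      uv_rate pc_normalized   acc    ar res_le10k
#>   <chr>         <dbl>         <dbl> <dbl> <dbl>     <dbl>
#> 1 demo_caller     0.4             1     1   0.6      0.34
```

The report reproduces the planted values exactly: 40% of the PETs were
built to pass the UV filters, the ChIP peaks coincide with the anchors
(PC = 1), the gold set built from the planted contacts is recovered in
full and the candidate set matches it (ACC = 1), 60% of loops carry
more active than repressive mark overlap, and a third of the planted
distances fall at 5 kb.

Simulate ChIA-PET contacts and recover the intensity parameter:

```r
sim <- simulate_chiapet(c(chr19 = 5e7), a = 10, max_delta = 10, seed = 1)
head(sim$loops, 3)
#> # A tibble: 3 × 7
#>   chrom1 start1  end1 chrom2 start2  end2 pet_count
#>   <chr>   <dbl> <dbl> <chr>   <dbl> <dbl>     <int>
#> 1 chr19       0  5000 chr19    5000 10000         6
#> 2 chr19    5000 10000 chr19   10000 15000         5
#> 3 chr19   10000 15000 chr19   15000 20000         6
estimate_a(sim$table)
#> [1] 9.982272
```

Report objects have broom-style accessors and plots:

```r
glance(attr(report, "details")$ar)
#> # A tibble: 1 × 8
#>   activation_rate n_classified active inactive other    ee    ep    pp
#>             <dbl>        <int>  <int>    <int> <int> <int> <int> <int>
#> 1             0.6          100     60       25    15     0   100     0
autoplot(compare_methods(reports))   # method × metric heatmap
```

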