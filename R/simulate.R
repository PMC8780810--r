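# Distance-decay Poisson simulation of ChIA-PET contacts, coverage-based
# HiChIP simulation, and the closed-form intensity estimator used to
# validate the simulator.

# Per-chromosome substream seed derived from the master seed and the
# chromosome name, so results do not depend on chromosome order.
chrom_seed <- function(seed, chrom) {
  h <- 0
  for (code in utf8ToInt(chrom)) h <- (h * 131 + code) %% 1000003
  as.integer((seed + 7919 * h) %% .Machine$integer.max)
}

#' Simulate ChIA-PET contacts with a distance-decay Poisson model
#'
#' Segments each chromosome into fixed-size bins and, for every
#' intra-chromosomal bin pair (i, j) with bin-distance
#' `delta = |i - j|` between 1 and `max_delta`, draws an interaction
#' count `n_ij ~ Poisson(lambda_ij)` with `lambda_ij = a / (1 + delta)`,
#' so contact frequency decays with genomic distance. Pairs with a
#' positive draw become loops whose anchors are the two bins and whose
#' `pet_count` is the draw. Self-pairs (delta = 0, where the expectation
#' equals `a`) are not emitted as loops but appear in the companion
#' table when `include_self = TRUE`.
#'
#' @param sizes Named chromosome lengths.
#' @param a Poisson intensity scale; the expected count at distance
#'   `delta` is `a / (1 + delta)`.
#' @param bin_size Bin width in bp; default 5000.
#' @param max_delta Largest bin distance simulated; clipped (with a
#'   warning) to the chromosome's bin count minus one.
#' @param seed Integer seed; each chromosome uses a substream derived
#'   from it and the chromosome name.
#' @param include_self Include delta = 0 rows in the table.
#' @return A list with `loops` (tibble of positive-count pairs) and
#'   `table` (tibble of all simulated pairs: `chrom, i, j, delta,
#'   lambda, n`).
#' @export
simulate_chiapet <- function(sizes, a, bin_size = 5000, max_delta = 100,
                             seed = 1, include_self = FALSE) {
  stopifnot(a > 0, bin_size > 0, max_delta >= 1)
  tabs <- vector("list", length(sizes))
  for (ci in seq_along(sizes)) {
    chrom <- names(sizes)[ci]
    n_bins <- floor(sizes[[ci]] / bin_size)
    if (n_bins < 2) next
    md <- max_delta
    if (md > n_bins - 1) {
      warn(paste0("max_delta clipped to ", n_bins - 1, " on ", chrom))
      md <- n_bins - 1
    }
    set.seed(chrom_seed(seed, chrom))
    d0 <- if (include_self) 0L else 1L
    parts <- vector("list", md - d0 + 1)
    for (delta in d0:md) {
      i <- seq_len(n_bins - delta)
      lambda <- a / (1 + delta)
      parts[[delta - d0 + 1]] <- tibble(
        chrom = chrom, i = i, j = i + delta, delta = delta,
        lambda = lambda, n = rpois(length(i), lambda)
      )
    }
    tabs[[ci]] <- bind_rows(parts)
  }
  tab <- bind_rows(tabs)
  if (nrow(tab) == 0) abort("no simulable bin pairs; enlarge the genome")
  emit <- tab[tab$n > 0 & tab$delta >= 1, , drop = FALSE]
  loops <- tibble(
    chrom1 = emit$chrom,
    start1 = (emit$i - 1) * bin_size, end1 = emit$i * bin_size,
    chrom2 = emit$chrom,
    start2 = (emit$j - 1) * bin_size, end2 = emit$j * bin_size,
    pet_count = emit$n
  )
  list(loops = loops, table = tab)
}

#' Simulate HiChIP anchor pairs by ChIP-coverage filtering
#'
#' HiChIP enriches Hi-C contacts at protein-bound sites, so simulated
#' HiChIP pairs are Hi-C anchor pairs kept when their ChIP-seq read
#' coverage is high. Each pair is scored by the number of ChIP reads
#' falling in either anchor; pairs whose score reaches the
#' `coverage_threshold` quantile of all pair scores are retained, so a
#' threshold of 0.5 (the default) keeps the better-covered half of the
#' pairs (exactly `ceiling((1 - threshold) * n)` pairs up to ties; when
#' every pair scores equally, all are retained).
#'
#' @param hic_pairs Loop tibble of Hi-C anchor pairs (binned).
#' @param chip_reads A [pet_track()] (or tibble with `chrom`, `pos`) of
#'   ChIP-seq read positions.
#' @param coverage_threshold Quantile in (0, 1); default 0.5.
#' @param mode `"quantile"` ranks pairs against each other (default);
#'   `"absolute"` instead keeps pairs whose covered anchor-base fraction
#'   is at least the threshold.
#' @return The retained pairs with a `chip_coverage` column.
#' @export
simulate_hichip <- function(hic_pairs, chip_reads, coverage_threshold = 0.5,
                            mode = c("quantile", "absolute")) {
  mode <- match.arg(mode)
  check_loops(hic_pairs, "hic_pair")
  if (nrow(hic_pairs) == 0) abort("empty Hi-C pair set")
  stopifnot(coverage_threshold > 0, coverage_threshold < 1)
  if (!inherits(chip_reads, "pet_track")) chip_reads <- pet_track(chip_reads)
  score <- count_track(chip_reads, hic_pairs$chrom1, hic_pairs$start1, hic_pairs$end1) +
    count_track(chip_reads, hic_pairs$chrom2, hic_pairs$start2, hic_pairs$end2)
  hic_pairs$chip_coverage <- score
  if (mode == "absolute") {
    width <- (hic_pairs$end1 - hic_pairs$start1) + (hic_pairs$end2 - hic_pairs$start2)
    keep <- score / width >= coverage_threshold
  } else {
    k <- floor(coverage_threshold * length(score) + 1e-9)
    cutoff <- if (k == 0) -Inf else sort(score)[k + 1]
    keep <- score >= cutoff
  }
  hic_pairs[keep, , drop = FALSE]
}

#' Closed-form intensity estimate from a simulation table
#'
#' Under the model `n_ij ~ Poisson(a / (1 + delta))` the maximum
#' likelihood estimate of `a` from observed pairs is
#' `sum(n) / sum(1 / (1 + delta))`. Used to validate that
#' [simulate_chiapet()] draws from the distribution it advertises.
#'
#' @param sim_table Tibble with columns `delta` and `n` (the companion
#'   table of [simulate_chiapet()]).
#' @return The estimate `a_hat`.
#' @export
estimate_a <- function(sim_table) {
  if (nrow(sim_table) == 0) abort("empty simulation table")
  stopifnot(all(c("delta", "n") %in% names(sim_table)))
  sum(sim_table$n) / sum(1 / (1 + sim_table$delta))
}
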