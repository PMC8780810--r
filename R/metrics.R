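# Loop-set quality metrics: UV Rate, peak co-occupancy, significance
# filtering, resolution levels and score rescaling.

#' Classify PETs by ligation type
#'
#' A paired-end tag is a self-ligation product when both ends map to the
#' same chromosome within a short span (the circularised fragment), an
#' inter-ligation product when the ends are far apart or on different
#' chromosomes, and invalid when flagged so upstream. Rows already
#' carrying a `ligation_class` of `"invalid"` keep it.
#'
#' @param pets PET tibble (see [read_pets()]).
#' @param self_ligation_cutoff Same-chromosome span (bp, midpoint to
#'   midpoint) below which a PET is self-ligation. Default 8000; sensible
#'   values lie in 5000--12000.
#' @return The tibble with a `ligation_class` column.
#' @export
classify_pets <- function(pets, self_ligation_cutoff = 8000) {
  stopifnot(self_ligation_cutoff >= 0)
  mid1 <- (pets$start1 + pets$end1) / 2
  mid2 <- (pets$start2 + pets$end2) / 2
  span <- abs(mid2 - mid1)
  cls <- ifelse(
    pets$chrom1 == pets$chrom2 & span < self_ligation_cutoff,
    "self_ligation", "inter_ligation"
  )
  if ("ligation_class" %in% names(pets)) {
    keep <- !is.na(pets$ligation_class) & pets$ligation_class == "invalid"
    cls[keep] <- "invalid"
  }
  pets$ligation_class <- cls
  pets
}

#' Uniquely mapped valid PET rate
#'
#' The UV Rate is the fraction of PETs that survive pre-processing: both
#' ends mapped with MAPQ at least `mapq_min`, not a PCR duplicate, and an
#' inter-ligation (valid) product. It summarises both wet-lab library
#' quality and the stringency of a pipeline's pre-processing.
#'
#' @param pets PET tibble with `mapq1`, `mapq2`, `duplicate`,
#'   `ligation_class`.
#' @param mapq_min Minimum mapping quality for both ends; default 30.
#' @return A single number in \[0, 1\].
#' @export
uv_rate <- function(pets, mapq_min = 30) {
  if (nrow(pets) == 0) abort("uv_rate is undefined for an empty PET set")
  stopifnot(all(c("mapq1", "mapq2", "duplicate", "ligation_class") %in% names(pets)))
  uv <- pets$mapq1 >= mapq_min & pets$mapq2 >= mapq_min &
    !pets$duplicate & pets$ligation_class == "inter_ligation"
  sum(uv) / nrow(pets)
}

#' Peak co-occupancy of loop anchors
#'
#' Measures how well loop anchors coincide with ChIP-seq peaks, the
#' reliability metric for peak-based loop callers. Every anchor with at
#' least 1 bp of peak overlap joins the candidate set A; for each such
#' anchor the peak with the longest overlap is selected (ties broken by
#' leftmost peak start) and the anchor contributes
#' `max(L(o)/L(p), L(o)/L(a))`, the overlap length relative to whichever
#' of peak or anchor it covers best. Anchors outside A contribute 0.
#'
#' Two summaries are available: `"literal"` returns
#' `N_A * sum(terms) / N` (the co-occupancy score as originally printed,
#' which exceeds 1 when many anchors match well), and `"normalized"`
#' (default) returns `sum(terms) / N`, bounded in \[0, 1\].
#'
#' Anchors should be merged beforehand ([merge_intervals()] at 90%
#' reciprocal overlap) so near-duplicate anchors are not double counted.
#'
#' @param anchors Tibble of anchor intervals (`chrom`, `start`, `end`).
#' @param peaks Tibble of ChIP-seq peaks.
#' @param mode `"normalized"` or `"literal"`.
#' @return A list with `pc` (the score), `n_anchors`, `n_candidate`, and
#'   `per_anchor` (tibble with the selected peak and term per anchor).
#' @export
peak_co_occupancy <- function(anchors, peaks, mode = c("normalized", "literal")) {
  mode <- match.arg(mode)
  if (nrow(anchors) == 0) abort("peak_co_occupancy needs at least one anchor")
  check_intervals(anchors, "anchor")
  n <- nrow(anchors)
  per_anchor <- tibble(
    anchor = seq_len(n),
    peak = NA_integer_,
    overlap = 0,
    term = 0
  )
  if (nrow(peaks) > 0) {
    check_intervals(peaks, "peak")
    hits <- overlap_pairs(anchors, peaks)
    if (nrow(hits) > 0) {
      best <- hits |>
        mutate(peak_start = peaks$start[.data$subject]) |>
        group_by(.data$query) |>
        arrange(dplyr::desc(.data$overlap), .data$peak_start, .data$subject,
                .by_group = TRUE) |>
        dplyr::slice(1) |>
        ungroup()
      la <- anchors$end[best$query] - anchors$start[best$query]
      lp <- peaks$end[best$subject] - peaks$start[best$subject]
      per_anchor$peak[best$query] <- best$subject
      per_anchor$overlap[best$query] <- best$overlap
      per_anchor$term[best$query] <- pmax(best$overlap / lp, best$overlap / la)
    }
  }
  n_a <- sum(!is.na(per_anchor$peak))
  total <- sum(per_anchor$term)
  pc <- switch(mode,
    literal = n_a * total / n,
    normalized = total / n
  )
  list(pc = pc, n_anchors = n, n_candidate = n_a, per_anchor = per_anchor, mode = mode)
}

#' Keep statistically significant loops
#'
#' Applies the pre-filters used before functional evaluation: a minimum
#' PET count of 3 for ChIA-PET or 8 for HiChIP, and, where the calling
#' method reports them, p-value and FDR at most 0.05. Missing p/FDR
#' values pass (not every method emits them).
#'
#' @param loops Loop tibble with `pet_count` and optional `p_value`, `fdr`.
#' @param protocol `"chiapet"` or `"hichip"`.
#' @param p_max,fdr_max Significance thresholds, default 0.05 each.
#' @return The filtered loop tibble.
#' @export
filter_significant <- function(loops, protocol = c("chiapet", "hichip"),
                               p_max = 0.05, fdr_max = 0.05) {
  protocol <- match.arg(protocol)
  if (!"pet_count" %in% names(loops)) abort("loops lack a pet_count column")
  pet_min <- switch(protocol, chiapet = 3, hichip = 8)
  keep <- !is.na(loops$pet_count) & loops$pet_count >= pet_min
  if ("p_value" %in% names(loops)) {
    keep <- keep & (is.na(loops$p_value) | loops$p_value <= p_max)
  }
  if ("fdr" %in% names(loops)) {
    keep <- keep & (is.na(loops$fdr) | loops$fdr <= fdr_max)
  }
  loops[keep, , drop = FALSE]
}

#' Resolution-level profile of a loop set
#'
#' Computes the anchor-to-anchor distance `d` (midpoint to midpoint) of
#' each intra-chromosomal loop and reports the fraction of loops in the
#' three resolution bins: `d <= 10 kb`, `10 kb < d <= 100 kb` and
#' `100 kb < d <= 1 Mb`. Loops beyond 1 Mb (and inter-chromosomal loops,
#' which carry no distance) are excluded from all bins.
#'
#' @param loops Loop tibble.
#' @return Tibble with columns `bin`, `n`, `fraction`; fractions sum to 1.
#' @export
resolution_levels <- function(loops) {
  check_loops(loops)
  intra <- loops[loops$chrom1 == loops$chrom2, , drop = FALSE]
  d <- abs((intra$start2 + intra$end2) / 2 - (intra$start1 + intra$end1) / 2)
  d <- d[d <= 1e6]
  if (length(d) == 0) abort("no loops within 1 Mb; resolution levels undefined")
  n_bins <- c(
    sum(d <= 1e4),
    sum(d > 1e4 & d <= 1e5),
    sum(d > 1e5 & d <= 1e6)
  )
  tibble(
    bin = c("le10k", "10k_100k", "100k_1m"),
    n = n_bins,
    fraction = n_bins / sum(n_bins)
  )
}

#' Min-max rescale scores across methods
#'
#' Rescales a vector of per-method scores to \[0, 1\] by
#' `(x - min) / (max - min)`, the transformation applied to ACC and AR
#' before cross-method comparison. When all inputs are equal every method
#' is treated as equally best and all values map to 1.
#'
#' @param values Numeric vector, length at least 2, all finite.
#' @return Rescaled numeric vector.
#' @export
scale_scores <- function(values) {
  if (length(values) < 2) abort("scale_scores needs at least 2 values")
  if (any(!is.finite(values))) abort("scale_scores needs finite values")
  rng <- range(values)
  if (rng[1] == rng[2]) return(rep(1, length(values)))
  (values - rng[1]) / (rng[2] - rng[1])
}
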