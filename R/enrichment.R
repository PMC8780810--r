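# Enrichment scores for cluster-based loop callers. A true loop anchor
# should be a local maximum of PET density, so each loop's PET count is
# compared with the PET count in flanking windows of width l_m (the mean
# anchor length) on both sides of each anchor.

flank_counts <- function(loops, track, sizes = NULL) {
  l_m <- ((loops$end1 - loops$start1) + (loops$end2 - loops$start2)) / 2
  clip_hi <- function(chrom, x) {
    if (is.null(sizes)) return(x)
    pmin(x, unname(sizes[chrom]))
  }
  # four flanks: [s1-lm, s1), [e1, e1+lm), [s2-lm, s2), [e2, e2+lm)
  p_l1 <- count_track(track, loops$chrom1, loops$start1 - l_m, loops$start1)
  p_r1 <- count_track(track, loops$chrom1, loops$end1,
                      clip_hi(loops$chrom1, loops$end1 + l_m))
  p_l2 <- count_track(track, loops$chrom2, loops$start2 - l_m, loops$start2)
  p_r2 <- count_track(track, loops$chrom2, loops$end2,
                      clip_hi(loops$chrom2, loops$end2 + l_m))
  pmin(p_l1 + p_r1, p_l2 + p_r2)
}

#' Per-loop enrichment score
#'
#' For each loop the score is `ES_i = C_i / P_n_i`, where `C_i` is the
#' loop's PET count and `P_n_i` is the smaller of the two anchors' total
#' flanking PET counts. Flanks have width `l_m = (l_a + l_b) / 2`, the
#' mean of the two anchor lengths, one on each side of each anchor;
#' windows are clipped at position 0 and, when `sizes` is supplied, at
#' the chromosome end. A zero flank count is replaced by 1 so the ratio
#' stays defined. `ES_i < 1` marks a loop whose neighbourhood is more
#' enriched than its anchors, i.e. a likely invalid loop.
#'
#' @param loops Loop tibble with `pet_count`.
#' @param track A [pet_track()] of PET end positions.
#' @param sizes Optional named vector of chromosome lengths used to clip
#'   flanking windows.
#' @return The loop tibble with extra columns `p_n`, `es`, and `valid`
#'   (`es >= 1`).
#' @export
enrichment_score <- function(loops, track, sizes = NULL) {
  check_loops(loops)
  if (!"pet_count" %in% names(loops) || any(is.na(loops$pet_count))) {
    abort("enrichment_score requires a pet_count for every loop")
  }
  p_n <- flank_counts(loops, track, sizes)
  loops$p_n <- p_n
  loops$es <- loops$pet_count / pmax(p_n, 1)
  loops$valid <- loops$es >= 1
  loops
}

#' Genome-wide enrichment score with coverage correction
#'
#' Aggregates per-loop enrichment into a global score while correcting
#' for uneven sequencing depth across chromosomes. The genome-wide PET
#' coverage is `C = L * N / G` (PET length times PET count over genome
#' length); each chromosome's coverage `C_j` is computed the same way
#' from the PETs mapped to it, and the chromosome's score
#' `sum(C_i) / sum(P_n_i)` is multiplied by `alpha_j = C / C_j`, boosting
#' chromosomes whose low coverage depresses raw counts. Chromosome scores
#' are combined into a single genome value by PET-count weights
#' `w_j = sum_j(C_i) / sum(C_i)`.
#'
#' @param loops Loop tibble with `pet_count`; intra-chromosomal loops.
#' @param track [pet_track()] of PET end positions (used both for flank
#'   counts and per-chromosome PET tallies).
#' @param sizes Named vector of chromosome lengths.
#' @param pet_length PET (read) length `L` in bp.
#' @param n_pets Total number of PETs `N`; defaults to the number of track
#'   positions.
#' @return An object of class `es_report`: a list with `per_loop`,
#'   `per_chrom` (with `alpha` and `es_g` per chromosome), and
#'   `es_global`.
#' @export
global_es <- function(loops, track, sizes, pet_length, n_pets = NULL) {
  scored <- enrichment_score(loops, track, sizes)
  if (any(scored$chrom1 != scored$chrom2)) {
    abort("global_es expects intra-chromosomal loops")
  }
  n_pets <- n_pets %||% track$n
  g <- sum(sizes)
  cov_genome <- pet_length * n_pets / g
  per_chrom <- scored |>
    group_by(chrom = .data$chrom1) |>
    summarise(
      sum_c = sum(.data$pet_count),
      sum_pn = sum(pmax(.data$p_n, 1)),
      .groups = "drop"
    )
  n_on_chrom <- vapply(per_chrom$chrom, function(chr) {
    length(track$pos[[chr]])
  }, numeric(1))
  if (any(n_on_chrom == 0)) {
    abort(paste0("chromosome with loops but no PET coverage: ",
                 per_chrom$chrom[which(n_on_chrom == 0)[1]]))
  }
  cov_chrom <- unname(pet_length * n_on_chrom / unname(sizes[per_chrom$chrom]))
  per_chrom$coverage <- cov_chrom
  per_chrom$alpha <- cov_genome / cov_chrom
  per_chrom$es_g <- per_chrom$sum_c / per_chrom$sum_pn * per_chrom$alpha
  per_chrom$weight <- per_chrom$sum_c / sum(per_chrom$sum_c)
  structure(
    list(
      per_loop = scored,
      per_chrom = per_chrom,
      es_global = sum(per_chrom$weight * per_chrom$es_g),
      coverage_genome = cov_genome
    ),
    class = "es_report"
  )
}

#' @export
print.es_report <- function(x, ...) {
  cat("<es_report> ", nrow(x$per_loop), " loops on ", nrow(x$per_chrom),
      " chromosome(s); global ES = ", format(x$es_global, digits = 4), "\n", sep = "")
  invisible(x)
}
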