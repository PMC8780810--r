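# Gold-standard loop construction: candidate loops significantly covered
# by externally verified contacts (eQTL variant-gene pairs, CRISPR-
# validated enhancer-gene pairs, strong Hi-C loops), plus the matched
# "false" loop sets sampled away from regulatory regions.

#' Expand variant loci by a flank
#'
#' eQTL variants are point (or near-point) loci; before overlapping with
#' loop anchors each is extended by `flank` bases on both ends, clipped
#' at position 0 and at the chromosome end when `sizes` is given.
#'
#' @param variants Tibble with `chrom`, `start`, `end`.
#' @param flank Extension in bp on each side; default 5000.
#' @param sizes Optional named chromosome lengths for clipping; variants
#'   lying beyond their chromosome end raise an error.
#' @return The expanded tibble.
#' @export
expand_variants <- function(variants, flank = 5000, sizes = NULL) {
  check_intervals(variants, "variant")
  stopifnot(flank >= 0)
  out <- variants
  out$start <- pmax(0, variants$start - flank)
  out$end <- variants$end + flank
  if (!is.null(sizes)) {
    len <- unname(sizes[variants$chrom])
    if (any(is.na(len))) abort("variant on a chromosome absent from sizes")
    if (any(variants$start >= len)) {
      abort(paste0("variant beyond chromosome end at row ",
                   which(variants$start >= len)[1]))
    }
    out$end <- pmin(out$end, len)
  }
  out
}

# Coverage of candidate loops by verified contacts: a contact covers a
# loop when its two regions each overlap a distinct anchor (either
# orientation). Contacts are loop-shaped tibbles (region A = anchor1
# columns, region B = anchor2 columns).
contact_coverage <- function(candidates, contacts, distinct_anchors = TRUE) {
  a1 <- tibble(chrom = candidates$chrom1, start = candidates$start1, end = candidates$end1)
  a2 <- tibble(chrom = candidates$chrom2, start = candidates$start2, end = candidates$end2)
  ra <- tibble(chrom = contacts$chrom1, start = contacts$start1, end = contacts$end1)
  rb <- tibble(chrom = contacts$chrom2, start = contacts$start2, end = contacts$end2)
  hit_tab <- function(regions, anchors) {
    h <- overlap_pairs(regions, anchors)
    tibble(contact = h$query, loop = h$subject)
  }
  # orientation 1: A on anchor1 & B on anchor2; orientation 2: swapped
  pairs <- bind_rows(
    inner_join(hit_tab(ra, a1), hit_tab(rb, a2), by = c("contact", "loop")),
    inner_join(hit_tab(ra, a2), hit_tab(rb, a1), by = c("contact", "loop"))
  ) |> dplyr::distinct(.data$contact, .data$loop)
  if (!distinct_anchors) {
    # relax: both regions may hit the same anchor
    same <- bind_rows(
      inner_join(hit_tab(ra, a1), hit_tab(rb, a1), by = c("contact", "loop")),
      inner_join(hit_tab(ra, a2), hit_tab(rb, a2), by = c("contact", "loop"))
    )
    pairs <- dplyr::distinct(bind_rows(pairs, same), .data$contact, .data$loop)
  }
  cov <- rep(0L, nrow(candidates))
  if (nrow(pairs) > 0) {
    agg <- pairs |> group_by(.data$loop) |> summarise(n = n())
    cov[agg$loop] <- agg$n
  }
  cov
}

# Place contacts uniformly at random preserving each contact's region
# lengths and inter-region distance (region-A-start to region-B-start).
# Chromosomes are drawn weighted by length among those long enough.
place_contacts_random <- function(len_a, len_b, gap, sizes, n_rep = 1) {
  total <- length(len_a) * n_rep
  span <- gap + len_b # footprint from A start to B end (gap = startB - startA)
  len_a_r <- rep(len_a, n_rep)
  span_r <- rep(span, n_rep)
  extent <- pmax(len_a_r, span_r)
  chroms <- names(sizes)
  w <- as.numeric(sizes) / sum(as.numeric(sizes))
  chr_idx <- sample.int(length(chroms), total, replace = TRUE, prob = w)
  max_start <- unname(sizes[chr_idx]) - extent
  # redraw chromosomes too short for a given contact
  retry <- which(max_start < 0)
  guard <- 0
  while (length(retry) > 0 && guard < 100) {
    chr_idx[retry] <- sample.int(length(chroms), length(retry), replace = TRUE, prob = w)
    max_start <- unname(sizes[chr_idx]) - extent
    retry <- which(max_start < 0)
    guard <- guard + 1
  }
  if (length(retry) > 0) abort("contacts too long for every chromosome")
  s_a <- floor(runif(total) * (max_start + 1))
  tibble(
    chrom1 = chroms[chr_idx], start1 = s_a, end1 = s_a + len_a_r,
    chrom2 = chroms[chr_idx], start2 = s_a + rep(gap, n_rep),
    end2 = s_a + span_r
  )
}

#' Build a gold-standard loop set from verified contacts
#'
#' Counts, for every candidate loop, how many verified contacts cover it
#' (both contact regions overlapping distinct anchors), then asks whether
#' that coverage is higher than expected by chance. The null is built by
#' permutation: the contact set is re-placed uniformly at random
#' `n_perm` times, preserving each contact's region lengths and
#' inter-region distance, and each candidate's empirical p-value is
#' `(1 + #permutations with coverage >= observed) / (n_perm + 1)`.
#' P-values are Benjamini-Hochberg adjusted and candidates with
#' `p < p_max` and `FDR < fdr_max` form the gold set.
#'
#' @param candidates Candidate loop tibble.
#' @param contacts Verified contacts as a loop-shaped tibble (region A in
#'   the anchor-1 columns, region B in the anchor-2 columns), e.g. eQTL
#'   variant (after [expand_variants()]) paired with its gene, or a
#'   CRISPR-validated enhancer-gene pair, or strong Hi-C loops.
#' @param sizes Named chromosome lengths (the permutation universe).
#' @param p_max,fdr_max Strict significance thresholds; default 0.05.
#' @param n_perm Number of permutations; default 1000.
#' @param seed Integer seed for the permutation draws.
#' @param distinct_anchors Require the two contact regions to hit
#'   different anchors (default TRUE).
#' @return The selected candidate rows with `coverage`, `p_value` and
#'   `fdr` columns; the full scored table is attached as attribute
#'   `"scores"`.
#' @export
build_gold_set <- function(candidates, contacts, sizes, p_max = 0.05,
                           fdr_max = 0.05, n_perm = 1000, seed = 1,
                           distinct_anchors = TRUE) {
  check_loops(candidates, "candidate")
  check_loops(contacts, "contact")
  if (nrow(contacts) == 0) abort("no verified contacts supplied")
  if (nrow(candidates) == 0) abort("no candidate loops supplied")
  obs <- contact_coverage(candidates, contacts, distinct_anchors)
  len_a <- contacts$end1 - contacts$start1
  len_b <- contacts$end2 - contacts$start2
  gap <- contacts$start2 - contacts$start1
  n_c <- nrow(contacts)
  exceed <- rep(0L, nrow(candidates))
  set.seed(seed)
  chunk <- max(1L, min(200L, floor(2e6 / max(1, n_c))))
  done <- 0L
  while (done < n_perm) {
    k <- min(chunk, n_perm - done)
    placed <- place_contacts_random(len_a, len_b, gap, sizes, n_rep = k)
    placed$perm <- rep(seq_len(k), each = n_c)
    # score all k permutations in one overlap join
    a1 <- tibble(chrom = candidates$chrom1, start = candidates$start1, end = candidates$end1)
    a2 <- tibble(chrom = candidates$chrom2, start = candidates$start2, end = candidates$end2)
    ra <- tibble(chrom = placed$chrom1, start = placed$start1, end = placed$end1)
    rb <- tibble(chrom = placed$chrom2, start = placed$start2, end = placed$end2)
    h_a1 <- overlap_pairs(ra, a1); h_b2 <- overlap_pairs(rb, a2)
    h_a2 <- overlap_pairs(ra, a2); h_b1 <- overlap_pairs(rb, a1)
    jn <- function(h1, h2) {
      inner_join(
        tibble(contact = h1$query, loop = h1$subject),
        tibble(contact = h2$query, loop = h2$subject),
        by = c("contact", "loop")
      )
    }
    pairs <- bind_rows(jn(h_a1, h_b2), jn(h_a2, h_b1))
    if (!distinct_anchors) {
      pairs <- bind_rows(pairs, jn(h_a1, h_b1), jn(h_a2, h_b2))
    }
    pairs <- dplyr::distinct(pairs, .data$contact, .data$loop)
    if (nrow(pairs) > 0) {
      pairs$perm <- placed$perm[pairs$contact]
      cov_tab <- pairs |>
        group_by(.data$perm, .data$loop) |>
        summarise(n = n(), .groups = "drop") |>
        filter(.data$n >= obs[.data$loop])
      if (nrow(cov_tab) > 0) {
        add <- cov_tab |> group_by(.data$loop) |> summarise(k = n())
        exceed[add$loop] <- exceed[add$loop] + add$k
      }
    }
    done <- done + k
  }
  # candidates with zero observed coverage can never beat the null
  p <- ifelse(obs == 0, 1, (1 + exceed) / (n_perm + 1))
  fdr <- p.adjust(p, method = "BH")
  scores <- candidates |>
    mutate(coverage = obs, p_value = p, fdr = fdr)
  gold <- scores[scores$coverage > 0 & p < p_max & fdr < fdr_max, , drop = FALSE]
  attr(gold, "scores") <- scores
  gold
}

#' Filter a Hi-C loop list down to strong signals
#'
#' Strong Hi-C loops, usable as verified contacts, are those with
#' `fdr <= fdr_max` and observed counts `>= min_count` (both boundaries
#' inclusive). Loop lists lacking an FDR column are filtered on counts
#' alone.
#'
#' @param hic_loops Loop tibble with `pet_count` (observed counts) and
#'   optionally `fdr`.
#' @param fdr_max Default 0.01.
#' @param min_count Default 5.
#' @return The filtered tibble.
#' @export
filter_strong_hic <- function(hic_loops, fdr_max = 0.01, min_count = 5) {
  has_fdr <- "fdr" %in% names(hic_loops) && any(!is.na(hic_loops$fdr))
  has_count <- "pet_count" %in% names(hic_loops) && any(!is.na(hic_loops$pet_count))
  if (!has_fdr && !has_count) abort("hic_loops carry neither fdr nor pet_count")
  keep <- rep(TRUE, nrow(hic_loops))
  if (has_count) keep <- keep & !is.na(hic_loops$pet_count) & hic_loops$pet_count >= min_count
  if (has_fdr) keep <- keep & !is.na(hic_loops$fdr) & hic_loops$fdr <= fdr_max
  hic_loops[keep, , drop = FALSE]
}

#' Sample matched false loop sets
#'
#' Builds `n_sets` sets of decoy loops, each the same size as `truth`,
#' for the TN/FP side of [loop_accuracy()]. Each false loop copies its
#' anchor lengths and anchor-to-anchor distance from a randomly chosen
#' truth loop (so accuracy penalises location, not geometry), and is
#' placed by rejection sampling so that neither anchor overlaps the
#' exclusion mask (TSS and enhancer-like regions) and the loop
#' intersects none of the excluded loop sets (gold loops, eQTL/CRISPR
#' loops, strong Hi-C loops). Replicate k is driven by the derived seed
#' `seed + k`, so the triplicate is reproducible.
#'
#' @param truth Gold-standard loop tibble (non-empty).
#' @param mask Interval tibble of regions false anchors must avoid (may
#'   be empty).
#' @param sizes Named chromosome lengths.
#' @param n_sets Number of replicates; default 3.
#' @param seed Integer master seed.
#' @param exclude_loops List of loop tibbles no false loop may intersect;
#'   defaults to `list(truth)`.
#' @param max_tries Rejection-sampling budget per loop; default 1e5.
#' @return A list of `n_sets` loop tibbles.
#' @export
build_false_sets <- function(truth, mask, sizes, n_sets = 3, seed = 1,
                             exclude_loops = list(truth), max_tries = 1e5) {
  check_loops(truth, "truth")
  if (nrow(truth) == 0) abort("truth loop set is empty")
  if (!is.null(mask) && nrow(mask) > 0) check_intervals(mask, "mask")
  mask_frac <- if (is.null(mask) || nrow(mask) == 0) 0 else {
    sum(merge_intervals(mask, 0)$end - merge_intervals(mask, 0)$start) / sum(sizes)
  }
  if (mask_frac >= 0.9) abort("exclusion mask covers >= 90% of the genome")
  len1 <- truth$end1 - truth$start1
  len2 <- truth$end2 - truth$start2
  d <- (truth$start2 + truth$end2) / 2 - (truth$start1 + truth$end1) / 2
  chroms <- names(sizes)
  w <- as.numeric(sizes) / sum(as.numeric(sizes))
  sample_one_set <- function() {
    out <- vector("list", nrow(truth))
    for (i in seq_len(nrow(truth))) {
      placed <- FALSE
      for (try in seq_len(max_tries)) {
        g <- sample.int(length(d), 1)
        l1 <- len1[g]; l2 <- len2[g]; dd <- abs(d[g])
        chr <- chroms[sample.int(length(chroms), 1, prob = w)]
        # anchor1 start s; anchor2 centred d downstream of anchor1 centre
        s2_of <- function(s1) round(s1 + l1 / 2 + dd - l2 / 2)
        limit <- unname(sizes[chr]) - max(l1, dd + l2 / 2 + l1 / 2 + 1)
        if (limit < 1) next
        s1 <- floor(runif(1) * limit)
        s2 <- s2_of(s1)
        if (s2 < 0 || s2 + l2 > unname(sizes[chr])) next
        cand <- tibble(
          chrom1 = chr, start1 = s1, end1 = s1 + l1,
          chrom2 = chr, start2 = s2, end2 = s2 + l2
        )
        anchors <- tibble(
          chrom = c(chr, chr), start = c(s1, s2), end = c(s1 + l1, s2 + l2)
        )
        if (!is.null(mask) && nrow(mask) > 0 &&
            nrow(overlap_pairs(anchors, mask)) > 0) next
        bad <- FALSE
        for (ex in exclude_loops) {
          if (nrow(ex) > 0 && any(loops_intersect(cand, ex))) { bad <- TRUE; break }
        }
        if (bad) next
        out[[i]] <- cand
        placed <- TRUE
        break
      }
      if (!placed) {
        abort(paste0("rejection sampling failed after ", max_tries,
                     " tries; the exclusion mask may be too dense"))
      }
    }
    bind_rows(out)
  }
  lapply(seq_len(n_sets), function(k) {
    set.seed((seed + k) %% .Machine$integer.max)
    sample_one_set()
  })
}
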