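# Accuracy of a detected loop set against gold-standard "true" loops and
# matched sampled "false" loop sets.

#' Which loops of one set intersect another
#'
#' A loop intersects a reference loop when, after ordering anchors along
#' the genome, anchor 1 overlaps the reference's anchor 1 and anchor 2
#' overlaps the reference's anchor 2. By default 1 bp of overlap
#' suffices; `min_fraction > 0` additionally requires that fraction of
#' reciprocal overlap on both anchors.
#'
#' @param loops,reference Loop tibbles.
#' @param min_fraction Reciprocal overlap fraction required per anchor;
#'   0 (default) means any 1 bp overlap.
#' @return Logical vector over `loops` rows.
#' @export
loops_intersect <- function(loops, reference, min_fraction = 0) {
  check_loops(loops)
  check_loops(reference)
  if (nrow(loops) == 0 || nrow(reference) == 0) return(rep(FALSE, nrow(loops)))
  loops <- order_anchors(loops)
  reference <- order_anchors(reference)
  a1 <- tibble(chrom = loops$chrom1, start = loops$start1, end = loops$end1)
  a2 <- tibble(chrom = loops$chrom2, start = loops$start2, end = loops$end2)
  r1 <- tibble(chrom = reference$chrom1, start = reference$start1, end = reference$end1)
  r2 <- tibble(chrom = reference$chrom2, start = reference$start2, end = reference$end2)
  qualify <- function(hits, q, s) {
    if (min_fraction <= 0 || nrow(hits) == 0) return(hits)
    lq <- q$end[hits$query] - q$start[hits$query]
    ls <- s$end[hits$subject] - s$start[hits$subject]
    hits[hits$overlap >= min_fraction * lq & hits$overlap >= min_fraction * ls, ,
         drop = FALSE]
  }
  h1 <- qualify(overlap_pairs(a1, r1), a1, r1)
  h2 <- qualify(overlap_pairs(a2, r2), a2, r2)
  pairs <- inner_join(
    h1[c("query", "subject")], h2[c("query", "subject")],
    by = c("query", "subject")
  )
  out <- rep(FALSE, nrow(loops))
  out[unique(pairs$query)] <- TRUE
  out
}

#' Loop-calling accuracy against true and false loop sets
#'
#' Scores a detected loop set against a gold-standard "true" set and one
#' or more sampled "false" sets of matched size. TP is the number of
#' detected loops intersecting the truth, FN the number of truth loops
#' not intersected by any detected loop; for each false set, FP is the
#' number of detected loops intersecting it and TN the number of its
#' loops not intersected. FP and TN are averaged over the false-set
#' replicates (three in the standard protocol), and
#' `ACC = (TP + TN) / (TP + TN + FP + FN)`.
#'
#' @param detected Loop tibble produced by the method under evaluation.
#' @param truth Gold-standard loop tibble (non-empty).
#' @param false_sets A list of loop tibbles (or a single tibble).
#' @param min_fraction Passed to [loops_intersect()].
#' @return An object of class `loop_confusion` with fields `tp`, `fp`,
#'   `tn`, `fn`, `acc`, and the per-false-set counts.
#' @export
loop_accuracy <- function(detected, truth, false_sets, min_fraction = 0) {
  if (nrow(truth) == 0) abort("truth loop set is empty")
  if (is.data.frame(false_sets)) false_sets <- list(false_sets)
  if (length(false_sets) == 0) abort("at least one false loop set is required")
  tp <- sum(loops_intersect(detected, truth, min_fraction))
  fn <- sum(!loops_intersect(truth, detected, min_fraction))
  fp_k <- vapply(false_sets, function(fs) {
    sum(loops_intersect(detected, fs, min_fraction))
  }, numeric(1))
  tn_k <- vapply(false_sets, function(fs) {
    sum(!loops_intersect(fs, detected, min_fraction))
  }, numeric(1))
  fp <- mean(fp_k)
  tn <- mean(tn_k)
  denom <- tp + tn + fp + fn
  if (denom <= 0) abort("confusion counts sum to zero; accuracy undefined")
  structure(
    list(
      tp = tp, fp = fp, tn = tn, fn = fn,
      acc = (tp + tn) / denom,
      fp_per_set = fp_k, tn_per_set = tn_k,
      n_detected = nrow(detected), n_truth = nrow(truth),
      n_false_sets = length(false_sets)
    ),
    class = "loop_confusion"
  )
}

#' @export
print.loop_confusion <- function(x, ...) {
  cat("<loop_confusion> TP=", x$tp, " FP=", format(x$fp, digits = 4),
      " TN=", format(x$tn, digits = 4), " FN=", x$fn,
      "  ACC=", format(x$acc, digits = 4), "\n", sep = "")
  invisible(x)
}
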