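# Activation rate: the fraction of enhancer/promoter loops whose anchors
# carry more active than repressive histone-mark signal.

anchor_overlap_len <- function(anchors, peaks) {
  if (is.null(peaks) || nrow(peaks) == 0) return(rep(0, nrow(anchors)))
  hits <- overlap_pairs(anchors, peaks)
  out <- rep(0, nrow(anchors))
  if (nrow(hits) > 0) {
    agg <- hits |> group_by(.data$query) |> summarise(len = sum(.data$overlap))
    out[agg$query] <- agg$len
  }
  out
}

union_peaks <- function(peak_sets) {
  if (is.data.frame(peak_sets)) peak_sets <- list(peak_sets)
  peak_sets <- peak_sets[!vapply(peak_sets, is.null, logical(1))]
  if (length(peak_sets) == 0) return(tibble(chrom = character(), start = numeric(), end = numeric()))
  all_pk <- bind_rows(lapply(peak_sets, function(p) as_tibble(p[c("chrom", "start", "end")])))
  if (nrow(all_pk) == 0) return(all_pk)
  # plain coordinate union (any overlap merges)
  out <- vector("list", 0)
  for (chr in unique(all_pk$chrom)) {
    sub <- all_pk[all_pk$chrom == chr, ]
    red <- IRanges::reduce(ir_from_df(sub))
    out[[length(out) + 1]] <- tibble(
      chrom = chr,
      start = BiocGenerics::start(red) - 1,
      end = BiocGenerics::end(red)
    )
  }
  bind_rows(out)
}

#' Activation rate of significant loops
#'
#' Classifies each loop functionally and scores the fraction that look
#' transcriptionally active. Anchors are labelled E when they overlap an
#' enhancer-like region by at least 1 bp and P when they overlap a
#' promoter-like region (an anchor overlapping both is labelled P, the
#' more specific annotation, for loop-class assignment). Loops with
#' neither anchor annotated are excluded; the remainder are classed
#' E-E, E-P or P-P when both anchors carry labels. Each retained loop's
#' anchors are then compared with the union of active-mark peak sets
#' (H3K27ac, H3K4me1, H3K4me3, ATAC) and the union of repressive-mark
#' sets (H3K27me3): the loop is active when the total active overlap
#' length across both anchors exceeds the repressive one, inactive when
#' smaller, and "other" when both are zero or equal. The activation rate
#' AR is active / (active + inactive + other).
#'
#' Loops should be pre-filtered with [filter_significant()].
#'
#' @param loops Loop tibble.
#' @param enhancers,promoters Annotation tibbles (`chrom`, `start`, `end`).
#' @param active_marks,repressive_marks A peak tibble or list of peak
#'   tibbles; each list is collapsed to its coordinate union before
#'   overlap lengths are measured (set `per_mark = TRUE` to sum overlap
#'   lengths per mark set instead).
#' @param per_mark Logical; see above.
#' @return An object of class `ar_report`: a list with `per_loop`
#'   (labels, overlap lengths, status), class counts, and
#'   `activation_rate`.
#' @export
activation_rate <- function(loops, enhancers, promoters, active_marks,
                            repressive_marks, per_mark = FALSE) {
  check_loops(loops)
  if (nrow(loops) == 0) abort("no loops supplied")
  a1 <- tibble(chrom = loops$chrom1, start = loops$start1, end = loops$end1)
  a2 <- tibble(chrom = loops$chrom2, start = loops$start2, end = loops$end2)
  label_anchor <- function(a) {
    is_e <- anchor_overlap_len(a, enhancers) > 0
    is_p <- anchor_overlap_len(a, promoters) > 0
    dplyr::case_when(is_p ~ "P", is_e ~ "E", .default = NA_character_)
  }
  lab1 <- label_anchor(a1)
  lab2 <- label_anchor(a2)
  keep <- !is.na(lab1) | !is.na(lab2)
  if (!any(keep)) abort("no loop has an enhancer- or promoter-annotated anchor")
  cls <- ifelse(
    !is.na(lab1) & !is.na(lab2),
    paste(pmin(lab1, lab2), pmax(lab1, lab2), sep = "-"),
    NA_character_
  )
  mark_len <- function(a, marks) {
    if (per_mark) {
      if (is.data.frame(marks)) marks <- list(marks)
      Reduce(`+`, lapply(marks, function(m) anchor_overlap_len(a, m)),
             accumulate = FALSE) %||% rep(0, nrow(a))
    } else {
      anchor_overlap_len(a, union_peaks(marks))
    }
  }
  active_len <- mark_len(a1, active_marks) + mark_len(a2, active_marks)
  repr_len <- mark_len(a1, repressive_marks) + mark_len(a2, repressive_marks)
  status <- dplyr::case_when(
    active_len > repr_len ~ "active",
    repr_len > active_len ~ "inactive",
    .default = "other"
  )
  per_loop <- loops |>
    mutate(
      anchor1_label = lab1, anchor2_label = lab2, loop_class = cls,
      active_len = active_len, repressive_len = repr_len, status = status,
      classified = keep
    )
  cl <- per_loop[keep, ]
  counts <- c(
    active = sum(cl$status == "active"),
    inactive = sum(cl$status == "inactive"),
    other = sum(cl$status == "other")
  )
  class_counts <- table(factor(cl$loop_class, levels = c("E-E", "E-P", "P-P")))
  structure(
    list(
      per_loop = per_loop,
      counts = counts,
      class_counts = as.vector(class_counts) |> setNames(names(class_counts)),
      n_classified = nrow(cl),
      activation_rate = unname(counts["active"]) / nrow(cl)
    ),
    class = "ar_report"
  )
}

#' @export
print.ar_report <- function(x, ...) {
  cat("<ar_report> ", x$n_classified, " classified loops; AR = ",
      format(x$activation_rate, digits = 4), "\n", sep = "")
  invisible(x)
}
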