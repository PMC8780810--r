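# Interval tibbles are 0-based half-open [start, end), the BED convention.
# IRanges is 1-based closed, so every conversion shifts start by +1; overlap
# widths computed on the converted ranges equal half-open overlap lengths.

ir_from_df <- function(df) {
  IRanges::IRanges(start = df$start + 1L, end = df$end)
}

check_intervals <- function(df, what = "interval") {
  required <- c("chrom", "start", "end")
  missing <- setdiff(required, names(df))
  if (length(missing) > 0) {
    abort(paste0(what, " table lacks column(s): ", paste(missing, collapse = ", ")))
  }
  bad <- which(df$start < 0 | df$end <= df$start)
  if (length(bad) > 0) {
    abort(paste0(
      what, " rows must satisfy 0 <= start < end; violated at row ",
      bad[1], " (start=", df$start[bad[1]], ", end=", df$end[bad[1]], ")"
    ))
  }
  invisible(df)
}

check_loops <- function(df, what = "loop") {
  required <- c("chrom1", "start1", "end1", "chrom2", "start2", "end2")
  missing <- setdiff(required, names(df))
  if (length(missing) > 0) {
    abort(paste0(what, " table lacks column(s): ", paste(missing, collapse = ", ")))
  }
  for (side in c("1", "2")) {
    s <- df[[paste0("start", side)]]
    e <- df[[paste0("end", side)]]
    bad <- which(s < 0 | e <= s)
    if (length(bad) > 0) {
      abort(paste0(
        what, " anchor", side, " must satisfy 0 <= start < end; violated at row ", bad[1]
      ))
    }
  }
  invisible(df)
}

#' Order the two anchors of each loop along the genome
#'
#' Guarantees that `anchor1` precedes `anchor2` (by chromosome name, then
#' start, then end), the convention every overlap-based metric in the
#' package assumes. Inter-chromosomal loops are ordered by chromosome name.
#'
#' @param loops A loop tibble with columns `chrom1,start1,end1,chrom2,start2,end2`.
#' @return The same tibble with anchors swapped where needed.
#' @export
order_anchors <- function(loops) {
  check_loops(loops)
  swap <- loops$chrom2 < loops$chrom1 |
    (loops$chrom2 == loops$chrom1 & loops$start2 < loops$start1) |
    (loops$chrom2 == loops$chrom1 & loops$start2 == loops$start1 &
       loops$end2 < loops$end1)
  if (any(swap)) {
    a1 <- loops[swap, c("chrom1", "start1", "end1")]
    loops[swap, c("chrom1", "start1", "end1")] <-
      setNames(loops[swap, c("chrom2", "start2", "end2")], c("chrom1", "start1", "end1"))
    loops[swap, c("chrom2", "start2", "end2")] <-
      setNames(a1, c("chrom2", "start2", "end2"))
  }
  loops
}

#' Overlap join between two interval tables
#'
#' Internal workhorse: returns every (query row, subject row) pair whose
#' intervals share at least one base on the same chromosome, with the
#' overlap length in bases.
#'
#' @noRd
overlap_pairs <- function(query, subject) {
  if (nrow(query) == 0 || nrow(subject) == 0) {
    return(tibble(query = integer(), subject = integer(), overlap = integer()))
  }
  out <- vector("list", 0)
  for (chr in intersect(unique(query$chrom), unique(subject$chrom))) {
    qi <- which(query$chrom == chr)
    si <- which(subject$chrom == chr)
    hits <- IRanges::findOverlaps(ir_from_df(query[qi, ]), ir_from_df(subject[si, ]))
    if (length(hits) == 0) next
    qh <- qi[S4Vectors::queryHits(hits)]
    sh <- si[S4Vectors::subjectHits(hits)]
    ov <- pmin(query$end[qh], subject$end[sh]) - pmax(query$start[qh], subject$start[sh])
    out[[length(out) + 1]] <- tibble(query = qh, subject = sh, overlap = ov)
  }
  if (length(out) == 0) {
    return(tibble(query = integer(), subject = integer(), overlap = integer()))
  }
  bind_rows(out)
}

#' Merge intervals sharing a minimum reciprocal length overlap
#'
#' Collapses intervals that overlap each other by at least
#' `min_reciprocal_overlap` of their lengths, the rule used to merge loop
#' anchors before computing peak co-occupancy (90% by default in that
#' context) and to merge ChIP-seq peak sets (80%). Merging is transitive:
#' groups are closed under the pairwise criterion and each group is
#' replaced by the union of its members, repeated until a fixpoint so the
#' result is idempotent and independent of input order.
#'
#' @param intervals Tibble with `chrom`, `start`, `end`.
#' @param min_reciprocal_overlap Fraction in \[0, 1\]. With
#'   `reciprocal = TRUE` (default) two intervals merge when the overlap is
#'   at least this fraction of *each* interval's length; with
#'   `reciprocal = FALSE` a fraction of either length suffices.
#' @param reciprocal Logical; see above.
#' @return Tibble of merged intervals, sorted by chromosome and start.
#' @examples
#' x <- tibble::tibble(chrom = "chr1", start = c(100, 105), end = c(200, 205))
#' merge_intervals(x, 0.9)
#' @export
merge_intervals <- function(intervals, min_reciprocal_overlap = 0.9,
                            reciprocal = TRUE) {
  if (nrow(intervals) == 0) {
    return(tibble(chrom = character(), start = numeric(), end = numeric()))
  }
  check_intervals(intervals)
  frac <- min_reciprocal_overlap
  stopifnot(frac >= 0, frac <= 1)
  cur <- as_tibble(intervals[c("chrom", "start", "end")])
  repeat {
    hits <- overlap_pairs(cur, cur)
    hits <- hits[hits$query < hits$subject, , drop = FALSE]
    if (nrow(hits) > 0) {
      len_q <- cur$end[hits$query] - cur$start[hits$query]
      len_s <- cur$end[hits$subject] - cur$start[hits$subject]
      ok <- if (reciprocal) {
        hits$overlap >= frac * len_q & hits$overlap >= frac * len_s
      } else {
        hits$overlap >= frac * len_q | hits$overlap >= frac * len_s
      }
      hits <- hits[ok, , drop = FALSE]
    }
    if (nrow(hits) == 0) break
    # union-find over the qualifying pairs, then union each component
    parent <- seq_len(nrow(cur))
    find <- function(i) {
      while (parent[i] != i) {
        parent[i] <<- parent[parent[i]]
        i <- parent[i]
      }
      i
    }
    for (k in seq_len(nrow(hits))) {
      a <- find(hits$query[k]); b <- find(hits$subject[k])
      if (a != b) parent[b] <- a
    }
    comp <- vapply(seq_len(nrow(cur)), find, integer(1))
    cur <- cur |>
      mutate(.comp = comp) |>
      group_by(.data$.comp) |>
      summarise(
        chrom = .data$chrom[1],
        start = min(.data$start),
        end = max(.data$end),
        .groups = "drop"
      ) |>
      select("chrom", "start", "end")
  }
  arrange(cur, .data$chrom, .data$start, .data$end)
}

#' Build a PET-end track supporting fast range counts
#'
#' A track is the collection of 1-D genomic positions of PET ends (or
#' ChIP-seq read positions), stored sorted per chromosome so that the
#' number of ends falling in any half-open window can be counted by
#' binary search.
#'
#' @param ends Tibble with columns `chrom` and `pos` (0-based positions).
#' @return An object of class `pet_track`.
#' @export
pet_track <- function(ends) {
  stopifnot(all(c("chrom", "pos") %in% names(ends)))
  if (any(ends$pos < 0)) abort("track positions must be >= 0")
  by_chr <- split(as.numeric(ends$pos), ends$chrom)
  by_chr <- lapply(by_chr, sort)
  structure(list(pos = by_chr, n = nrow(ends)), class = "pet_track")
}

#' @export
print.pet_track <- function(x, ...) {
  cat("<pet_track> ", x$n, " ends on ", length(x$pos), " chromosome(s)\n", sep = "")
  invisible(x)
}

#' Count track positions falling in windows
#'
#' Vectorised count of PET ends within the half-open windows
#' `[start, end)` on `chrom`. Windows are clipped below zero; windows on
#' chromosomes absent from the track count zero.
#'
#' @param track A [pet_track()].
#' @param chrom,start,end Parallel vectors defining the query windows.
#' @return Integer vector of counts.
#' @export
count_track <- function(track, chrom, start, end) {
  stopifnot(inherits(track, "pet_track"))
  start <- pmax(start, 0)
  n <- length(chrom)
  out <- integer(n)
  for (chr in unique(chrom)) {
    pos <- track$pos[[chr]]
    idx <- which(chrom == chr)
    if (is.null(pos)) next
    # ends in [s, e): positions < e minus positions < s
    out[idx] <- findInterval(end[idx] - 0.5, pos) - findInterval(start[idx] - 0.5, pos)
  }
  out
}
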