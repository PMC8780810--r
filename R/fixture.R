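# Self-contained synthetic fixture bundle with planted ground truth.
# Everything the evaluation pipeline consumes -- loops, PETs, ChIP peaks,
# annotations, verified contacts, chromosome sizes -- is generated with
# known expected values, so every metric can be checked end to end
# without any external data.

#' Generate a synthetic evaluation bundle with planted truth
#'
#' Writes a directory of plain-text inputs (chrom.sizes, candidate loops
#' as BEDPE, a tabular PET file, ChIP peaks, enhancer/promoter/TSS
#' annotations, active and repressive mark peaks, verified contacts) in
#' which every quantity the evaluation metrics measure is planted by
#' construction:
#'
#' * a fraction `uv_fraction` of the PETs pass all three UV filters
#'   exactly (the rest fail exactly one: low MAPQ, duplicate, or
#'   self-ligation);
#' * `n_true` of the `n_candidates` candidate loops carry
#'   `contacts_per_true` verified contacts placed exactly on their
#'   anchors, and no other candidate touches any contact;
#' * every candidate's anchor 1 is an enhancer-like region and anchor 2 a
#'   promoter-like region, and active/repressive marks are placed so that
#'   a chosen fraction of loops is active, a fraction inactive, and the
#'   remainder unmarked ("other");
#' * ChIP peaks coincide exactly with the loop anchors, so normalized
#'   peak co-occupancy is 1;
#' * anchor-to-anchor distances cycle over 5 kb / 50 kb / 500 kb so the
#'   resolution profile is known.
#'
#' Candidate loops are laid out on disjoint genomic windows, so no
#' planted signal bleeds between loops. All randomness is driven by
#' `seed`; the same seed reproduces the bundle byte for byte.
#'
#' @param dir Output directory (created if needed).
#' @param seed Integer seed.
#' @param n_candidates,n_true Candidate loop count and planted gold count.
#' @param n_pets,uv_fraction PET count and the exact UV Rate to plant.
#' @param contacts_per_true Verified contacts planted per true loop.
#' @param active_fraction,inactive_fraction Fractions of candidates
#'   planted active / inactive; the remainder is "other".
#' @param anchor_len Anchor width in bp.
#' @return Invisibly, a list with `paths` (named file paths), `truth`
#'   (the planted expectations, also written as `truth.json`), and
#'   `sizes`.
#' @export
make_fixture <- function(dir, seed = 1, n_candidates = 100, n_true = 20,
                         n_pets = 1000, uv_fraction = 0.4,
                         contacts_per_true = 8, active_fraction = 0.6,
                         inactive_fraction = 0.25, anchor_len = 2000) {
  stopifnot(n_true <= n_candidates, uv_fraction >= 0, uv_fraction <= 1,
            active_fraction + inactive_fraction <= 1)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  set.seed(seed %% .Machine$integer.max)

  spacing <- 60000
  dists <- rep(c(5000, 50000, 500000), length.out = n_candidates)
  s1 <- 10000 + (seq_len(n_candidates) - 1) * spacing
  s2 <- round(s1 + anchor_len / 2 + dists - anchor_len / 2)
  size_a <- max(s2 + anchor_len) + 600000
  sizes <- c(chrA = size_a, chrB = 5e6)
  if (any(s2 + anchor_len > size_a)) abort("planted loop beyond chromosome end")

  candidates <- tibble(
    chrom1 = "chrA", start1 = s1, end1 = s1 + anchor_len,
    chrom2 = "chrA", start2 = s2, end2 = s2 + anchor_len,
    pet_count = 5 + seq_len(n_candidates) %% 7,
    p_value = 0.01
  )

  true_idx <- sort(sample.int(n_candidates, n_true))
  contacts <- candidates[rep(true_idx, each = contacts_per_true),
                         c("chrom1", "start1", "end1", "chrom2", "start2", "end2")]

  # PETs: exactly n_uv pass MAPQ>=30, non-duplicate, inter-ligation; the
  # rest fail exactly one filter.
  n_uv <- round(uv_fraction * n_pets)
  n_bad <- n_pets - n_uv
  fail_mode <- rep(c("mapq", "dup", "self"), length.out = n_bad)
  p1 <- floor(runif(n_pets) * (size_a - 2e5))
  span <- 20000 + floor(runif(n_pets) * 1e5) # > self-ligation cutoff
  pets <- tibble(
    chrom1 = "chrA", start1 = p1, end1 = p1 + 50, mapq1 = 60,
    chrom2 = "chrA", start2 = p1 + span, end2 = p1 + span + 50, mapq2 = 60,
    duplicate = FALSE
  )
  bad <- n_uv + seq_len(n_bad)
  pets$mapq1[bad[fail_mode == "mapq"]] <- 5
  pets$duplicate[bad[fail_mode == "dup"]] <- TRUE
  short <- bad[fail_mode == "self"]
  pets$start2[short] <- pets$start1[short] + 1000
  pets$end2[short] <- pets$start2[short] + 50
  pets <- classify_pets(pets, self_ligation_cutoff = 8000)

  anchors <- bind_rows(
    tibble(chrom = "chrA", start = candidates$start1, end = candidates$end1),
    tibble(chrom = "chrA", start = candidates$start2, end = candidates$end2)
  )
  enhancers <- tibble(chrom = "chrA", start = candidates$start1, end = candidates$end1)
  promoters <- tibble(chrom = "chrA", start = candidates$start2, end = candidates$end2)

  n_active <- round(active_fraction * n_candidates)
  n_inactive <- round(inactive_fraction * n_candidates)
  status <- rep("other", n_candidates)
  status[seq_len(n_active)] <- "active"
  status[n_active + seq_len(n_inactive)] <- "inactive"
  status <- status[sample.int(n_candidates)]
  active_marks <- enhancers[status == "active", ]
  repressive_marks <- enhancers[status == "inactive", ]

  res <- table(cut(dists, c(0, 1e4, 1e5, 1e6), labels = c("le10k", "10k_100k", "100k_1m")))

  paths <- list(
    sizes = file.path(dir, "genome.chrom.sizes"),
    loops = file.path(dir, "candidates.bedpe"),
    pets = file.path(dir, "pets.tsv"),
    chip_peaks = file.path(dir, "chip_peaks.bed"),
    enhancers = file.path(dir, "enhancers.bed"),
    promoters = file.path(dir, "promoters.bed"),
    tss = file.path(dir, "tss.bed"),
    active_marks = file.path(dir, "active_h3k27ac.bed"),
    repressive_marks = file.path(dir, "repressive_h3k27me3.bed"),
    contacts = file.path(dir, "verified_contacts.bedpe"),
    truth = file.path(dir, "truth.json")
  )
  readr::write_tsv(
    tibble(chrom = names(sizes), len = unname(sizes)),
    paths$sizes, col_names = FALSE, progress = FALSE
  )
  write_bedpe(candidates, paths$loops)
  write_pets(pets, paths$pets)
  write_bed(anchors, paths$chip_peaks)
  write_bed(enhancers, paths$enhancers)
  write_bed(promoters, paths$promoters)
  write_bed(promoters, paths$tss)
  write_bed(active_marks, paths$active_marks)
  write_bed(repressive_marks, paths$repressive_marks)
  write_bedpe(contacts, paths$contacts)

  truth <- list(
    seed = seed,
    uv_rate = n_uv / n_pets,
    n_candidates = n_candidates,
    true_loops = true_idx,
    n_true = n_true,
    activation_rate = n_active / n_candidates,
    loop_status = status,
    pc_normalized = 1,
    resolution = as.list(setNames(as.vector(res) / sum(res), names(res)))
  )
  jsonlite::write_json(truth, paths$truth, auto_unbox = TRUE, digits = NA)
  invisible(list(paths = paths, truth = truth, sizes = sizes))
}
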