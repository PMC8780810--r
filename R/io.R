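# Readers/writers for the tab-separated formats the framework touches:
# BED (3+ cols), BEDPE (6+ cols), chrom.sizes (2 cols) and the tabular
# PET export. readr handles gzip transparently.

read_tsv_raw <- function(path, what) {
  if (!file.exists(path)) abort(paste0(what, " file not found: ", path))
  df <- suppressWarnings(readr::read_tsv(
    path,
    col_names = FALSE, col_types = readr::cols(.default = readr::col_character()),
    comment = "#", progress = FALSE
  ))
  df
}

num_or_error <- function(x, col, what) {
  out <- suppressWarnings(as.numeric(x))
  bad <- which(!is.na(x) & x != "." & is.na(out))
  if (length(bad) > 0) {
    abort(paste0(what, ": non-numeric value '", x[bad[1]], "' in column ", col,
                 " at line ", bad[1]))
  }
  out[!is.na(x) & x == "."] <- NA_real_
  out
}

#' Read loops from a BEDPE file
#'
#' Parses a 6+ column BEDPE file into a loop tibble. Coordinates are
#' 0-based half-open. Extra columns are mapped to loop fields through
#' `columns`, a named integer vector; loop callers disagree on output
#' layout, so the default (`pet_count` in column 7, `p_value` in 8,
#' `fdr` in 9) can be overridden.
#'
#' @param path Path to a BEDPE file (optionally gzipped).
#' @param columns Named integer vector mapping any of `pet_count`,
#'   `p_value`, `fdr` to 1-based column indices. Entries pointing past the
#'   last column present are ignored.
#' @return A tibble with columns `chrom1,start1,end1,chrom2,start2,end2`
#'   plus any mapped extras; anchors are ordered along the genome.
#' @export
read_bedpe <- function(path, columns = c(pet_count = 7, p_value = 8, fdr = 9)) {
  df <- read_tsv_raw(path, "BEDPE")
  if (nrow(df) == 0) {
    return(tibble(
      chrom1 = character(), start1 = numeric(), end1 = numeric(),
      chrom2 = character(), start2 = numeric(), end2 = numeric(),
      pet_count = numeric(), p_value = numeric(), fdr = numeric()
    ))
  }
  if (ncol(df) < 6) abort(paste0("BEDPE needs >= 6 columns, found ", ncol(df)))
  loops <- tibble(
    chrom1 = df[[1]],
    start1 = num_or_error(df[[2]], 2, "BEDPE"),
    end1 = num_or_error(df[[3]], 3, "BEDPE"),
    chrom2 = df[[4]],
    start2 = num_or_error(df[[5]], 5, "BEDPE"),
    end2 = num_or_error(df[[6]], 6, "BEDPE")
  )
  for (field in names(columns)) {
    j <- columns[[field]]
    if (j <= ncol(df)) loops[[field]] <- num_or_error(df[[j]], j, "BEDPE")
  }
  bad <- which(is.na(loops$start1) | is.na(loops$end1) |
                 is.na(loops$start2) | is.na(loops$end2))
  if (length(bad) > 0) abort(paste0("BEDPE: malformed row at line ", bad[1]))
  for (side in c("1", "2")) {
    s <- loops[[paste0("start", side)]]
    e <- loops[[paste0("end", side)]]
    bad <- which(s < 0 | e <= s)
    if (length(bad) > 0) {
      abort(paste0("BEDPE: invalid anchor", side, " (need 0 <= start < end) at line ",
                   bad[1]))
    }
  }
  order_anchors(loops)
}

#' Write loops to a BEDPE file
#'
#' Emits 6 coordinate columns plus `pet_count`, `p_value` and `fdr` (in
#' that order) when present; missing values are written as `.` so the file
#' round-trips through [read_bedpe()] field-for-field.
#'
#' @param loops A loop tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_bedpe <- function(loops, path) {
  check_loops(loops)
  cols <- c("chrom1", "start1", "end1", "chrom2", "start2", "end2")
  extras <- intersect(c("pet_count", "p_value", "fdr"), names(loops))
  out <- loops[c(cols, extras)]
  for (j in seq_along(out)) {
    v <- out[[j]]
    if (is.numeric(v)) {
      v <- ifelse(is.na(v), ".", format(v, scientific = FALSE, trim = TRUE, digits = 15))
    }
    out[[j]] <- v
  }
  readr::write_tsv(out, path, col_names = FALSE, progress = FALSE)
  invisible(path)
}

#' Read a BED file of peaks or annotations
#'
#' @param path Path to a BED file (3+ tab-separated columns, 0-based
#'   half-open; optionally gzipped). Column 4 is kept as `name` and
#'   column 5 as `score` when present.
#' @return Tibble with `chrom`, `start`, `end` and optional extras.
#' @export
read_bed <- function(path) {
  df <- read_tsv_raw(path, "BED")
  if (nrow(df) == 0) {
    return(tibble(chrom = character(), start = numeric(), end = numeric()))
  }
  if (ncol(df) < 3) abort(paste0("BED needs >= 3 columns, found ", ncol(df)))
  out <- tibble(
    chrom = df[[1]],
    start = num_or_error(df[[2]], 2, "BED"),
    end = num_or_error(df[[3]], 3, "BED")
  )
  if (ncol(df) >= 4) out$name <- df[[4]]
  if (ncol(df) >= 5) out$score <- num_or_error(df[[5]], 5, "BED")
  bad <- which(is.na(out$start) | is.na(out$end) | out$start < 0 | out$end <= out$start)
  if (length(bad) > 0) abort(paste0("BED: invalid interval at line ", bad[1]))
  out
}

#' Write intervals to a BED file
#'
#' @param intervals Tibble with `chrom`, `start`, `end`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_bed <- function(intervals, path) {
  check_intervals(intervals)
  out <- intervals[c("chrom", "start", "end")]
  out$start <- format(out$start, scientific = FALSE, trim = TRUE)
  out$end <- format(out$end, scientific = FALSE, trim = TRUE)
  readr::write_tsv(out, path, col_names = FALSE, progress = FALSE)
  invisible(path)
}

#' Read a chrom.sizes file
#'
#' @param path Two-column tab-separated file: chromosome name, length.
#' @return Named numeric vector of chromosome lengths; the genome length
#'   `G` is `sum(read_chrom_sizes(path))`.
#' @export
read_chrom_sizes <- function(path) {
  df <- read_tsv_raw(path, "chrom.sizes")
  if (ncol(df) < 2) abort("chrom.sizes needs 2 columns")
  len <- num_or_error(df[[2]], 2, "chrom.sizes")
  if (any(is.na(len) | len <= 0)) abort("chrom.sizes: lengths must be positive")
  setNames(len, df[[1]])
}

#' Read PET records from a tabular export
#'
#' PETs arrive as a tab-separated table exported upstream of this package
#' (one row per paired-end tag) with columns `chrom1, start1, end1, mapq1,
#' chrom2, start2, end2, mapq2, duplicate` and optionally
#' `ligation_class`. When `ligation_class` is absent it is derived with
#' [classify_pets()].
#'
#' @param path Path to the PET table (with header; optionally gzipped).
#' @param self_ligation_cutoff Span in bp below which a same-chromosome
#'   PET is classed as self-ligation when the file carries no class
#'   column. Default 8000 bp, configurable within the 5--12 kb range
#'   typical of ChIA-PET fragment circularisation.
#' @return A PET tibble.
#' @export
read_pets <- function(path, self_ligation_cutoff = 8000) {
  if (!file.exists(path)) abort(paste0("PET file not found: ", path))
  df <- readr::read_tsv(path, col_types = readr::cols(), progress = FALSE)
  required <- c("chrom1", "start1", "end1", "mapq1",
                "chrom2", "start2", "end2", "mapq2", "duplicate")
  missing <- setdiff(required, names(df))
  if (length(missing) > 0) {
    abort(paste0("PET table lacks column(s): ", paste(missing, collapse = ", ")))
  }
  df$duplicate <- as.logical(df$duplicate)
  if (!"ligation_class" %in% names(df)) {
    df <- classify_pets(df, self_ligation_cutoff = self_ligation_cutoff)
  }
  as_tibble(df)
}

#' Write PET records to a tabular file
#'
#' @param pets A PET tibble as returned by [read_pets()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_pets <- function(pets, path) {
  readr::write_tsv(pets, path, progress = FALSE)
  invisible(path)
}
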