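# Pipeline orchestration: one call evaluates a loop set with every
# metric its inputs allow, and a comparison step assembles the
# method-by-metric matrix with min-max scaled columns.

default_config <- function() {
  list(
    protocol = "chiapet",
    method_class = "peak",       # "peak" -> PC, "cluster" -> ES
    label = "method",
    dataset = "dataset",
    mapq_min = 30,
    p_max = 0.05,
    fdr_max = 0.05,
    merge_fraction = 0.9,
    self_ligation_cutoff = 8000,
    pet_length = 50,
    min_intersect_fraction = 0,
    seed = 1
  )
}

load_input <- function(x, reader) {
  if (is.null(x)) return(NULL)
  if (is.character(x) && length(x) >= 1) {
    if (length(x) > 1) return(lapply(x, reader))
    return(reader(x))
  }
  x
}

#' Evaluate one loop set with the full metric suite
#'
#' Runs every evaluation step its inputs allow: UV Rate when PETs are
#' supplied; anchor merging followed by peak co-occupancy (peak-based
#' methods) or enrichment score (cluster-based methods, which also need
#' PETs for the background track); significance filtering; accuracy when
#' a gold-standard set plus false sets (or the ingredients to build
#' them) are supplied; activation rate when annotations are supplied;
#' and the resolution-level profile. Metrics whose inputs are missing
#' are reported `NA`, never 0.
#'
#' @param config A named list (or path to a YAML file) with entries:
#'   `loops` (required; path or tibble), `sizes` (path or named vector),
#'   `pets`, `chip_peaks`, `enhancers`, `promoters`, `tss`,
#'   `active_marks`, `repressive_marks` (paths, tibbles, or lists of
#'   either), `truth` and `false_sets`, or `contacts` (+ optional `mask`)
#'   from which gold and false sets are built; `protocol`
#'   (`"chiapet"`/`"hichip"`), `method_class` (`"peak"`/`"cluster"`),
#'   `label`, `dataset`, thresholds (`mapq_min`, `p_max`, `fdr_max`,
#'   `merge_fraction`, `self_ligation_cutoff`, `pet_length`), and `seed`.
#' @param out_dir Optional directory; when given, the report row is
#'   written as `report.tsv` and `report.json` there.
#' @return An object of class `loop_report`: a one-row tibble of metric
#'   values with the detailed per-step results in attribute `"details"`.
#' @export
evaluate_loops <- function(config, out_dir = NULL) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  cfg <- utils::modifyList(default_config(), config)
  if (is.null(cfg$loops)) abort("config must name a loop set (`loops`)")
  loops <- load_input(cfg$loops, read_bedpe)
  sizes <- cfg$sizes
  if (is.character(sizes)) sizes <- read_chrom_sizes(sizes)
  pets <- load_input(cfg$pets, function(p) read_pets(p, cfg$self_ligation_cutoff))
  chip <- load_input(cfg$chip_peaks, read_bed)
  enhancers <- load_input(cfg$enhancers, read_bed)
  promoters <- load_input(cfg$promoters, read_bed)
  tss <- load_input(cfg$tss, read_bed)
  active <- load_input(cfg$active_marks, read_bed)
  repressive <- load_input(cfg$repressive_marks, read_bed)
  contacts <- load_input(cfg$contacts, read_bedpe)
  truth <- load_input(cfg$truth, read_bedpe)
  false_sets <- load_input(cfg$false_sets, read_bedpe)
  if (is.data.frame(false_sets)) false_sets <- list(false_sets)

  details <- list()
  uv <- NA_real_
  track <- NULL
  if (!is.null(pets)) {
    uv <- uv_rate(pets, mapq_min = cfg$mapq_min)
    track <- pet_track(tibble(
      chrom = c(pets$chrom1, pets$chrom2),
      pos = c(floor((pets$start1 + pets$end1) / 2),
              floor((pets$start2 + pets$end2) / 2))
    ))
  }

  anchors <- bind_rows(
    tibble(chrom = loops$chrom1, start = loops$start1, end = loops$end1),
    tibble(chrom = loops$chrom2, start = loops$start2, end = loops$end2)
  )
  merged <- merge_intervals(anchors, cfg$merge_fraction)
  details$merged_anchors <- merged

  pc_lit <- pc_norm <- NA_real_
  if (identical(cfg$method_class, "peak") && !is.null(chip)) {
    pc <- peak_co_occupancy(merged, chip, mode = "normalized")
    pc_norm <- pc$pc
    pc_lit <- pc$n_candidate * sum(pc$per_anchor$term) / pc$n_anchors
    details$pc <- pc
  }

  es_g <- NA_real_
  if (identical(cfg$method_class, "cluster") && !is.null(track) &&
      !is.null(sizes) && "pet_count" %in% names(loops)) {
    esr <- global_es(loops, track, sizes, pet_length = cfg$pet_length,
                     n_pets = if (is.null(pets)) NULL else nrow(pets))
    es_g <- esr$es_global
    details$es <- esr
  }

  sig <- filter_significant(loops, cfg$protocol, cfg$p_max, cfg$fdr_max)
  details$significant <- sig

  acc <- NA_real_
  if (is.null(truth) && !is.null(contacts) && !is.null(sizes)) {
    truth <- build_gold_set(loops, contacts, sizes, p_max = cfg$p_max,
                            fdr_max = cfg$fdr_max, seed = cfg$seed)
    details$gold <- truth
  }
  if (!is.null(truth) && nrow(truth) > 0) {
    if (is.null(false_sets)) {
      mask <- bind_rows(
        if (!is.null(tss)) tss[c("chrom", "start", "end")],
        if (!is.null(enhancers)) enhancers[c("chrom", "start", "end")]
      )
      if (is.null(sizes)) abort("accuracy requested but `sizes` is missing")
      false_sets <- build_false_sets(truth, mask, sizes, n_sets = 3,
                                     seed = cfg$seed)
      details$false_sets <- false_sets
    }
    conf <- loop_accuracy(sig, truth, false_sets,
                          min_fraction = cfg$min_intersect_fraction)
    acc <- conf$acc
    details$confusion <- conf
  }

  ar <- NA_real_
  if (!is.null(enhancers) && !is.null(promoters)) {
    arr <- activation_rate(sig, enhancers, promoters, active, repressive)
    ar <- arr$activation_rate
    details$ar <- arr
  }

  res <- tryCatch(resolution_levels(sig), error = function(e) NULL)
  res_frac <- if (is.null(res)) rep(NA_real_, 3) else res$fraction

  report <- tibble(
    method = cfg$label,
    dataset = cfg$dataset,
    n_loops = nrow(loops),
    n_significant = nrow(sig),
    uv_rate = uv,
    pc_literal = pc_lit,
    pc_normalized = pc_norm,
    es_global = es_g,
    acc = acc,
    ar = ar,
    res_le10k = res_frac[1],
    res_10k_100k = res_frac[2],
    res_100k_1m = res_frac[3]
  )
  class(report) <- c("loop_report", class(report))
  attr(report, "details") <- details
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    readr::write_tsv(as_tibble(report), file.path(out_dir, "report.tsv"),
                     progress = FALSE)
    jsonlite::write_json(as.list(as_tibble(report)[1, ]),
                         file.path(out_dir, "report.json"),
                         auto_unbox = TRUE, digits = NA, na = "null")
  }
  report
}

#' Assemble the cross-method comparison matrix
#'
#' Takes per-method, per-dataset report rows (from [evaluate_loops()] or
#' an equivalent tibble), averages each metric across datasets within a
#' method, then min-max rescales ACC and AR across methods
#' ([scale_scores()]), mirroring how benchmark summaries annotate method
#' performance.
#'
#' @param reports A list of `loop_report` rows or a tibble with columns
#'   `method`, `dataset`, and metric columns.
#' @return An object of class `loop_comparison`: a tibble with one row
#'   per method, mean metric columns, and `acc_scaled` / `ar_scaled`.
#' @export
compare_methods <- function(reports) {
  if (is.list(reports) && !is.data.frame(reports)) {
    reports <- bind_rows(lapply(reports, as_tibble))
  }
  reports <- as_tibble(reports)
  methods <- unique(reports$method)
  if (length(methods) < 2) abort("compare_methods needs at least 2 methods")
  ds <- split(reports$dataset, reports$method)
  ref <- sort(unique(ds[[1]]))
  for (m in names(ds)) {
    diff <- union(setdiff(sort(unique(ds[[m]])), ref), setdiff(ref, unique(ds[[m]])))
    if (length(diff) > 0) {
      abort(paste0("methods cover different datasets; mismatch: ",
                   paste(diff, collapse = ", ")))
    }
  }
  metric_cols <- intersect(
    c("uv_rate", "pc_literal", "pc_normalized", "es_global", "acc", "ar",
      "res_le10k", "res_10k_100k", "res_100k_1m"),
    names(reports)
  )
  out <- reports |>
    group_by(.data$method) |>
    summarise(across(all_of(metric_cols), ~ mean(.x, na.rm = TRUE)),
              .groups = "drop")
  for (col in intersect(c("acc", "ar"), metric_cols)) {
    v <- out[[col]]
    out[[paste0(col, "_scaled")]] <- if (all(is.finite(v))) scale_scores(v) else NA_real_
  }
  class(out) <- c("loop_comparison", class(out))
  out
}
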