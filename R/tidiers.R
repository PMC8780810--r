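# broom-style accessors for the fitted/report objects.

#' Tidy a loop confusion object
#'
#' @param x A `loop_confusion` from [loop_accuracy()].
#' @param ... Unused.
#' @return A tibble with one row per confusion cell.
#' @export
tidy.loop_confusion <- function(x, ...) {
  tibble(
    term = c("tp", "fp", "tn", "fn"),
    count = c(x$tp, x$fp, x$tn, x$fn)
  )
}

#' @rdname tidy.loop_confusion
#' @return For `glance`, a one-row tibble with `acc` and set sizes.
#' @export
glance.loop_confusion <- function(x, ...) {
  tibble(
    acc = x$acc, tp = x$tp, fp = x$fp, tn = x$tn, fn = x$fn,
    n_detected = x$n_detected, n_truth = x$n_truth,
    n_false_sets = x$n_false_sets
  )
}

#' Tidy an enrichment-score report
#'
#' @param x An `es_report` from [global_es()].
#' @param ... Unused.
#' @return Per-loop tibble with `p_n` and `es` columns.
#' @export
tidy.es_report <- function(x, ...) as_tibble(x$per_loop)

#' @rdname tidy.es_report
#' @return For `glance`, one row with the global ES and genome coverage.
#' @export
glance.es_report <- function(x, ...) {
  tibble(
    es_global = x$es_global,
    n_loops = nrow(x$per_loop),
    n_chroms = nrow(x$per_chrom),
    coverage_genome = x$coverage_genome
  )
}

#' Tidy an activation-rate report
#'
#' @param x An `ar_report` from [activation_rate()].
#' @param ... Unused.
#' @return Per-loop tibble with labels, overlap lengths and status.
#' @export
tidy.ar_report <- function(x, ...) as_tibble(x$per_loop)

#' @rdname tidy.ar_report
#' @return For `glance`, one row with AR and the class counts.
#' @export
glance.ar_report <- function(x, ...) {
  tibble(
    activation_rate = x$activation_rate,
    n_classified = x$n_classified,
    active = unname(x$counts["active"]),
    inactive = unname(x$counts["inactive"]),
    other = unname(x$counts["other"]),
    ee = unname(x$class_counts["E-E"]),
    ep = unname(x$class_counts["E-P"]),
    pp = unname(x$class_counts["P-P"])
  )
}
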