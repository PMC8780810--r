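# Independent brute-force implementations of every metric, used as
# oracles. Deliberately naive (explicit loops, linear scans) and kept
# free of any code path from the package internals they check.

ov_len <- function(s1, e1, s2, e2) max(0, min(e1, e2) - max(s1, s2))

oracle_uv <- function(pets, mapq_min = 30) {
  n_uv <- 0
  for (i in seq_len(nrow(pets))) {
    if (pets$mapq1[i] >= mapq_min && pets$mapq2[i] >= mapq_min &&
        !pets$duplicate[i] && pets$ligation_class[i] == "inter_ligation") {
      n_uv <- n_uv + 1
    }
  }
  n_uv / nrow(pets)
}

oracle_pc <- function(anchors, peaks, mode) {
  n <- nrow(anchors)
  terms <- numeric(n)
  in_a <- logical(n)
  for (i in seq_len(n)) {
    best_ov <- 0
    best_j <- NA
    for (j in seq_len(nrow(peaks))) {
      if (peaks$chrom[j] != anchors$chrom[i]) next
      o <- ov_len(anchors$start[i], anchors$end[i], peaks$start[j], peaks$end[j])
      if (o > best_ov ||
          (o == best_ov && o > 0 && !is.na(best_j) &&
           peaks$start[j] < peaks$start[best_j])) {
        best_ov <- o
        best_j <- j
      }
    }
    if (best_ov > 0) {
      in_a[i] <- TRUE
      la <- anchors$end[i] - anchors$start[i]
      lp <- peaks$end[best_j] - peaks$start[best_j]
      terms[i] <- max(best_ov / lp, best_ov / la)
    }
  }
  if (mode == "literal") sum(in_a) * sum(terms) / n else sum(terms) / n
}

oracle_track_count <- function(track_df, chrom, lo, hi) {
  lo <- max(lo, 0)
  sum(track_df$chrom == chrom & track_df$pos >= lo & track_df$pos < hi)
}

oracle_es <- function(loops, track_df, sizes = NULL) {
  out <- numeric(nrow(loops))
  pn_out <- numeric(nrow(loops))
  for (i in seq_len(nrow(loops))) {
    lm <- ((loops$end1[i] - loops$start1[i]) + (loops$end2[i] - loops$start2[i])) / 2
    clip <- function(chrom, x) if (is.null(sizes)) x else min(x, sizes[[chrom]])
    p1 <- oracle_track_count(track_df, loops$chrom1[i], loops$start1[i] - lm, loops$start1[i]) +
      oracle_track_count(track_df, loops$chrom1[i], loops$end1[i],
                         clip(loops$chrom1[i], loops$end1[i] + lm))
    p2 <- oracle_track_count(track_df, loops$chrom2[i], loops$start2[i] - lm, loops$start2[i]) +
      oracle_track_count(track_df, loops$chrom2[i], loops$end2[i],
                         clip(loops$chrom2[i], loops$end2[i] + lm))
    pn <- min(p1, p2)
    pn_out[i] <- pn
    out[i] <- loops$pet_count[i] / max(pn, 1)
  }
  list(es = out, p_n = pn_out)
}

oracle_global_es <- function(loops, track_df, sizes, pet_length, n_pets) {
  pn <- oracle_es(loops, track_df, sizes)$p_n
  g <- sum(sizes)
  cov_genome <- pet_length * n_pets / g
  chroms <- unique(loops$chrom1)
  es_g <- 0
  total_c <- sum(loops$pet_count)
  for (chr in chroms) {
    idx <- which(loops$chrom1 == chr)
    n_chr <- sum(track_df$chrom == chr)
    cov_chr <- pet_length * n_chr / sizes[[chr]]
    alpha <- cov_genome / cov_chr
    es_chr <- sum(loops$pet_count[idx]) / sum(pmax(pn[idx], 1)) * alpha
    es_g <- es_g + es_chr * sum(loops$pet_count[idx]) / total_c
  }
  es_g
}

oracle_loop_hit <- function(l, ref, i, j) {
  # both loops assumed anchor-ordered
  l$chrom1[i] == ref$chrom1[j] && l$chrom2[i] == ref$chrom2[j] &&
    ov_len(l$start1[i], l$end1[i], ref$start1[j], ref$end1[j]) > 0 &&
    ov_len(l$start2[i], l$end2[i], ref$start2[j], ref$end2[j]) > 0
}

oracle_intersects_any <- function(l, ref, i) {
  any(vapply(seq_len(nrow(ref)), function(j) oracle_loop_hit(l, ref, i, j), logical(1)))
}

oracle_acc <- function(detected, truth, false_sets) {
  detected <- order_anchors(detected)
  truth <- order_anchors(truth)
  false_sets <- lapply(false_sets, order_anchors)
  tp <- sum(vapply(seq_len(nrow(detected)),
                   function(i) oracle_intersects_any(detected, truth, i), logical(1)))
  fn <- sum(!vapply(seq_len(nrow(truth)),
                    function(i) oracle_intersects_any(truth, detected, i), logical(1)))
  fp_k <- vapply(false_sets, function(fs) {
    sum(vapply(seq_len(nrow(detected)),
               function(i) oracle_intersects_any(detected, fs, i), logical(1)))
  }, numeric(1))
  tn_k <- vapply(false_sets, function(fs) {
    sum(!vapply(seq_len(nrow(fs)),
                function(i) oracle_intersects_any(fs, detected, i), logical(1)))
  }, numeric(1))
  tp_tn <- tp + mean(tn_k)
  list(tp = tp, fp = mean(fp_k), tn = mean(tn_k), fn = fn,
       acc = tp_tn / (tp_tn + mean(fp_k) + fn))
}

# union of a list of interval tables, then total overlap length of one
# interval with that union, by a scan over merged pieces
oracle_union <- function(sets) {
  if (is.data.frame(sets)) sets <- list(sets)
  all_iv <- do.call(rbind, lapply(sets, function(s) s[c("chrom", "start", "end")]))
  out <- NULL
  for (chr in unique(all_iv$chrom)) {
    sub <- all_iv[all_iv$chrom == chr, , drop = FALSE]
    sub <- sub[order(sub$start), , drop = FALSE]
    cur_s <- sub$start[1]; cur_e <- sub$end[1]
    for (i in seq_len(nrow(sub))[-1]) {
      if (sub$start[i] <= cur_e) cur_e <- max(cur_e, sub$end[i])
      else {
        out <- rbind(out, data.frame(chrom = chr, start = cur_s, end = cur_e))
        cur_s <- sub$start[i]; cur_e <- sub$end[i]
      }
    }
    out <- rbind(out, data.frame(chrom = chr, start = cur_s, end = cur_e))
  }
  out
}

oracle_anchor_marklen <- function(chrom, s, e, marks_union) {
  if (is.null(marks_union)) return(0)
  tot <- 0
  for (j in seq_len(nrow(marks_union))) {
    if (marks_union$chrom[j] != chrom) next
    tot <- tot + ov_len(s, e, marks_union$start[j], marks_union$end[j])
  }
  tot
}

oracle_ar <- function(loops, enh, prom, act_sets, rep_sets) {
  act_u <- if (length(act_sets) > 0) oracle_union(act_sets) else NULL
  rep_u <- if (length(rep_sets) > 0) oracle_union(rep_sets) else NULL
  has_hit <- function(chrom, s, e, ann) {
    any(ann$chrom == chrom & pmin(ann$end, e) - pmax(ann$start, s) > 0)
  }
  n_active <- 0; n_class <- 0; status <- character(nrow(loops))
  for (i in seq_len(nrow(loops))) {
    e1 <- has_hit(loops$chrom1[i], loops$start1[i], loops$end1[i], enh)
    p1 <- has_hit(loops$chrom1[i], loops$start1[i], loops$end1[i], prom)
    e2 <- has_hit(loops$chrom2[i], loops$start2[i], loops$end2[i], enh)
    p2 <- has_hit(loops$chrom2[i], loops$start2[i], loops$end2[i], prom)
    if (!(e1 || p1 || e2 || p2)) { status[i] <- "excluded"; next }
    n_class <- n_class + 1
    al <- oracle_anchor_marklen(loops$chrom1[i], loops$start1[i], loops$end1[i], act_u) +
      oracle_anchor_marklen(loops$chrom2[i], loops$start2[i], loops$end2[i], act_u)
    rl <- oracle_anchor_marklen(loops$chrom1[i], loops$start1[i], loops$end1[i], rep_u) +
      oracle_anchor_marklen(loops$chrom2[i], loops$start2[i], loops$end2[i], rep_u)
    status[i] <- if (al > rl) "active" else if (rl > al) "inactive" else "other"
    if (al > rl) n_active <- n_active + 1
  }
  list(ar = n_active / n_class, n_classified = n_class, status = status)
}

oracle_resolution <- function(loops) {
  d <- abs((loops$start2 + loops$end2) / 2 - (loops$start1 + loops$end1) / 2)
  d <- d[loops$chrom1 == loops$chrom2]
  d <- d[d <= 1e6]
  c(sum(d <= 1e4), sum(d > 1e4 & d <= 1e5), sum(d > 1e5 & d <= 1e6)) / length(d)
}

# O(n^2) merge to fixpoint: each round scans every pair, links the
# qualifying ones, and replaces each linked group by its union; repeats
# until no pair qualifies, so the result is order-independent.
oracle_merge <- function(iv, frac, reciprocal = TRUE) {
  iv <- iv[c("chrom", "start", "end")]
  repeat {
    n <- nrow(iv)
    group <- seq_len(n)
    root <- function(i) { while (group[i] != i) i <- group[i]; i }
    linked <- FALSE
    for (i in seq_len(n - 1)) {
      for (j in (i + 1):n) {
        if (iv$chrom[i] != iv$chrom[j]) next
        o <- ov_len(iv$start[i], iv$end[i], iv$start[j], iv$end[j])
        li <- iv$end[i] - iv$start[i]
        lj <- iv$end[j] - iv$start[j]
        hit <- if (reciprocal) o >= frac * li && o >= frac * lj
               else o >= frac * li || o >= frac * lj
        if (o > 0 && hit) {
          ri <- root(i); rj <- root(j)
          if (ri != rj) group[max(ri, rj)] <- min(ri, rj)
          linked <- TRUE
        }
      }
    }
    if (!linked) break
    comp <- vapply(seq_len(n), root, integer(1))
    iv <- do.call(rbind, lapply(split(seq_len(n), comp), function(idx) {
      data.frame(chrom = iv$chrom[idx[1]],
                 start = min(iv$start[idx]), end = max(iv$end[idx]))
    }))
  }
  iv <- iv[order(iv$chrom, iv$start, iv$end), , drop = FALSE]
  rownames(iv) <- NULL
  iv
}

# --- random instance generators (callers fix the seed) ---

rand_intervals <- function(n, g = 1e5, max_len = 2000, chroms = "chrT") {
  s <- floor(runif(n) * (g - max_len))
  len <- 1 + floor(runif(n) * (max_len - 1))
  tibble::tibble(chrom = sample(chroms, n, replace = TRUE), start = s, end = s + len)
}

rand_loops <- function(n, g = 1e6, max_len = 2000, max_d = 5e5, chroms = "chrT") {
  s1 <- floor(runif(n) * (g / 2))
  l1 <- 1 + floor(runif(n) * (max_len - 1))
  l2 <- 1 + floor(runif(n) * (max_len - 1))
  d <- 1000 + floor(runif(n) * max_d)
  s2 <- s1 + d
  tibble::tibble(
    chrom1 = sample(chroms, n, replace = TRUE), start1 = s1, end1 = s1 + l1,
    chrom2 = NA_character_, start2 = s2, end2 = s2 + l2,
    pet_count = 1 + stats::rpois(n, 5)
  ) |> (\(x) { x$chrom2 <- x$chrom1; x })()
}

rand_pets <- function(n, g = 1e6) {
  s1 <- floor(runif(n) * g)
  s2 <- floor(runif(n) * g)
  tibble::tibble(
    chrom1 = "chrT", start1 = s1, end1 = s1 + 50,
    mapq1 = sample(c(0, 10, 30, 60), n, replace = TRUE),
    chrom2 = "chrT", start2 = s2, end2 = s2 + 50,
    mapq2 = sample(c(0, 10, 30, 60), n, replace = TRUE),
    duplicate = runif(n) < 0.2,
    ligation_class = sample(c("inter_ligation", "self_ligation", "invalid"),
                            n, replace = TRUE, prob = c(0.6, 0.3, 0.1))
  )
}

rand_track <- function(n, g = 1e6, chroms = "chrT") {
  tibble::tibble(chrom = sample(chroms, n, replace = TRUE),
                 pos = floor(runif(n) * g))
}
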