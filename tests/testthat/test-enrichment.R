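# A loop's enrichment score compares its PET count with the PET count in
# flanking windows of width l_m around both anchors.

track_from_counts <- function(windows) {
  # place `n` distinct positions inside each window [lo, hi)
  pos <- unlist(mapply(function(lo, hi, n) {
    if (n == 0) return(numeric(0))
    lo + seq_len(n) - 1
  }, windows$lo, windows$hi, windows$n, SIMPLIFY = FALSE))
  pet_track(tibble::tibble(chrom = "c", pos = pos))
}

test_that("ES follows the min-of-flank-sums formula on a constructed track", {
  # anchors [1000,2000) and [9000,10000): l_m = 1000
  loop <- tibble::tibble(
    chrom1 = "c", start1 = 1000, end1 = 2000,
    chrom2 = "c", start2 = 9000, end2 = 10000,
    pet_count = 10
  )
  track <- track_from_counts(tibble::tibble(
    lo = c(0, 2000, 8000, 10000),
    hi = c(1000, 3000, 9000, 11000),
    n = c(2, 3, 4, 4)
  ))
  out <- enrichment_score(loop, track)
  expect_equal(out$p_n, 5) # min(2 + 3, 4 + 4)
  expect_equal(out$es, 2)
  expect_true(out$valid)

  loop$pet_count <- 0
  expect_equal(enrichment_score(loop, track)$es, 0)
  loop$pet_count <- NA
  expect_error(enrichment_score(loop, track), "pet_count")
})

test_that("a zero flank count falls back to a pseudocount of 1", {
  loop <- tibble::tibble(
    chrom1 = "c", start1 = 1000, end1 = 2000,
    chrom2 = "c", start2 = 9000, end2 = 10000, pet_count = 4
  )
  empty <- pet_track(tibble::tibble(chrom = "c", pos = 5000))
  out <- enrichment_score(loop, empty)
  expect_equal(out$p_n, 0)
  expect_equal(out$es, 4)
})

test_that("per-loop ES equals a naive window recount on random tracks", {
  for (seed in 1:4) {
    withr::local_seed(seed)
    loops <- rand_loops(100, g = 1e6)
    track_df <- rand_track(5000, g = 1.6e6)
    want <- oracle_es(as.data.frame(loops), as.data.frame(track_df))
    got <- enrichment_score(loops, pet_track(track_df))
    expect_equal(got$p_n, want$p_n)
    expect_equal(got$es, want$es)
  }
})

test_that("ES is invariant to doubling counts on a uniform track", {
  withr::local_seed(9)
  loops <- rand_loops(50, g = 1e6)
  track_df <- rand_track(4000, g = 1.6e6)
  base <- enrichment_score(loops, pet_track(track_df))
  doubled_loops <- dplyr::mutate(loops, pet_count = pet_count * 2)
  doubled_track <- pet_track(dplyr::bind_rows(track_df, track_df))
  doubled <- enrichment_score(doubled_loops, doubled_track)
  nz <- base$p_n > 0 # away from the pseudocount guard
  expect_equal(doubled$es[nz], base$es[nz])
})

test_that("global ES collapses to sum(C)/sum(Pn) under uniform coverage", {
  # one chromosome: alpha = C/C_j = 1 by construction
  withr::local_seed(10)
  sizes <- c(cA = 2e6)
  loops <- rand_loops(80, g = 1e6, chroms = "cA")
  track_df <- rand_track(5000, g = 2e6, chroms = "cA")
  rep <- global_es(loops, pet_track(track_df), sizes, pet_length = 50)
  expect_equal(rep$per_chrom$alpha, 1)
  scored <- enrichment_score(loops, pet_track(track_df), sizes)
  expect_equal(rep$es_global, sum(scored$pet_count) / sum(pmax(scored$p_n, 1)))
})

test_that("per-chromosome global ES applies alpha as printed", {
  # single loop with C = 6, P_n = 2, on a chromosome holding half the
  # track density of the genome average -> alpha = 2, ES_G = 6/2 * 2 = 6
  sizes <- c(cA = 1e6, cB = 1e6)
  loop <- tibble::tibble(
    chrom1 = "cA", start1 = 1000, end1 = 2000,
    chrom2 = "cA", start2 = 50000, end2 = 51000, pet_count = 6
  )
  track_df <- dplyr::bind_rows(
    tibble::tibble(chrom = "cA", pos = c(500, 600, 49500, 49600, 49700,
                                         seq(2e5, 9e5, length.out = 95))),
    tibble::tibble(chrom = "cB", pos = seq(1e5, 9e5, length.out = 300))
  )
  # flanks of anchor1: [0,1000) + [2000,3000) -> 2; anchor2: 3 + 0 -> 3; Pn = 2
  rep <- global_es(loop, pet_track(track_df), sizes, pet_length = 50)
  expect_equal(rep$per_chrom$alpha, (400 / 2e6) / (100 / 1e6))
  expect_equal(rep$es_global, 6 / 2 * 2)
})

test_that("two-chromosome coverage imbalance yields alpha = C/C_j exactly", {
  # chromosomes of equal length with a 2:1 PET split -> alpha 0.75 and 1.5
  withr::local_seed(12)
  sizes <- c(cA = 1e6, cB = 1e6)
  loops <- dplyr::bind_rows(
    rand_loops(40, g = 5e5, chroms = "cA"),
    rand_loops(40, g = 5e5, chroms = "cB")
  )
  track_df <- dplyr::bind_rows(
    rand_track(4000, g = 1e6, chroms = "cA"),
    rand_track(2000, g = 1e6, chroms = "cB")
  )
  rep <- global_es(loops, pet_track(track_df), sizes, pet_length = 50)
  expect_equal(sort(rep$per_chrom$alpha), c(0.75, 1.5))
  expect_equal(
    rep$es_global,
    oracle_global_es(as.data.frame(loops), as.data.frame(track_df), sizes, 50, 6000)
  )
  # a chromosome with loops but no PETs is an error
  bad_track <- track_df[track_df$chrom == "cA", ]
  expect_error(global_es(loops, pet_track(bad_track), sizes, 50, n_pets = 4000),
               "no PET coverage")
})
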