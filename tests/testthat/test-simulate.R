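test_that("simulated counts carry the advertised distance-decay intensity", {
  sim <- simulate_chiapet(c(cS = 5e7), a = 10, max_delta = 5, seed = 17,
                          include_self = TRUE)
  tab <- sim$table
  expect_equal(unique(tab$lambda[tab$delta == 0]), 10) # E[n] at delta 0 is a
  expect_equal(unique(tab$lambda[tab$delta == 3]), 10 / 4)
  # self-pairs appear in the table but never as loops
  expect_true(all(sim$loops$start1 != sim$loops$start2))
  expect_true(all(sim$loops$pet_count > 0))
  # bins are bin_size wide and delta is measured in bins
  expect_equal(unique(sim$loops$end1 - sim$loops$start1), 5000)
  d_bins <- (sim$loops$start2 - sim$loops$start1) / 5000
  expect_true(all(d_bins >= 1 & d_bins <= 5))

  # Monte-Carlo check of the Poisson mean at delta = 1: a/(1+1) = 5
  n1 <- tab$n[tab$delta == 1]
  se <- sd(n1) / sqrt(length(n1))
  expect_gt(length(n1), 9000)
  expect_lt(abs(mean(n1) - 5), 3 * se)
})

test_that("the simulator is seed-deterministic and chromosome-order invariant", {
  sizes <- c(c1 = 2e6, c2 = 1e6)
  s1 <- simulate_chiapet(sizes, a = 5, max_delta = 20, seed = 4)
  s2 <- simulate_chiapet(sizes, a = 5, max_delta = 20, seed = 4)
  expect_identical(s1, s2)
  s3 <- simulate_chiapet(rev(sizes), a = 5, max_delta = 20, seed = 4)
  expect_equal(
    dplyr::arrange(s1$loops, chrom1, start1, start2),
    dplyr::arrange(s3$loops, chrom1, start1, start2)
  )
  expect_warning(simulate_chiapet(c(tiny = 20000), a = 5, max_delta = 50, seed = 1),
                 "clipped")
})

test_that("HiChIP filtering keeps the upper coverage quantile with tie rules", {
  mk_pairs <- function(n) {
    s <- (seq_len(n) - 1) * 10000
    tibble::tibble(
      chrom1 = "c", start1 = s, end1 = s + 5000,
      chrom2 = "c", start2 = s + 1e6, end2 = s + 1e6 + 5000
    )
  }
  pairs <- mk_pairs(100)
  # 50 pairs get 10 reads in anchor1, 50 get none
  covered <- seq_len(50)
  reads <- tibble::tibble(
    chrom = "c",
    pos = rep(pairs$start1[covered] + 100, each = 10) + sequence(rep(10, 50))
  )
  kept <- simulate_hichip(pairs, reads, coverage_threshold = 0.5)
  expect_equal(nrow(kept), 50)
  expect_equal(kept$start1, pairs$start1[covered])

  # identical coverage everywhere: all retained
  uniform <- tibble::tibble(chrom = "c", pos = pairs$start1 + 1)
  expect_equal(nrow(simulate_hichip(pairs, uniform, 0.5)), 100)
  expect_error(simulate_hichip(pairs[0, ], uniform, 0.5), "empty")
})

test_that("HiChIP filtering equals an oracle quantile filter on skewed coverage", {
  withr::local_seed(23)
  n <- 200
  s <- (seq_len(n) - 1) * 8000
  pairs <- tibble::tibble(
    chrom1 = "c", start1 = s, end1 = s + 4000,
    chrom2 = "c", start2 = s + 2e6, end2 = s + 2e6 + 4000
  )
  hot <- sample.int(n, 60) # reads concentrated on 30% of anchors
  reads <- tibble::tibble(
    chrom = "c",
    pos = unlist(lapply(hot, function(i) pairs$start1[i] + sample.int(4000, 30)))
  )
  for (thr in c(0.3, 0.5, 0.7)) {
    kept <- simulate_hichip(pairs, reads, coverage_threshold = thr)
    score <- vapply(seq_len(n), function(i) {
      sum(reads$pos >= pairs$start1[i] & reads$pos < pairs$end1[i]) +
        sum(reads$pos >= pairs$start2[i] & reads$pos < pairs$end2[i])
    }, numeric(1))
    cutoff <- sort(score)[floor(thr * n) + 1]
    expect_equal(kept$start1, pairs$start1[score >= cutoff], info = thr)
    expect_gte(nrow(kept), ceiling((1 - thr) * n - 1e-9))
  }
})

test_that("the closed-form estimator inverts the simulator", {
  # plug-in identity on a noise-free table
  tab <- tibble::tibble(delta = c(1, 2, 5), n = 10 / (1 + c(1, 2, 5)))
  expect_equal(estimate_a(tab), 10)
  expect_equal(estimate_a(tibble::tibble(delta = 0, n = 7)), 7)
  expect_error(estimate_a(tibble::tibble(delta = numeric(), n = numeric())),
               "empty")

  sim <- simulate_chiapet(c(cS = 3e7), a = 10, max_delta = 10, seed = 19)
  tab <- sim$table[seq_len(5000), ]
  expect_lt(abs(estimate_a(tab) - 10), 0.5)
})

test_that("fixture bundles are deterministic and carry their planted truth", {
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  fx1 <- make_fixture(d1, seed = 13)
  fx2 <- make_fixture(d2, seed = 13)
  for (nm in setdiff(names(fx1$paths), "truth")) {
    expect_identical(readLines(fx1$paths[[nm]]), readLines(fx2$paths[[nm]]),
                     info = nm)
  }
  expect_equal(fx1$truth, fx2$truth)

  # planted UV Rate is reproduced exactly by the metric
  pets <- read_pets(fx1$paths$pets)
  expect_equal(uv_rate(pets), fx1$truth$uv_rate)
  # planted gold loops are exactly the contact-covered candidates
  cand <- read_bedpe(fx1$paths$loops)
  contacts <- read_bedpe(fx1$paths$contacts)
  gold <- build_gold_set(cand, contacts, fx1$sizes, n_perm = 300, seed = 2)
  expect_equal(which(attr(gold, "scores")$coverage > 0), fx1$truth$true_loops)
  expect_equal(nrow(gold), fx1$truth$n_true)
})
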