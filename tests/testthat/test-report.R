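fixture_config <- function(fx, ...) {
  utils::modifyList(list(
    loops = fx$paths$loops, sizes = fx$paths$sizes, pets = fx$paths$pets,
    chip_peaks = fx$paths$chip_peaks, enhancers = fx$paths$enhancers,
    promoters = fx$paths$promoters, tss = fx$paths$tss,
    active_marks = fx$paths$active_marks,
    repressive_marks = fx$paths$repressive_marks,
    contacts = fx$paths$contacts,
    protocol = "chiapet", method_class = "peak", seed = 5
  ), list(...))
}

test_that("the pipeline reproduces every planted value of a fixture bundle", {
  fx <- make_fixture(withr::local_tempdir(), seed = 29)
  rep <- evaluate_loops(fixture_config(fx))
  truth <- fx$truth
  expect_equal(rep$uv_rate, truth$uv_rate)
  expect_equal(rep$pc_normalized, truth$pc_normalized)
  expect_equal(rep$ar, truth$activation_rate)
  expect_equal(rep$res_le10k, truth$resolution$le10k)
  expect_equal(rep$res_10k_100k, truth$resolution$`10k_100k`)
  expect_equal(rep$res_100k_1m, truth$resolution$`100k_1m`)
  gold <- attr(rep, "details")$gold
  expect_equal(nrow(gold), truth$n_true)
  # a perfect caller against its own gold set
  expect_equal(rep$acc, 1)
})

test_that("missing inputs surface as NA, never zero", {
  fx <- make_fixture(withr::local_tempdir(), seed = 30, n_candidates = 40,
                     n_true = 8, n_pets = 200)
  cfg <- fixture_config(fx)
  cfg$pets <- NULL
  cfg$contacts <- NULL
  rep <- evaluate_loops(cfg)
  expect_true(is.na(rep$uv_rate))
  expect_true(is.na(rep$acc))
  expect_equal(rep$ar, fx$truth$activation_rate) # others still computed
})

test_that("cluster-class methods get ES instead of PC", {
  fx <- make_fixture(withr::local_tempdir(), seed = 31, n_candidates = 40,
                     n_true = 8, n_pets = 500)
  rep <- evaluate_loops(fixture_config(fx, method_class = "cluster"))
  expect_true(is.na(rep$pc_normalized))
  expect_true(is.finite(rep$es_global))
})

test_that("reports are reproducible and written to disk on request", {
  fx <- make_fixture(withr::local_tempdir(), seed = 32, n_candidates = 40,
                     n_true = 8, n_pets = 200)
  out1 <- withr::local_tempdir()
  out2 <- withr::local_tempdir()
  r1 <- evaluate_loops(fixture_config(fx), out_dir = out1)
  r2 <- evaluate_loops(fixture_config(fx), out_dir = out2)
  expect_identical(readLines(file.path(out1, "report.tsv")),
                   readLines(file.path(out2, "report.tsv")))
  expect_true(file.exists(file.path(out1, "report.json")))
  expect_equal(as.data.frame(r1), as.data.frame(r2))
})

test_that("the comparison matrix averages then rescales across methods", {
  reports <- tibble::tibble(
    method = rep(c("m1", "m2", "m3"), each = 3),
    dataset = rep(c("d1", "d2", "d3"), 3),
    uv_rate = c(0.1, 0.2, 0.3, 0.4, 0.5, 0.6, 0.2, 0.2, 0.2),
    acc = c(0.5, 0.6, 0.7, 0.8, 0.9, 1.0, 0.6, 0.6, 0.6),
    ar = c(0.2, 0.2, 0.2, 0.5, 0.5, 0.5, 0.8, 0.8, 0.8)
  )
  cmp <- compare_methods(reports)
  # spreadsheet-style oracle: means by hand, then min-max
  means <- c(m1 = 0.6, m2 = 0.9, m3 = 0.6)
  expect_equal(setNames(cmp$acc, cmp$method), means)
  expect_equal(setNames(cmp$acc_scaled, cmp$method),
               (means - 0.6) / 0.3)
  expect_equal(sort(cmp$ar_scaled), c(0, 0.5, 1))

  two <- tibble::tibble(
    method = c("m1", "m2"), dataset = "d", acc = c(0.6, 0.9), ar = c(0.5, 0.5)
  )
  cmp2 <- compare_methods(two)
  expect_equal(sort(cmp2$acc_scaled), c(0, 1))
  expect_equal(cmp2$ar_scaled, c(1, 1))

  expect_error(compare_methods(two[1, ]), "at least 2")
  mismatched <- tibble::tibble(
    method = c("m1", "m2"), dataset = c("d1", "d2"), acc = c(0.5, 0.6)
  )
  expect_error(compare_methods(mismatched), "d1")
})

test_that("tidiers and plots expose the report objects", {
  fx <- make_fixture(withr::local_tempdir(), seed = 33, n_candidates = 40,
                     n_true = 8, n_pets = 200)
  rep <- evaluate_loops(fixture_config(fx))
  arr <- attr(rep, "details")$ar
  expect_s3_class(tidy(arr), "tbl_df")
  expect_equal(glance(arr)$activation_rate, rep$ar)
  conf <- attr(rep, "details")$confusion
  expect_equal(nrow(tidy(conf)), 4)

  cmp <- compare_methods(tibble::tibble(
    method = c("m1", "m2"), dataset = "d",
    acc = c(0.5, 0.9), ar = c(0.1, 0.3), uv_rate = c(0.2, 0.4)
  ))
  expect_s3_class(autoplot(cmp), "ggplot")
  expect_s3_class(plot_resolution_levels(read_bedpe(fx$paths$loops)), "ggplot")
})

test_that("the command-line wrapper drives the simulator end to end", {
  skip_if_not_installed("optparse")
  cli <- system.file("exec", "loopeval", package = "loopeval")
  if (!nzchar(cli)) cli <- file.path(find.package("loopeval"), "exec", "loopeval")
  skip_if(!file.exists(cli), "CLI script not installed")
  td <- withr::local_tempdir()
  sizes_f <- file.path(td, "g.sizes")
  writeLines("cS\t2000000", sizes_f)
  out_f <- file.path(td, "sim.bedpe")
  rscript <- file.path(R.home("bin"), "Rscript")
  status <- system2(rscript, c(cli, "simulate-chiapet",
                               "--chrom-sizes", sizes_f, "--a", "5",
                               "--max-delta", "20", "--seed", "3",
                               "--out", out_f),
                    stdout = FALSE, stderr = FALSE)
  expect_equal(status, 0)
  loops <- read_bedpe(out_f)
  expect_gt(nrow(loops), 0)
  expect_equal(unique(loops$end1 - loops$start1), 5000)
  # validation errors exit with status 2
  status2 <- system2(rscript, c(cli, "goldset", "--loops", "missing.bedpe",
                                "--contacts", "missing.bedpe",
                                "--chrom-sizes", sizes_f),
                     stdout = FALSE, stderr = FALSE)
  expect_equal(status2, 2)
})
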