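test_that("a long-format table parses into a validated batch", {
  tmp <- withr::local_tempfile(fileext = ".tsv")
  df <- data.frame(clone_id = "c1", time_months = c(0, 2, 4, 6, 8),
                   pct_total = c(0, 10, 20, 10, 0))
  utils::write.table(df, tmp, sep = "\t", quote = FALSE, row.names = FALSE)
  b <- read_kinetics(tmp)
  expect_s3_class(b, "kinetic_batch")
  expect_length(b, 1)
  expect_equal(length(b$clones$c1$times), 5)
  expect_equal(b$clones$c1$lifespan, 8)
})

test_that("malformed tables yield diagnostics naming the clone, never partial objects", {
  tmp <- withr::local_tempfile(fileext = ".tsv")
  df <- data.frame(clone_id = "bad", time_months = c(0, 2, 2, 4),
                   pct_total = c(0, 5, 6, 0))
  utils::write.table(df, tmp, sep = "\t", quote = FALSE, row.names = FALSE)
  expect_error(read_kinetics(tmp), "bad.*non-monotone", ignore.case = TRUE)

  df2 <- data.frame(clone_id = "neg", time_months = c(0, 2, 4, 6),
                    pct_total = c(0, -5, 6, 0))
  utils::write.table(df2, tmp, sep = "\t", quote = FALSE, row.names = FALSE)
  expect_error(read_kinetics(tmp), "negative")

  utils::write.table(df2[, 1:2], tmp, sep = "\t", quote = FALSE, row.names = FALSE)
  expect_error(read_kinetics(tmp), "missing required column")
})

test_that("validation reports every violation with field and index, without raising", {
  ok <- toy_kinetic()
  expect_identical(validate_kinetic(ok), character(0))

  bad <- unclass(ok)
  bad$lineages <- list(T = c(0, 60, 10, 5, 0), B = c(0, 60, 10, 5, 0),
                       My = c(0, 0, 0, 0, 0))
  out <- validate_kinetic(bad)
  expect_length(out, 1)
  expect_match(out, "lineage sum.*index 2")

  short <- list(clone_id = "s", times = c(0, 2, 4), total = c(0, 1, 0),
                n_min = 4L)
  expect_match(validate_kinetic(short), "too short", all = FALSE)
})

test_that("write/read round-trips are bit-exact and deterministic", {
  co <- small_batch(n = 3, seed = 7)
  tmp <- withr::local_tempfile(fileext = ".tsv")
  tmp2 <- withr::local_tempfile(fileext = ".tsv")
  write_results(co$batch, tmp)
  write_results(co$batch, tmp2)
  expect_identical(readBin(tmp, "raw", file.size(tmp)),
                   readBin(tmp2, "raw", file.size(tmp2)))
  again <- read_kinetics(tmp)
  expect_equal(length(again), length(co$batch))
  for (id in names(co$batch$clones)) {
    expect_equal(again$clones[[id]]$times, co$batch$clones[[id]]$times)
    expect_equal(again$clones[[id]]$total,
                 signif(co$batch$clones[[id]]$total, 12))
    for (nm in names(co$batch$clones[[id]]$lineages))
      expect_equal(again$clones[[id]]$lineages[[nm]],
                   signif(co$batch$clones[[id]]$lineages[[nm]], 12))
  }
})

test_that("result objects serialize deterministically in both formats", {
  p <- reliability_profile(toy_kinetic())
  tsv <- withr::local_tempfile(fileext = ".tsv")
  write_results(p, tsv)
  hdr <- strsplit(readLines(tsv, n = 1), "\t")[[1]]
  expect_true(all(c("time_months", "rate", "R", "F", "f", "lambda",
                    "population", "trunc_m", "trunc_n") %in% hdr))

  f <- estimate_ou(simulate_ou(0.2, 0.05, 0.01, 2, 30, seed = 1), 2)
  js1 <- withr::local_tempfile(fileext = ".json")
  js2 <- withr::local_tempfile(fileext = ".json")
  write_results(f, js1, format = "json")
  write_results(f, js2, format = "json")
  expect_identical(readLines(js1), readLines(js2))
  parsed <- jsonlite::read_json(js1)
  expect_true(all(c("mu", "sigma", "beta", "halflife", "n", "dt") %in%
                  names(parsed)))
})

test_that("duplicate clone ids are rejected at batch construction", {
  k <- toy_kinetic()
  expect_error(kinetic_batch(list(k, k)), "duplicate clone_id")
})
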