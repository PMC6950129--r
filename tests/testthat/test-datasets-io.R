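test_that("the bundled survey table parses into 32 samples and 4 sources", {
  expect_identical(nrow(gz_table), 36L)
  expect_identical(sum(gz_table$is_source), 4L)
  expect_identical(length(gz_samples), 32L)
  expect_identical(gz_sources$names,
                   c("coking_coal", "smelter_ore", "power_coal", "background"))
  expect_identical(attr(gz_table, "param"), "ref204")
  # ratio headers are preserved verbatim even though values are read as ref204
  expect_identical(attr(gz_table, "ratio_headers"),
                   c("204Pb/206Pb", "206Pb/207Pb", "207Pb/208Pb"))
  # the reinterpretation is announced unless silenced
  expect_message(
    read_sample_table(system.file("extdata", "guanzhong_samples.csv",
                                  package = "pbapportion")),
    "ratios to 204Pb")
  # concentration is metadata: present for N-1000, absent for background
  expect_equal(gz_samples[[14]]$concentration, 27.3358)
  expect_true(is.na(gz_table$concentration_ppm[36]))
})

test_that("malformed sample tables are rejected with located errors", {
  bad <- tempfile(fileext = ".csv")
  writeLines(c("sample_no,sample_code,concentration_ppm,a,b,c",
               "1,E-500,10,38.1,-15.6,18.0"), bad)
  err <- expect_error(read_sample_table(bad), class = "pb_io_error")
  expect_match(conditionMessage(err), "column 'b'")
  expect_match(conditionMessage(err), "E-500")
  writeLines("sample_no,sample_code,concentration_ppm,a,b,c", bad)
  expect_error(read_sample_table(bad), class = "pb_io_error")
  writeLines(c("sample_no,code,a,b,c", "1,x,1,2,3"), bad)
  expect_error(read_sample_table(bad), "missing required")
})

test_that("sample tables survive a write/read round trip at full precision", {
  tmp <- tempfile(fileext = ".csv")
  df <- as.data.frame(gz_table)[, 1:6]
  names(df) <- c("sample_no", "sample_code", "concentration_ppm",
                 attr(gz_table, "ratio_headers"))
  utils::write.csv(format(df, digits = 17, trim = TRUE), tmp, row.names = FALSE,
                   quote = FALSE)
  back <- read_sample_table(tmp, quiet = TRUE)
  expect_equal(back$r1, gz_table$r1, tolerance = 1e-15)
  expect_equal(back$r2, gz_table$r2, tolerance = 1e-15)
  expect_equal(back$r3, gz_table$r3, tolerance = 1e-15)
  expect_identical(back$sample_code, gz_table$sample_code)
})

test_that("result tables round to two-decimal percentages that sum to 100", {
  res <- batch_apportion(gz_sources, gz_samples)
  expect_equal(unname(rowSums(res[, gz_sources$names])), rep(1, 32), tolerance = 1e-10)
  out <- tempfile(fileext = ".csv")
  full <- tempfile(fileext = ".csv")
  write_result_table(res, out, full_precision_path = full)
  tab <- utils::read.csv(out, stringsAsFactors = FALSE)
  expect_identical(nrow(tab), 33L) # 32 samples + mean row
  # N-1000 row carries the expected rounded cells
  r14 <- tab[tab$sample_id == "N-1000", ]
  expect_identical(unname(unlist(r14[paste0("f_", gz_sources$names)])),
                   c("-13.86%", "57.25%", "41.24%", "15.37%"))
  pct <- function(v) as.numeric(sub("%", "", v))
  sums <- rowSums(vapply(paste0("f_", gz_sources$names),
                         function(cc) pct(tab[[cc]]), numeric(33)))
  expect_true(all(abs(sums - 100) <= 0.02 + 1e-12))
  # a clean 50/50 split prints as 50.00%
  s2 <- generate_sources(2, seed = 1)
  res2 <- batch_apportion(s2, list(forward_mix(s2, c(0.5, 0.5), id = "even")))
  out2 <- tempfile(fileext = ".csv")
  write_result_table(res2, out2, summary = FALSE)
  tab2 <- utils::read.csv(out2, stringsAsFactors = FALSE)
  expect_identical(tab2$f_S1, "50.00%")
  # empty batch writes a header-only file
  out3 <- tempfile(fileext = ".csv")
  write_result_table(batch_apportion(s2, list()), out3)
  expect_identical(length(readLines(out3)), 1L)
})

test_that("the case study flags the three published invalid points and diffs the table", {
  cs <- case_study()
  expect_identical(nrow(cs$results), 32L)
  # every published negative-coking sample is flagged with a negative coking fraction
  expect_true(all(c("N-1000", "N-1500", "N-2000") %in% cs$negative_samples))
  neg_coking <- cs$results$sample_id[cs$results$coking_coal < 0]
  expect_true(all(c("N-1000", "N-1500", "N-2000") %in% neg_coking))
  # the anchor row reproduces the published fractions to 0.1 pp
  expect_lt(max(abs(cs$diff["N-1000", ])), 0.1)
  # diff is informational: it exposes non-reproducible published rows
  expect_identical(dim(cs$diff), c(32L, 4L))
  expect_true(is.finite(cs$max_abs_diff_pp))
  # published rows 31 and 32 are printed identical despite different inputs
  pub <- cs$published
  expect_identical(unlist(pub[31, -(1:2)]), unlist(pub[32, -(1:2)]))
  expect_false(isTRUE(all.equal(cs$diff["EN-1500", ], cs$diff["EN-2000", ])))
})

test_that("repeated case-study runs write byte-identical full-precision outputs", {
  f1 <- tempfile(fileext = ".csv")
  f2 <- tempfile(fileext = ".csv")
  write_result_table(case_study()$results, tempfile(), full_precision_path = f1)
  write_result_table(case_study()$results, tempfile(), full_precision_path = f2)
  expect_identical(readLines(f1), readLines(f2))
})
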