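# Sample codes of field samples look like "N-1000" (azimuth-distance);
# rows whose code does not match are treated as end-member sources.
is_azimuth_code <- function(code) grepl("^[A-Z]{1,2}-[0-9]+$", code)

#' Read a sample/fingerprint table from CSV
#'
#' Reads a table of isotope-ratio measurements: columns `sample_no`,
#' `sample_code`, `concentration_ppm` (optional values), followed by three
#' ratio columns. The three ratio columns are interpreted in order according
#' to `param`:
#' \describe{
#'   \item{`ref204`}{(208Pb/204Pb, 207Pb/204Pb, 206Pb/204Pb). This is the
#'     default because published soil-lead tables of this shape carry values
#'     near (38, 15.6, 18), which are only physical as ratios to 204Pb even
#'     when the printed headers claim otherwise; the mismatch with the
#'     file's headers, if any, is reported via `message()`.}
#'   \item{`chain204`}{(204Pb/206Pb, 206Pb/207Pb, 207Pb/208Pb), honoring
#'     headers of that form literally (strict mode for sensitivity
#'     analysis).}
#' }
#' Rows whose `sample_code` matches the azimuth-distance pattern
#' (`"N-1000"`) are field samples; other rows are end-member sources.
#'
#' @param path CSV file path (comma-separated, UTF-8, "." decimal point).
#' @param param Ratio-column interpretation, `"ref204"` (default) or
#'   `"chain204"`.
#' @param quiet Suppress the interpretation message.
#' @return A data frame of class `"pb_sample_table"` with columns
#'   `sample_no`, `sample_code`, `concentration_ppm`, `r1`, `r2`, `r3`,
#'   `is_source`; attributes `param` and `ratio_headers` (the original
#'   ratio column headers).
#' @export
read_sample_table <- function(path, param = c("ref204", "chain204"),
                              quiet = FALSE) {
  param <- match.arg(param)
  if (!file.exists(path)) {
    stop_pb("pb_io_error", sprintf("file not found: %s", path))
  }
  raw <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE,
                         fileEncoding = "UTF-8")
  if (nrow(raw) == 0L) {
    stop_pb("pb_io_error", sprintf("empty sample table: %s", path))
  }
  need <- c("sample_no", "sample_code", "concentration_ppm")
  missing_cols <- setdiff(need, names(raw))
  if (length(missing_cols)) {
    stop_pb("pb_io_error", sprintf("missing required column(s): %s",
                                   paste(missing_cols, collapse = ", ")))
  }
  ratio_cols <- setdiff(names(raw), need)
  if (length(ratio_cols) != 3L) {
    stop_pb("pb_io_error", sprintf(
      "expected exactly 3 ratio columns after %s; found %d",
      paste(need, collapse = "/"), length(ratio_cols)))
  }
  if (anyDuplicated(raw$sample_code)) {
    stop_pb("pb_io_error", "sample codes must be unique")
  }
  for (cc in ratio_cols) {
    v <- suppressWarnings(as.numeric(raw[[cc]]))
    bad <- which(is.na(v) | !is.finite(v) | v <= 0)
    if (length(bad)) {
      stop_pb("pb_io_error", sprintf(
        "non-numeric or non-positive ratio in column '%s', row %d (sample %s)",
        cc, bad[1L], raw$sample_code[bad[1L]]))
    }
    raw[[cc]] <- v
  }
  if (!quiet && param == "ref204" &&
      any(grepl("204Pb/206Pb|206Pb/207Pb|207Pb/208Pb", ratio_cols))) {
    message("interpreting ratio columns as (208Pb/204Pb, 207Pb/204Pb, 206Pb/204Pb) ",
            "despite chain-style headers; the printed values (~38, ~15.6, ~18) are ",
            "only physical as ratios to 204Pb. Use param = \"chain204\" to honor ",
            "the headers literally.")
  }
  conc <- suppressWarnings(as.numeric(raw$concentration_ppm))
  out <- data.frame(
    sample_no = raw$sample_no,
    sample_code = as.character(raw$sample_code),
    concentration_ppm = conc,
    r1 = raw[[ratio_cols[1L]]],
    r2 = raw[[ratio_cols[2L]]],
    r3 = raw[[ratio_cols[3L]]],
    stringsAsFactors = FALSE
  )
  out$is_source <- !is_azimuth_code(out$sample_code)
  structure(out, param = param, ratio_headers = ratio_cols,
            class = c("pb_sample_table", "data.frame"))
}

row_fingerprint <- function(tbl, i) {
  ratio_triple(tbl$r1[i], tbl$r2[i], tbl$r3[i], param = attr(tbl, "param"))
}

#' Extract the end-member sources from a sample table
#'
#' @param tbl A `"pb_sample_table"` from [read_sample_table()].
#' @return A [source_set()] built from the non-azimuth rows.
#' @export
table_sources <- function(tbl) {
  stopifnot(inherits(tbl, "pb_sample_table"))
  idx <- which(tbl$is_source)
  if (length(idx) < 2L) {
    stop_pb("pb_validation_error", "table contains fewer than 2 source rows")
  }
  source_set(lapply(idx, function(i) row_fingerprint(tbl, i)),
             names = tbl$sample_code[idx])
}

#' Extract the field samples from a sample table
#'
#' @param tbl A `"pb_sample_table"` from [read_sample_table()].
#' @return A list of [mixture_sample()] objects, one per azimuth-coded row.
#' @export
table_samples <- function(tbl) {
  stopifnot(inherits(tbl, "pb_sample_table"))
  idx <- which(!tbl$is_source)
  lapply(idx, function(i) {
    conc <- tbl$concentration_ppm[i]
    mixture_sample(row_fingerprint(tbl, i), id = tbl$sample_code[i],
                   concentration = if (is.na(conc)) NULL else conc)
  })
}

#' Bundled Guanzhong industrial-park measurements
#'
#' `guanzhong_survey()` loads the bundled isotope measurements of 32 soil
#' samples (eight directions x four distances around a lead-zinc smelter)
#' plus four end-member sources (coking-plant raw coal, smelter ore,
#' power-plant raw coal, regional background). `guanzhong_published()` loads
#' the published contribution-rate table for the same samples, in percent,
#' for side-by-side comparison (see [case_study()]); it is reference
#' output, not an input to any computation.
#'
#' @param param Passed to [read_sample_table()].
#' @return `guanzhong_survey()`: a `"pb_sample_table"`;
#'   `guanzhong_published()`: a data frame with `sample_no`, `sample_code` and
#'   four percent columns.
#' @export
guanzhong_survey <- function(param = "ref204") {
  read_sample_table(
    system.file("extdata", "guanzhong_samples.csv", package = "pbapportion",
                mustWork = TRUE),
    param = param, quiet = TRUE)
}

#' @rdname guanzhong_survey
#' @export
guanzhong_published <- function() {
  p <- system.file("extdata", "guanzhong_published_fractions.csv",
                   package = "pbapportion", mustWork = TRUE)
  out <- utils::read.csv(p, stringsAsFactors = FALSE, fileEncoding = "UTF-8")
  # published tables sometimes use the Unicode minus; normalize to ASCII
  for (cc in names(out)[-(1:2)]) {
    if (is.character(out[[cc]])) {
      out[[cc]] <- as.numeric(gsub("−", "-", out[[cc]]))
    }
  }
  out
}

#' Write an apportionment result table to CSV
#'
#' Writes one row per sample with percentages rounded to two decimals
#' (round-half-even, ASCII minus, `"%"` suffix), a negativity flag and the
#' residual norm. A companion full-precision CSV (raw fractions, no
#' rounding) can be written alongside for lossless downstream use.
#'
#' @param results A `"pb_batch"` from [batch_apportion()].
#' @param path Output CSV path.
#' @param full_precision_path Optional path for the unrounded companion.
#' @param summary Append a mean row over valid samples (those with all
#'   fractions non-negative), when any exist.
#' @return `path`, invisibly.
#' @export
write_result_table <- function(results, path, full_precision_path = NULL,
                               summary = TRUE) {
  stopifnot(inherits(results, "pb_batch"))
  src <- attr(results, "source_names")
  fmt_pct <- function(x) {
    ifelse(is.na(x), "", paste0(formatC(round(100 * x, 2), format = "f", digits = 2), "%"))
  }
  out <- data.frame(sample_id = results$sample_id, stringsAsFactors = FALSE)
  for (s in src) out[[paste0("f_", s)]] <- fmt_pct(results[[s]])
  out$negative <- results$negative
  out$residual_norm <- formatC(results$residual_norm, format = "e", digits = 6)
  if (isTRUE(summary) && !is.null(attr(results, "summary"))) {
    m <- attr(results, "summary")
    srow <- data.frame(sample_id = sprintf("mean_over_%d_valid", attr(results, "n_valid")),
                       stringsAsFactors = FALSE)
    for (s in src) srow[[paste0("f_", s)]] <- fmt_pct(m[[s]])
    srow$negative <- NA
    srow$residual_norm <- ""
    out <- rbind(out, srow)
  }
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE, fileEncoding = "UTF-8")
  if (!is.null(full_precision_path)) {
    fp <- as.data.frame(results)[, c("sample_id", src, "negative", "residual_norm",
                                     "condition_number", "error")]
    utils::write.csv(format(fp, digits = 17, trim = TRUE), full_precision_path,
                     row.names = FALSE, quote = FALSE, fileEncoding = "UTF-8")
  }
  invisible(path)
}

#' Run the bundled Guanzhong case study
#'
#' Apportions all 32 bundled soil samples among the four bundled end-member
#' sources with the mass-balance model and compares the computed
#' contribution fractions cell by cell against the published table. The
#' comparison is informational: per-cell discrepancies are reported, not
#' reconciled (several published rows are not reproducible from the printed
#' inputs, and two are printed identical). Samples with any negative fitted
#' fraction are listed as invalid and excluded from the mean row.
#'
#' @param param Ratio-column interpretation for the bundled table.
#' @return A list of class `"pb_case_study"`: `results` (the
#'   [batch_apportion()] table), `published` (the published percent table),
#'   `diff` (computed minus published, percentage points, per cell),
#'   `negative_samples` (codes with any negative fraction),
#'   `mean_fractions` (over valid samples), `max_abs_diff_pp`.
#' @export
case_study <- function(param = "ref204") {
  tbl <- guanzhong_survey(param = param)
  sources <- table_sources(tbl)
  samples <- table_samples(tbl)
  results <- batch_apportion(sources, samples)
  published <- guanzhong_published()
  stopifnot(identical(published$sample_code, results$sample_id))
  comp <- as.matrix(results[, attr(results, "source_names")]) * 100
  pub <- as.matrix(published[, -(1:2)])
  diff <- comp - pub
  rownames(diff) <- results$sample_id
  negs <- results$sample_id[!is.na(results$negative) & results$negative]
  structure(list(
    results = results,
    published = published,
    diff = diff,
    negative_samples = negs,
    mean_fractions = attr(results, "summary"),
    n_valid = attr(results, "n_valid"),
    max_abs_diff_pp = max(abs(diff))
  ), class = "pb_case_study")
}

#' @export
print.pb_case_study <- function(x, ...) {
  cat(sprintf("<pb_case_study> %d samples, %d valid\n", nrow(x$results), x$n_valid))
  cat("samples with a negative fitted fraction: ",
      paste(x$negative_samples, collapse = ", "), "\n")
  cat("mean fractions over valid samples (%):\n")
  print(round(100 * x$mean_fractions, 2))
  cat(sprintf("max |computed - published| = %.2f pp\n", x$max_abs_diff_pp))
  cat("per-cell diff (pp), first rows:\n")
  print(round(utils::head(x$diff), 2))
  invisible(x)
}
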