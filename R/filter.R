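# Mean/median phred-cutoff filtering of paired quality/sequence streams.
# A read is retained iff statistic(qvs) >= threshold (inclusive boundary,
# exact unrounded statistics); format-rejected records never reach the
# filter and are accounted for in the validation log, not in the discard
# count, so retention percentages stay reproducible.

#' Filter configuration
#'
#' @param statistic Read-level statistic the cutoff applies to: `"mean"`
#'   or `"median"`.
#' @param threshold Phred cutoff (e.g. 20, 23, 25); a read is kept iff its
#'   statistic is `>= threshold`. Must be `>= -1`, the minimum possible
#'   quality value.
#' @return An object of class `filter_config`.
#' @export
filter_config <- function(statistic = c("mean", "median"), threshold) {
  statistic <- match.arg(statistic)
  threshold <- as.numeric(threshold)
  stopifnot(length(threshold) == 1L, !is.na(threshold))
  if (threshold < -1) stop("threshold must be >= -1")
  structure(list(statistic = statistic, threshold = threshold),
            class = "filter_config")
}

read_statistic <- function(qvs, statistic) {
  if (statistic == "mean") read_mean(qvs) else read_median(qvs)
}

#' Apply a quality cutoff to read pairs
#'
#' Single pass, order preserving. The discard count covers only
#' quality-rejected reads; upstream validation eliminations live in the
#' parsers' logs.
#'
#' @param pairs List of [read_pair()] (or [quality_read()] for
#'   quality-only filtering).
#' @param cfg A [filter_config()].
#' @return A list with `kept` (retained elements, input order), `raw_count`,
#'   `kept_count` and `discarded_count`.
#' @export
filter_pairs <- function(pairs, cfg) {
  stopifnot(inherits(cfg, "filter_config"))
  keep <- vapply(pairs, function(p) {
    q <- if (inherits(p, "read_pair")) p$qual$qvs else p$qvs
    read_statistic(q, cfg$statistic) >= cfg$threshold
  }, logical(1L))
  list(kept = pairs[keep],
       raw_count = length(pairs),
       kept_count = sum(keep),
       discarded_count = sum(!keep))
}

filter_outcome <- function(raw, kept, qual_out, seq_out) {
  structure(list(
    raw_count = raw, kept_count = kept, discarded_count = raw - kept,
    retention_percent = if (raw >= 1) retention_percentage(kept, raw) else NA,
    qual_path = qual_out, seq_path = seq_out
  ), class = "filter_outcome")
}

#' @export
print.filter_outcome <- function(x, ...) {
  cat("Phred quality filter:\n",
      "  raw reads:      ", x$raw_count, "\n",
      "  kept reads:     ", x$kept_count,
      if (!is.na(x$retention_percent))
        sprintf(" (%.2f%%)", x$retention_percent) else "", "\n",
      "  discarded:      ", x$discarded_count, "\n",
      "  quality output: ", x$qual_path, "\n",
      if (!is.na(x$seq_path))
        paste0("  sequence output: ", x$seq_path, "\n") else "",
      sep = "")
  invisible(x)
}

#' Run a complete filter job on input files
#'
#' Composes parse, pair, filter and write: both inputs are parsed once
#' against the expected read length, records are paired positionally with
#' id verification, the cutoff is applied, and the retained pairs are
#' written as `.new` files next to the originals. When `seq_path` is `NULL`
#' the job runs quality-only and emits a single `.new` file.
#'
#' Outcome counts refer to successfully paired records only;
#' format-eliminated and unpaired records are reported in the returned
#' validation log.
#'
#' @param qual_path Quality file path.
#' @param seq_path Sequence file path, or `NULL`.
#' @param expected_length Expected read length `L`.
#' @param cfg A [filter_config()].
#' @param encoding Sequence encoding, or `"auto"` to detect from the first
#'   parsed record.
#' @return A list with `outcome` (a `filter_outcome`) and `log` (combined
#'   [validation_log()]).
#' @export
run_filter_job <- function(qual_path, seq_path = NULL, expected_length, cfg,
                           encoding = c("auto", "nucleotide", "colorspace")) {
  encoding <- match.arg(encoding)
  stopifnot(file.exists(qual_path))
  pq <- parse_quality_file(qual_path, expected_length)
  if (is.null(seq_path)) {
    res <- filter_pairs(pq$reads, cfg)
    paths <- write_filtered_pair(res$kept, qual_path, NULL)
    return(list(outcome = filter_outcome(res$raw_count, res$kept_count,
                                         paths$qual, paths$seq),
                log = pq$log))
  }
  stopifnot(file.exists(seq_path))
  if (encoding == "auto") encoding <- sniff_encoding(seq_path)
  ps <- parse_sequence_file(seq_path, expected_length, encoding)
  pr <- pair_records(pq$reads, ps$reads)
  res <- filter_pairs(pr$pairs, cfg)
  paths <- write_filtered_pair(res$kept, qual_path, seq_path)
  list(outcome = filter_outcome(res$raw_count, res$kept_count,
                                paths$qual, paths$seq),
       log = rbind_logs(pq$log, ps$log, pr$log))
}

# First record's symbols decide the encoding for the whole file.
sniff_encoding <- function(seq_path) {
  lines <- readLines(seq_path, n = 50L, warn = FALSE)
  in_record <- FALSE
  body <- character()
  for (line in lines) {
    if (startsWith(line, ">")) {
      if (in_record && length(body)) break
      in_record <- TRUE
    } else if (in_record && nzchar(trimws(line))) {
      body[[length(body) + 1L]] <- line
    }
  }
  if (!length(body)) stop("cannot detect encoding: no sequence record found")
  detect_encoding(gsub("\\s+", "", paste(body, collapse = "")))
}

#' Serialize a filter outcome as key:value text and JSON
#'
#' @param outcome A `filter_outcome`.
#' @param txt_path,json_path Output paths (either may be `NULL` to skip).
#' @param coverage Optional fold coverage of the kept set to include.
#' @param log_path Optional path of the written validation log, echoed in
#'   the JSON summary.
#' @return Invisibly, the JSON-ready summary list.
#' @export
write_filter_summary <- function(outcome, txt_path = NULL, json_path = NULL,
                                 coverage = NULL, log_path = NULL) {
  stopifnot(inherits(outcome, "filter_outcome"))
  summary <- list(
    raw = outcome$raw_count,
    kept = outcome$kept_count,
    retention_percent = outcome$retention_percent,
    coverage = coverage,
    outputs = Filter(Negate(is.na), c(outcome$qual_path, outcome$seq_path)),
    log_path = log_path
  )
  if (!is.null(txt_path)) {
    writeLines(c(
      paste0("raw: ", summary$raw),
      paste0("kept: ", summary$kept),
      paste0("retention_percent: ",
             formatC(summary$retention_percent, format = "f", digits = 2)),
      if (!is.null(coverage)) paste0("coverage: ", coverage),
      paste0("outputs: ", paste(summary$outputs, collapse = " "))
    ), txt_path)
  }
  if (!is.null(json_path)) {
    jsonlite::write_json(summary, json_path, auto_unbox = TRUE,
                         null = "null", digits = NA)
  }
  invisible(summary)
}
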