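# Streaming readers/writers for SOLiD-style .qual files and
# nucleotide/color-space sequence files. All parsers make exactly one pass
# over the line stream, eliminate malformed records, and report every
# elimination in a validation_log instead of failing.

read_stream <- function(input) {
  if (is.character(input)) {
    list(lines = readLines(input, warn = FALSE), source = input)
  } else if (inherits(input, "connection")) {
    list(lines = readLines(input, warn = FALSE),
         source = summary(input)$description)
  } else {
    stop("input must be a file path or a connection")
  }
}

header_id <- function(line) {
  tok <- strsplit(trimws(sub("^>", "", line)), "\\s+")[[1L]]
  if (length(tok) == 0L || is.na(tok[1L])) "" else tok[1L]
}

# Shared record-walker: splits a multifasta line stream into
# (header line number, id, body lines) triples, logging blank lines and
# stray pre-header lines. `validate(id, body_lines)` returns either a
# retained object or a reason code string.
walk_records <- function(lines, src, validate) {
  reads <- vector("list", 64L)
  n_reads <- 0L
  lf <- list(source_file = character(), line_number = integer(),
             record_id = character(), reason = character())
  add_log <- function(line_no, id, reason) {
    lf$source_file[[length(lf$source_file) + 1L]] <<- src
    lf$line_number[[length(lf$line_number) + 1L]] <<- line_no
    lf$record_id[[length(lf$record_id) + 1L]] <<- id
    lf$reason[[length(lf$reason) + 1L]] <<- reason
  }
  cur_id <- NULL
  cur_line <- NA_integer_
  body <- character()
  flush <- function() {
    if (is.null(cur_id)) return()
    res <- validate(cur_id, body)
    if (is.character(res)) {
      add_log(cur_line, cur_id, res)
    } else {
      n_reads <<- n_reads + 1L
      if (n_reads > length(reads)) length(reads) <<- 2L * n_reads
      reads[[n_reads]] <<- res
    }
  }
  for (i in seq_along(lines)) {
    line <- lines[[i]]
    if (!nzchar(trimws(line))) {
      add_log(i, if (is.null(cur_id)) "" else cur_id, "BLANK_LINE")
    } else if (startsWith(line, ">")) {
      flush()
      cur_id <- header_id(line)
      cur_line <- i
      body <- character()
    } else if (is.null(cur_id)) {
      add_log(i, "", "MALFORMED_HEADER")
    } else {
      body[[length(body) + 1L]] <- line
    }
  }
  flush()
  list(reads = reads[seq_len(n_reads)],
       log = validation_log(lf$source_file, lf$line_number,
                            lf$record_id, lf$reason))
}

#' Parse a multifasta phred quality file
#'
#' Reads a quality file in the SOLiD `.qual` dialect: each record is a `>`
#' header followed by one or more lines of whitespace-separated integer
#' phred values (values for one record may span several lines). Records are
#' validated against the expected read length `L` in a single pass over the
#' stream; a record is eliminated — never fatally — when it contains a
#' non-integer token (`NON_INTEGER_QV`), a value outside \[-1, 93\]
#' (`QV_OUT_OF_RANGE`), or the wrong number of values (`WRONG_LENGTH`).
#' Blank lines and pre-header junk lines are skipped and logged
#' (`BLANK_LINE`, `MALFORMED_HEADER`) without terminating any record.
#'
#' @param input File path or text connection (read exactly once, never
#'   rewound).
#' @param expected_length Expected number of quality values per read
#'   (`L >= 1`).
#' @return A list with `reads` (list of [quality_read()], input order) and
#'   `log` (a [validation_log()]).
#' @export
#' @examples
#' f <- tempfile()
#' writeLines(c(">r1", paste(rep(20, 5), collapse = " ")), f)
#' parse_quality_file(f, expected_length = 5)$reads
parse_quality_file <- function(input, expected_length) {
  L <- as.integer(expected_length)
  stopifnot(length(L) == 1L, !is.na(L), L >= 1L)
  st <- read_stream(input)
  validate <- function(id, body) {
    tokens <- unlist(strsplit(trimws(body), "\\s+"), use.names = FALSE)
    tokens <- tokens[nzchar(tokens)]
    if (!all(grepl("^[-+]?[0-9]+$", tokens))) return("NON_INTEGER_QV")
    qvs <- as.integer(tokens)
    if (any(qvs < QV_MIN | qvs > QV_MAX)) return("QV_OUT_OF_RANGE")
    if (length(qvs) != L) return("WRONG_LENGTH")
    quality_read(id, qvs)
  }
  walk_records(st$lines, st$source, validate)
}

#' Parse a nucleotide FASTA or SOLiD csfasta sequence file
#'
#' Same elimination/log contract as [parse_quality_file()]. A nucleotide
#' record must consist of exactly `L` symbols from `ACGTN` (lowercase
#' accepted and uppercased); a colorspace record must be one primer base
#' from `ACGT` followed by exactly `L` color calls from `0123.` (total
#' length `L + 1`). Any other symbol — including a bad primer base —
#' eliminates the record with reason `INVALID_CHARACTER`; a clean record of
#' the wrong length is eliminated with `WRONG_LENGTH`.
#'
#' @inheritParams parse_quality_file
#' @param encoding `"nucleotide"` or `"colorspace"` (declared by the
#'   caller; see [detect_encoding()]).
#' @return A list with `reads` (list of [sequence_read()]) and `log`.
#' @export
parse_sequence_file <- function(input, expected_length,
                                encoding = c("nucleotide", "colorspace")) {
  encoding <- match.arg(encoding)
  L <- as.integer(expected_length)
  stopifnot(length(L) == 1L, !is.na(L), L >= 1L)
  st <- read_stream(input)
  validate <- function(id, body) {
    symbols <- gsub("\\s+", "", paste(body, collapse = ""))
    if (encoding == "nucleotide") {
      symbols <- toupper(symbols)
      if (grepl("[^ACGTN]", symbols)) return("INVALID_CHARACTER")
      if (nchar(symbols) != L) return("WRONG_LENGTH")
    } else {
      primer <- toupper(substr(symbols, 1L, 1L))
      if (!nzchar(symbols) || !primer %in% c("A", "C", "G", "T")) {
        return("INVALID_CHARACTER")
      }
      colors <- substr(symbols, 2L, nchar(symbols))
      if (grepl("[^0123.]", colors)) return("INVALID_CHARACTER")
      if (nchar(symbols) != L + 1L) return("WRONG_LENGTH")
      symbols <- paste0(primer, colors)
    }
    sequence_read(id, symbols, encoding)
  }
  walk_records(st$lines, st$source, validate)
}

#' Guess the encoding of a symbol string
#'
#' A string is colorspace iff its first symbol is a primer base in `ACGT`
#' and every following symbol is a color call in `0123.`; anything else is
#' treated as nucleotide.
#'
#' @param symbols Non-empty symbol string (typically the first record of a
#'   sequence file).
#' @return `"colorspace"` or `"nucleotide"`.
#' @export
#' @examples
#' detect_encoding("T01230")  # colorspace
#' detect_encoding("ACGTN")   # nucleotide
detect_encoding <- function(symbols) {
  stopifnot(is.character(symbols), length(symbols) == 1L)
  if (!nzchar(symbols)) stop("cannot detect encoding of an empty string")
  first <- substr(symbols, 1L, 1L)
  rest <- substr(symbols, 2L, nchar(symbols))
  if (first %in% c("A", "C", "G", "T") && !grepl("[^0123.]", rest)) {
    "colorspace"
  } else {
    "nucleotide"
  }
}

#' Pair quality and sequence records positionally
#'
#' Records are paired by file position, with id verification: a positional
#' pair whose record ids differ is dropped entirely (both records) under a
#' single `UNPAIRED_RECORD` log entry, and trailing records of the longer
#' input are dropped and logged one by one. Positional pairing preserves
#' streaming and surfaces file corruption that id-keyed lookup would hide.
#'
#' @param quals List of [quality_read()] in file order.
#' @param seqs List of [sequence_read()] in file order.
#' @return A list with `pairs` (list of [read_pair()]) and `log`; the log's
#'   `line_number` column holds the record's position index.
#' @export
pair_records <- function(quals, seqs) {
  m <- min(length(quals), length(seqs))
  pairs <- vector("list", m)
  n_pairs <- 0L
  lg <- validation_log()
  for (i in seq_len(m)) {
    if (identical(quals[[i]]$record_id, seqs[[i]]$record_id)) {
      n_pairs <- n_pairs + 1L
      pairs[[n_pairs]] <- read_pair(seqs[[i]], quals[[i]])
    } else {
      lg <- rbind_logs(lg, validation_log(
        "pairing", i,
        paste0(quals[[i]]$record_id, "/", seqs[[i]]$record_id),
        "UNPAIRED_RECORD"))
    }
  }
  longer <- if (length(quals) > m) quals else seqs
  for (i in seq.int(m + 1L, length.out = length(longer) - m)) {
    lg <- rbind_logs(lg, validation_log(
      "pairing", i, longer[[i]]$record_id, "UNPAIRED_RECORD"))
  }
  list(pairs = pairs[seq_len(n_pairs)], log = lg)
}

format_quality_records <- function(reads) {
  unlist(lapply(reads, function(r) {
    c(paste0(">", r$record_id), paste(r$qvs, collapse = " "))
  }), use.names = FALSE) %||% character()
}

format_sequence_records <- function(reads) {
  unlist(lapply(reads, function(r) {
    c(paste0(">", r$record_id), r$symbols)
  }), use.names = FALSE) %||% character()
}

`%||%` <- function(x, y) if (is.null(x)) y else x

#' Write retained read pairs as filtered ".new" files
#'
#' Emits the retained records next to the originals, each under the original
#' file name with the extension `.new` appended. The quality file gets one
#' header line plus one line of space-separated values per record; the
#' sequence file one header line plus one symbol line. Record order is
#' preserved, and on any write failure both partial outputs are removed.
#'
#' @param pairs List of [read_pair()] to emit (may be empty).
#' @param qual_path Path of the original quality file.
#' @param seq_path Path of the original sequence file, or `NULL` for
#'   quality-only output.
#' @return A list with elements `qual` and `seq` (`NA` when no sequence
#'   file was written) holding the `.new` paths.
#' @export
write_filtered_pair <- function(pairs, qual_path, seq_path = NULL) {
  qual_out <- paste0(qual_path, ".new")
  seq_out <- if (!is.null(seq_path)) paste0(seq_path, ".new") else NULL
  tryCatch({
    writeLines(format_quality_records(lapply(pairs, function(p) {
      if (inherits(p, "read_pair")) p$qual else p
    })), qual_out)
    if (!is.null(seq_out)) {
      writeLines(format_sequence_records(lapply(pairs, `[[`, "seq")),
                 seq_out)
    }
  }, error = function(e) {
    unlink(c(qual_out, seq_out))
    stop("failed to write filtered output: ", conditionMessage(e),
         call. = FALSE)
  })
  list(qual = qual_out, seq = seq_out %||% NA_character_)
}
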