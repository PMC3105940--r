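#' @keywords internal
"_PACKAGE"

QV_MIN <- -1L
QV_MAX <- 93L

VALIDATION_REASONS <- c(
  "WRONG_LENGTH", "INVALID_CHARACTER", "BLANK_LINE", "MALFORMED_HEADER",
  "NON_INTEGER_QV", "QV_OUT_OF_RANGE", "UNPAIRED_RECORD"
)

# Reasons that eliminate a whole record (as opposed to skipping a line).
ELIMINATING_REASONS <- c(
  "WRONG_LENGTH", "INVALID_CHARACTER", "NON_INTEGER_QV", "QV_OUT_OF_RANGE"
)

#' One read's phred quality vector
#'
#' A retained quality record: the record identifier (first
#' whitespace-delimited token of its `>` header) and its ordered integer
#' phred values. Values lie in \[-1, 93\]; -1 is the SOLiD missed-call
#' sentinel and is kept as-is.
#'
#' @param record_id Single character string.
#' @param qvs Integer vector of phred values.
#' @return An object of class `quality_read`.
#' @export
quality_read <- function(record_id, qvs) {
  stopifnot(is.character(record_id), length(record_id) == 1L)
  qvs <- as.integer(qvs)
  if (anyNA(qvs)) stop("qvs must be integers")
  if (any(qvs < QV_MIN | qvs > QV_MAX)) {
    stop("quality values must lie in [", QV_MIN, ", ", QV_MAX, "]")
  }
  structure(list(record_id = record_id, qvs = qvs), class = "quality_read")
}

#' One read's symbol string
#'
#' A retained sequence record in either `nucleotide` encoding (symbols from
#' ACGTN, uppercased on parse) or SOLiD `colorspace` encoding (one primer
#' base from ACGT followed by color calls from `0123.`).
#'
#' @param record_id Single character string.
#' @param symbols Symbol string.
#' @param encoding `"nucleotide"` or `"colorspace"`.
#' @return An object of class `sequence_read`.
#' @export
sequence_read <- function(record_id, symbols,
                          encoding = c("nucleotide", "colorspace")) {
  encoding <- match.arg(encoding)
  stopifnot(is.character(record_id), length(record_id) == 1L,
            is.character(symbols), length(symbols) == 1L)
  structure(list(record_id = record_id, symbols = symbols,
                 encoding = encoding),
            class = "sequence_read")
}

#' A synchronized sequence/quality record pair
#'
#' @param seq A [sequence_read()].
#' @param qual A [quality_read()] with the same `record_id` and one quality
#'   value per sequence position (colors for colorspace, bases otherwise).
#' @return An object of class `read_pair`.
#' @export
read_pair <- function(seq, qual) {
  stopifnot(inherits(seq, "sequence_read"), inherits(qual, "quality_read"))
  if (seq$record_id != qual$record_id) {
    stop("record ids differ: ", seq$record_id, " vs ", qual$record_id)
  }
  n_pos <- nchar(seq$symbols) - (seq$encoding == "colorspace")
  if (length(qual$qvs) != n_pos) {
    stop("quality length ", length(qual$qvs),
         " does not match sequence positions ", n_pos)
  }
  structure(list(record_id = seq$record_id, seq = seq, qual = qual),
            class = "read_pair")
}

#' Validation log of eliminated or skipped input records
#'
#' An ordered table with one row per formatting problem: source file, line
#' number, record id (empty when unknown) and a machine-readable reason code
#' (`WRONG_LENGTH`, `INVALID_CHARACTER`, `BLANK_LINE`, `MALFORMED_HEADER`,
#' `NON_INTEGER_QV`, `QV_OUT_OF_RANGE`, `UNPAIRED_RECORD`). Formatting
#' problems are logged and processing continues; they are never fatal.
#'
#' @param source_file,line_number,record_id,reason Parallel vectors.
#' @return An object of class `validation_log` (also a `data.frame`).
#' @export
validation_log <- function(source_file = character(),
                           line_number = integer(),
                           record_id = character(),
                           reason = character()) {
  if (length(reason) && !all(reason %in% VALIDATION_REASONS)) {
    stop("unknown reason code(s): ",
         paste(setdiff(reason, VALIDATION_REASONS), collapse = ", "))
  }
  structure(
    data.frame(source_file = as.character(source_file),
               line_number = as.integer(line_number),
               record_id = as.character(record_id),
               reason = as.character(reason),
               stringsAsFactors = FALSE),
    class = c("validation_log", "data.frame")
  )
}

rbind_logs <- function(...) {
  out <- do.call(rbind, lapply(list(...), as.data.frame))
  class(out) <- c("validation_log", "data.frame")
  rownames(out) <- NULL
  out
}

#' Write a validation log as tab-separated text
#'
#' @param log A [validation_log()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_validation_log <- function(log, path) {
  utils::write.table(as.data.frame(log), path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @export
print.validation_log <- function(x, ...) {
  cat("Validation log:", nrow(x), "entr",
      if (nrow(x) == 1L) "y" else "ies", "\n", sep = "")
  if (nrow(x)) print.data.frame(x, ...)
  invisible(x)
}

#' @export
print.quality_read <- function(x, ...) {
  cat("<quality_read> ", x$record_id, ": L=", length(x$qvs),
      " qvs=[", paste(utils::head(x$qvs, 8L), collapse = " "),
      if (length(x$qvs) > 8L) " ..." else "", "]\n", sep = "")
  invisible(x)
}

#' @export
print.sequence_read <- function(x, ...) {
  cat("<sequence_read> ", x$record_id, " (", x$encoding, "): ",
      substr(x$symbols, 1L, 40L),
      if (nchar(x$symbols) > 40L) "..." else "", "\n", sep = "")
  invisible(x)
}
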