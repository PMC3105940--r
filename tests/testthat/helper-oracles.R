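# Independent oracles and fixture builders, deliberately implemented with
# different machinery than the package (slurp + regex split instead of a
# streaming state machine; dense matrices instead of bounded tallies).

# Non-streaming reference parser for quality files: slurps the whole text,
# splits it into ">"-delimited records, keeps records whose tokens are all
# integers in [-1, 93] and whose count equals L.
oracle_parse_quality <- function(path, L) {
  txt <- paste(readLines(path, warn = FALSE), collapse = "\n")
  chunks <- strsplit(paste0("\n", txt), "\n>", fixed = TRUE)[[1L]][-1L]
  out <- list()
  for (chunk in chunks) {
    lines <- strsplit(chunk, "\n", fixed = TRUE)[[1L]]
    id <- strsplit(trimws(lines[[1L]]), "\\s+")[[1L]][1L]
    if (is.na(id)) id <- ""
    tokens <- unlist(strsplit(trimws(lines[-1L]), "\\s+"))
    tokens <- tokens[nzchar(tokens)]
    if (length(tokens) == L && all(grepl("^[-+]?[0-9]+$", tokens))) {
      qvs <- as.integer(tokens)
      if (all(qvs >= -1L & qvs <= 93L)) {
        out[[length(out) + 1L]] <- list(record_id = id, qvs = qvs)
      }
    }
  }
  out
}

# Dense-matrix aggregate oracle: stacks all reads into an n x L matrix and
# tallies columns with table().
oracle_dense_aggregate <- function(reads, L) {
  m <- do.call(rbind, lapply(reads, `[[`, "qvs"))
  list(
    n_reads = nrow(m),
    col_means = colMeans(m),
    position_tables = lapply(seq_len(L), function(p) table(m[, p])),
    means = rowMeans(m),
    medians = apply(m, 1L, stats::median)
  )
}

random_quality_reads <- function(n, L, qv_pool = 0:45) {
  lapply(seq_len(n), function(i) {
    quality_read(sprintf("r%05d", i), sample(qv_pool, L, replace = TRUE))
  })
}

write_qual_fixture <- function(lines, path = tempfile(fileext = ".qual")) {
  writeLines(lines, path)
  path
}

# Count log entries whose reason eliminates a record (vs. skips a line).
n_eliminating <- function(log) {
  sum(log$reason %in% c("WRONG_LENGTH", "INVALID_CHARACTER",
                        "NON_INTEGER_QV", "QV_OUT_OF_RANGE"))
}
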