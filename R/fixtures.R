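# Deterministic synthetic read generator: paired .qual / sequence files
# with a controllable per-position quality profile, optional deliberate
# corruption (one mode per validation reason code), and a ground-truth
# manifest computed directly from the sampled values. Uses R's
# Mersenne-Twister so identical seeds give byte-identical files on any
# platform.

CORRUPTION_KINDS <- c("wrong_length", "invalid_char", "blank_line",
                      "non_integer_qv")

#' Per-position quality profile for the synthetic generator
#'
#' @param L Read length.
#' @param position_dists List of length `L`; element `p` is a named numeric
#'   vector mapping quality values to sampling probabilities (summing to 1
#'   within 1e-9) for position `p`. Defaults to a point mass at phred 25
#'   everywhere.
#' @param fraction_malformed Proportion of records to corrupt deliberately,
#'   in `[0, 1]`.
#' @param seed Integer seed.
#' @return An object of class `quality_profile`.
#' @export
quality_profile <- function(L, position_dists = NULL,
                            fraction_malformed = 0, seed = 1L) {
  L <- as.integer(L)
  stopifnot(L >= 1L, fraction_malformed >= 0, fraction_malformed <= 1)
  if (is.null(position_dists)) {
    position_dists <- rep(list(c("25" = 1)), L)
  }
  stopifnot(length(position_dists) == L)
  for (p in seq_len(L)) {
    d <- position_dists[[p]]
    qv <- suppressWarnings(as.integer(names(d)))
    if (anyNA(qv) || any(qv < QV_MIN | qv > QV_MAX)) {
      stop("position ", p, ": names must be quality values in [",
           QV_MIN, ", ", QV_MAX, "]")
    }
    if (abs(sum(d) - 1) > 1e-9) {
      stop("position ", p, ": probabilities sum to ", sum(d), ", not 1")
    }
  }
  structure(list(L = L, position_dists = position_dists,
                 fraction_malformed = fraction_malformed,
                 seed = as.integer(seed)),
            class = "quality_profile")
}

#' Analytic expected mean quality at each position
#'
#' @param profile A [quality_profile()].
#' @return Numeric vector of length `L`.
#' @export
expected_position_means <- function(profile) {
  stopifnot(inherits(profile, "quality_profile"))
  vapply(profile$position_dists,
         function(d) sum(as.numeric(names(d)) * d), numeric(1L))
}

#' A 35-bp profile with a mid-read quality plateau and degraded tail
#'
#' Emulates the shape of SOLiD 35-bp fragment-library data: a short
#' low-quality start, a 17-position interior plateau whose expected mean
#' quality is at or above phred 20, a tail that decays below 20, and a
#' bimodal last base whose most common quality value is phred 5.
#'
#' @return A [quality_profile()] with `L = 35`.
#' @export
degraded_tail_profile <- function() {
  dists <- c(
    rep(list(c("15" = 0.7, "25" = 0.3)), 2),           # slow start, E = 18
    rep(list(c("20" = 0.5, "30" = 0.5)), 17),          # plateau,    E = 25
    rep(list(c("15" = 0.6, "25" = 0.4)), 8),           # decay,      E = 19
    rep(list(c("10" = 0.6, "22" = 0.4)), 7),           # decay,      E = 14.8
    list(c("5" = 0.6, "26" = 0.4))                     # last base,  E = 13.4
  )
  quality_profile(35L, dists)
}

sample_qv_matrix <- function(profile, n) {
  m <- matrix(0L, nrow = n, ncol = profile$L)
  for (p in seq_len(profile$L)) {
    d <- profile$position_dists[[p]]
    qv <- as.integer(names(d))
    m[, p] <- if (length(qv) == 1L) rep.int(qv, n)
              else sample(qv, n, replace = TRUE, prob = d)
  }
  m
}

#' Generate a paired synthetic dataset with ground truth
#'
#' Writes a quality file, a matching sequence file and a tab-separated
#' truth manifest into `out_dir`. The manifest records each read's exact
#' mean and median (computed straight from the sampled matrix), whether it
#' was deliberately corrupted, the corruption kind, and whether that kind
#' eliminates the record on parse (`blank_line` is logged but never
#' eliminates). Corruption kinds cycle through `wrong_length` (quality
#' record one value short), `invalid_char` (bad symbol in the sequence
#' record), `blank_line` (inserted inside the quality record) and
#' `non_integer_qv`.
#'
#' @param profile A [quality_profile()].
#' @param n Number of records.
#' @param encoding `"colorspace"` or `"nucleotide"`.
#' @param out_dir Output directory (created if missing).
#' @param basename Stem for the output file names.
#' @return A list with `qual_path`, `seq_path`, `manifest_path` and the
#'   `manifest` data frame.
#' @export
generate_dataset <- function(profile, n,
                             encoding = c("colorspace", "nucleotide"),
                             out_dir, basename = "reads") {
  stopifnot(inherits(profile, "quality_profile"), n >= 1L)
  encoding <- match.arg(encoding)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)

  old_seed <- if (exists(".Random.seed", globalenv())) {
    get(".Random.seed", globalenv())
  }
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed,
                                         globalenv()))
  set.seed(profile$seed, kind = "Mersenne-Twister")

  L <- profile$L
  qmat <- sample_qv_matrix(profile, n)
  ids <- sprintf("%s_%05d", basename, seq_len(n))
  bases <- c("A", "C", "G", "T")
  seqs <- if (encoding == "colorspace") {
    paste0(sample(bases, n, replace = TRUE),
           apply(matrix(sample(0:3, n * L, replace = TRUE), n, L),
                 1L, paste, collapse = ""))
  } else {
    apply(matrix(sample(bases, n * L, replace = TRUE), n, L),
          1L, paste, collapse = "")
  }

  n_bad <- round(profile$fraction_malformed * n)
  bad_idx <- if (n_bad > 0L) sort(sample.int(n, n_bad)) else integer()
  kind <- rep("", n)
  kind[bad_idx] <- CORRUPTION_KINDS[(seq_along(bad_idx) - 1L) %%
                                      length(CORRUPTION_KINDS) + 1L]

  qv_lines <- apply(qmat, 1L, paste, collapse = " ")
  for (i in bad_idx) {
    switch(kind[i],
      wrong_length = qv_lines[i] <- paste(qmat[i, -L], collapse = " "),
      non_integer_qv = qv_lines[i] <- sub("^\\S+", "x7", qv_lines[i]),
      invalid_char = seqs[i] <- sub("^(.)", "\\1X", seqs[i]),
      blank_line = NULL
    )
  }
  qual_recs <- mapply(function(h, b, q) {
    if (b) c(h, "", q) else c(h, q)
  }, paste0(">", ids), kind == "blank_line", qv_lines, SIMPLIFY = FALSE)
  qual_lines <- unlist(qual_recs, use.names = FALSE)
  seq_lines <- as.vector(rbind(paste0(">", ids), seqs))

  qual_path <- file.path(out_dir, paste0(basename, ".qual"))
  seq_path <- file.path(out_dir, paste0(
    basename, if (encoding == "colorspace") ".csfasta" else ".fasta"))
  writeLines(qual_lines, qual_path)
  writeLines(seq_lines, seq_path)

  manifest <- data.frame(
    record_id = ids,
    mean = rowSums(qmat) / L,
    median = apply(qmat, 1L, read_median),
    corrupted = kind != "",
    corruption_kind = kind,
    eliminated = kind %in% c("wrong_length", "invalid_char",
                             "non_integer_qv"),
    stringsAsFactors = FALSE
  )
  manifest_path <- file.path(out_dir, paste0(basename, ".manifest.tsv"))
  utils::write.table(manifest, manifest_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  list(qual_path = qual_path, seq_path = seq_path,
       manifest_path = manifest_path, manifest = manifest)
}
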