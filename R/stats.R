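# Single-pass accumulation of per-position quality tallies and read-level
# mean/median distributions, plus fold-coverage arithmetic.
#
# Memory is bounded by the quality-value domain and the read length, never
# by the number of reads: position tallies live in a fixed (95 x L) count
# matrix (rows = QV -1..93), read sums in a vector indexed by the exact
# integer sum (range [-L, 93 L]) and read medians in a vector indexed by the
# exact doubled median (always an integer). The exact integer tallies are
# what coverage_table() thresholds against, so its counts agree with
# brute-force re-filtering bit for bit; the 2-decimal mean keys exist only
# for the exported frequency table.

QV_DOMAIN <- QV_MIN:QV_MAX

trunc2 <- function(x) trunc(x * 100) / 100

#' Arithmetic mean of a read's quality values
#'
#' Exact (unrounded) mean; this is the statistic the mean filter compares
#' against the cutoff.
#'
#' @param qvs Non-empty integer vector of phred values.
#' @return The mean, as a double.
#' @export
read_mean <- function(qvs) {
  if (length(qvs) == 0L) stop("cannot take the mean of an empty read")
  sum(as.numeric(qvs)) / length(qvs)
}

#' Median of a read's quality values
#'
#' Middle value after sorting for odd-length reads; the arithmetic mean of
#' the two middle values (an integer or half-integer) for even length. The
#' median ignores how far values sit above or below it, which is what makes
#' the median filter robust to isolated low-quality bases.
#'
#' @inheritParams read_mean
#' @return The median (integer or half-integer), as a double.
#' @export
read_median <- function(qvs) {
  n <- length(qvs)
  if (n == 0L) stop("cannot take the median of an empty read")
  s <- sort.int(as.integer(qvs))
  if (n %% 2L == 1L) as.numeric(s[(n + 1L) %/% 2L])
  else (s[n %/% 2L] + s[n %/% 2L + 1L]) / 2
}

#' Accumulate per-base and per-read quality frequency tables
#'
#' One pass over the reads produces a `per_base_aggregate`: for every
#' position `p` in `1..L` the frequency of each observed quality value, and
#' for every read the frequency of its mean (keyed truncated to 2 decimals)
#' and median. Exact integer tallies of read quality sums and doubled
#' medians are kept alongside for cutoff arithmetic.
#'
#' @param reads List of [quality_read()] (or [read_pair()]; qualities are
#'   taken from each pair), all of length `L`.
#' @param L Read length.
#' @return An object of class `per_base_aggregate` with fields
#'   `read_length`, `n_reads`, `position_freq` (list of named count
#'   vectors), `read_mean_freq` and `read_median_freq` (named count
#'   vectors).
#' @export
accumulate_quality <- function(reads, L) {
  L <- as.integer(L)
  stopifnot(L >= 1L)
  n_qv <- length(QV_DOMAIN)
  counts <- matrix(0L, nrow = n_qv, ncol = L)
  sum_freq <- integer(QV_MAX * L - QV_MIN * L + 1L)  # sums in [-L, 93 L]
  med2_freq <- integer(2L * QV_MAX - 2L * QV_MIN + 1L)
  n_reads <- 0L
  for (r in reads) {
    q <- if (inherits(r, "read_pair")) r$qual$qvs else r$qvs
    if (length(q) != L) {
      stop("read ", n_reads + 1L, " has length ", length(q), ", expected ", L)
    }
    idx <- cbind(q - QV_MIN + 1L, seq_len(L))
    counts[idx] <- counts[idx] + 1L
    s <- sum(q) - QV_MIN * L + 1L
    sum_freq[s] <- sum_freq[s] + 1L
    m2 <- as.integer(2 * read_median(q)) - 2L * QV_MIN + 1L
    med2_freq[m2] <- med2_freq[m2] + 1L
    n_reads <- n_reads + 1L
  }
  qv_names <- as.character(QV_DOMAIN)
  position_freq <- lapply(seq_len(L), function(p) {
    nz <- counts[, p] > 0L
    stats::setNames(counts[nz, p], qv_names[nz])
  })
  sums <- which(sum_freq > 0L) - 1L + QV_MIN * L
  mean_keys <- sprintf("%.2f", trunc2(sums / L))
  read_mean_freq <- vapply(split(sum_freq[sum_freq > 0L], mean_keys),
                           sum, integer(1L))
  meds <- (which(med2_freq > 0L) - 1L + 2L * QV_MIN) / 2
  read_median_freq <- stats::setNames(med2_freq[med2_freq > 0L],
                                      format(meds, trim = TRUE))
  structure(list(read_length = L, n_reads = n_reads,
                 position_freq = position_freq,
                 read_mean_freq = read_mean_freq,
                 read_median_freq = read_median_freq,
                 counts = counts, sum_freq = sum_freq,
                 med2_freq = med2_freq),
            class = "per_base_aggregate")
}

#' @export
print.per_base_aggregate <- function(x, ...) {
  cat("<per_base_aggregate> ", x$n_reads, " reads of length ",
      x$read_length, "\n", sep = "")
  if (x$n_reads > 0L) {
    m <- per_base_mean_series(x)
    cat("  per-base mean quality: ",
        sprintf("%.2f", min(m)), " .. ", sprintf("%.2f", max(m)), "\n",
        sep = "")
  }
  invisible(x)
}

#' Mean quality observed at each base position
#'
#' @param agg A `per_base_aggregate` with at least one read.
#' @return Numeric vector of length `L`; entry `p` is the mean quality over
#'   all reads at (1-based) position `p`.
#' @export
per_base_mean_series <- function(agg) {
  stopifnot(inherits(agg, "per_base_aggregate"))
  if (agg$n_reads == 0L) stop("aggregate contains no reads")
  drop(crossprod(QV_DOMAIN, agg$counts)) / agg$n_reads
}

#' Frequency of quality values at one base position
#'
#' @param agg A `per_base_aggregate`.
#' @param position 1-based base position in `1..L`.
#' @return Named integer vector: observed quality value (name) to count.
#' @export
base_quality_histogram <- function(agg, position) {
  stopifnot(inherits(agg, "per_base_aggregate"))
  position <- as.integer(position)
  if (is.na(position) || position < 1L || position > agg$read_length) {
    stop("position must lie in [1, ", agg$read_length, "]")
  }
  agg$position_freq[[position]]
}

#' Estimate fold genome coverage
#'
#' Computes `C = (n * L) / S` — reads times read length over expected
#' genome size — truncated to a whole number of folds. Truncation (not
#' rounding) is deliberate: it is the convention under which published
#' coverage tables for this estimator reproduce exactly from their read
#' counts.
#'
#' @param n_reads Number of reads (`>= 0`).
#' @param read_length Read length in bases (`L >= 1`).
#' @param genome_size Expected genome size in bases (`S >= 1`).
#' @return Whole-number fold coverage, as a double.
#' @export
#' @examples
#' estimate_coverage(11349208, 35, 2.3e6)  # 172
estimate_coverage <- function(n_reads, read_length, genome_size) {
  n <- as.numeric(n_reads)
  L <- as.numeric(read_length)
  S <- as.numeric(genome_size)
  stopifnot(length(n) == 1L, length(L) == 1L, length(S) == 1L,
            !is.na(n), !is.na(L), !is.na(S), n >= 0, L >= 1)
  if (S < 1) stop("genome size must be >= 1")
  (n * L) %/% S
}

#' Percentage of raw reads retained by a filter
#'
#' `100 * kept / raw`, truncated (not rounded) to two decimals — again the
#' convention under which published retention tables reproduce.
#'
#' @param kept Number of retained reads, `0 <= kept <= raw`.
#' @param raw Number of raw reads, `>= 1`.
#' @return Percentage with two decimals.
#' @export
#' @examples
#' retention_percentage(11349208, 21102241)  # 53.78
retention_percentage <- function(kept, raw) {
  kept <- as.numeric(kept)
  raw <- as.numeric(raw)
  stopifnot(length(kept) == 1L, length(raw) == 1L, !is.na(kept), !is.na(raw))
  if (raw < 1) stop("raw read count must be >= 1")
  if (kept < 0 || kept > raw) stop("kept must lie in [0, raw]")
  floor(1e4 * kept / raw) / 100
}

#' Kept reads and coverage across quality cutoffs
#'
#' For each statistic (mean and median) and each threshold `t`, counts the
#' reads whose read-level statistic is `>= t` (inclusive cutoff, exact
#' arithmetic — computed from the aggregate's exact tallies without
#' re-scanning the reads) and converts the count to fold coverage.
#'
#' @param agg A `per_base_aggregate`.
#' @param thresholds Non-empty numeric vector of phred cutoffs.
#' @param genome_size Expected genome size `S` in bases.
#' @return A data frame with columns `statistic`, `threshold`, `kept`,
#'   `coverage`, ordered mean rows first.
#' @export
coverage_table <- function(agg, thresholds, genome_size) {
  stopifnot(inherits(agg, "per_base_aggregate"), length(thresholds) >= 1L)
  L <- agg$read_length
  sum_idx <- which(agg$sum_freq > 0L)
  sum_counts <- agg$sum_freq[sum_idx]
  means <- (sum_idx - 1L + QV_MIN * L) / L  # same division the filter does
  med_idx <- which(agg$med2_freq > 0L)
  med_counts <- agg$med2_freq[med_idx]
  meds <- (med_idx - 1L + 2L * QV_MIN) / 2
  one <- function(stat, t) {
    kept <- if (stat == "mean") sum(sum_counts[means >= t])
            else sum(med_counts[meds >= t])
    data.frame(statistic = stat, threshold = t, kept = kept,
               coverage = estimate_coverage(kept, L, genome_size))
  }
  out <- do.call(rbind, c(
    lapply(thresholds, function(t) one("mean", t)),
    lapply(thresholds, function(t) one("median", t))
  ))
  rownames(out) <- NULL
  out
}

#' Export aggregate frequency tables as tab-separated text
#'
#' Writes two tables: per-position quality counts (`position`, `qv`,
#' `count`) and read-level statistic counts (`statistic`, `value`,
#' `count`).
#'
#' @param agg A `per_base_aggregate`.
#' @param position_path,stat_path Output paths.
#' @return Invisibly, the two paths.
#' @export
write_aggregate_tables <- function(agg, position_path, stat_path) {
  stopifnot(inherits(agg, "per_base_aggregate"))
  pos <- do.call(rbind, c(
    list(data.frame(position = integer(), qv = integer(),
                    count = integer())),
    lapply(seq_len(agg$read_length), function(p) {
      f <- agg$position_freq[[p]]
      if (!length(f)) return(NULL)
      data.frame(position = p, qv = as.integer(names(f)),
                 count = as.integer(f))
    })))
  utils::write.table(pos, position_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  stat <- rbind(
    data.frame(statistic = rep("mean", length(agg$read_mean_freq)),
               value = names(agg$read_mean_freq),
               count = as.integer(agg$read_mean_freq)),
    data.frame(statistic = rep("median", length(agg$read_median_freq)),
               value = names(agg$read_median_freq),
               count = as.integer(agg$read_median_freq))
  )
  utils::write.table(stat, stat_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(c(position_path, stat_path))
}

#' Export a coverage table in wide (publication) layout
#'
#' One row per statistic (Mean, Median), one pair of columns
#' (`kept_QV<t>`, `coverage_QV<t>`) per threshold.
#'
#' @param tab Output of [coverage_table()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_coverage_table <- function(tab, path) {
  ts <- unique(tab$threshold)
  wide <- data.frame(statistic = c("Mean", "Median"))
  for (t in ts) {
    m <- tab[tab$statistic == "mean" & tab$threshold == t, ]
    d <- tab[tab$statistic == "median" & tab$threshold == t, ]
    wide[[paste0("kept_QV", t)]] <- c(m$kept, d$kept)
    wide[[paste0("coverage_QV", t)]] <- c(m$coverage, d$coverage)
  }
  utils::write.table(wide, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
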