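# Chart-ready series for the three standard read-QC plots (per-base mean
# quality, quality histogram at a position, read-statistic distribution)
# and their static rendering. Series are pure functions of the aggregate;
# rendering is presentation only.

chart_series <- function(kind, x, y, xlab, ylab, title, n_reads) {
  stopifnot(length(x) == length(y))
  structure(list(kind = kind, x = x, y = y, xlab = xlab, ylab = ylab,
                 title = title, n_reads = n_reads),
            class = "chart_series")
}

#' @export
print.chart_series <- function(x, ...) {
  cat("<chart_series> ", x$kind, ": ", length(x$x), " points (",
      x$n_reads, " reads)\n", sep = "")
  invisible(x)
}

#' Per-base mean quality series
#'
#' Base position (x) against mean base quality (y) — the curve that shows
#' where along the read quality degrades, typically at the terminal bases.
#'
#' @param agg A `per_base_aggregate` with at least one read.
#' @return A `chart_series` of kind `per_base_mean` with `x = 1..L`.
#' @export
mean_per_base_series <- function(agg) {
  stopifnot(inherits(agg, "per_base_aggregate"))
  if (agg$n_reads == 0L) stop("aggregate contains no reads")
  chart_series("per_base_mean", seq_len(agg$read_length),
               per_base_mean_series(agg),
               "Base position", "Mean phred quality",
               "Mean quality per base", agg$n_reads)
}

#' Quality-value histogram series at one position
#'
#' Observed phred value (x) against frequency of occurrence (y). Defaults
#' to the last base, where second-generation reads degrade most and where a
#' low mode (e.g. phred 5) drags the per-base mean down.
#'
#' @param agg A `per_base_aggregate` with at least one read.
#' @param position 1-based base position; default `L` (last base).
#' @return A `chart_series` of kind `base_qv_histogram`; counts sum to
#'   `n_reads`.
#' @export
position_histogram_series <- function(agg, position = agg$read_length) {
  stopifnot(inherits(agg, "per_base_aggregate"))
  if (agg$n_reads == 0L) stop("aggregate contains no reads")
  f <- base_quality_histogram(agg, position)
  chart_series("base_qv_histogram", as.integer(names(f)),
               as.integer(f),
               "Phred quality value", "Frequency",
               sprintf("Quality distribution at base %d", position),
               agg$n_reads)
}

#' Last-base quality histogram series
#'
#' Convenience wrapper for [position_histogram_series()] at position `L`.
#'
#' @inheritParams mean_per_base_series
#' @return A `chart_series` of kind `base_qv_histogram`.
#' @export
last_base_histogram_series <- function(agg) {
  position_histogram_series(agg, agg$read_length)
}

#' Distribution of read-level mean or median quality
#'
#' @inheritParams mean_per_base_series
#' @param statistic `"mean"` or `"median"`.
#' @return A `chart_series` of kind `read_stat_distribution`; counts sum to
#'   `n_reads`.
#' @export
read_stat_distribution_series <- function(agg,
                                          statistic = c("mean", "median")) {
  statistic <- match.arg(statistic)
  stopifnot(inherits(agg, "per_base_aggregate"))
  if (agg$n_reads == 0L) stop("aggregate contains no reads")
  f <- if (statistic == "mean") agg$read_mean_freq else agg$read_median_freq
  chart_series("read_stat_distribution", as.numeric(names(f)),
               as.integer(f),
               sprintf("Read %s phred quality", statistic), "Frequency",
               sprintf("Distribution of read %s quality", statistic),
               agg$n_reads)
}

#' Render a chart series to a static image
#'
#' Writes a PNG or SVG (chosen from the file extension). Histogram kinds
#' are drawn as bar charts, the per-base mean as a line. Rendering reads
#' only the series — every number on the chart comes from its `x`/`y`.
#'
#' @param series A `chart_series`.
#' @param path Output path ending in `.png` or `.svg`.
#' @param width,height Device size in inches.
#' @return `path`, invisibly.
#' @export
render_chart <- function(series, path, width = 7, height = 5) {
  stopifnot(inherits(series, "chart_series"))
  ext <- tolower(tools::file_ext(path))
  switch(ext,
    png = grDevices::png(path, width = width, height = height,
                         units = "in", res = 120),
    svg = grDevices::svg(path, width = width, height = height),
    stop("unsupported image format: .", ext)
  )
  on.exit(grDevices::dev.off())
  graphics::par(mar = c(4.5, 4.5, 2.5, 1))
  if (series$kind == "per_base_mean") {
    graphics::plot(series$x, series$y, type = "o", pch = 16, cex = 0.6,
                   col = "steelblue4", xlab = series$xlab,
                   ylab = series$ylab, main = series$title,
                   ylim = c(0, max(series$y, 40)))
    graphics::abline(h = 20, lty = 2, col = "grey40")
  } else {
    graphics::barplot(series$y, names.arg = series$x, col = "steelblue3",
                      border = NA, xlab = series$xlab, ylab = series$ylab,
                      main = series$title)
  }
  invisible(path)
}

#' Export a chart series as tab-separated (x, y) text
#'
#' @param series A `chart_series`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_series_tsv <- function(series, path) {
  stopifnot(inherits(series, "chart_series"))
  utils::write.table(data.frame(x = series$x, y = series$y), path,
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
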