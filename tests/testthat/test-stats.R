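test_that("read_mean and read_median follow their conventions", {
  expect_equal(read_mean(c(20, 20, 20)), 20)
  expect_equal(read_mean(c(5, 10, 30)), 15)
  # 13 values of 23 and 12 of 15: mean 479/25 = 19.16 exactly, median 23
  fig4a <- c(rep(23L, 13), rep(15L, 12))
  expect_equal(read_mean(fig4a), 19.16)
  expect_equal(read_median(fig4a), 23)

  expect_equal(read_median(c(10, 20, 30)), 20)
  expect_equal(read_median(c(10, 20, 20, 30)), 20)  # even: mean of middles
  expect_equal(read_median(c(10, 20, 30, 50)), 25)
  expect_equal(read_median(c(1, 1, 50)), 1)         # robust to one outlier
  expect_error(read_mean(integer()), "empty")
  expect_error(read_median(integer()), "empty")
})

test_that("read_median ignores side-preserving perturbations", {
  set.seed(5)
  for (rep_i in 1:25) {
    L <- sample(c(5L, 11L, 25L, 35L), 1L)
    q <- sample(0:40, L, replace = TRUE)
    m <- read_median(q)
    q2 <- q
    above <- q > m
    below <- q < m
    q2[above] <- q2[above] + sample(0:20, sum(above), replace = TRUE)
    q2[below] <- pmax(-1L, q2[below] - sample(0:20, sum(below),
                                              replace = TRUE))
    expect_equal(read_median(q2), m)
  }
})

test_that("accumulate_quality matches small hand-checked tallies", {
  reads <- list(quality_read("a", c(10L, 20L)),
                quality_read("b", c(30L, 40L)))
  agg <- accumulate_quality(reads, 2)
  expect_equal(agg$n_reads, 2L)
  expect_equal(agg$position_freq[[1]], c("10" = 1L, "30" = 1L))
  expect_equal(agg$position_freq[[2]], c("20" = 1L, "40" = 1L))
  expect_equal(per_base_mean_series(agg), c(20, 30))
  expect_equal(sum(agg$read_mean_freq), 2L)
  expect_equal(sum(agg$read_median_freq), 2L)

  expect_equal(per_base_mean_series(accumulate_quality(
    list(quality_read("a", c(7L, 8L, 9L))), 3)), c(7, 8, 9))
  expect_error(accumulate_quality(list(quality_read("a", 1:3)), 4),
               "length")
})

test_that("streaming aggregate equals the dense-matrix oracle", {
  for (seed in 1:3) {
    set.seed(seed)
    n <- sample(200:800, 1)
    L <- sample(c(10L, 25L, 35L, 50L), 1)
    reads <- random_quality_reads(n, L, qv_pool = -1:60)
    agg <- accumulate_quality(reads, L)
    oracle <- oracle_dense_aggregate(reads, L)
    expect_identical(agg$n_reads, oracle$n_reads)
    expect_equal(per_base_mean_series(agg), oracle$col_means)
    for (p in seq_len(L)) {
      o <- oracle$position_tables[[p]]
      expect_equal(base_quality_histogram(agg, p),
                   stats::setNames(as.integer(o), names(o)))
      # conservation: counts at every position sum to n_reads
      expect_equal(sum(agg$position_freq[[p]]), n)
    }
    expect_equal(sum(agg$read_mean_freq), n)
    expect_equal(sum(agg$read_median_freq), n)
    # median frequency table matches a brute-force tally
    o_med <- table(oracle$medians)
    expect_equal(as.integer(agg$read_median_freq), as.integer(o_med))
  }
})

test_that("base_quality_histogram validates its position", {
  agg <- accumulate_quality(list(quality_read("a", c(5L, 5L)),
                                 quality_read("b", c(5L, 10L))), 2)
  expect_equal(base_quality_histogram(agg, 1), c("5" = 2L))
  expect_equal(base_quality_histogram(agg, 2), c("5" = 1L, "10" = 1L))
  expect_error(base_quality_histogram(agg, 0), "position")
  expect_error(base_quality_histogram(agg, 3), "position")
})

test_that("estimate_coverage truncates and is monotone", {
  expect_equal(estimate_coverage(0, 35, 2.3e6), 0)
  # 199.97x must truncate to 199, not round to 200
  expect_equal(estimate_coverage(13140825, 35, 2.3e6), 199)
  expect_error(estimate_coverage(10, 35, 0), "genome size")
  set.seed(9)
  for (i in 1:20) {
    n <- sample(1e6, 1); L <- sample(20:100, 1); S <- sample(1e5, 1)
    expect_equal(estimate_coverage(n, L, S), floor(n * L / S))
    expect_gte(estimate_coverage(n + 1000, L, S),
               estimate_coverage(n, L, S))   # non-decreasing in n
    expect_lte(estimate_coverage(n, L, S + 1000),
               estimate_coverage(n, L, S))   # non-increasing in S
  }
})

test_that("retention_percentage truncates to two decimals", {
  expect_equal(retention_percentage(5, 10), 50.00)
  # 74.994... truncates to 74.99
  expect_equal(retention_percentage(33765330, 45024226), 74.99)
  expect_equal(retention_percentage(0, 10), 0)
  expect_error(retention_percentage(5, 0), "raw")
  expect_error(retention_percentage(11, 10), "kept")
})

test_that("coverage_table equals brute-force re-filtering of the reads", {
  set.seed(13)
  L <- 25L
  reads <- random_quality_reads(500, L, qv_pool = 0:45)
  agg <- accumulate_quality(reads, L)
  means <- vapply(reads, function(r) read_mean(r$qvs), numeric(1))
  meds <- vapply(reads, function(r) read_median(r$qvs), numeric(1))
  S <- 12345
  tab <- coverage_table(agg, c(0, 15, 20, 20.5, 23, 25, 94), S)
  for (i in seq_len(nrow(tab))) {
    stat_vals <- if (tab$statistic[i] == "mean") means else meds
    kept <- sum(stat_vals >= tab$threshold[i])
    expect_equal(tab$kept[i], kept)
    expect_equal(tab$coverage[i], estimate_coverage(kept, L, S))
  }
  # threshold 0 keeps everything for both statistics
  t0 <- tab[tab$threshold == 0, ]
  expect_equal(t0$kept, c(500L, 500L))

  # two-read example: means {19.16, 23}, cutoff 20 keeps one
  two <- accumulate_quality(list(
    quality_read("a", c(rep(23L, 13), rep(15L, 12))),
    quality_read("b", rep(23L, 25))), 25)
  expect_equal(coverage_table(two, 20, 100)$kept[1], 1L)
})

test_that("aggregate tables export round-trips through read.delim", {
  agg <- accumulate_quality(list(quality_read("a", c(10L, 20L)),
                                 quality_read("b", c(10L, 40L))), 2)
  pos_f <- tempfile(fileext = ".tsv"); stat_f <- tempfile(fileext = ".tsv")
  write_aggregate_tables(agg, pos_f, stat_f)
  pos <- utils::read.delim(pos_f)
  expect_equal(pos$count[pos$position == 1 & pos$qv == 10], 2L)
  stat <- utils::read.delim(stat_f)
  expect_equal(sum(stat$count[stat$statistic == "median"]), 2L)
})
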