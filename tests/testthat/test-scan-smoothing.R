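test_that("window fit matches hand-worked examples", {
  expect_equal(fit_snpnum_window(c(5, 2, 9), window_snps = 1), c(5, 2, 9))
  expect_equal(fit_snpnum_window(rep(3.5, 7), window_snps = 5), rep(3.5, 7))
  # truncated edge windows on a 5-point toy
  expect_equal(fit_snpnum_window(c(0, 1, 10, 1, 0), window_snps = 3),
               c(0.5, 1, 1, 1, 0.5))
  expect_equal(fit_snpnum_window(numeric(0)), numeric(0))
  # even windows are bumped to the next odd width
  expect_equal(fit_snpnum_window(c(0, 1, 10, 1, 0), window_snps = 2),
               fit_snpnum_window(c(0, 1, 10, 1, 0), window_snps = 3))
})

test_that("window fit equals the brute-force sliding oracle", {
  set.seed(77)
  for (i in 1:60) {
    n <- sample(3:60, 1)
    x <- rnorm(n)
    x[sample(n, floor(n / 6))] <- NA
    w <- sample(c(3, 5, 9, 15), 1)
    expect_equal(fit_snpnum_window(x, w), oracle_window_fit(x, w, median))
    expect_equal(fit_snpnum_window(x, w, stat = "mean"),
                 oracle_window_fit(x, w, mean))
  }
})

test_that("per-chromosome fitting never mixes chromosomes", {
  track <- tibble::tibble(
    chrom = rep(c("chr01", "chr02"), each = 4),
    pos = rep(1:4 * 100, 2),
    val = c(rep(0, 4), rep(10, 4))
  )
  fit <- fit_scan_track(track, "val", window_snps = 3)
  expect_equal(fit$val_fitted, c(rep(0, 4), rep(10, 4)))
})

test_that("ED threshold is median + 3 population SD", {
  expect_equal(ed_threshold(rep(0.7, 5)), 0.7)
  expect_equal(ed_threshold(c(0, 0, 0, 0, 1)), 1.2)
  expect_error(ed_threshold(c(1, NA, Inf)), "at least two")
})

test_that("delta threshold follows the interpolated quantile with a floor", {
  v <- c(rep(0.01, 100), 0.9)
  expect_equal(delta_threshold(v, q = 0.99), 0.01)
  expect_equal(delta_threshold(v, q = 1 - 1e-9), 0.9, tolerance = 1e-6)
  expect_equal(delta_threshold(rep(0.01, 50), q = 0.99, floor = 0.05), 0.05)
  expect_error(delta_threshold(v, q = 1.5), "q must be")
  expect_error(delta_threshold(c(0.2, NA), q = 0.99), "at least two")
})

test_that("interval calling snaps runs to the 10 kb grid and merges gaps", {
  track <- tibble::tibble(
    chrom = "chr01",
    pos = c(105000, 115000, 125000, 135000),
    fitted = c(0.1, 0.9, 0.9, 0.1)
  )
  iv <- call_intervals(track, 0.5)
  expect_equal(nrow(iv), 1)
  expect_equal(iv$start, 110000)
  expect_equal(iv$end, 130000)
  expect_equal(iv$size_mb, 0.02)
  expect_equal(iv$n_snps, 2L)

  expect_equal(nrow(call_intervals(track, 2)), 0)

  single <- call_intervals(tibble::tibble(chrom = "chr01", pos = 55500,
                                          fitted = 3), 1)
  expect_equal(single$end - single$start, 1e4)

  # two runs separated by less than merge_gap collapse into one interval
  track2 <- tibble::tibble(
    chrom = "chr01", pos = c(100000, 150000, 150100),
    fitted = c(1, 0, 1)
  )
  expect_equal(nrow(call_intervals(track2, 0.5, merge_gap = 1e5)), 1)
  expect_equal(nrow(call_intervals(track2, 0.5, merge_gap = 2e4)), 2)
})

test_that("published interval tables intersect to the expected region", {
  f <- system.file("extdata", "published_intervals.tsv", package = "starchbsa")
  tab <- read.delim(f)
  ed <- genomic_intervals(tab$chrom[tab$method == "ED"],
                          tab$start[tab$method == "ED"],
                          tab$end[tab$method == "ED"])
  si <- genomic_intervals(tab$chrom[tab$method == "SNP-index"],
                          tab$start[tab$method == "SNP-index"],
                          tab$end[tab$method == "SNP-index"])
  ov <- intersect_intervals(ed, si)
  expect_equal(nrow(ov), 1)
  expect_equal(ov$chrom, "Chr02")
  expect_equal(ov$start, 0)
  expect_equal(ov$end, 5620000)
  expect_equal(ov$size_mb, 5.62)
})

test_that("interval intersection is commutative, associative and idempotent", {
  rand_set <- function(n) {
    start <- sample(0:50, n, TRUE) * 1e4
    genomic_intervals(sample(c("chr01", "chr02"), n, TRUE),
                      start, start + sample(1:20, n, TRUE) * 1e4)
  }
  key <- function(x) as.data.frame(x[order(x$chrom, x$start),
                                     c("chrom", "start", "end")])
  set.seed(13)
  for (i in 1:15) {
    a <- rand_set(4); b <- rand_set(4); c <- rand_set(4)
    expect_equal(key(intersect_intervals(a, b)), key(intersect_intervals(b, a)))
    expect_equal(
      key(intersect_intervals(intersect_intervals(a, b), c)),
      key(intersect_intervals(a, intersect_intervals(b, c)))
    )
    aa <- intersect_intervals(a, a)
    expect_equal(key(intersect_intervals(aa, aa)), key(aa))
  }
  # nesting: a subset of b intersects to itself
  a <- genomic_intervals("chr01", 2e4, 6e4)
  b <- genomic_intervals("chr01", 0, 1e5)
  expect_equal(key(intersect_intervals(a, b)), key(a))
  # disjoint chromosomes give nothing
  expect_equal(nrow(intersect_intervals(
    genomic_intervals("chr01", 0, 1e5), genomic_intervals("chr02", 0, 1e5)
  )), 0)
})
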