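test_that("the toy VCF parses with multi-allelic sites preserved", {
  f <- system.file("extdata", "toy_pools.vcf", package = "starchbsa")
  rec <- read_pool_variants(f)
  expect_equal(nrow(rec), 2)
  expect_equal(rec$n_alt, c(1L, 2L))
  expect_equal(rec$hp_ref, c(3, 4))
  expect_equal(rec$hp_alt, c(9, NA))   # first-alt count undefined when multi-allelic
  expect_equal(rec$hp_dp, c(12, 12))
})

test_that("a VCF without a required sample raises a schema error naming it", {
  f <- system.file("extdata", "toy_pools.vcf", package = "starchbsa")
  lines <- readLines(f)
  drop_lp <- sub("\tLP$", "", lines)
  drop_lp <- vapply(strsplit(drop_lp, "\t"), function(x) {
    if (length(x) >= 13) paste(x[-13], collapse = "\t") else paste(x, collapse = "\t")
  }, character(1))
  g <- withr::local_tempfile(fileext = ".vcf")
  writeLines(drop_lp, g)
  expect_error(read_pool_variants(g), "LP")
})

test_that("TSV input round-trips through write and read", {
  rec <- make_records(
    chrom = c("chr01", "chr01"), pos = c(100, 200),
    ref = c("A", "C"), alt = c("G", "T"),
    p1 = c("0,9", "1,7"), p2 = c("8,0", "9,1"),
    hp = c("2,6", "3,5"), lp = c("7,1", "6,2")
  )
  f <- withr::local_tempfile(fileext = ".tsv")
  write_pool_tsv(rec, f)
  back <- read_pool_variants(f, format = "tsv")
  expect_equal(back[names(rec)], rec)
  # missing columns are a schema error
  g <- withr::local_tempfile(fileext = ".tsv")
  tab <- read.delim(f)
  write.table(tab[, -5], g, sep = "\t", quote = FALSE, row.names = FALSE)
  expect_error(read_pool_variants(g, format = "tsv"), "P1_ref")
})

# hand-built 10-SNP toy: 2 triallelic; 2 with one sample below 4x depth;
# 2 with both pools fixed for the same allele; 1 with identical parents;
# 3 clean survivors
toy_cascade <- function() {
  make_records(
    chrom = rep("chr01", 10), pos = (1:10) * 100,
    ref = rep("A", 10),
    alt = c("G,T", "G,C", "G", "G", "G", "G", "G", "G", "G", "G"),
    p1 = c("4,3,3", "4,3,3", "0,10", "0,10", "0,9", "0,9", "9,0", "0,10", "0,10", "0,12"),
    p2 = c("9,0,0", "9,0,0", "10,0", "10,0", "9,0", "8,0", "8,0", "10,0", "9,0", "11,0"),
    hp = c("5,5,0", "5,5,0", "1,2", "5,5", "0,8", "0,7", "4,4", "2,8", "3,7", "0,9"),
    lp = c("5,0,5", "5,0,5", "5,5", "2,1", "0,9", "0,6", "5,3", "8,2", "9,1", "7,3")
  )
}

test_that("the cascade removes stages in order with exact accounting", {
  res <- apply_filter_cascade(toy_cascade())
  rep <- res$report
  expect_equal(rep$input_count, 10)
  expect_equal(rep$removed_multiallelic, 2)
  expect_equal(rep$removed_low_depth, 2)
  expect_equal(rep$removed_identical_pools, 2)
  expect_equal(rep$removed_parent_rule, 1)
  expect_equal(rep$surviving_count, 3)
  expect_equal(nrow(res$records), 3)
  expect_equal(res$records$pos, c(800, 900, 1000))
})

test_that("a site failing several rules is counted at its first failing stage", {
  # triallelic AND low depth AND identical parents: only stage 1 counts it
  rec <- make_records("chr01", 100, "A", "G,T",
                      p1 = "1,1,0", p2 = "1,1,0", hp = "1,1,0", lp = "1,1,0")
  rep <- apply_filter_cascade(rec)$report
  expect_equal(rep$removed_multiallelic, 1)
  expect_equal(rep$removed_low_depth, 0)
  expect_equal(rep$removed_parent_rule, 0)
})

test_that("empty input yields a zero report and filtering is idempotent", {
  empty <- toy_cascade()[0, ]
  res <- apply_filter_cascade(empty)
  expect_equal(res$report$surviving_count, 0)
  expect_equal(res$report$input_count, 0)

  once <- apply_filter_cascade(toy_cascade())
  twice <- apply_filter_cascade(once$records)
  expect_equal(twice$records, once$records)
  expect_equal(twice$report$surviving_count, once$report$surviving_count)
  expect_equal(twice$report$removed_identical_pools, 0)
})

test_that("filter accounting balances on random tables", {
  set.seed(31)
  for (i in 1:20) {
    n <- sample(5:40, 1)
    ad <- function() paste0(sample(0:9, n, TRUE), ",", sample(0:9, n, TRUE))
    rec <- make_records(
      chrom = "chr01", pos = seq_len(n) * 10,
      ref = rep("A", n),
      alt = ifelse(runif(n) < 0.2, "G,T", "G"),
      p1 = ad(), p2 = ad(), hp = ad(), lp = ad()
    )
    rep <- apply_filter_cascade(rec)$report
    removed <- rep$removed_multiallelic + rep$removed_low_depth +
      rep$removed_identical_pools + rep$removed_parent_rule
    expect_equal(rep$surviving_count, rep$input_count - removed)
    expect_equal(rep$surviving_count, nrow(apply_filter_cascade(rec)$records))
  }
})

test_that("the strict allele-set pool rule also removes shared heterozygous sites", {
  rec <- make_records("chr01", 100, "A", "G",
                      p1 = "0,10", p2 = "10,0", hp = "5,5", lp = "4,6")
  expect_equal(apply_filter_cascade(rec)$report$surviving_count, 1)
  strict <- apply_filter_cascade(rec, pool_rule = "allele_set")$report
  expect_equal(strict$removed_identical_pools, 1)
  expect_equal(strict$surviving_count, 0)
})

test_that("missing depth is treated as zero and fails the depth stage", {
  rec <- make_records("chr01", 100, "A", "G",
                      p1 = NA, p2 = "10,0", hp = "5,5", lp = "4,6")
  expect_true(rec$missing_depth)
  expect_equal(rec$p1_dp, 0)
  expect_equal(apply_filter_cascade(rec)$report$removed_low_depth, 1)
})
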