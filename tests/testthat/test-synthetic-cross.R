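small_cfg <- function(...) {
  args <- utils::modifyList(
    list(n_chromosomes = 1, chrom_length_bp = 2e6, n_snps_per_chrom = 60,
         qtl_pos_bp = 1e6),
    list(...)
  )
  do.call(sim_config, args)
}

test_that("invalid configuration errors name the offending field", {
  expect_error(sim_config(bulk_size = 60, n_progeny = 100), "bulk_size")
  expect_error(sim_config(qtl_pos_bp = 1e9), "qtl_pos_bp")
  expect_error(sim_config(mean_depth = 0), "mean_depth")
  expect_error(sim_config(qtl_chrom = 7, n_chromosomes = 3), "qtl_chrom")
})

test_that("same config and seed give bitwise-identical simulations", {
  a <- simulate_cross(small_cfg(seed = 42))
  b <- simulate_cross(small_cfg(seed = 42))
  expect_identical(a$markers, b$markers)
  expect_identical(a$progeny_dosage, b$progeny_dosage)
  expect_identical(a$phenotype, b$phenotype)
  c <- simulate_cross(small_cfg(seed = 43))
  expect_false(identical(a$phenotype, c$phenotype))
})

test_that("noiseless additive model yields exactly three dosage-spaced values", {
  st <- simulate_cross(small_cfg(noise_sd = 0, qtl_effect = 3, seed = 5))
  vals <- sort(unique(st$phenotype$starch))
  expect_true(all(vals %in% (13 + 3 * 0:2)))
  expect_equal(st$phenotype$starch, 13 + 3 * st$qtl_dosage)
})

test_that("with no QTL effect, phenotype is uncorrelated with dosage", {
  # null-model Monte Carlo: |r| < 0.2 at n = 106 for at least 95% of seeds
  inside <- vapply(1:200, function(s) {
    st <- simulate_cross(small_cfg(qtl_effect = 0, n_snps_per_chrom = 20,
                                   seed = s))
    abs(cor(st$phenotype$starch, st$qtl_dosage)) < 0.2
  }, logical(1))
  expect_gte(mean(inside), 0.95)
})

test_that("genotype dosages stay in 0..2 and markers are biallelic", {
  st <- simulate_cross(small_cfg(seed = 9))
  expect_true(all(st$progeny_dosage %in% 0:2))
  expect_true(all(st$markers$ref != st$markers$alt))
  expect_false(is.unsorted(st$markers$pos, strictly = TRUE))
})

test_that("bulks take the phenotype tails and partition cleanly", {
  st <- simulate_cross(small_cfg(seed = 3, n_progeny = 10, bulk_size = 2))
  st$phenotype$starch <- 1:10  # ids F_001..F_010
  b <- sample_bulks(st, 2)
  expect_setequal(b$high, c("F_010", "F_009"))
  expect_setequal(b$low, c("F_001", "F_002"))
  half <- sample_bulks(st, 5)
  expect_length(intersect(half$high, half$low), 0)
  expect_setequal(c(half$high, half$low), st$phenotype$id)
  expect_error(sample_bulks(st, 6), "bulk_size")
})

test_that("ties at the bulk cut are broken by ascending id, reproducibly", {
  st <- simulate_cross(small_cfg(seed = 3, n_progeny = 6, bulk_size = 2))
  st$phenotype$starch <- c(5, 5, 5, 1, 1, 1)
  b1 <- sample_bulks(st, 2)
  b2 <- sample_bulks(st, 2)
  expect_identical(b1$high, c("F_001", "F_002"))
  expect_identical(b1$low, c("F_004", "F_005"))
  expect_identical(b1, b2)
})

test_that("pool counts follow the bulk allele frequencies", {
  # a bulk fixed for the alt allele gives alt fraction 1
  dos <- matrix(c(2L, 0L), nrow = 2, ncol = 3,
                dimnames = list(NULL, NULL))
  st <- make_micro_study(dos, starch = c(10, 1))
  b <- sample_bulks(st, 1)
  rec <- emit_pool_counts(st, b, mean_depth = 50, seed = 2)
  expect_true(all(rec$hp_ref == 0))
  expect_true(all(rec$hp_alt > 0))
  expect_true(all(rec$lp_alt == 0))

  # binomial concentration: frequency 0.5 at depth 10,000 stays within 0.02
  dos2 <- matrix(1L, nrow = 2, ncol = 5)
  st2 <- make_micro_study(dos2, starch = c(2, 1))
  rec2 <- emit_pool_counts(st2, sample_bulks(st2, 1), mean_depth = 1e4, seed = 7)
  expect_true(all(abs(rec2$hp_alt / rec2$hp_dp - 0.5) < 0.02))

  # parents are genotype-consistent and counts never exceed depth
  expect_true(all(rec2$p1_ref == 0))
  expect_true(all(rec2$p2_alt == 0))
  expect_true(all(rec2$hp_alt <= rec2$hp_dp & rec2$lp_alt <= rec2$lp_dp))
})

test_that("pool VCF round-trips positions, alleles and depth fields", {
  st <- simulate_cross(small_cfg(seed = 11, n_snps_per_chrom = 25))
  rec <- emit_pool_counts(st, sample_bulks(st))
  f <- withr::local_tempfile(fileext = ".vcf")
  write_pool_vcf(rec, f)
  back <- read_pool_variants(f)
  for (col in c("chrom", "pos", "ref", "alt", "p1_ad", "p2_ad", "hp_ad", "lp_ad")) {
    expect_identical(back[[col]], rec[[col]])
  }
})

test_that("H/L frequency contrast is larger at the QTL than off-target", {
  # averaged over 50 seeds with a strong, low-noise QTL
  diff_at <- function(st, b, col) {
    hi <- match(b$high, st$phenotype$id)
    lo <- match(b$low, st$phenotype$id)
    mean(st$progeny_dosage[hi, col]) - mean(st$progeny_dosage[lo, col])
  }
  d_qtl <- d_far <- numeric(50)
  for (s in 1:50) {
    cfg <- sim_config(n_chromosomes = 2, chrom_length_bp = 2e6,
                      n_snps_per_chrom = 30, qtl_pos_bp = 1e6,
                      qtl_effect = 3, noise_sd = 0.5, seed = s)
    st <- simulate_cross(cfg)
    b <- sample_bulks(st)
    near <- which.min(abs(st$markers$pos - 1e6) +
                        (st$markers$chrom != "chr01") * 1e9)
    far <- which(st$markers$chrom == "chr02")[1]
    d_qtl[s] <- diff_at(st, b, near)
    d_far[s] <- diff_at(st, b, far)
  }
  expect_gt(mean(d_qtl), mean(abs(d_far)))
})
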