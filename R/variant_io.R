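POOL_SAMPLES <- c("P1", "P2", "HP", "LP")

# Canonical pool-record tibble.  One row per variant site; per-sample
# allele depths kept both as the raw AD string (exact round-tripping,
# multi-allelic sites included) and as derived numeric convenience columns
# (first-alt counts are NA at multi-allelic sites, which are removed by the
# first filter stage anyway).  Missing AD ("." or "") is encoded as zero
# depth with `missing_depth = TRUE`.
new_pool_records <- function(chrom, pos, ref, alt, ad) {
  stopifnot(all(c("p1", "p2", "hp", "lp") %in% names(ad)))
  n_alt <- lengths(strsplit(alt, ",", fixed = TRUE))
  rec <- tibble(
    chrom = as.character(chrom), pos = as.numeric(pos),
    ref = as.character(ref), alt = as.character(alt),
    n_alt = as.integer(n_alt)
  )
  missing_any <- rep(FALSE, nrow(rec))
  for (s in c("p1", "p2", "hp", "lp")) {
    a <- as.character(ad[[s]])
    miss <- is.na(a) | a %in% c(".", "")
    a[miss] <- NA_character_
    parsed <- strsplit(a, ",", fixed = TRUE)
    counts <- lapply(parsed, function(x) {
      if (length(x) == 1L && is.na(x)) return(numeric(0))
      suppressWarnings(as.numeric(x))
    })
    dp <- vapply(counts, function(x) sum(x, na.rm = TRUE), numeric(1))
    refc <- vapply(counts, function(x) if (length(x) >= 1L) x[1] else 0, numeric(1))
    altc <- vapply(counts, function(x) if (length(x) >= 2L) x[2] else 0, numeric(1))
    rec[[paste0(s, "_ad")]] <- a
    rec[[paste0(s, "_ref")]] <- refc
    rec[[paste0(s, "_alt")]] <- ifelse(n_alt > 1L, NA_real_, altc)
    rec[[paste0(s, "_dp")]] <- dp
    missing_any <- missing_any | miss
  }
  rec$missing_depth <- missing_any
  if (any(rec$pos < 1, na.rm = TRUE)) {
    abort_starchbsa("variant positions must be >= 1", "starchbsa_parse_error")
  }
  rec
}

#' Read a four-sample pooled variant table
#'
#' Reads the variant input of a bulked-segregant experiment: two parents (P1,
#' P2) and the high/low bulks (HP, LP), with per-sample allele depths.  Two
#' formats are supported: a VCF with an `AD` FORMAT field, or a tab-separated
#' table with columns `chrom, pos, ref, alt, P1_ref, P1_alt, P2_ref, P2_alt,
#' HP_ref, HP_alt, LP_ref, LP_alt`.  Multi-allelic lines are preserved as
#' parsed (removing them is the first stage of [apply_filter_cascade()], not
#' the reader's job).
#'
#' @param path path to the VCF (`.vcf`) or TSV file.
#' @param format `"auto"` (by file extension), `"vcf"` or `"tsv"`.
#' @return A pool-record tibble with columns `chrom, pos, ref, alt, n_alt`,
#'   per-sample `*_ad` depth strings, derived `*_ref`, `*_alt`, `*_dp`
#'   numeric columns, and a `missing_depth` flag.
#' @examples
#' f <- system.file("extdata", "toy_pools.vcf", package = "starchbsa")
#' read_pool_variants(f)
#' @export
read_pool_variants <- function(path, format = c("auto", "vcf", "tsv")) {
  format <- match.arg(format)
  if (!file.exists(path)) {
    abort_starchbsa(sprintf("input file not found: %s", path),
                    "starchbsa_io_error")
  }
  if (format == "auto") {
    format <- if (grepl("\\.vcf(\\.gz)?$", path, ignore.case = TRUE)) "vcf" else "tsv"
  }
  if (format == "vcf") read_pool_vcf(path) else read_pool_tsv(path)
}

read_pool_vcf <- function(path) {
  vcf <- vcfR::read.vcfR(path, verbose = FALSE)
  samples <- colnames(vcf@gt)[-1]
  missing <- setdiff(POOL_SAMPLES, samples)
  if (length(missing) > 0L) {
    abort_starchbsa(
      sprintf("VCF is missing required sample(s): %s",
              paste(missing, collapse = ", ")),
      "starchbsa_schema_error"
    )
  }
  ad <- vcfR::extract.gt(vcf, element = "AD")
  fix <- vcfR::getFIX(vcf)
  fix <- matrix(fix, ncol = 7, dimnames = list(NULL, colnames(fix)))
  new_pool_records(
    chrom = fix[, "CHROM"], pos = as.numeric(fix[, "POS"]),
    ref = fix[, "REF"], alt = fix[, "ALT"],
    ad = list(p1 = ad[, "P1"], p2 = ad[, "P2"], hp = ad[, "HP"], lp = ad[, "LP"])
  )
}

read_pool_tsv <- function(path) {
  tab <- tryCatch(
    read.delim(path, stringsAsFactors = FALSE, check.names = FALSE),
    error = function(e) abort_starchbsa(
      sprintf("failed to parse %s: %s", path, conditionMessage(e)),
      "starchbsa_parse_error"
    )
  )
  need <- c("chrom", "pos", "ref", "alt",
            paste0(rep(POOL_SAMPLES, each = 2), "_", c("ref", "alt")))
  missing <- setdiff(need, names(tab))
  if (length(missing) > 0L) {
    abort_starchbsa(
      sprintf("TSV is missing required column(s): %s",
              paste(missing, collapse = ", ")),
      "starchbsa_schema_error"
    )
  }
  ad_str <- function(prefix) {
    r <- tab[[paste0(prefix, "_ref")]]
    a <- tab[[paste0(prefix, "_alt")]]
    out <- paste0(r, ",", a)
    out[is.na(r) | is.na(a)] <- NA_character_
    out
  }
  new_pool_records(
    chrom = tab$chrom, pos = tab$pos, ref = tab$ref, alt = tab$alt,
    ad = list(p1 = ad_str("P1"), p2 = ad_str("P2"),
              hp = ad_str("HP"), lp = ad_str("LP"))
  )
}

#' Write pool records
#'
#' `write_pool_vcf()` writes a minimal VCF v4.2 with samples ordered
#' P1, P2, HP, LP and a per-sample `AD` (allele depth) FORMAT field;
#' `write_pool_tsv()` writes the flat ref/alt count table (biallelic sites
#' only).  Both round-trip through [read_pool_variants()].
#'
#' @param records a pool-record tibble.
#' @param path output file path.
#' @return The path, invisibly.
#' @export
write_pool_vcf <- function(records, path) {
  header <- c(
    "##fileformat=VCFv4.2",
    "##source=starchbsa",
    "##FORMAT=<ID=AD,Number=R,Type=Integer,Description=\"Allelic depths for the ref and alt alleles\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", POOL_SAMPLES), collapse = "\t")
  )
  fmt_ad <- function(x) ifelse(is.na(x), ".", x)
  body <- paste(
    records$chrom, format(records$pos, scientific = FALSE, trim = TRUE),
    ".", records$ref, records$alt, ".", "PASS", ".", "AD",
    fmt_ad(records$p1_ad), fmt_ad(records$p2_ad),
    fmt_ad(records$hp_ad), fmt_ad(records$lp_ad),
    sep = "\t"
  )
  writeLines(c(header, body), path)
  invisible(path)
}

#' @rdname write_pool_vcf
#' @export
write_pool_tsv <- function(records, path) {
  if (any(records$n_alt > 1L)) {
    abort_starchbsa("TSV output supports biallelic records only; filter first",
                    "starchbsa_io_error")
  }
  out <- data.frame(
    chrom = records$chrom, pos = records$pos,
    ref = records$ref, alt = records$alt,
    P1_ref = records$p1_ref, P1_alt = records$p1_alt,
    P2_ref = records$p2_ref, P2_alt = records$p2_alt,
    HP_ref = records$hp_ref, HP_alt = records$hp_alt,
    LP_ref = records$lp_ref, LP_alt = records$lp_alt,
    check.names = FALSE
  )
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
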