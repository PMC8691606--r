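#' Base frequencies of one pool at one site
#'
#' Converts per-base read counts (A, C, G, T) into read frequencies.  A pool
#' with zero total depth yields an all-zero vector flagged `zero_depth`;
#' downstream statistics treat such sites as missing.
#'
#' @param counts numeric vector of length 4, named or in A, C, G, T order.
#' @return A `base_freqs` list with `freq` (named numeric of length 4 summing
#'   to 1, or all zero) and `zero_depth` (logical flag).
#' @examples
#' base_frequencies(c(A = 8, C = 0, G = 0, T = 2))
#' @export
base_frequencies <- function(counts) {
  bases <- c("A", "C", "G", "T")
  if (is.null(names(counts))) names(counts) <- bases
  counts <- counts[bases]
  if (anyNA(counts) || any(counts < 0)) {
    abort_starchbsa("base counts must be non-negative and non-missing",
                    "starchbsa_domain_error")
  }
  total <- sum(counts)
  if (total == 0) {
    return(structure(list(freq = setNames(rep(0, 4), bases), zero_depth = TRUE),
                     class = "base_freqs"))
  }
  structure(list(freq = counts / total, zero_depth = FALSE),
            class = "base_freqs")
}

#' Euclidean distance between two pools' base-frequency vectors
#'
#' The per-SNP ED statistic: the Euclidean distance between the high and low
#' bulks' (A, C, G, T) read-frequency vectors,
#' \deqn{ED = \sqrt{\sum_{b \in \{A,C,G,T\}} (f_{H,b} - f_{L,b})^2},}
#' bounded by \eqn{\sqrt{2}} (two pools fixed for different bases).  Raising
#' ED to a power (default 5) suppresses the genome-wide background relative
#' to true association peaks, and it is the powered value the scan smooths
#' and thresholds.
#'
#' @param f_h,f_l `base_freqs` for the high and low pool.
#' @param power exponent of the background-suppressing transform.
#' @return A list with `ed` and `ed_powered` (`ed^power`); both `NA` when
#'   either pool has zero depth.
#' @examples
#' euclidean_distance(base_frequencies(c(1, 0, 0, 0)),
#'                    base_frequencies(c(0, 0, 0, 1)))
#' @export
euclidean_distance <- function(f_h, f_l, power = 5) {
  stopifnot(inherits(f_h, "base_freqs"), inherits(f_l, "base_freqs"))
  if (f_h$zero_depth || f_l$zero_depth) {
    return(list(ed = NA_real_, ed_powered = NA_real_))
  }
  ed <- sqrt(sum((f_h$freq - f_l$freq)^2))
  list(ed = ed, ed_powered = ed^power)
}

#' SNP-index per pool and its high-minus-low difference
#'
#' The SNP-index of a pool is the fraction of its reads carrying the
#' alternate allele.  `delta = index_H - index_L`, so values near +1 flag an
#' allele private to the high bulk and values near -1 an allele private to
#' the low bulk; both tails are scanned downstream.  A pool with zero total
#' depth gives missing statistics at that site.
#'
#' @param h_ref,h_alt,l_ref,l_alt reference/alternate read counts in the high
#'   and low pools (vectorised).
#' @return A tibble with columns `snp_index_h`, `snp_index_l`, `delta`.
#' @examples
#' snp_index(2, 6, 10, 0)
#' @export
snp_index <- function(h_ref, h_alt, l_ref, l_alt) {
  if (any(c(h_ref, h_alt, l_ref, l_alt) < 0, na.rm = TRUE)) {
    abort_starchbsa("read counts must be non-negative", "starchbsa_domain_error")
  }
  th <- h_ref + h_alt
  tl <- l_ref + l_alt
  ih <- ifelse(th > 0, h_alt / th, NA_real_)
  il <- ifelse(tl > 0, l_alt / tl, NA_real_)
  tibble(snp_index_h = ih, snp_index_l = il, delta = ih - il)
}

#' Per-SNP BSA statistics for a pool-record table
#'
#' Computes, for every biallelic record, the ED statistic (from the bulks'
#' A/C/G/T frequency vectors, reconstructed from the ref/alt counts and
#' allele bases), its power transform, and the per-pool SNP-index with
#' `delta = index_H - index_L`.  Sites where either bulk has zero depth get
#' `NA` statistics and are skipped by the window fit.
#'
#' @param records a (filtered) pool-record tibble.
#' @param power ED power-transform exponent (default 5).
#' @return `records` with columns `ed`, `ed_powered`, `snp_index_h`,
#'   `snp_index_l`, `delta` appended.
#' @export
compute_bsa_stats <- function(records, power = 5) {
  if (any(records$n_alt > 1L)) {
    abort_starchbsa("statistics require biallelic records; run the filter cascade first",
                    "starchbsa_domain_error")
  }
  th <- records$hp_ref + records$hp_alt
  tl <- records$lp_ref + records$lp_alt
  fh <- ifelse(th > 0, records$hp_alt / th, NA_real_)
  fl <- ifelse(tl > 0, records$lp_alt / tl, NA_real_)

  # For a biallelic site the four-base frequency vectors differ only in the
  # ref- and alt-base coordinates, each by (fh - fl), so ED reduces to
  # sqrt(2) * |fh - fl|.  Sites where ref == alt base cannot occur (enforced
  # at parse time by VCF semantics).
  ed <- sqrt(2) * abs(fh - fl)
  records$ed <- ed
  records$ed_powered <- ed^power
  si <- snp_index(records$hp_ref, records$hp_alt, records$lp_ref, records$lp_alt)
  records$snp_index_h <- si$snp_index_h
  records$snp_index_l <- si$snp_index_l
  records$delta <- si$delta
  records
}

#' Export the per-SNP statistic track
#'
#' Writes the scan track as TSV: `chrom, pos, ed, ed_powered, snp_index_h,
#' snp_index_l, delta` (plus any fitted columns present).
#'
#' @param stats output of [compute_bsa_stats()].
#' @param path output path.
#' @return The path, invisibly.
#' @export
write_stats_tsv <- function(stats, path) {
  keep <- intersect(
    c("chrom", "pos", "ed", "ed_powered", "snp_index_h", "snp_index_l",
      "delta", "ed_powered_fitted", "delta_fitted", "delta_abs_fitted"),
    names(stats)
  )
  write.table(stats[, keep], path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
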