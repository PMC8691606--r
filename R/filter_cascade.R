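#' Filter-stage accounting
#'
#' Book-keeping record of the four-stage SNP filter: sites removed because
#' they are multi-allelic, low depth, uninformative between the bulks, or
#' uninformative between the parents.  `surviving_count` is always computed
#' from the identity `input - sum(removed)`, so accounting cannot drift from
#' the stage counts.
#'
#' @param input_count number of sites entering the cascade.
#' @param removed_multiallelic sites with more than one alternate allele.
#' @param removed_low_depth sites where any of the four samples is below the
#'   depth cutoff.
#' @param removed_identical_pools sites failing the bulk-genotype rule.
#' @param removed_parent_rule sites failing the parent informativeness rule.
#' @return A `filter_report` object.
#' @examples
#' filter_report(6301408, 135107, 464306, 70487, 4654022)
#' @export
filter_report <- function(input_count,
                          removed_multiallelic,
                          removed_low_depth,
                          removed_identical_pools,
                          removed_parent_rule) {
  counts <- c(
    input_count = input_count,
    removed_multiallelic = removed_multiallelic,
    removed_low_depth = removed_low_depth,
    removed_identical_pools = removed_identical_pools,
    removed_parent_rule = removed_parent_rule
  )
  if (any(counts < 0)) {
    abort_starchbsa("filter counts must be non-negative", "starchbsa_filter_error")
  }
  rep <- as.list(counts)
  rep$surviving_count <- input_count -
    (removed_multiallelic + removed_low_depth +
       removed_identical_pools + removed_parent_rule)
  if (rep$surviving_count < 0) {
    abort_starchbsa("removed counts exceed input count", "starchbsa_filter_error")
  }
  structure(rep, class = "filter_report")
}

#' @export
print.filter_report <- function(x, ...) {
  cat("<filter_report>\n")
  cat(sprintf("  input sites:              %d\n", x$input_count))
  cat(sprintf("  - multi-allelic:          %d\n", x$removed_multiallelic))
  cat(sprintf("  - depth below cutoff:     %d\n", x$removed_low_depth))
  cat(sprintf("  - pools uninformative:    %d\n", x$removed_identical_pools))
  cat(sprintf("  - parents uninformative:  %d\n", x$removed_parent_rule))
  cat(sprintf("  surviving high-quality:   %d\n", x$surviving_count))
  invisible(x)
}

#' @export
format.filter_report <- function(x, ...) {
  jsonlite::toJSON(unclass(x), auto_unbox = TRUE)
}

# supported-allele set of one sample at a biallelic site, under the
# minor-allele read floor: "r", "a", "ra" or "" (none reaches the floor)
supported_alleles <- function(ref_count, alt_count, floor_reads) {
  paste0(ifelse(ref_count >= floor_reads, "r", ""),
         ifelse(alt_count >= floor_reads, "a", ""))
}

#' Apply the four-stage high-quality SNP filter
#'
#' Removes, in order: (1) multi-allelic sites; (2) sites where any of the
#' four samples has total depth below `min_depth`; (3) sites uninformative
#' between the bulks; (4) sites uninformative between the parents.  A site is
#' counted at the first stage it fails, so the per-stage counts always sum
#' with the survivors to the input count.
#'
#' Stages 3 and 4 call a sample's genotype as its *supported allele set*:
#' the alleles backed by at least `min_allele_reads` reads (pools are
#' mixtures, so the observed allele set is the natural pool-level genotype).
#' Two bulk rules are available:
#' \describe{
#'   \item{`"fixed"` (default)}{remove a site only when both bulks are fixed
#'     for the same single allele, i.e. the bulks are monomorphic and
#'     identical.  Bulks that share both alleles are retained: their
#'     frequency contrast is exactly what the downstream ED and
#'     \eqn{\Delta}(SNP-index) statistics measure.}
#'   \item{`"allele_set"`}{the stricter reading: remove whenever the two
#'     bulks' supported allele sets are identical, including the shared
#'     heterozygous set.}
#' }
#' The parent rule removes sites whose two parental supported allele sets
#' are identical (non-informative markers).
#'
#' @param records a pool-record tibble from [read_pool_variants()] or
#'   [emit_pool_counts()].
#' @param min_depth minimum total depth required of every sample (default 4).
#' @param min_allele_reads reads required to call an allele present in a
#'   sample (default 2).
#' @param pool_rule `"fixed"` or `"allele_set"` (see Details).
#' @return A list with `records` (the surviving rows) and `report`
#'   (a [filter_report()]).
#' @examples
#' study <- simulate_cross(sim_config(n_chromosomes = 1, n_snps_per_chrom = 100,
#'                                    chrom_length_bp = 1e6, qtl_pos_bp = 5e5))
#' counts <- emit_pool_counts(study, sample_bulks(study))
#' apply_filter_cascade(counts)$report
#' @export
apply_filter_cascade <- function(records, min_depth = 4, min_allele_reads = 2,
                                 pool_rule = c("fixed", "allele_set")) {
  pool_rule <- match.arg(pool_rule)
  n_in <- nrow(records)
  if (n_in == 0L) {
    return(list(records = records, report = filter_report(0, 0, 0, 0, 0)))
  }

  fail_multi <- records$n_alt > 1L
  depth_ok <- records$p1_dp >= min_depth & records$p2_dp >= min_depth &
    records$hp_dp >= min_depth & records$lp_dp >= min_depth
  fail_depth <- !fail_multi & !depth_ok

  live <- !fail_multi & !fail_depth
  hp_set <- supported_alleles(records$hp_ref, records$hp_alt, min_allele_reads)
  lp_set <- supported_alleles(records$lp_ref, records$lp_alt, min_allele_reads)
  pools_same <- if (pool_rule == "fixed") {
    hp_set == lp_set & hp_set %in% c("r", "a")
  } else {
    hp_set == lp_set
  }
  fail_pools <- live & pools_same

  live <- live & !fail_pools
  p1_set <- supported_alleles(records$p1_ref, records$p1_alt, min_allele_reads)
  p2_set <- supported_alleles(records$p2_ref, records$p2_alt, min_allele_reads)
  fail_parents <- live & (p1_set == p2_set)

  keep <- live & !fail_parents
  list(
    records = records[keep, , drop = FALSE],
    report = filter_report(
      input_count = n_in,
      removed_multiallelic = sum(fail_multi),
      removed_low_depth = sum(fail_depth),
      removed_identical_pools = sum(fail_pools),
      removed_parent_rule = sum(fail_parents)
    )
  )
}
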