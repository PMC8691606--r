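# Independent brute-force oracles and small fixture builders shared by the
# unit and acceptance tests.  The oracles deliberately re-derive results from
# first principles (explicit loops, naive window scans) so that agreement
# with the package is informative.

# sliding SNP-count window statistic, truncated at the edges, NAs skipped
oracle_window_fit <- function(x, window, stat = median) {
  if (window %% 2 == 0) window <- window + 1
  half <- (window - 1) / 2
  n <- length(x)
  out <- rep(NA_real_, n)
  for (i in seq_len(n)) {
    win <- x[max(1, i - half):min(n, i + half)]
    win <- win[is.finite(win)]
    if (length(win) > 0) out[i] <- stat(win)
  }
  out
}

IUPAC_SETS <- list(
  A = "A", C = "C", G = "G", T = "T",
  R = c("A", "G"), Y = c("C", "T"), S = c("C", "G"), W = c("A", "T"),
  K = c("G", "T"), M = c("A", "C"),
  B = c("C", "G", "T"), D = c("A", "G", "T"), H = c("A", "C", "T"),
  V = c("A", "C", "G"), N = c("A", "C", "G", "T")
)

oracle_revcomp <- function(s) {
  comp <- c(A = "T", C = "G", G = "C", T = "A",
            R = "Y", Y = "R", S = "S", W = "W", K = "M", M = "K",
            B = "V", D = "H", H = "D", V = "B", N = "N")
  paste(rev(comp[strsplit(s, "")[[1]]]), collapse = "")
}

# naive all-window IUPAC matcher; subject N never matches a non-N code
oracle_match_starts <- function(sequence, pattern) {
  sq <- strsplit(sequence, "")[[1]]
  pt <- strsplit(pattern, "")[[1]]
  L <- length(pt)
  n <- length(sq)
  if (n < L) return(integer(0))
  hits <- integer(0)
  for (s in seq_len(n - L + 1)) {
    ok <- TRUE
    for (j in seq_len(L)) {
      if (!(sq[s + j - 1] %in% IUPAC_SETS[[pt[j]]])) { ok <- FALSE; break }
    }
    if (ok) hits <- c(hits, s)
  }
  hits
}

# naive cut-position scan under the same coordinate convention the package
# documents (forward: start + offset - 1; reverse-strand site: start + len -
# 1 - offset; palindromes scanned once with the centre cut; end cuts dropped)
oracle_find_sites <- function(sequence, site, cut_offset) {
  L <- nchar(site)
  rc <- oracle_revcomp(site)
  if (rc == site) {
    cuts <- oracle_match_starts(sequence, site) + L %/% 2 - 1
  } else {
    cuts <- c(oracle_match_starts(sequence, site) + cut_offset - 1,
              oracle_match_starts(sequence, rc) + L - 1 - cut_offset)
  }
  cuts <- sort(unique(cuts))
  cuts[cuts >= 1 & cuts <= nchar(sequence) - 1]
}

random_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# build a pool-record table from per-sample AD strings
make_records <- function(chrom, pos, ref, alt, p1, p2, hp, lp) {
  starchbsa:::new_pool_records(
    chrom = chrom, pos = pos, ref = ref, alt = alt,
    ad = list(p1 = p1, p2 = p2, hp = hp, lp = lp)
  )
}

# minimal hand-built study for targeted pool-count tests
make_micro_study <- function(dosage, starch, chrom = "chr01",
                             pos = NULL, seed = 1) {
  n <- nrow(dosage)
  m <- ncol(dosage)
  if (is.null(pos)) pos <- seq(1e4, by = 1e4, length.out = m)
  cfg <- sim_config(n_chromosomes = 1, chrom_length_bp = max(pos) + 1e4,
                    n_snps_per_chrom = m, qtl_pos_bp = pos[1],
                    n_progeny = max(n, 2), bulk_size = max(floor(n / 2), 1),
                    seed = seed)
  ids <- sprintf("F_%03d", seq_len(n))
  rownames(dosage) <- ids
  structure(list(
    config = cfg,
    markers = tibble::tibble(chrom = chrom, pos = pos,
                             ref = rep("A", m), alt = rep("G", m)),
    progeny_dosage = dosage,
    parent_dosage = list(p1 = rep(2L, m), p2 = rep(0L, m)),
    phenotype = tibble::tibble(id = ids, starch = starch),
    qtl_dosage = dosage[, 1],
    truth = list(qtl_chrom = chrom, qtl_pos_bp = pos[1], qtl_effect = 0)
  ), class = "simulated_study")
}
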