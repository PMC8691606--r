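#' Built-in restriction enzyme table
#'
#' A small panel of common 4- and 6-cutters used for CAPS screening:
#' RsaI (GT^AC), HaeIII (GG^CC), EcoRI (G^AATTC), HindIII (A^AGCTT) and
#' TaqI (T^CGA).  `site` is the recognition sequence (IUPAC codes allowed)
#' and `cut_offset` the number of bases from the site's 5' end to the cut.
#' Extend or replace the panel with [read_enzyme_table()].
#'
#' @return A tibble with columns `name`, `site`, `cut_offset`.
#' @examples
#' restriction_enzymes()
#' @export
restriction_enzymes <- function() {
  tibble(
    name = c("RsaI", "HaeIII", "EcoRI", "HindIII", "TaqI"),
    site = c("GTAC", "GGCC", "GAATTC", "AAGCTT", "TCGA"),
    cut_offset = c(2L, 2L, 1L, 1L, 1L)
  )
}

#' Read a restriction enzyme table from TSV
#'
#' @param path TSV with columns `name`, `site`, `cut_offset`.
#' @return A validated enzyme tibble.
#' @export
read_enzyme_table <- function(path) {
  tab <- read.delim(path, stringsAsFactors = FALSE)
  need <- c("name", "site", "cut_offset")
  missing <- setdiff(need, names(tab))
  if (length(missing) > 0L) {
    abort_starchbsa(
      sprintf("enzyme table is missing column(s): %s",
              paste(missing, collapse = ", ")),
      "starchbsa_schema_error"
    )
  }
  for (i in seq_len(nrow(tab))) {
    check_enzyme(tab$site[i], tab$cut_offset[i])
  }
  as_tibble(tab[, need])
}

check_enzyme <- function(site, cut_offset) {
  site <- toupper(site)
  if (nchar(site) < 4L) {
    abort_starchbsa("enzyme recognition sequence must be >= 4 bases",
                    "starchbsa_enzyme_error")
  }
  if (!grepl("^[ACGTRYSWKMBDHVN]+$", site)) {
    abort_starchbsa("enzyme recognition sequence must use IUPAC codes",
                    "starchbsa_enzyme_error")
  }
  if (cut_offset < 0L || cut_offset > nchar(site)) {
    abort_starchbsa("cut offset must lie within the recognition site",
                    "starchbsa_enzyme_error")
  }
  invisible(TRUE)
}

check_sequence <- function(sequence) {
  sequence <- toupper(sequence)
  if (!grepl("^[ACGTN]*$", sequence)) {
    abort_starchbsa("sequence may contain only A, C, G, T or N",
                    "starchbsa_sequence_error")
  }
  sequence
}

#' Find restriction cut positions in a sequence
#'
#' Scans both the given strand and its reverse complement for the enzyme's
#' IUPAC recognition pattern and maps every cut to forward-strand
#' coordinates.  A returned value `p` means the enzyme cuts between bases
#' `p` and `p + 1` (1-based).  `N` in the subject never matches a
#' non-`N` pattern base.  For palindromic recognition sites (always of even
#' length) the reverse strand adds no new site and the double-strand cut is
#' reported at the site centre -- the mean of the two staggered strand cuts,
#' which keeps fragment lengths identical for a sequence and its reverse
#' complement and coincides with the offset rule for centre-cutting enzymes.
#' Cuts at the extreme ends of the sequence (before base 1 or after the
#' last base) produce no fragment boundary and are dropped.
#'
#' @param sequence character scalar over A/C/G/T/N.
#' @param site recognition sequence (IUPAC codes allowed).
#' @param cut_offset bases from the site's 5' end to the cut.
#' @return Sorted integer vector of cut positions.
#' @examples
#' find_sites("AAGTACAA", "GTAC", 2)  # RsaI: one cut between bases 4 and 5
#' @export
find_sites <- function(sequence, site, cut_offset) {
  sequence <- check_sequence(sequence)
  site <- toupper(site)
  check_enzyme(site, cut_offset)
  len <- nchar(site)
  if (nchar(sequence) < len) return(integer(0))

  subj <- Biostrings::DNAString(sequence)
  pat <- Biostrings::DNAString(site)
  # fixed = "subject": IUPAC codes in the pattern are ambiguity sets, while
  # subject letters (incl. N) stay literal, so N never matches A/C/G/T codes
  fwd <- Biostrings::start(
    Biostrings::matchPattern(pat, subj, fixed = "subject")
  )
  rc <- as.character(Biostrings::reverseComplement(pat))
  if (rc == site) {
    # palindrome: both strands cut within the same site; use its centre
    cuts <- fwd + len %/% 2L - 1L
  } else {
    cuts <- fwd + cut_offset - 1L
    rev <- Biostrings::start(
      Biostrings::matchPattern(Biostrings::DNAString(rc), subj,
                               fixed = "subject")
    )
    # site read on the reverse strand: offset counts from its right end
    cuts <- c(cuts, rev + len - cut_offset - 1L)
  }
  cuts <- sort(unique(cuts))
  cuts[cuts >= 1L & cuts <= nchar(sequence) - 1L]
}

#' Digest an amplicon in silico
#'
#' Cuts the sequence at every position reported by [find_sites()] and
#' returns the fragment lengths.  With no recognition site the full-length
#' amplicon is the single fragment (one band on a gel).
#'
#' @inheritParams find_sites
#' @return Sorted integer vector of fragment lengths, summing to
#'   `nchar(sequence)`.
#' @examples
#' digest_fragments("AAGTACAA", "GTAC", 2)  # two 4 bp fragments
#' @export
digest_fragments <- function(sequence, site, cut_offset) {
  sequence <- check_sequence(sequence)
  cuts <- find_sites(sequence, site, cut_offset)
  sort(diff(c(0L, cuts, nchar(sequence))))
}

#' Screen SNPs for CAPS marker candidates
#'
#' For every SNP x enzyme pair, builds the two allele versions of the
#' amplicon spanning `flank` bp either side of the SNP (clipped at the
#' sequence ends), digests both in silico, and keeps the pair as a CAPS
#' candidate when the predicted band counts differ between alleles.  The
#' allele yielding more bands is the "positive" (cut, 2-band) pattern and
#' the other the "negative" (uncut, 1-band) pattern.  Candidates are ranked
#' with single differential cut sites first, then by the length balance of
#' the cut allele's fragments (similar-length fragments separate best on a
#' gel).
#'
#' @param sequence the gene/region sequence (A/C/G/T/N) the SNP positions
#'   refer to.
#' @param snps tibble/data.frame with columns `pos` (1-based within
#'   `sequence`), `ref`, `alt`, and optionally `id`.
#' @param enzymes enzyme tibble (default [restriction_enzymes()]).
#' @param flank bp of flanking sequence either side of the SNP (default 500,
#'   i.e. primer windows ~500 bp above and below the site).
#' @return A tibble of candidates: snp id/pos/ref/alt, enzyme, amplicon
#'   window, per-allele fragment lengths (comma strings) and band counts,
#'   cut allele, and primer window coordinates.
#' @export
scan_caps_candidates <- function(sequence, snps, enzymes = restriction_enzymes(),
                                 flank = 500) {
  sequence <- check_sequence(sequence)
  seq_len_bp <- nchar(sequence)
  if (any(snps$pos < 1 | snps$pos > seq_len_bp)) {
    abort_starchbsa("SNP position outside the supplied sequence",
                    "starchbsa_coordinate_error")
  }
  if (flank < max(nchar(enzymes$site))) {
    abort_starchbsa("flank must be at least the longest recognition site",
                    "starchbsa_domain_error")
  }
  if (!("id" %in% names(snps))) snps$id <- sprintf("snp%02d", seq_len(nrow(snps)))

  out <- list()
  for (i in seq_len(nrow(snps))) {
    pos <- snps$pos[i]
    ref <- toupper(snps$ref[i])
    alt <- toupper(snps$alt[i])
    a_start <- max(1, pos - flank)
    a_end <- min(seq_len_bp, pos + flank)
    amp <- substr(sequence, a_start, a_end)
    at <- pos - a_start + 1L
    if (substr(amp, at, at) != ref) {
      warning(sprintf("sequence base at position %d is not the stated ref allele '%s'",
                      pos, ref))
    }
    amp_ref <- amp
    substr(amp_ref, at, at) <- ref
    amp_alt <- amp
    substr(amp_alt, at, at) <- alt

    for (j in seq_len(nrow(enzymes))) {
      fr_ref <- digest_fragments(amp_ref, enzymes$site[j], enzymes$cut_offset[j])
      fr_alt <- digest_fragments(amp_alt, enzymes$site[j], enzymes$cut_offset[j])
      if (length(fr_ref) == length(fr_alt)) next
      cut_allele <- if (length(fr_ref) > length(fr_alt)) "ref" else "alt"
      fr_cut <- if (cut_allele == "ref") fr_ref else fr_alt
      out[[length(out) + 1L]] <- tibble(
        snp_id = snps$id[i], pos = pos, ref = ref, alt = alt,
        enzyme = enzymes$name[j],
        amplicon_start = a_start, amplicon_end = a_end,
        fragments_ref = paste(fr_ref, collapse = ","),
        fragments_alt = paste(fr_alt, collapse = ","),
        bands_ref = length(fr_ref), bands_alt = length(fr_alt),
        cut_allele = cut_allele,
        single_diff_site = abs(length(fr_ref) - length(fr_alt)) == 1L,
        balance = min(fr_cut) / max(fr_cut)
      )
    }
  }
  if (length(out) == 0L) {
    return(tibble(
      snp_id = character(), pos = numeric(), ref = character(),
      alt = character(), enzyme = character(),
      amplicon_start = numeric(), amplicon_end = numeric(),
      fragments_ref = character(), fragments_alt = character(),
      bands_ref = integer(), bands_alt = integer(), cut_allele = character(),
      single_diff_site = logical(), balance = numeric()
    ))
  }
  res <- dplyr::bind_rows(out)
  res[order(-res$single_diff_site, -res$balance, res$pos, res$enzyme), ]
}

#' Read gene sequences from FASTA
#'
#' Thin wrapper over [Biostrings::readDNAStringSet()] returning plain
#' character sequences named by record id.
#'
#' @param path FASTA file.
#' @return Named character vector of sequences.
#' @export
read_gene_fasta <- function(path) {
  seqs <- Biostrings::readDNAStringSet(path)
  setNames(as.character(seqs), sub("\\s.*$", "", names(seqs)))
}
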