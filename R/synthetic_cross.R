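#' Configuration for a simulated bi-parental cross
#'
#' Bundles and validates all parameters of the synthetic study generator.  The
#' defaults emulate the mapping design the package targets: a cross between a
#' high-starch (~19%) and a low-starch (~13%) tetraploid potato parent, 106
#' progeny, extreme bulks of 20 individuals per tail, and pooled sequencing at
#' a mean depth of 25x per pool -- with inheritance simplified to a diploid
#' pseudo-testcross so that each marker carries a high-allele dosage in
#' \{0, 1, 2\} (see the package vignette for the rationale).
#'
#' @param n_chromosomes number of chromosomes to simulate.
#' @param chrom_length_bp physical length of each chromosome in bp.
#' @param n_snps_per_chrom number of biallelic markers per chromosome.
#' @param qtl_chrom index of the chromosome carrying the planted QTL.
#' @param qtl_pos_bp position (bp) of the planted QTL on `qtl_chrom`.
#' @param qtl_effect additive phenotype shift, in starch percentage points,
#'   per copy of the high allele.
#' @param noise_sd residual (environmental) standard deviation of the starch
#'   phenotype, in percentage points.
#' @param baseline_starch phenotype mean of the zero-dosage class (the
#'   low-parent mean, in starch %).  With the default effect of 3 the
#'   two-dosage class sits at 19%, reproducing the parental contrast.
#' @param n_progeny number of progeny in the mapping population.
#' @param bulk_size number of individuals in each extreme bulk.
#' @param mean_depth mean sequencing depth per pool per SNP (Poisson mean).
#' @param recomb_rate probability of a crossover per bp between adjacent
#'   simulated loci (default 1e-8, i.e. ~1 cM/Mb).
#' @param seed integer seed governing all randomness of the simulation.
#' @return A `sim_config` object (a validated named list).
#' @examples
#' cfg <- sim_config(n_chromosomes = 2, n_snps_per_chrom = 200, seed = 7)
#' @export
sim_config <- function(n_chromosomes = 3,
                       chrom_length_bp = 6e7,
                       n_snps_per_chrom = 2000,
                       qtl_chrom = 1,
                       qtl_pos_bp = 3e7,
                       qtl_effect = 3,
                       noise_sd = 1.5,
                       baseline_starch = 13,
                       n_progeny = 106,
                       bulk_size = 20,
                       mean_depth = 25,
                       recomb_rate = 1e-8,
                       seed = 1) {
  cfg <- list(
    n_chromosomes = as.integer(n_chromosomes),
    chrom_length_bp = as.numeric(chrom_length_bp),
    n_snps_per_chrom = as.integer(n_snps_per_chrom),
    qtl_chrom = as.integer(qtl_chrom),
    qtl_pos_bp = as.numeric(qtl_pos_bp),
    qtl_effect = as.numeric(qtl_effect),
    noise_sd = as.numeric(noise_sd),
    baseline_starch = as.numeric(baseline_starch),
    n_progeny = as.integer(n_progeny),
    bulk_size = as.integer(bulk_size),
    mean_depth = as.numeric(mean_depth),
    recomb_rate = as.numeric(recomb_rate),
    seed = as.integer(seed)
  )
  check <- function(ok, field, what) {
    if (!isTRUE(ok)) {
      abort_starchbsa(
        sprintf("invalid configuration: field '%s' %s", field, what),
        "starchbsa_config_error"
      )
    }
  }
  scalar_ok <- function(x) length(x) == 1L && !is.na(x)
  for (f in names(cfg)) check(scalar_ok(cfg[[f]]), f, "must be a non-missing scalar")
  check(cfg$n_chromosomes > 0L, "n_chromosomes", "must be > 0")
  check(cfg$chrom_length_bp > 0, "chrom_length_bp", "must be > 0")
  check(cfg$n_snps_per_chrom > 0L, "n_snps_per_chrom", "must be > 0")
  check(cfg$qtl_chrom >= 1L && cfg$qtl_chrom <= cfg$n_chromosomes,
        "qtl_chrom", "must index a simulated chromosome")
  check(cfg$qtl_pos_bp >= 0 && cfg$qtl_pos_bp < cfg$chrom_length_bp,
        "qtl_pos_bp", "must lie in [0, chrom_length_bp)")
  check(cfg$qtl_effect >= 0, "qtl_effect", "must be >= 0")
  check(cfg$noise_sd >= 0, "noise_sd", "must be >= 0")
  check(cfg$n_progeny > 0L, "n_progeny", "must be > 0")
  check(cfg$bulk_size > 0L, "bulk_size", "must be > 0")
  check(2L * cfg$bulk_size <= cfg$n_progeny,
        "bulk_size", "must not exceed n_progeny / 2")
  check(cfg$mean_depth >= 1, "mean_depth", "must be >= 1")
  check(cfg$recomb_rate >= 0, "recomb_rate", "must be >= 0")
  structure(cfg, class = "sim_config")
}

#' @export
print.sim_config <- function(x, ...) {
  cat("<sim_config>\n")
  for (f in names(x)) cat(sprintf("  %-18s %s\n", f, format(x[[f]])))
  invisible(x)
}

#' Simulate a bi-parental mapping population with a planted QTL
#'
#' Generates a marker map, founder-phased progeny genotypes and starch
#' phenotypes.  The two founders are fixed for opposite alleles at every
#' marker (the high parent carries the alternate allele); each progeny
#' individual receives two recombinant founder gametes, so marker dosages
#' follow Mendelian F2-style segregation with crossovers placed independently
#' in each marker interval with probability `recomb_rate * gap_bp`.  The
#' phenotype is `baseline_starch + qtl_effect * dosage_at_QTL + N(0, noise_sd)`.
#' The causal locus is simulated as a latent locus at `qtl_pos_bp`; it is part
#' of the recombination map but only appears in the marker table if a marker
#' happens to fall exactly there.
#'
#' @param config a [sim_config()] object.
#' @return A `simulated_study` list with elements `config`, `markers`
#'   (tibble: chrom, pos, ref, alt), `progeny_dosage` (n_progeny x n_markers
#'   integer matrix of high-allele dosages), `parent_dosage` (list with
#'   fixed founder dosages `p1` = 2 and `p2` = 0 per marker), `phenotype`
#'   (tibble: id, starch), `qtl_dosage` (per-individual dosage at the causal
#'   locus) and `truth` (chrom label, position and effect of the planted QTL).
#' @examples
#' study <- simulate_cross(sim_config(n_chromosomes = 1, n_snps_per_chrom = 50,
#'                                    chrom_length_bp = 1e6, qtl_pos_bp = 5e5))
#' head(study$phenotype)
#' @export
simulate_cross <- function(config) {
  if (!inherits(config, "sim_config")) {
    abort_starchbsa("`config` must be a sim_config object", "starchbsa_config_error")
  }
  set.seed(config$seed)
  n <- config$n_progeny
  n2 <- 2L * n
  bases <- c("A", "C", "G", "T")
  chrom_labels <- sprintf("chr%02d", seq_len(config$n_chromosomes))

  marker_tabs <- vector("list", config$n_chromosomes)
  dosage_mats <- vector("list", config$n_chromosomes)
  qtl_dosage <- integer(n)

  for (ci in seq_len(config$n_chromosomes)) {
    pos <- sort(sample.int(config$chrom_length_bp, config$n_snps_per_chrom))
    sim_pos <- pos
    qtl_here <- ci == config$qtl_chrom
    if (qtl_here && !(config$qtl_pos_bp %in% pos)) {
      sim_pos <- sort(c(pos, config$qtl_pos_bp))
    }
    m <- length(sim_pos)

    # gamete haplotypes: 1 = high-founder (alt) allele, 0 = low-founder (ref)
    H <- matrix(0L, nrow = n2, ncol = m)
    h <- rbinom(n2, 1L, 0.5)
    H[, 1L] <- h
    if (m > 1L) {
      p_switch <- pmin(1, config$recomb_rate * diff(sim_pos))
      for (j in seq_len(m - 1L)) {
        h <- (h + rbinom(n2, 1L, p_switch[j])) %% 2L
        H[, j + 1L] <- h
      }
    }
    dos <- H[seq_len(n), , drop = FALSE] + H[n + seq_len(n), , drop = FALSE]

    if (qtl_here) {
      qtl_col <- match(config$qtl_pos_bp, sim_pos)
      qtl_dosage <- dos[, qtl_col]
      if (!(config$qtl_pos_bp %in% pos)) {
        dos <- dos[, -qtl_col, drop = FALSE]
      }
    }

    ref <- sample(bases, length(pos), replace = TRUE)
    alt <- vapply(ref, function(b) sample(setdiff(bases, b), 1L), character(1))
    marker_tabs[[ci]] <- tibble(
      chrom = chrom_labels[ci], pos = pos, ref = ref, alt = unname(alt)
    )
    dosage_mats[[ci]] <- dos
  }

  markers <- dplyr::bind_rows(marker_tabs)
  progeny_dosage <- do.call(cbind, dosage_mats)
  phenotype <- tibble(
    id = sprintf("F_%03d", seq_len(n)),
    starch = config$baseline_starch + config$qtl_effect * qtl_dosage +
      rnorm(n, 0, config$noise_sd)
  )
  rownames(progeny_dosage) <- phenotype$id

  structure(list(
    config = config,
    markers = markers,
    progeny_dosage = progeny_dosage,
    parent_dosage = list(p1 = rep(2L, nrow(markers)), p2 = rep(0L, nrow(markers))),
    phenotype = phenotype,
    qtl_dosage = qtl_dosage,
    truth = list(
      qtl_chrom = chrom_labels[config$qtl_chrom],
      qtl_pos_bp = config$qtl_pos_bp,
      qtl_effect = config$qtl_effect
    )
  ), class = "simulated_study")
}

#' Select the extreme-phenotype bulks
#'
#' Assigns the `bulk_size` highest-starch individuals to the high (H) bulk and
#' the `bulk_size` lowest to the low (L) bulk.  Ties at the phenotype cut are
#' broken by individual id in ascending order, so bulk membership is fully
#' reproducible.
#'
#' @param study a `simulated_study` from [simulate_cross()].
#' @param bulk_size individuals per tail; defaults to the study configuration.
#' @return A `bulk_pair` list with character vectors `high` and `low` of
#'   individual ids (disjoint by construction).
#' @export
sample_bulks <- function(study, bulk_size = study$config$bulk_size) {
  stopifnot(inherits(study, "simulated_study"))
  bulk_size <- as.integer(bulk_size)
  n <- nrow(study$phenotype)
  if (bulk_size < 1L || 2L * bulk_size > n) {
    abort_starchbsa(
      sprintf("bulk_size %d is invalid for %d progeny (need 2 * bulk_size <= n)",
              bulk_size, n),
      "starchbsa_size_error"
    )
  }
  ph <- study$phenotype
  high_order <- order(-ph$starch, ph$id)
  low_order <- order(ph$starch, ph$id)
  structure(list(
    high = ph$id[high_order[seq_len(bulk_size)]],
    low = ph$id[low_order[seq_len(bulk_size)]],
    bulk_size = bulk_size
  ), class = "bulk_pair")
}

#' Simulate pooled sequencing read counts for parents and bulks
#'
#' For every marker and each pool, total depth is drawn as Poisson with mean
#' `mean_depth` and the alternate-read count as Binomial(depth, alt-allele
#' frequency among the pool's chromosomes).  The parents are fixed (high
#' parent all-alternate, low parent all-reference), so their counts are
#' genotype-consistent by construction.
#'
#' @param study a `simulated_study`.
#' @param bulks a `bulk_pair` from [sample_bulks()].
#' @param mean_depth mean reads per pool per SNP; defaults to the study
#'   configuration.
#' @param seed seed for the read-sampling stream.  Defaults to the study seed
#'   plus one, so genotype simulation and read sampling use distinct but
#'   deterministically derived streams.
#' @return A pool-record tibble (see [read_pool_variants()] for the column
#'   layout) with samples P1 (high parent), P2 (low parent), HP and LP.
#' @export
emit_pool_counts <- function(study, bulks,
                             mean_depth = study$config$mean_depth,
                             seed = study$config$seed + 1L) {
  stopifnot(inherits(study, "simulated_study"), inherits(bulks, "bulk_pair"))
  if (length(bulks$high) == 0L || length(bulks$low) == 0L) {
    abort_starchbsa("each bulk must contain at least one individual",
                    "starchbsa_composition_error")
  }
  ids <- study$phenotype$id
  hi <- match(bulks$high, ids)
  lo <- match(bulks$low, ids)
  if (anyNA(hi) || anyNA(lo)) {
    abort_starchbsa("bulk ids not found in study", "starchbsa_composition_error")
  }
  set.seed(as.integer(seed))
  m <- nrow(study$markers)
  freq_h <- colSums(study$progeny_dosage[hi, , drop = FALSE]) / (2 * length(hi))
  freq_l <- colSums(study$progeny_dosage[lo, , drop = FALSE]) / (2 * length(lo))

  dp_p1 <- rpois(m, mean_depth)
  dp_p2 <- rpois(m, mean_depth)
  dp_hp <- rpois(m, mean_depth)
  dp_lp <- rpois(m, mean_depth)
  alt_hp <- rbinom(m, dp_hp, freq_h)
  alt_lp <- rbinom(m, dp_lp, freq_l)

  new_pool_records(
    chrom = study$markers$chrom, pos = study$markers$pos,
    ref = study$markers$ref, alt = study$markers$alt,
    ad = list(
      p1 = paste0(0L, ",", dp_p1),        # high parent fixed for alt
      p2 = paste0(dp_p2, ",", 0L),        # low parent fixed for ref
      hp = paste0(dp_hp - alt_hp, ",", alt_hp),
      lp = paste0(dp_lp - alt_lp, ",", alt_lp)
    )
  )
}
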