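---
title: "Mapping a starch QTL from pooled extreme bulks: methods and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mapping a starch QTL from pooled extreme bulks: methods and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(starchbsa)
```

## The problem

Bulked segregant analysis (BSA) localises a quantitative trait locus (QTL)
by sequencing two DNA pools built from the phenotypic extremes of a
segregating population — here, the starch content of tetraploid potato
tubers in a bi-parental cross (a high-starch female of about 19% crossed
with a low-starch male of about 13%, 106 progeny, 20 individuals per
extreme bulk).  At a marker linked to a starch locus the high and low
pools carry different allele frequencies; away from any locus the pools
are, in expectation, identical.  `starchbsa` implements the complete desk
side of such an experiment: variant filtering, two per-SNP association
statistics, window smoothing with thresholds, candidate-interval calling
and intersection, CAPS marker design, and marker validation — plus a
synthetic-cross generator so the whole pipeline can be exercised and
tested without any sequencing data.

## The synthetic cross

`simulate_cross()` generates the study design the package targets.
Inheritance is simplified to a diploid pseudo-testcross: the two founders
are fixed for opposite alleles at every marker, each progeny receives two
recombinant founder gametes, and the high-allele dosage at any locus is
0, 1 or 2.  The original genome-scale analysis works purely with pooled read
frequencies, and the diploid model reproduces exactly the quantity those
statistics consume — the alternate-allele frequency among the bulk's
chromosomes — so full tetrasomic simulation is deliberately out of scope.

Crossovers are placed independently in each marker interval with
probability `recomb_rate * gap_bp` (no interference).  The default
`recomb_rate = 1e-8` per bp corresponds to about 1 cM/Mb, a typical
plant genome figure, giving the default 60 Mb chromosome a genetic length
of about 0.6 Morgan.

The phenotype is `baseline + qtl_effect * dosage + N(0, noise_sd)` with
defaults `baseline = 13`, `qtl_effect = 3`, `noise_sd = 1.5`: the
zero-dosage class sits at the low parent's 13% and the two-dosage class
at the high parent's 19%, and the effect is twice the residual standard
deviation.  Pooled sequencing is modelled per SNP and pool as
Poisson(`mean_depth`) total reads (default 25x, matching the study's
mean depths of roughly 23–29x) with Binomial(depth, pool allele
frequency) alternate reads.  A single seed governs the whole study;
read sampling uses a sub-stream derived from it (seed + 1), and the
null-envelope simulation described below another (seed + 2), so stages
are reproducible independently.

What the generator does *not* emulate: read-level errors, mapping and
calling artefacts, tetrasomic dosages, segregation distortion, and any
real linkage-disequilibrium structure.  Passing tests therefore
demonstrate the internal consistency and calibration of the analysis
machinery under the stated sampling model, not performance on real
tetraploid data.

## Filtering

`apply_filter_cascade()` applies four stages in a fixed order, each site
counted at its first failing stage so the per-stage counts and survivors
always sum to the input (the accounting is a constructor invariant of
`filter_report()`):

1. multi-allelic sites;
2. sites where any of the four samples (two parents, two bulks) has total
   depth below `min_depth = 4` — the published depth rule does not say
   which sample it applies to, and requiring all four is the strictest
   reading consistent with downstream frequency estimates;
3. bulk-uninformative sites;
4. parent-uninformative sites, read as: the two parents' *supported
   allele sets* (alleles backed by at least `min_allele_reads = 2` reads)
   are identical.

Stage 3 deserves its own paragraph.  A pool is a mixture, so its natural
"genotype" is its supported allele set.  Two readings of "the bulks have
the same genotype" are implemented.  The strict reading
(`pool_rule = "allele_set"`) removes every site with identical supported
sets — including sites where both bulks carry both alleles.  In an
F2-style cross essentially *every* informative marker has both alleles
in both bulks at 25x depth, so the strict rule removes the genome-wide
background wholesale, leaving nothing for the scan thresholds to
calibrate against.  The default (`pool_rule = "fixed"`) therefore removes
a site only when both bulks are fixed for the *same single* allele —
truly monomorphic, uninformative sites — and retains shared-heterozygous
sites, whose frequency contrast is exactly what the downstream statistics
measure.

## The two scan statistics

For each surviving SNP the package computes:

- **ED** — the Euclidean distance between the two bulks' (A, C, G, T)
  read-frequency vectors, in [0, sqrt(2)], raised to a power (default
  `k = 5`, the conventional choice for this statistic; the original method description
  only says the values are multiplied to suppress background).  For a
  biallelic SNP this reduces to `sqrt(2) * |delta|`.
- **SNP-index** per pool — the alternate-read fraction — and
  `delta = index_H - index_L` in [-1, 1], positive when the alternate
  allele is enriched in the high bulk.  The orientation allele is the VCF
  alternate allele; both tails of delta are scanned, so the choice of
  orientation does not affect interval calls.

## Smoothing, thresholds and the null envelope

Both statistics are smoothed per chromosome with SNP-count windows
("SNPNUM" fitting): the fitted value at a SNP is the median (default)
over the `window_snps` SNPs centred on it, truncated at chromosome ends,
missing values skipped.  The window is 101 SNPs by default — the original
analysis does not state its window, and 101 SNPs spans about 3 Mb at the
default marker density, wide enough to suppress single-SNP noise and
narrow enough not to blur a several-Mb QTL peak.  The signed delta is
smoothed and its absolute fitted value thresholded, so read noise cancels
around zero instead of folding.

The ED threshold is `median + 3 SD` of all fitted values genome-wide
(population SD; the divisor is not specified in the original analysis and the
choice is recorded in the run report).

The delta threshold is `max(quantile(fitted |delta|, q), floor)`.  Two
points matter here:

- **The quantile.**  A 99th-percentile rule flags the top 1% of SNPs by
  construction.  That is adequate when the signal occupies far less than
  1% of the genome (the original analysis scanned ~977k SNPs across a
  ~840 Mb genome), but on a compact simulated genome of three
  chromosomes a linked region can span more than 10% of all SNPs, and a
  99th percentile then sits *inside* the peak and truncates the call to
  its summit.  The pipeline therefore defaults to `delta_q = 0.90`,
  which tracks the background level, while `delta_threshold()` itself
  keeps 0.99 as its default and the genome-scale combination
  (`delta_q = 0.99`, `delta_floor = 0.05`) remains available in the
  configuration.
- **The floor.**  Window smoothing removes independent read noise but
  not bulk-composition drift: with 20 individuals (40 chromosomes) per
  pool, each pool's allele frequency wanders around its expectation with
  variance `p(1-p)/40`, and the wander is correlated along the
  chromosome (gamete-path covariance `exp(-2d)` at genetic distance `d`
  Morgans).  Since intervals are called wherever the *maximum* of the
  fitted field crosses the threshold, the correct null calibration is on
  the distribution of that genome-wide maximum.
  `delta_drift_envelope()` simulates the null drift field as an AR(1)
  process on the actual marker map, adds read noise, applies the same
  window smoothing, and returns the 99% quantile of the genome-wide
  maximum of |fitted delta| — the confidence-envelope logic of QTL-seq
  style analyses.  With the default design this envelope is around 0.6,
  roughly twice the pointwise three-sigma value (`delta_null_floor()`),
  which is exactly why a pointwise floor under-controls a genome scan.

Candidate intervals are maximal runs of SNPs with fitted values at or
above threshold, snapped outward to a 10 kb coordinate grid (matching
the granularity of the published interval table), merged when closer
than 100 kb, and reported 0-based half-open with sizes in Mb rounded
half-up to two decimals.  The final candidate region is the intersection
of the ED and delta interval sets.

## CAPS marker design

`scan_caps_candidates()` turns candidate SNPs into cleaved amplified
polymorphic sequence (CAPS) markers: for each SNP and enzyme it builds
the two allele versions of an amplicon spanning 500 bp either side of
the SNP (the primer-window convention of the original protocol), digests
both in silico, and keeps enzymes whose band counts differ between
alleles — the allele that is cut gives the 2-band "positive" pattern,
the uncut one the 1-band "negative" pattern.  Recognition sites are
IUPAC patterns matched on both strands; subject `N` never matches.  For
palindromic sites (always even-length) the double-strand cut is reported
at the site centre — the mean of the two staggered strand cuts — which
makes fragment lengths identical for a sequence and its reverse
complement and coincides with the offset rule for centre-cutting
enzymes; for non-palindromic sites the top-strand offset is used in each
orientation, which is strand-symmetric by construction.  Melting
temperature, dimer and specificity checks are out of scope.  The
built-in enzyme panel (RsaI, HaeIII, EcoRI, HindIII, TaqI) is a starting
set, extensible via TSV.

## Marker validation

`classify_phenotype()` applies the published starch cutoffs (high >= 18%,
low <= 15%, medium otherwise).  `concordance()` scores a marker against
classes exactly as in the published validation tables: negatives
(1 band) are expected high-starch, positives (2 bands) low-starch;
per-class and overall agreement are reported as percentages rounded
half-up to two decimals (the table convention).  Medium individuals are
excluded by default, as only the extremes were scored.
`marker_trait_correlation()` reports the Pearson correlation between
starch content and the binary marker code (negative = 1, so positive `r`
means the uncut pattern tracks high starch); the published per-individual
starch values are not available, so correlation values are demonstrated
on synthetic panels only.

## Numerical and degenerate-input conventions

- Quantiles use linear interpolation between order statistics (R type 7).
- Percentages are rounded half away from zero to two decimals.
- Bulk ties at the phenotype cut are broken by ascending individual id.
- Zero-depth pools give missing statistics, skipped by the window fit;
  tracks with fewer than two finite fitted values yield no threshold and
  hence no intervals.
- Missing per-sample depth strings are parsed as zero depth and flagged,
  so they fail the depth stage.
- Filtering an empty table returns an all-zero report.

## Problem sizes used in the test-suite

The acceptance-scale synthetic runs use the study design itself — three
chromosomes of 60 Mb with 2,000 SNPs each, 106 progeny, 20 + 20 bulks,
25x pools, effect twice the residual SD — repeated over 50 seeds for
recovery and 50 for null specificity.  Unit tests use smaller genomes;
where a compact genome is needed with realistic threshold behaviour, the
test configuration uses a denser genetic map (`recomb_rate = 1e-7`) so
the linked region remains a small fraction of the genome, mirroring the
geometry of the full-scale design.

## Known limitations

- Tetrasomic inheritance, preferential pairing and double reduction are
  not modelled; dosages are diploid.
- The ED power `k`, window width, and the parent/bulk genotype-set rules
  are conventions where the original description is silent or ambiguous; all are
  configuration parameters echoed in the run report.
- The drift envelope assumes the worst-case allele frequency (0.5),
  Haldane-style crossover independence and a user-supplied cM/Mb figure;
  for real data the latter is an assumption, as it is in any QTL-seq
  style confidence interval.
- Gene annotation within candidate intervals is out of scope.
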