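Package: starchbsa
Title: Bulked Segregant Analysis of Pooled Sequencing Data with CAPS Marker Design
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for mapping quantitative trait loci from pooled sequencing
    of extreme-phenotype bulks (bulked segregant analysis, BSA). Reads a
    four-sample variant table (two parents and a high/low bulk pair), applies a
    staged high-quality SNP filter with full per-stage accounting, computes the
    per-SNP Euclidean-distance (ED) statistic between bulk base-frequency
    vectors and the per-pool SNP-index with its high-minus-low difference,
    smooths both statistics along chromosomes with SNP-count windows, derives
    association thresholds (median + 3 SD for ED, an upper quantile for the
    SNP-index difference), extracts and intersects candidate intervals, designs
    cleaved amplified polymorphic sequence (CAPS) markers by differential
    in-silico restriction digestion of the two SNP alleles, and scores
    marker-phenotype concordance in validation panels. A synthetic bi-parental
    cross simulator with a planted quantitative trait locus, extreme-tail
    bulking and binomial pooled read sampling provides fully reproducible test
    data, so no sequencing download is required.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Biostrings,
    GenomicRanges,
    IRanges,
    dplyr,
    ggplot2,
    jsonlite,
    rlang,
    stats,
    tibble,
    utils,
    vcfR,
    yaml,
    zoo
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
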