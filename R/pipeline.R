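#' Pipeline configuration
#'
#' One flat configuration governing every stage of the BSA pipeline:
#' simulation (see [sim_config()]), filtering, statistics, scan smoothing
#' and interval calling.  Every analysis default mirrors a conventional
#' choice of the underlying method (depth cutoff 4x, ED power 5, SNP-count
#' window 101, 10 kb coordinate grid, 100 kb merge gap) and is echoed in
#' the run report.  The delta scan defaults to quantile 0.90 with the
#' simulated genome-wide bulk-drift envelope (`delta_floor = "auto"`, see
#' [delta_drift_envelope()]): on a compact simulated genome a QTL-linked
#' region can span well over 1% of all SNPs, so a 99th-percentile threshold
#' would sit inside the signal; the quantile tracks the background level
#' and the envelope carries the null calibration.  Set `delta_q = 0.99` and
#' `delta_floor = 0.05` to mimic the genome-scale settings of the original
#' analysis.
#'
#' @param ... overrides for any simulation or analysis parameter.
#' @return A `bsa_config` list with `sim` (a [sim_config()]) and analysis
#'   fields.
#' @examples
#' cfg <- bsa_config(n_snps_per_chrom = 500, window_snps = 51)
#' @export
bsa_config <- function(...) {
  over <- list(...)
  analysis_defaults <- list(
    min_depth = 4, min_allele_reads = 2, pool_rule = "fixed",
    ed_power = 5, window_snps = 101, window_stat = "median",
    delta_q = 0.90, delta_floor = "auto",
    grid_bp = 1e4, merge_gap = 1e5,
    flank = 500, high_cutoff = 18, low_cutoff = 15
  )
  sim_names <- names(formals(sim_config))
  bad <- setdiff(names(over), c(sim_names, names(analysis_defaults)))
  if (length(bad) > 0L) {
    abort_starchbsa(
      sprintf("unknown configuration field(s): %s", paste(bad, collapse = ", ")),
      "starchbsa_config_error"
    )
  }
  analysis <- utils::modifyList(analysis_defaults,
                                over[intersect(names(over), names(analysis_defaults))])
  sim <- do.call(sim_config, over[intersect(names(over), sim_names)])
  structure(c(list(sim = sim), analysis), class = "bsa_config")
}

#' Read a pipeline configuration from a YAML file
#'
#' The file holds a flat mapping whose keys mirror the [bsa_config()] and
#' [sim_config()] field names.
#'
#' @param path YAML file.
#' @return A `bsa_config`.
#' @export
read_bsa_config <- function(path) {
  if (!file.exists(path)) {
    abort_starchbsa(sprintf("config file not found: %s", path),
                    "starchbsa_io_error")
  }
  vals <- yaml::read_yaml(path)
  if (is.null(vals)) vals <- list()
  do.call(bsa_config, vals)
}

#' Null calibration of the fitted delta(SNP-index)
#'
#' The smoothing window removes independent read-sampling noise but not the
#' locally correlated allele-frequency drift that comes from bulking a
#' finite number of individuals: with `bulk_size` individuals (2 x
#' `bulk_size` chromosomes) per pool, the drift of each pool frequency
#' around its expectation has variance p(1-p) / (2 bulk_size), the
#' high-minus-low difference twice that, and the drift is correlated along
#' the chromosome with the gamete-path covariance exp(-2 d) at genetic
#' distance d (Morgans).
#'
#' `delta_null_floor()` is the pointwise three-sigma envelope at the worst
#' case p = 0.5 -- the smallest |fitted delta| at a *given* locus not
#' explained by bulk composition alone.  Because candidate intervals are
#' called wherever the *genome-wide maximum* of the fitted field crosses
#' the threshold, the operative calibration must be on the distribution of
#' that maximum: `delta_drift_envelope()` simulates the null drift field as
#' an AR(1) process on the observed marker map (plus independent read
#' noise), applies the same SNP-count window smoothing, and returns the
#' `1 - alpha` quantile of the genome-wide maximum of |fitted delta| --
#' the confidence-interval logic of QTL-seq style analyses, conditioned on
#' bulk size, depth, marker spacing and recombination rate.
#'
#' @param bulk_size individuals per bulk.
#' @param n_sigma pointwise envelope width (default 3, matching the ED
#'   rule's 3 SD).
#' @return The floor / envelope value.
#' @examples
#' delta_null_floor(20)
#' @export
delta_null_floor <- function(bulk_size, n_sigma = 3) {
  n_sigma * sqrt(2 * 0.25 / (2 * bulk_size))
}

#' @rdname delta_null_floor
#' @param chrom,pos marker map the scan runs on.
#' @param mean_depth mean read depth per pool.
#' @param window_snps smoothing window (SNP count) used by the scan.
#' @param recomb_rate assumed recombination rate per bp (Morgans/bp).
#' @param alpha genome-wide false-positive level (default 0.01, i.e. a 99%
#'   confidence envelope).
#' @param n_rep Monte-Carlo replicates of the null field.
#' @param seed seed for the envelope simulation (restores the caller's RNG
#'   state afterwards).
#' @param p allele frequency at which drift variance is evaluated (worst
#'   case 0.5).
#' @export
delta_drift_envelope <- function(chrom, pos, bulk_size, mean_depth,
                                 window_snps = 101, recomb_rate = 1e-8,
                                 alpha = 0.01, n_rep = 200, seed = 1,
                                 p = 0.5) {
  ord <- order(chrom, pos)
  groups <- split(pos[ord], chrom[ord])
  sigma_pool <- sqrt(p * (1 - p) / (2 * bulk_size))
  sigma_read <- sqrt(2 * p * (1 - p) / max(mean_depth, 1))
  window_snps <- as.integer(window_snps)
  if (window_snps %% 2L == 0L) window_snps <- window_snps + 1L

  old_seed <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv()))
  set.seed(as.integer(seed))

  maxes <- numeric(n_rep)
  for (g in groups) {
    m <- length(g)
    phi <- exp(-2 * recomb_rate * diff(g))
    innov_sd <- sqrt(1 - phi^2)
    # drift fields for both pools, vectorised across replicates
    field <- function() {
      x <- matrix(0, nrow = m, ncol = n_rep)
      x[1, ] <- rnorm(n_rep)
      for (j in seq_len(m - 1L)) {
        x[j + 1L, ] <- phi[j] * x[j, ] + innov_sd[j] * rnorm(n_rep)
      }
      x * sigma_pool
    }
    delta <- field() - field() +
      matrix(rnorm(m * n_rep, 0, sigma_read), nrow = m)
    k <- min(window_snps, if (m %% 2L == 1L) m else m - 1L)
    sm <- if (k >= 3L) {
      apply(delta, 2, stats::runmed, k = k, endrule = "median")
    } else delta
    maxes <- pmax(maxes, apply(abs(sm), 2, max))
  }
  unname(quantile(maxes, 1 - alpha, type = 7))
}

#' Smooth, threshold and call candidate intervals for both scan statistics
#'
#' Runs the shared scan stage: SNP-count window fit of the powered ED track
#' and of the signed delta(SNP-index) track, genome-wide thresholds
#' (median + 3 SD for ED; upper quantile with floor for |fitted delta|),
#' interval calling for each method, and their intersection.  If a track
#' has fewer than two finite fitted values (e.g. after aggressive filtering
#' of a null data set) its threshold is undefined and no intervals are
#' called for that method.
#'
#' @param stats output of [compute_bsa_stats()].
#' @param window_snps,window_stat window fit parameters.
#' @param delta_q,delta_floor delta-threshold parameters; `delta_floor =
#'   "auto"` uses the pointwise [delta_null_floor()] for the supplied
#'   `bulk_size` ([run_bsa_pipeline()] instead computes the genome-wide
#'   [delta_drift_envelope()], which also needs depth and the marker map).
#' @param grid_bp,merge_gap interval-calling parameters.
#' @param bulk_size bulk size used for the automatic floor.
#' @return A list with `track` (the fitted track), `ed_threshold`,
#'   `delta_threshold`, `ed_intervals`, `delta_intervals`, `intersection`.
#' @export
run_bsa_scan <- function(stats, window_snps = 101, window_stat = "median",
                         delta_q = 0.90, delta_floor = "auto",
                         grid_bp = 1e4, merge_gap = 1e5, bulk_size = 20) {
  track <- fit_scan_track(stats, "ed_powered", window_snps, window_stat)
  track <- fit_scan_track(track, "delta", window_snps, window_stat)
  track$delta_abs_fitted <- abs(track$delta_fitted)
  if (identical(delta_floor, "auto")) delta_floor <- delta_null_floor(bulk_size)

  thr <- function(expr) tryCatch(expr, starchbsa_threshold_error = function(e) NA_real_)
  ed_thr <- thr(ed_threshold(track$ed_powered_fitted))
  d_thr <- thr(delta_threshold(track$delta_abs_fitted, q = delta_q,
                               floor = delta_floor))

  call_or_empty <- function(threshold, col) {
    if (!is.finite(threshold)) return(new_intervals())
    call_intervals(track, threshold, fitted_col = col,
                   grid_bp = grid_bp, merge_gap = merge_gap)
  }
  ed_iv <- call_or_empty(ed_thr, "ed_powered_fitted")
  d_iv <- call_or_empty(d_thr, "delta_abs_fitted")
  list(
    track = track,
    ed_threshold = ed_thr, delta_threshold = d_thr,
    ed_intervals = ed_iv, delta_intervals = d_iv,
    intersection = intersect_intervals(ed_iv, d_iv)
  )
}

#' Run the full BSA pipeline on a synthetic cross
#'
#' Orchestrates simulate -> bulk -> pool counts -> filter -> statistics ->
#' scan -> intersect, and returns a consolidated run report.  With an
#' `out_dir`, the stage outputs are also written to disk (pool VCF, stats
#' TSV, per-method interval BED/TSV, and the report as JSON).
#'
#' @param config a [bsa_config()].
#' @param out_dir optional output directory.
#' @return A `bsa_run_report` list: configuration echo, filter report,
#'   thresholds, interval tables, intersection, the simulation truth and the
#'   package version.
#' @examples
#' \donttest{
#' rep <- run_bsa_pipeline(bsa_config(n_chromosomes = 3, n_snps_per_chrom = 300,
#'                                    chrom_length_bp = 3e7, qtl_pos_bp = 1.5e7,
#'                                    recomb_rate = 1e-7, window_snps = 31,
#'                                    seed = 42))
#' rep$intersection
#' }
#' @export
run_bsa_pipeline <- function(config = bsa_config(), out_dir = NULL) {
  if (!inherits(config, "bsa_config")) {
    abort_starchbsa("`config` must be a bsa_config object", "starchbsa_config_error")
  }
  study <- simulate_cross(config$sim)
  bulks <- sample_bulks(study)
  counts <- emit_pool_counts(study, bulks)
  filtered <- apply_filter_cascade(counts,
                                   min_depth = config$min_depth,
                                   min_allele_reads = config$min_allele_reads,
                                   pool_rule = config$pool_rule)
  stats <- compute_bsa_stats(filtered$records, power = config$ed_power)
  floor <- config$delta_floor
  if (identical(floor, "auto") && nrow(stats) > 1L) {
    floor <- delta_drift_envelope(
      stats$chrom, stats$pos,
      bulk_size = config$sim$bulk_size,
      mean_depth = config$sim$mean_depth,
      window_snps = config$window_snps,
      recomb_rate = config$sim$recomb_rate,
      seed = config$sim$seed + 2L
    )
  }
  scan <- run_bsa_scan(stats,
                       window_snps = config$window_snps,
                       window_stat = config$window_stat,
                       delta_q = config$delta_q, delta_floor = floor,
                       grid_bp = config$grid_bp, merge_gap = config$merge_gap,
                       bulk_size = config$sim$bulk_size)

  report <- structure(list(
    config = config,
    filter_report = filtered$report,
    ed_threshold = scan$ed_threshold,
    delta_threshold = scan$delta_threshold,
    ed_intervals = scan$ed_intervals,
    delta_intervals = scan$delta_intervals,
    intersection = scan$intersection,
    truth = study$truth,
    seed = config$sim$seed,
    version = as.character(utils::packageVersion("starchbsa"))
  ), class = "bsa_run_report")

  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    write_pool_vcf(counts, file.path(out_dir, "pool_counts.vcf"))
    write_stats_tsv(scan$track, file.path(out_dir, "scan_track.tsv"))
    write_intervals_bed(scan$ed_intervals, file.path(out_dir, "ed_intervals.bed"))
    write_intervals_bed(scan$delta_intervals, file.path(out_dir, "delta_intervals.bed"))
    write_intervals_bed(scan$intersection, file.path(out_dir, "intersection.bed"))
    write.table(scan$intersection[, c("chrom", "start", "end", "size_mb")],
                file.path(out_dir, "intersection.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
    jsonlite::write_json(report_to_list(report),
                         file.path(out_dir, "run_report.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  report
}

report_to_list <- function(report) {
  list(
    config = c(unclass(report$config$sim),
               unclass(report$config)[setdiff(names(report$config), "sim")]),
    filter_report = unclass(report$filter_report),
    ed_threshold = report$ed_threshold,
    delta_threshold = report$delta_threshold,
    ed_intervals = as.data.frame(report$ed_intervals),
    delta_intervals = as.data.frame(report$delta_intervals),
    intersection = as.data.frame(report$intersection),
    truth = report$truth,
    seed = report$seed,
    version = report$version
  )
}

#' @export
print.bsa_run_report <- function(x, ...) {
  cat("<bsa_run_report>\n")
  cat(sprintf("  seed %d, starchbsa %s\n", x$seed, x$version))
  print(x$filter_report)
  cat(sprintf("  ED threshold:    %s\n", format(x$ed_threshold, digits = 4)))
  cat(sprintf("  delta threshold: %s\n", format(x$delta_threshold, digits = 4)))
  cat(sprintf("  ED intervals: %d, delta intervals: %d, intersection: %d\n",
              nrow(x$ed_intervals), nrow(x$delta_intervals),
              nrow(x$intersection)))
  if (nrow(x$intersection) > 0L) {
    print(as.data.frame(x$intersection[, c("chrom", "start", "end", "size_mb")]))
  }
  cat(sprintf("  planted QTL: %s @ %s bp (effect %.2f)\n",
              x$truth$qtl_chrom,
              format(x$truth$qtl_pos_bp, scientific = FALSE),
              x$truth$qtl_effect))
  invisible(x)
}

#' Does an interval set cover a position?
#'
#' @param intervals an interval tibble (0-based half-open).
#' @param chrom,pos the queried locus.
#' @return TRUE if any interval on `chrom` contains `pos`.
#' @export
intervals_contain <- function(intervals, chrom, pos) {
  any(intervals$chrom == chrom & intervals$start <= pos & pos < intervals$end)
}
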