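#' SNP-count window fit of a scan statistic
#'
#' Smooths a per-SNP statistic along one chromosome with windows defined by a
#' fixed number of SNPs ("SNPNUM" fitting) rather than a fixed bp span: the
#' fitted value at SNP i is the window statistic (median by default) of the
#' `window_snps` SNPs centred on i.  At the chromosome ends the window is
#' truncated to the available neighbours; missing raw values are skipped
#' within each window.
#'
#' @param x numeric vector of raw statistic values, ordered by position
#'   within one chromosome.
#' @param window_snps window width in SNPs; even values are bumped up to the
#'   next odd number so the window is centred.
#' @param stat window statistic, `"median"` (default) or `"mean"`.
#' @return Numeric vector of fitted values, same length as `x`; `NA` where a
#'   window contains no finite value.
#' @examples
#' fit_snpnum_window(c(0, 1, 10, 1, 0), window_snps = 3)
#' @export
fit_snpnum_window <- function(x, window_snps = 101, stat = c("median", "mean")) {
  stat <- match.arg(stat)
  n <- length(x)
  if (n == 0L) return(numeric(0))
  window_snps <- as.integer(window_snps)
  if (window_snps < 1L) {
    abort_starchbsa("window_snps must be >= 1", "starchbsa_domain_error")
  }
  if (window_snps %% 2L == 0L) window_snps <- window_snps + 1L
  fun <- if (stat == "median") median else mean
  wfun <- function(z) {
    z <- z[is.finite(z)]
    if (length(z) == 0L) NA_real_ else fun(z)
  }
  zoo::rollapply(x, width = window_snps, FUN = wfun, partial = TRUE,
                 align = "center")
}

#' Fit a whole-genome scan track per chromosome
#'
#' Applies [fit_snpnum_window()] chromosome by chromosome to one statistic
#' column of a track table.
#'
#' @param track a tibble with at least `chrom`, `pos` and the value column;
#'   must be sorted by position within each chromosome.
#' @param value_col name of the raw statistic column.
#' @param window_snps,stat passed to [fit_snpnum_window()].
#' @return `track` with a `<value_col>_fitted` column appended.
#' @export
fit_scan_track <- function(track, value_col, window_snps = 101,
                           stat = c("median", "mean")) {
  stat <- match.arg(stat)
  track <- track[order(track$chrom, track$pos), ]
  fitted <- numeric(nrow(track))
  for (idx in split(seq_len(nrow(track)), track$chrom)) {
    fitted[idx] <- fit_snpnum_window(track[[value_col]][idx],
                                     window_snps = window_snps, stat = stat)
  }
  track[[paste0(value_col, "_fitted")]] <- fitted
  track
}

#' Association threshold for the fitted ED scan
#'
#' `median + 3 * SD` of all finite fitted values genome-wide, using the
#' population standard deviation (divisor n).
#'
#' @param fitted numeric vector of fitted values across all chromosomes.
#' @return The threshold (scalar).
#' @examples
#' ed_threshold(c(0, 0, 0, 0, 1))  # median 0, population SD 0.4 -> 1.2
#' @export
ed_threshold <- function(fitted) {
  v <- fitted[is.finite(fitted)]
  if (length(v) < 2L) {
    abort_starchbsa("need at least two finite fitted values for a threshold",
                    "starchbsa_threshold_error")
  }
  median(v) + 3 * pop_sd(v)
}

#' Quantile threshold for the fitted |delta(SNP-index)| scan
#'
#' The empirical `q`-quantile (linear interpolation between order statistics,
#' R's default type 7) of the fitted absolute delta values, with an optional
#' lower `floor`.  The floor mirrors manually lowering the scan threshold to
#' a fixed value such as 0.05 when the quantile is judged too permissive or
#' too strict.
#'
#' @param fitted numeric vector of fitted `|delta|` values.
#' @param q quantile level (default 0.99).
#' @param floor lower bound for the returned threshold (default 0).
#' @return The threshold (scalar): `max(quantile(fitted, q), floor)`.
#' @export
delta_threshold <- function(fitted, q = 0.99, floor = 0) {
  if (q <= 0 || q >= 1) {
    abort_starchbsa("quantile level q must be in (0, 1)", "starchbsa_domain_error")
  }
  v <- fitted[is.finite(fitted)]
  if (length(v) < 2L) {
    abort_starchbsa("need at least two finite fitted values for a threshold",
                    "starchbsa_threshold_error")
  }
  max(unname(quantile(v, q, type = 7)), floor)
}

new_intervals <- function(chrom = character(), start = numeric(),
                          end = numeric(), peak = numeric(),
                          n_snps = integer()) {
  tibble(
    chrom = chrom, start = start, end = end,
    size_mb = round_half_up((end - start) / 1e6, 2),
    peak = peak, n_snps = n_snps
  )
}

#' Extract candidate intervals from a fitted scan
#'
#' Maximal runs of consecutive SNPs whose fitted value meets the threshold
#' become candidate intervals.  Interval coordinates are reported 0-based
#' half-open and snapped to a coordinate grid (default 10 kb): the first SNP
#' of a run is snapped down to the start of its containing bin and the last
#' SNP up to the end of its bin.  Intervals on the same chromosome separated
#' by less than `merge_gap` bp are merged.
#'
#' @param track tibble with `chrom`, `pos` and a fitted-value column.
#' @param threshold scalar threshold; SNPs with fitted >= threshold are in.
#' @param fitted_col name of the fitted column (default `"fitted"`).
#' @param grid_bp snapping grid in bp (default 1e4).
#' @param merge_gap merge intervals closer than this many bp (default 1e5).
#' @return An interval tibble: `chrom`, `start`, `end` (0-based half-open),
#'   `size_mb` (2 decimals), `peak` (max fitted inside), `n_snps`.
#' @export
call_intervals <- function(track, threshold, fitted_col = "fitted",
                           grid_bp = 1e4, merge_gap = 1e5) {
  if (!is.finite(threshold)) {
    abort_starchbsa("threshold must be finite", "starchbsa_threshold_error")
  }
  track <- track[order(track$chrom, track$pos), ]
  val <- track[[fitted_col]]
  above <- is.finite(val) & val >= threshold
  if (!any(above)) return(new_intervals())

  pieces <- lapply(split(seq_len(nrow(track)), track$chrom), function(idx) {
    a <- above[idx]
    if (!any(a)) return(NULL)
    r <- rle(a)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    runs <- which(r$values)
    pos <- track$pos[idx]
    tibble(
      chrom = track$chrom[idx][1],
      start = floor(pos[starts[runs]] / grid_bp) * grid_bp,
      end = floor(pos[ends[runs]] / grid_bp) * grid_bp + grid_bp
    )
  })
  raw <- dplyr::bind_rows(pieces)

  gr <- GenomicRanges::GRanges(raw$chrom,
                               IRanges::IRanges(raw$start + 1, raw$end))
  merged <- GenomicRanges::reduce(gr, min.gapwidth = merge_gap)
  merged <- sort(merged)
  out_chrom <- as.character(GenomicRanges::seqnames(merged))
  out_start <- GenomicRanges::start(merged) - 1
  out_end <- GenomicRanges::end(merged)

  peak <- numeric(length(merged))
  nsnp <- integer(length(merged))
  for (i in seq_along(merged)) {
    inside <- track$chrom == out_chrom[i] &
      track$pos >= out_start[i] & track$pos < out_end[i] & is.finite(val)
    peak[i] <- if (any(inside)) max(val[inside]) else NA_real_
    nsnp[i] <- sum(inside & above)
  }
  new_intervals(out_chrom, out_start, out_end, peak, nsnp)
}

#' Intersect two sets of candidate intervals
#'
#' Same-chromosome pairwise overlaps `[max(starts), min(ends))`; empty
#' overlaps are dropped and the result is sorted by chromosome and start.
#' Used to combine the ED and delta(SNP-index) candidate regions into the
#' final candidate region.
#'
#' @param set_a,set_b interval tibbles (`chrom`, `start`, `end`, 0-based
#'   half-open), e.g. from [call_intervals()] or [genomic_intervals()].
#' @return An interval tibble of the overlaps, with `size_mb`.
#' @examples
#' ed <- genomic_intervals("Chr02", 0, 5620000)
#' si <- genomic_intervals("Chr02", 0, 6370000)
#' intersect_intervals(ed, si)
#' @export
intersect_intervals <- function(set_a, set_b) {
  if (nrow(set_a) == 0L || nrow(set_b) == 0L) return(new_intervals())
  to_gr <- function(x) {
    GenomicRanges::GRanges(x$chrom, IRanges::IRanges(x$start + 1, x$end))
  }
  ga <- to_gr(set_a)
  gb <- to_gr(set_b)
  suppressWarnings({
    ov <- GenomicRanges::intersect(ga, gb, ignore.strand = TRUE)
  })
  ov <- sort(ov)
  if (length(ov) == 0L) return(new_intervals())
  new_intervals(
    chrom = as.character(GenomicRanges::seqnames(ov)),
    start = GenomicRanges::start(ov) - 1,
    end = GenomicRanges::end(ov),
    peak = rep(NA_real_, length(ov)),
    n_snps = rep(NA_integer_, length(ov))
  )
}

#' Build an interval table from coordinates
#'
#' Convenience constructor for candidate-region tables in 0-based half-open
#' coordinates (the BED convention), e.g. to enter published interval tables.
#'
#' @param chrom,start,end vectors of chromosome labels and 0-based half-open
#'   coordinates.
#' @return An interval tibble with `size_mb` computed.
#' @export
genomic_intervals <- function(chrom, start, end) {
  if (any(start < 0) || any(end <= start)) {
    abort_starchbsa("need 0 <= start < end for every interval",
                    "starchbsa_domain_error")
  }
  new_intervals(as.character(chrom), as.numeric(start), as.numeric(end),
                peak = rep(NA_real_, length(chrom)),
                n_snps = rep(NA_integer_, length(chrom)))
}

#' Write intervals as BED
#'
#' @param intervals an interval tibble.
#' @param path output path.
#' @return The path, invisibly.
#' @export
write_intervals_bed <- function(intervals, path) {
  bed <- data.frame(
    chrom = intervals$chrom,
    start = format(intervals$start, scientific = FALSE, trim = TRUE),
    end = format(intervals$end, scientific = FALSE, trim = TRUE)
  )
  write.table(bed, path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Plot a fitted genome scan
#'
#' Raw per-SNP values as points, the window fit as a line and the association
#' threshold as a dashed horizontal line, one panel per chromosome.
#'
#' @param track tibble with `chrom`, `pos`, a raw value column and a fitted
#'   column.
#' @param value_col,fitted_col column names of the raw and fitted statistic.
#' @param threshold scalar threshold drawn as a dashed line (optional).
#' @return A ggplot object.
#' @export
plot_scan_track <- function(track, value_col, fitted_col, threshold = NULL) {
  p <- ggplot2::ggplot(track, ggplot2::aes(x = .data$pos / 1e6)) +
    ggplot2::geom_point(ggplot2::aes(y = .data[[value_col]]),
                        size = 0.3, alpha = 0.4, colour = "steelblue") +
    ggplot2::geom_line(ggplot2::aes(y = .data[[fitted_col]]), colour = "black") +
    ggplot2::facet_wrap(~chrom, nrow = 1, scales = "free_x") +
    ggplot2::labs(x = "position (Mb)", y = value_col) +
    ggplot2::theme_minimal()
  if (!is.null(threshold) && is.finite(threshold)) {
    p <- p + ggplot2::geom_hline(yintercept = threshold,
                                 linetype = "dashed", colour = "red")
  }
  p
}
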