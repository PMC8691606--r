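#' Classify starch phenotypes into high / medium / low
#'
#' Applies the fixed starch-content cutoffs used when scoring validation
#' panels: high if starch >= `high_cutoff` (default 18%), low if
#' starch <= `low_cutoff` (default 15%), medium otherwise.
#'
#' @param starch numeric vector of starch contents (percent).
#' @param high_cutoff,low_cutoff class boundaries in starch %.
#' @return Character vector in `c("high", "medium", "low")`.
#' @examples
#' classify_phenotype(c(18.34, 14.71, 16.5))
#' @export
classify_phenotype <- function(starch, high_cutoff = 18, low_cutoff = 15) {
  if (any(!is.finite(starch)) || any(starch < 0)) {
    abort_starchbsa("starch content must be finite and non-negative",
                    "starchbsa_domain_error")
  }
  ifelse(starch >= high_cutoff, "high",
         ifelse(starch <= low_cutoff, "low", "medium"))
}

#' Marker-phenotype concordance
#'
#' Scores a CAPS marker against phenotype classes exactly as in a validation
#' contingency table.  The expected pattern is: negative (1-band, uncut)
#' individuals are high starch; positive (2-band, cut) individuals are low
#' starch.  Per-class agreement is the percentage of negatives that are high
#' and of positives that are low; overall agreement is the percentage of all
#' scored individuals whose call matches their class.  Percentages are
#' rounded half-up to two decimals.
#'
#' @param calls tibble/data.frame with columns `id` and `call`
#'   (`"positive"`/`"negative"`, or the band synonyms `"2band"`/`"1band"`).
#' @param classes tibble/data.frame with columns `id` and `class`
#'   (`"high"`/`"medium"`/`"low"`), e.g. from [classify_phenotype()].
#' @param exclude_medium drop medium-class individuals before scoring
#'   (default TRUE: validation panels score only the extremes).
#' @return A `concordance_result` list: counts per call x class, per-class
#'   agreement percentages, overall agreement, and `n_scored`.
#' @examples
#' calls <- data.frame(id = 1:4, call = c("negative", "negative", "positive", "positive"))
#' classes <- data.frame(id = 1:4, class = c("high", "high", "low", "low"))
#' concordance(calls, classes)
#' @export
concordance <- function(calls, classes, exclude_medium = TRUE) {
  calls <- as_tibble(calls)
  classes <- as_tibble(classes)
  calls$call <- c("1band" = "negative", "2band" = "positive",
                  "negative" = "negative", "positive" = "positive")[calls$call]
  if (anyNA(calls$call)) {
    abort_starchbsa("marker calls must be 'positive'/'negative' (or '2band'/'1band')",
                    "starchbsa_domain_error")
  }
  unmatched <- union(setdiff(calls$id, classes$id), setdiff(classes$id, calls$id))
  if (length(unmatched) > 0L) {
    abort_starchbsa(
      sprintf("ids do not match between calls and classes: %s",
              paste(unmatched, collapse = ", ")),
      "starchbsa_join_error"
    )
  }
  d <- dplyr::left_join(calls, classes, by = "id")
  if (exclude_medium) d <- d[d$class != "medium", ]

  n_pos <- sum(d$call == "positive")
  n_neg <- sum(d$call == "negative")
  pos_high <- sum(d$call == "positive" & d$class == "high")
  pos_low <- sum(d$call == "positive" & d$class == "low")
  neg_high <- sum(d$call == "negative" & d$class == "high")
  neg_low <- sum(d$call == "negative" & d$class == "low")
  n_scored <- nrow(d)

  pct <- function(num, den) {
    if (den == 0L) NA_real_ else round_half_up(100 * num / den, 2)
  }
  structure(list(
    n_positive = n_pos, n_negative = n_neg, n_scored = n_scored,
    positive_high = pos_high, positive_low = pos_low,
    negative_high = neg_high, negative_low = neg_low,
    pct_positive = pct(pos_low, n_pos),   # positives expected low starch
    pct_negative = pct(neg_high, n_neg),  # negatives expected high starch
    pct_overall = pct(neg_high + pos_low, n_scored)
  ), class = "concordance_result")
}

#' @export
print.concordance_result <- function(x, ...) {
  cat("<concordance_result>\n")
  cat(sprintf("  positive (2-band): %d  [high %d / low %d]  agreement %.2f%%\n",
              x$n_positive, x$positive_high, x$positive_low, x$pct_positive))
  cat(sprintf("  negative (1-band): %d  [high %d / low %d]  agreement %.2f%%\n",
              x$n_negative, x$negative_high, x$negative_low, x$pct_negative))
  cat(sprintf("  overall: %d scored, agreement %.2f%%\n",
              x$n_scored, x$pct_overall))
  invisible(x)
}

#' Correlation between starch content and marker call
#'
#' Pearson correlation between the continuous starch phenotype and the
#' binary marker code (negative/1-band = 1, positive/2-band = 0, so a
#' positive r means the uncut pattern tracks high starch), with the
#' two-sided t-test significance.
#'
#' @param calls tibble with `id`, `call` (as in [concordance()]).
#' @param phenotypes tibble with `id`, `starch`.
#' @return A list with `r`, `p_value` and `n`.
#' @export
marker_trait_correlation <- function(calls, phenotypes) {
  calls <- as_tibble(calls)
  phenotypes <- as_tibble(phenotypes)
  calls$call <- c("1band" = "negative", "2band" = "positive",
                  "negative" = "negative", "positive" = "positive")[calls$call]
  d <- dplyr::inner_join(calls, phenotypes, by = "id")
  if (nrow(d) < 3L) {
    abort_starchbsa("need at least 3 matched individuals", "starchbsa_domain_error")
  }
  code <- as.numeric(d$call == "negative")
  if (length(unique(code)) < 2L || length(unique(d$starch)) < 2L) {
    abort_starchbsa("correlation undefined: constant marker code or phenotype",
                    "starchbsa_domain_error")
  }
  ct <- stats::cor.test(d$starch, code, method = "pearson")
  list(r = unname(ct$estimate), p_value = ct$p.value, n = nrow(d))
}

#' Expand a validation contingency table into individual records
#'
#' Utility to rebuild per-individual call and class tables from published
#' count summaries (number of high/low individuals among positives and
#' negatives), so the same [concordance()] code path scores both raw data
#' and printed tables.
#'
#' @param positive_high,positive_low,negative_high,negative_low counts.
#' @return A list with `calls` and `classes` tibbles sharing generated ids.
#' @export
expand_contingency <- function(positive_high, positive_low,
                               negative_high, negative_low) {
  n <- positive_high + positive_low + negative_high + negative_low
  id <- sprintf("ind%03d", seq_len(n))
  call <- rep(c("positive", "positive", "negative", "negative"),
              c(positive_high, positive_low, negative_high, negative_low))
  class <- rep(c("high", "low", "high", "low"),
               c(positive_high, positive_low, negative_high, negative_low))
  list(calls = tibble(id = id, call = call),
       classes = tibble(id = id, class = class))
}
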