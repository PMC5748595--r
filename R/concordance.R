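# Paired fresh-frozen / FFPE comparison: quality exclusions, borderline
# filtering of FFPE scores, switch counting and agreement.

#' Exclude low-quality pairs before concordance analysis
#'
#' Drops pairs whose FFPE sample fails either quality criterion, tallied by
#' reason. Tumor percentage is checked first, so a sample failing both
#' criteria is counted once, under low tumor percentage. When a cutoff is
#' active (positive) the corresponding annotation must be present for every
#' pair — gating quality on an unknown quantity is an error, not a pass.
#'
#' @param pairs data frame with at least `sample_id`, `ff_score`,
#'   `ffpe_score` (one row per paired tumor).
#' @param ann annotation table carrying `tumor_pct` and `signal_intensity`
#'   for every paired sample.
#' @param min_tumor_pct minimum percent tumor cells (pairs strictly below
#'   are excluded).
#' @param min_signal minimum array signal intensity (pairs strictly below
#'   are excluded).
#' @return list: `kept` (the surviving pairs), `excluded` (data frame
#'   `sample_id`, `reason`), `n_excluded_low_tumor`,
#'   `n_excluded_low_signal`.
#' @export
apply_exclusions <- function(pairs, ann, min_tumor_pct = 30, min_signal = 0) {
  if (!is.data.frame(pairs) ||
      !all(c("sample_id", "ff_score", "ffpe_score") %in% names(pairs)))
    stop("pairs must be a data frame with sample_id, ff_score, ffpe_score")
  ann <- validate_annotations(ann)
  idx <- match(pairs$sample_id, ann$sample_id)
  if (anyNA(idx))
    stop("no annotation for sample(s): ",
         paste(pairs$sample_id[is.na(idx)], collapse = ", "))
  tumor <- ann$tumor_pct[idx]
  signal <- ann$signal_intensity[idx]
  if (min_tumor_pct > 0 && anyNA(tumor))
    stop("tumor_pct missing for sample(s): ",
         paste(pairs$sample_id[is.na(tumor)], collapse = ", "))
  if (min_signal > 0 && anyNA(signal))
    stop("signal_intensity missing for sample(s): ",
         paste(pairs$sample_id[is.na(signal)], collapse = ", "))
  low_tumor <- min_tumor_pct > 0 & tumor < min_tumor_pct
  low_signal <- !low_tumor & min_signal > 0 & signal < min_signal
  reason <- rep(NA_character_, nrow(pairs))
  reason[low_signal] <- "low_signal"
  reason[low_tumor] <- "low_tumor_pct"
  drop <- !is.na(reason)
  list(kept = pairs[!drop, , drop = FALSE],
       excluded = data.frame(sample_id = pairs$sample_id[drop],
                             reason = reason[drop],
                             stringsAsFactors = FALSE),
       n_excluded_low_tumor = sum(low_tumor, na.rm = TRUE),
       n_excluded_low_signal = sum(low_signal, na.rm = TRUE))
}

#' Paired fresh-frozen / FFPE concordance report
#'
#' Calls each pair on both channels (strict-greater rule, channel-specific
#' thresholds), flags pairs whose FFPE score falls inside the borderline
#' region (inclusive of the region edges; the region applies to the FFPE
#' score only), and counts outcome switches among the pairs outside the
#' region. Agreement is `1 - n_switched / n_outside_borderline`. The
#' Pearson correlation of the paired scores is computed over all kept
#' pairs, before borderline filtering.
#'
#' @param pairs data frame with `sample_id`, `ff_score`, `ffpe_score`
#'   (post-exclusion).
#' @param ff_threshold threshold for the fresh-frozen scores.
#' @param ffpe_threshold threshold for the FFPE scores.
#' @param region [borderline_region()] for the FFPE scores.
#' @return object of class `concordance_report`: counts, `agreement`,
#'   `pearson_r`, `agreement_defined`, plus the per-pair table `pairs`
#'   (with `ff_call`, `ffpe_call`, `in_borderline`, `switched`).
#' @export
concordance_report <- function(pairs, ff_threshold, ffpe_threshold, region) {
  if (!is.data.frame(pairs) ||
      !all(c("sample_id", "ff_score", "ffpe_score") %in% names(pairs)))
    stop("pairs must be a data frame with sample_id, ff_score, ffpe_score")
  if (!inherits(region, "borderline_region"))
    stop("region must come from borderline_region()")
  if (nrow(pairs) < 2L) stop("need at least 2 pairs")
  pairs$ff_call <- classify_scores(pairs$ff_score, ff_threshold)
  pairs$ffpe_call <- classify_scores(pairs$ffpe_score, ffpe_threshold)
  pairs$in_borderline <- pairs$ffpe_score >= region$low &
    pairs$ffpe_score <= region$high
  pairs$switched <- !pairs$in_borderline & pairs$ff_call != pairs$ffpe_call
  outside <- sum(!pairs$in_borderline)
  switched <- sum(pairs$switched)
  defined <- outside >= 2L
  if (!defined)
    warning("fewer than 2 pairs outside the borderline region; ",
            "agreement undefined")
  structure(list(n_pairs = nrow(pairs),
                 n_outside_borderline = outside,
                 n_switched = switched,
                 agreement = if (defined) 1 - switched / outside else NA_real_,
                 agreement_defined = defined,
                 pearson_r = stats::cor(pairs$ff_score, pairs$ffpe_score),
                 pairs = pairs),
            class = "concordance_report")
}

#' @export
print.concordance_report <- function(x, ...) {
  cat(sprintf("Paired FF/FFPE concordance: %d pairs, r = %.2f\n",
              x$n_pairs, x$pearson_r))
  cat(sprintf("  outside borderline: %d; switched: %d; agreement: %s\n",
              x$n_outside_borderline, x$n_switched,
              if (x$agreement_defined)
                sprintf("%.1f%%", 100 * x$agreement) else "undefined"))
  invisible(x)
}
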