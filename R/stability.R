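# Assay stability QC. The signature score range is estimated symmetrically
# from the largest absolute cohort score,
#
#     range = [-max(|scores|), +max(|scores|)],
#
# and a technical control passes if the standard deviation of its replicate
# scores does not exceed 10% of that range width. The borderline region
# around the classification threshold is threshold +/- 1.96 * SD, with SD
# the larger (conservative) of the control SDs.

#' Estimate the signature score range
#'
#' Symmetric about zero by construction: the range is
#' `[-max(|scores|), +max(|scores|)]` with width `2 * max(|scores|)`,
#' regardless of the sign of any individual score. A range estimated from a
#' cohort smaller than `n_reference` samples is flagged conservative — the
#' true score range of the population is expected to be wider.
#'
#' @param scores numeric vector of cohort signature scores (at least one,
#'   all finite).
#' @param n_reference cohort size below which the estimate is flagged
#'   conservative (default 302).
#' @return object of class `score_range`: `range_low`, `range_high`,
#'   `range_width`, `n`, `conservative`.
#' @export
estimate_range <- function(scores, n_reference = 302L) {
  if (length(scores) < 1L) stop("need at least one score")
  if (!all(is.finite(scores))) stop("scores must be finite")
  m <- max(abs(scores))
  structure(list(range_low = -m, range_high = m, range_width = 2 * m,
                 n = length(scores),
                 conservative = length(scores) < n_reference),
            class = "score_range")
}

#' @export
print.score_range <- function(x, ...) {
  cat(sprintf("Signature score range: (%.3f, %.3f), width %.3f (n = %d%s)\n",
              x$range_low, x$range_high, x$range_width, x$n,
              if (x$conservative) ", conservative estimate" else ""))
  invisible(x)
}

#' Assess a technical control against the SD/range criterion
#'
#' Computes the sample (n-1) standard deviation of the control's replicate
#' scores and divides it by the cohort score-range width. The predefined
#' acceptance criterion is SD/range not exceeding 10%. Each replicate is
#' also classified (strict-greater rule) and checked against the control's
#' known class.
#'
#' @param scores numeric vector of replicate signature scores (>= 2).
#' @param range_width positive width of the cohort score range, from
#'   [estimate_range()].
#' @param true_class the control's known class, `"mutation_like"` or
#'   `"wildtype_like"`.
#' @param threshold classification threshold.
#' @param control_id identifier carried into the report.
#' @param max_sd_over_range acceptance cutoff (default 0.10).
#' @return object of class `stability_report`: `control_id`, `n_reps`,
#'   `sd`, `sd_over_range`, `passed`, `all_calls_consistent`, `calls`.
#' @export
assess_control <- function(scores, range_width, true_class, threshold,
                           control_id = "control", max_sd_over_range = 0.10) {
  if (length(scores) < 2L) stop("need at least 2 replicate scores")
  if (!all(is.finite(scores))) stop("replicate scores must be finite")
  if (!is.numeric(range_width) || range_width <= 0)
    stop("range_width must be positive")
  if (!true_class %in% c("mutation_like", "wildtype_like"))
    stop("true_class must be 'mutation_like' or 'wildtype_like'")
  sd_rep <- stats::sd(scores)
  calls <- classify_scores(scores, threshold)
  structure(list(control_id = control_id, n_reps = length(scores),
                 sd = sd_rep, sd_over_range = sd_rep / range_width,
                 passed = sd_rep / range_width <= max_sd_over_range,
                 all_calls_consistent = all(calls == true_class),
                 calls = calls),
            class = "stability_report")
}

#' @export
print.stability_report <- function(x, ...) {
  cat(sprintf(
    "Control '%s': %d replicates, SD = %.3f, SD/range = %.1f%% -> %s; calls %s\n",
    x$control_id, x$n_reps, x$sd, 100 * x$sd_over_range,
    if (x$passed) "PASS" else "FAIL",
    if (x$all_calls_consistent) "all consistent" else "INCONSISTENT"))
  invisible(x)
}

#' Borderline region around the classification threshold
#'
#' `threshold +/- 1.96 * SD`, where SD is taken conservatively as the
#' largest of the supplied control standard deviations. Scores inside this
#' region are considered too close to the threshold for a reliable call.
#'
#' @param threshold classification threshold.
#' @param sds numeric vector of control replicate SDs (>= 1 value, all
#'   non-negative).
#' @return object of class `borderline_region`: `threshold`, `sd`, `low`,
#'   `high`.
#' @export
borderline_region <- function(threshold, sds) {
  if (length(sds) < 1L) stop("need at least one control SD")
  if (any(!is.finite(sds)) || any(sds < 0))
    stop("control SDs must be finite and non-negative")
  sd_use <- max(sds)
  structure(list(threshold = threshold, sd = sd_use,
                 low = threshold - 1.96 * sd_use,
                 high = threshold + 1.96 * sd_use),
            class = "borderline_region")
}

#' @export
print.borderline_region <- function(x, ...) {
  cat(sprintf(
    "Borderline region: threshold %.3f +/- 1.96 x %.3f = (%.3f, %.3f)\n",
    x$threshold, x$sd, x$low, x$high))
  invisible(x)
}
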