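# Performance estimation: leave-one-out cross-validation, threshold
# selection at optimal overall accuracy, confusion metrics against the
# sequenced BRAF status, and the enrichment accounting for pre-screened
# cohorts.

#' Leave-one-out cross-validated signature scores
#'
#' For each sample, the two centroid templates are rebuilt on all the other
#' samples and the left-out sample is scored against them. Deterministic;
#' no randomness is involved. Both classes must keep at least two samples
#' in every fold, hence at least three samples per class overall.
#'
#' @param m signature-aligned expression matrix (signature genes x samples).
#' @param labels `"mutated"` / `"wildtype"` per column of `m`.
#' @param metric similarity metric, `"pearson"` (default) or `"cosine"`.
#' @return named numeric vector of per-sample LOOCV scores, in column order.
#' @export
loocv_scores <- function(m, labels, metric = c("pearson", "cosine")) {
  metric <- match.arg(metric)
  validate_expression_matrix(m)
  if (length(labels) != ncol(m))
    stop("labels must have one entry per sample")
  bad <- setdiff(unique(labels), c("mutated", "wildtype"))
  if (length(bad))
    stop("labels must be 'mutated' or 'wildtype'; found: ",
         paste(bad, collapse = ", "))
  is_mut <- labels == "mutated"
  n_mut <- sum(is_mut); n_wt <- sum(!is_mut)
  if (n_mut < 3L || n_wt < 3L)
    stop("each class needs at least 3 samples for LOOCV (mutated: ",
         n_mut, ", wildtype: ", n_wt, ")")
  sum_mut <- rowSums(m[, is_mut, drop = FALSE])
  sum_wt <- rowSums(m[, !is_mut, drop = FALSE])
  scores <- vapply(seq_len(ncol(m)), function(i) {
    x <- m[, i]
    if (is_mut[i]) {
      tm <- (sum_mut - x) / (n_mut - 1L); tw <- sum_wt / n_wt
    } else {
      tm <- sum_mut / n_mut; tw <- (sum_wt - x) / (n_wt - 1L)
    }
    tryCatch(.score_one(x, tm, tw, metric),
             error = function(e) stop("sample '", colnames(m)[i], "': ",
                                      conditionMessage(e), call. = FALSE))
  }, numeric(1))
  stats::setNames(scores, colnames(m))
}

#' Threshold at optimal overall accuracy
#'
#' Scans candidate thresholds — the midpoints of adjacent distinct sorted
#' scores, plus one sentinel below the minimum and one above the maximum —
#' and returns the candidate maximizing overall accuracy under the
#' strict-greater calling rule (score > threshold is mutation-like). Among
#' accuracy ties the lowest threshold is returned, making the search fully
#' deterministic.
#'
#' @param scores numeric signature scores.
#' @param labels `"mutated"` / `"wildtype"` per score.
#' @return the selected threshold.
#' @export
optimize_threshold <- function(scores, labels) {
  if (length(scores) != length(labels)) stop("scores/labels length mismatch")
  bad <- setdiff(unique(labels), c("mutated", "wildtype"))
  if (length(bad))
    stop("labels must be 'mutated' or 'wildtype'; found: ",
         paste(bad, collapse = ", "))
  if (!any(labels == "mutated") || !any(labels == "wildtype"))
    stop("need at least one sample per class")
  if (!all(is.finite(scores))) stop("scores must be finite")
  s <- sort(unique(scores))
  cand <- c(s[1L] - 1,
            if (length(s) > 1L) (s[-1L] + s[-length(s)]) / 2,
            s[length(s)] + 1)
  truth <- labels == "mutated"
  acc <- vapply(cand, function(th) mean((scores > th) == truth), numeric(1))
  cand[which.max(acc)]  # candidates ascend, so ties resolve to the lowest
}

#' Confusion metrics against sequenced BRAF status
#'
#' Tallies calls (`mutation_like` / `wildtype_like`) against sequenced
#' labels (`mutated` / `wildtype`): a mutation-like call on a sequenced
#' mutant is a true positive. Note that with a pre-screen-enriched cohort
#' the "false positives" include wild-type tumors that genuinely belong to
#' the mutation-like expression subtype; see [expected_specificity()] for
#' the corresponding accounting.
#'
#' @param calls character vector of class calls.
#' @param labels character vector of sequenced statuses, same length.
#' @return object of class `confusion_summary`: counts `tp`, `fp`, `fn`,
#'   `tn` and rates `sensitivity`, `specificity`, `accuracy`,
#'   `fraction_called_positive`.
#' @export
confusion_metrics <- function(calls, labels) {
  if (length(calls) != length(labels)) stop("calls/labels length mismatch")
  bad_c <- setdiff(unique(calls), c("mutation_like", "wildtype_like"))
  if (length(bad_c))
    stop("calls must be 'mutation_like' or 'wildtype_like'; found: ",
         paste(bad_c, collapse = ", "))
  bad_l <- setdiff(unique(labels), c("mutated", "wildtype"))
  if (length(bad_l))
    stop("labels must be 'mutated' or 'wildtype'; found: ",
         paste(bad_l, collapse = ", "))
  pos <- calls == "mutation_like"
  mut <- labels == "mutated"
  tp <- sum(pos & mut); fp <- sum(pos & !mut)
  fn <- sum(!pos & mut); tn <- sum(!pos & !mut)
  n <- tp + fp + fn + tn
  structure(list(tp = tp, fp = fp, fn = fn, tn = tn, n = n,
                 sensitivity = tp / (tp + fn),
                 specificity = tn / (tn + fp),
                 accuracy = (tp + tn) / n,
                 fraction_called_positive = (tp + fp) / n),
            class = "confusion_summary")
}

#' @export
print.confusion_summary <- function(x, ...) {
  cat("Confusion vs sequenced BRAF status (n = ", x$n, ")\n",
      "                 mutated  wildtype\n",
      sprintf("  mutation-like  %7d  %8d\n", x$tp, x$fp),
      sprintf("  wildtype-like  %7d  %8d\n", x$fn, x$tn),
      sprintf("  sensitivity %.1f%%, specificity %.1f%%, accuracy %.1f%%, called mutation-like %.1f%%\n",
              100 * x$sensitivity, 100 * x$specificity, 100 * x$accuracy,
              100 * x$fraction_called_positive),
      sep = "")
  invisible(x)
}

#' Expected specificity under pre-screen enrichment
#'
#' Pre-screening by signature score enriches a sequencing cohort not only
#' for BRAF mutants but equally for wild-type tumors of the mutation-like
#' expression subtype. Assuming the enriched wild-type mutation-like
#' prevalence matches the enriched mutant count, the specificity one should
#' expect to observe is `1 - n_mut / n_wt`.
#'
#' @param n_mut number of sequenced mutants in the cohort.
#' @param n_wt number of sequenced wild-type samples (> 0).
#' @return expected specificity as a fraction in [0, 1].
#' @examples
#' expected_specificity(57, 245)  # 0.767
#' @export
expected_specificity <- function(n_mut, n_wt) {
  stopifnot(n_mut >= 0)
  if (n_wt <= 0) stop("n_wt must be positive")
  1 - n_mut / n_wt
}

#' Pre-screen selection: top-ranked plus a random complement
#'
#' Reproduces the enrichment design used to assemble a sequencing cohort:
#' the `k_top` highest-scoring samples are taken, then `k_random` further
#' samples are drawn uniformly without replacement from the remainder.
#'
#' @param scores named numeric vector of signature scores for the candidate
#'   pool (names are sample ids).
#' @param k_top number of top-ranked samples to take.
#' @param k_random number of random additional samples.
#' @param seed integer seed for the random draw.
#' @return character vector of selected sample ids: the top block (in
#'   descending score order) followed by the random block.
#' @export
prescreen_select <- function(scores, k_top, k_random, seed = 1L) {
  if (is.null(names(scores))) stop("scores must be named by sample id")
  if (!all(is.finite(scores))) stop("scores must be finite")
  n <- length(scores)
  if (k_top < 0L || k_random < 0L || k_top + k_random > n)
    stop("k_top + k_random (", k_top + k_random,
         ") exceeds pool size (", n, ")")
  ord <- order(scores, decreasing = TRUE)
  top <- names(scores)[ord[seq_len(k_top)]]
  rest <- names(scores)[ord[-seq_len(k_top)]]
  rnd <- if (k_random > 0L)
    withr::with_seed(seed, sample(rest, k_random)) else character(0)
  c(top, rnd)
}

#' Mutation prevalence by cohort block
#'
#' Tallies sequenced-mutant counts and fractions within each `cohort_tag`
#' block of an annotation table, plus an overall row — the bookkeeping
#' behind statements like "35.4% of the pre-screened block and 11.2% of the
#' random block carried the mutation (18.9% overall)".
#'
#' @param ann annotation data frame (see [validate_annotations()]).
#' @return data frame with columns `cohort_tag`, `n`, `n_mutated`,
#'   `frac_mutated`; last row `cohort_tag == "all"`.
#' @export
cohort_composition <- function(ann) {
  ann <- validate_annotations(ann)
  tally <- function(sub, tag) {
    data.frame(cohort_tag = tag, n = nrow(sub),
               n_mutated = sum(sub$braf_status == "mutated"),
               frac_mutated = mean(sub$braf_status == "mutated"),
               stringsAsFactors = FALSE)
  }
  blocks <- lapply(split(ann, ann$cohort_tag), function(sub)
    tally(sub, sub$cohort_tag[1L]))
  out <- do.call(rbind, c(blocks, list(tally(ann, "all"))))
  rownames(out) <- NULL
  out
}
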