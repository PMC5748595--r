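# Centroid templates and the correlation-difference signature score.
#
# A sample is scored against two class templates (per-gene mean profiles of
# the BRAF-mutated and BRAF-wild-type training samples) as
#
#     score = cor(x, mut_template) - cor(x, wt_template)
#
# with Pearson correlation by default (cosine similarity available as an
# alternative metric). The score lies in [-2, 2]; large positive values mean
# the profile resembles the mutated centroid. A sample is called
# mutation-like iff its score is STRICTLY greater than the threshold.

.metric_choices <- c("pearson", "cosine")

.similarity <- function(x, y, metric) {
  if (metric == "pearson") {
    if (stats::sd(x) == 0) stop("zero-variance profile: correlation undefined")
    if (stats::sd(y) == 0) stop("zero-variance template: correlation undefined")
    stats::cor(x, y)
  } else {
    nx <- sqrt(sum(x^2)); ny <- sqrt(sum(y^2))
    if (nx == 0 || ny == 0) stop("zero-norm profile or template: cosine undefined")
    sum(x * y) / (nx * ny)
  }
}

.score_one <- function(x, mut_template, wt_template, metric) {
  .similarity(x, mut_template, metric) - .similarity(x, wt_template, metric)
}

#' Build the two class-centroid templates
#'
#' Each template is the unweighted per-gene arithmetic mean of the log2
#' expression of its class's training samples. No gene standardization or
#' class weighting is applied; class imbalance (e.g. 57 mutated vs 245
#' wild-type) is deliberately left as-is.
#'
#' @param m signature-aligned expression matrix (signature genes x samples).
#' @param labels character vector, one of `"mutated"` / `"wildtype"` per
#'   column of `m`. Unknown labels among training samples are an error.
#' @return an object of class `signature_templates`: list with `gene_ids`,
#'   `mut_template`, `wt_template`, `n_mut`, `n_wt`.
#' @export
build_templates <- function(m, labels) {
  validate_expression_matrix(m)
  if (length(labels) != ncol(m))
    stop("labels must have one entry per sample (", ncol(m), ")")
  bad <- setdiff(unique(labels), c("mutated", "wildtype"))
  if (length(bad))
    stop("training labels must be 'mutated' or 'wildtype'; found: ",
         paste(bad, collapse = ", "))
  is_mut <- labels == "mutated"
  for (cls in c(mutated = TRUE, wildtype = FALSE)) {
    n_cls <- sum(is_mut == cls)
    if (n_cls < 2L)
      stop("class '", if (cls) "mutated" else "wildtype",
           "' has ", n_cls, " sample(s); need at least 2")
  }
  tm <- rowMeans(m[, is_mut, drop = FALSE])
  tw <- rowMeans(m[, !is_mut, drop = FALSE])
  if (isTRUE(all.equal(tm, tw)))
    stop("mutated and wild-type templates are identical; classes are indistinguishable")
  structure(list(gene_ids = rownames(m), mut_template = tm, wt_template = tw,
                 n_mut = sum(is_mut), n_wt = sum(!is_mut)),
            class = "signature_templates")
}

#' @export
print.signature_templates <- function(x, ...) {
  cat("Signature centroid templates\n",
      "  genes: ", length(x$gene_ids), "\n",
      "  training samples: ", x$n_mut, " mutated, ", x$n_wt, " wild-type\n",
      sep = "")
  invisible(x)
}

#' Score one expression profile against a template pair
#'
#' Returns `cor(x, mut_template) - cor(x, wt_template)`; bounded in
#' [-2, 2]. Under Pearson correlation the score is invariant to positive
#' affine transforms of `x` and antisymmetric in the two templates.
#'
#' @param x numeric expression vector over the signature genes, in template
#'   gene order.
#' @param templates a `signature_templates` object from [build_templates()].
#' @param metric `"pearson"` (default) or `"cosine"`.
#' @return the signature score, a single number in [-2, 2].
#' @export
score_sample <- function(x, templates, metric = c("pearson", "cosine")) {
  metric <- match.arg(metric)
  if (!inherits(templates, "signature_templates"))
    stop("templates must come from build_templates()")
  if (length(x) != length(templates$gene_ids))
    stop("profile length ", length(x), " does not match template length ",
         length(templates$gene_ids))
  if (!all(is.finite(x))) stop("profile contains non-finite values")
  .score_one(x, templates$mut_template, templates$wt_template, metric)
}

#' Classify signature scores against a threshold
#'
#' Strict-inequality rule: a score greater than the threshold is
#' `mutation_like`, a score less than or equal to it is `wildtype_like`.
#'
#' @param scores numeric vector of signature scores.
#' @param threshold classification threshold.
#' @return character vector of calls.
#' @export
classify_scores <- function(scores, threshold) {
  ifelse(scores > threshold, "mutation_like", "wildtype_like")
}

#' Score every sample of a cohort
#'
#' @param m signature-aligned expression matrix whose rows match the
#'   template gene order exactly.
#' @inheritParams score_sample
#' @param threshold classification threshold (strict-greater rule).
#' @return data frame with columns `sample_id`, `score`, `call`.
#' @export
score_cohort <- function(m, templates, threshold,
                         metric = c("pearson", "cosine")) {
  metric <- match.arg(metric)
  validate_expression_matrix(m)
  if (!identical(rownames(m), templates$gene_ids))
    stop("matrix rows are not aligned to the template gene order; ",
         "run align_to_signature() first")
  scores <- vapply(seq_len(ncol(m)), function(j) {
    tryCatch(score_sample(m[, j], templates, metric = metric),
             error = function(e) stop("sample '", colnames(m)[j], "': ",
                                      conditionMessage(e), call. = FALSE))
  }, numeric(1))
  data.frame(sample_id = colnames(m), score = scores,
             call = classify_scores(scores, threshold),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Read / write a template pair as a three-column table
#'
#' Columns: `gene_id`, `mut_template`, `wt_template`.
#'
#' @inheritParams read_matrix
#' @export
read_templates <- function(path, dialect = c("tsv", "csv")) {
  dialect <- match.arg(dialect)
  df <- utils::read.table(path, header = TRUE, sep = .sep_for(dialect),
                          quote = "", stringsAsFactors = FALSE)
  need <- c("gene_id", "mut_template", "wt_template")
  if (!all(need %in% names(df)))
    stop("template file must have columns ", paste(need, collapse = ", "))
  structure(list(gene_ids = df$gene_id,
                 mut_template = stats::setNames(df$mut_template, df$gene_id),
                 wt_template = stats::setNames(df$wt_template, df$gene_id),
                 n_mut = NA_integer_, n_wt = NA_integer_),
            class = "signature_templates")
}

#' @rdname read_templates
#' @param templates a `signature_templates` object.
#' @export
write_templates <- function(templates, path, dialect = c("tsv", "csv")) {
  dialect <- match.arg(dialect)
  df <- data.frame(gene_id = templates$gene_ids,
                   mut_template = as.numeric(templates$mut_template),
                   wt_template = as.numeric(templates$wt_template))
  utils::write.table(df, path, sep = .sep_for(dialect), quote = FALSE,
                     row.names = FALSE, eol = "\n")
  invisible(path)
}
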