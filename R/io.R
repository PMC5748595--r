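# I/O and validation for expression matrices, signature gene lists and
# sample annotation tables. Matrices are genes-as-rows, samples-as-columns
# (microarray convention); values are assumed log2-transformed and already
# normalized. Missing values are rejected outright: the downstream scoring
# never imputes, so a hole in the matrix is treated as a data defect.

.sep_for <- function(dialect) if (dialect == "tsv") "\t" else ","

#' Validate an expression matrix
#'
#' Checks the invariants every expression matrix in this package must hold:
#' a numeric matrix with at least one gene (row) and one sample (column),
#' unique non-empty gene and sample identifiers in the dimnames, and all
#' values finite (no `NA`, `NaN` or infinities).
#'
#' @param m numeric matrix, genes as rows, samples as columns, with
#'   `rownames(m)` the gene identifiers and `colnames(m)` the sample
#'   identifiers.
#' @return `m`, invisibly, if valid; otherwise an error naming the first
#'   offending identifier or cell.
#' @export
validate_expression_matrix <- function(m) {
  if (!is.matrix(m) || !is.numeric(m))
    stop("expression data must be a numeric matrix")
  if (nrow(m) < 1L || ncol(m) < 1L)
    stop("expression matrix must have at least one gene and one sample")
  if (is.null(rownames(m)) || is.null(colnames(m)))
    stop("expression matrix must carry gene (row) and sample (column) names")
  if (any(rownames(m) == "") || any(colnames(m) == ""))
    stop("empty gene or sample identifier")
  dup_g <- unique(rownames(m)[duplicated(rownames(m))])
  if (length(dup_g))
    stop("duplicated gene identifier(s): ", paste(dup_g, collapse = ", "))
  dup_s <- unique(colnames(m)[duplicated(colnames(m))])
  if (length(dup_s))
    stop("duplicated sample identifier(s): ", paste(dup_s, collapse = ", "))
  bad <- which(!is.finite(m), arr.ind = TRUE)
  if (nrow(bad))
    stop("non-finite value at gene '", rownames(m)[bad[1L, 1L]],
         "', sample '", colnames(m)[bad[1L, 2L]], "'")
  invisible(m)
}

#' Read a gene-expression matrix from a delimited text file
#'
#' The file layout is the usual microarray export: a header row of sample
#' identifiers, a first column of gene identifiers, and numeric log2
#' expression values in the body. Row and column order are preserved.
#'
#' @param path path to the file.
#' @param dialect `"tsv"` (default) or `"csv"`.
#' @return a validated numeric matrix (genes x samples) with gene ids as
#'   rownames and sample ids as colnames.
#' @seealso [write_matrix()] for the canonical on-disk form.
#' @export
read_matrix <- function(path, dialect = c("tsv", "csv")) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("file not found: ", path)
  raw <- utils::read.table(path, header = TRUE, sep = .sep_for(dialect),
                           quote = "", comment.char = "",
                           check.names = FALSE, colClasses = "character")
  if (ncol(raw) < 2L)
    stop("matrix file needs a gene-id column plus at least one sample column")
  gene_ids <- raw[[1L]]
  sample_ids <- colnames(raw)[-1L]
  txt <- as.matrix(raw[, -1L, drop = FALSE])
  vals <- suppressWarnings(matrix(as.numeric(txt), nrow = nrow(txt)))
  bad <- which(is.na(vals), arr.ind = TRUE)
  if (nrow(bad)) {
    i <- bad[1L, 1L]; j <- bad[1L, 2L]
    stop("cannot parse value '", txt[i, j], "' at row ", i, " (gene '",
         gene_ids[i], "'), column ", j, " (sample '", sample_ids[j], "')")
  }
  dimnames(vals) <- list(gene_ids, sample_ids)
  validate_expression_matrix(vals)
  vals
}

#' Write a gene-expression matrix in canonical delimited form
#'
#' The canonical form is the exact layout [read_matrix()] expects: header
#' `gene_id` followed by the sample identifiers, unquoted, one gene per row.
#' `write_matrix(read_matrix(f), g)` reproduces `f` byte-for-byte when `f`
#' is itself in canonical form.
#'
#' @inheritParams read_matrix
#' @param m validated expression matrix.
#' @return `path`, invisibly.
#' @export
write_matrix <- function(m, path, dialect = c("tsv", "csv")) {
  dialect <- match.arg(dialect)
  validate_expression_matrix(m)
  df <- data.frame(gene_id = rownames(m), m, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = .sep_for(dialect), quote = FALSE,
                     row.names = FALSE, col.names = TRUE, eol = "\n")
  invisible(path)
}

#' Validate a signature gene set
#'
#' A signature gene set is a data frame with columns `gene_id` and
#' `direction` (`"up"` or `"down"`), one row per signature gene in
#' signature order. The canonical 58-gene BRAF-mutation-like signature has
#' 58 rows, but any set of two or more genes is accepted.
#'
#' @param sig data frame with columns `gene_id`, `direction`.
#' @return `sig`, invisibly, if valid.
#' @export
validate_signature <- function(sig) {
  if (!is.data.frame(sig) || !all(c("gene_id", "direction") %in% names(sig)))
    stop("signature must be a data frame with columns gene_id and direction")
  if (nrow(sig) < 2L) stop("signature must contain at least 2 genes")
  dup <- unique(sig$gene_id[duplicated(sig$gene_id)])
  if (length(dup))
    stop("duplicated signature gene(s): ", paste(dup, collapse = ", "))
  bad <- setdiff(unique(sig$direction), c("up", "down"))
  if (length(bad))
    stop("direction must be 'up' or 'down'; found: ",
         paste(bad, collapse = ", "))
  invisible(sig)
}

#' Read / write a signature gene list
#'
#' Two-column delimited file with header `gene_id`, `direction`.
#'
#' @inheritParams read_matrix
#' @return `read_signature()`: a validated signature data frame.
#' @export
read_signature <- function(path, dialect = c("tsv", "csv")) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("file not found: ", path)
  sig <- utils::read.table(path, header = TRUE, sep = .sep_for(dialect),
                           quote = "", comment.char = "",
                           stringsAsFactors = FALSE,
                           colClasses = "character")
  validate_signature(sig)
  sig[c("gene_id", "direction")]
}

#' @rdname read_signature
#' @param sig signature data frame.
#' @export
write_signature <- function(sig, path, dialect = c("tsv", "csv")) {
  dialect <- match.arg(dialect)
  validate_signature(sig)
  utils::write.table(sig[c("gene_id", "direction")], path,
                     sep = .sep_for(dialect), quote = FALSE,
                     row.names = FALSE, eol = "\n")
  invisible(path)
}

.braf_levels <- c("mutated", "wildtype", "unknown")
.msi_levels <- c("MSI", "MSS", "unknown")

#' Validate a sample annotation table
#'
#' Required columns: `sample_id` (unique) and `braf_status` (one of
#' `mutated`, `wildtype`, `unknown`). Optional columns, filled with neutral
#' defaults when absent: `tumor_pct` (percent tumor cells, 0-100 or `NA`),
#' `cohort_tag` (free-text cohort label, e.g. `"prescreen"`, `"random"`,
#' `"control"`), `msi_status` (`MSI`, `MSS`, `unknown`) and
#' `signal_intensity` (per-sample array signal summary used for
#' low-signal exclusion of paired FFPE samples).
#'
#' @param ann data frame of per-sample annotations.
#' @return the completed annotation data frame.
#' @export
validate_annotations <- function(ann) {
  if (!is.data.frame(ann) || !all(c("sample_id", "braf_status") %in% names(ann)))
    stop("annotations must be a data frame with columns sample_id and braf_status")
  dup <- unique(ann$sample_id[duplicated(ann$sample_id)])
  if (length(dup))
    stop("duplicated sample_id(s): ", paste(dup, collapse = ", "))
  bad <- setdiff(unique(ann$braf_status), .braf_levels)
  if (length(bad))
    stop("braf_status must be one of ", paste(.braf_levels, collapse = "/"),
         "; found: ", paste(bad, collapse = ", "))
  if (!"tumor_pct" %in% names(ann)) ann$tumor_pct <- NA_real_
  ann$tumor_pct <- as.numeric(ann$tumor_pct)
  out_of_range <- !is.na(ann$tumor_pct) &
    (ann$tumor_pct < 0 | ann$tumor_pct > 100)
  if (any(out_of_range))
    stop("tumor_pct outside [0, 100] for sample(s): ",
         paste(ann$sample_id[out_of_range], collapse = ", "))
  if (!"cohort_tag" %in% names(ann)) ann$cohort_tag <- "random"
  if (!"msi_status" %in% names(ann)) ann$msi_status <- "unknown"
  bad_msi <- setdiff(unique(ann$msi_status), .msi_levels)
  if (length(bad_msi))
    stop("msi_status must be one of ", paste(.msi_levels, collapse = "/"),
         "; found: ", paste(bad_msi, collapse = ", "))
  if (!"signal_intensity" %in% names(ann)) ann$signal_intensity <- NA_real_
  ann$signal_intensity <- as.numeric(ann$signal_intensity)
  ann
}

#' Read / write a sample annotation table
#'
#' @inheritParams read_matrix
#' @return `read_annotations()`: a validated, completed annotation data
#'   frame (see [validate_annotations()]).
#' @export
read_annotations <- function(path, dialect = c("tsv", "csv")) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("file not found: ", path)
  ann <- utils::read.table(path, header = TRUE, sep = .sep_for(dialect),
                           quote = "", comment.char = "",
                           stringsAsFactors = FALSE)
  validate_annotations(ann)
}

#' @rdname read_annotations
#' @param ann annotation data frame.
#' @export
write_annotations <- function(ann, path, dialect = c("tsv", "csv")) {
  dialect <- match.arg(dialect)
  ann <- validate_annotations(ann)
  utils::write.table(ann, path, sep = .sep_for(dialect), quote = FALSE,
                     row.names = FALSE, eol = "\n")
  invisible(path)
}

#' Restrict an expression matrix to the signature genes
#'
#' Subsets and reorders the rows of `m` to the signature's gene order. Every
#' downstream scoring function expects its input in this aligned form. In
#' strict mode (`max_missing = 0`, the default) any signature gene absent
#' from the matrix is an error listing the absent genes; a tolerance of up
#' to `max_missing` absent genes can be declared, in which case the missing
#' genes are dropped from the output (with a warning).
#'
#' @param m expression matrix (genes x samples).
#' @param sig signature gene set (see [validate_signature()]).
#' @param max_missing maximum number of signature genes allowed to be
#'   absent from `m`.
#' @return the matrix restricted to the signature genes, rows in signature
#'   order. The result is invariant to the row order of `m`.
#' @export
align_to_signature <- function(m, sig, max_missing = 0L) {
  validate_expression_matrix(m)
  validate_signature(sig)
  missing <- setdiff(sig$gene_id, rownames(m))
  if (length(missing) > max_missing)
    stop(length(missing), " signature gene(s) absent from matrix: ",
         paste(missing, collapse = ", "))
  if (length(missing))
    warning("dropping ", length(missing), " absent signature gene(s): ",
            paste(missing, collapse = ", "))
  keep <- sig$gene_id[sig$gene_id %in% rownames(m)]
  m[keep, , drop = FALSE]
}
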