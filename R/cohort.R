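#' Labeled expression cohort
#'
#' An `ipre_cohort` bundles a genes x samples expression matrix with a
#' per-sample clinical table and (optionally) good/poor prognosis labels.
#' The expression matrix is a plain numeric matrix with gene identifiers as
#' row names and sample identifiers as column names; after
#' [minmax_normalize()] every non-constant gene row lies in `[0, 1]`.
#'
#' @param expr Numeric matrix, genes in rows (unique row names), samples in
#'   columns (unique column names).
#' @param clinical Data frame with one row per sample; see
#'   [read_clinical_tsv()] for the expected columns. Only samples present in
#'   `expr` are kept.
#' @param labels Optional named character vector of `"poor"`/`"good"` labels;
#'   names must be sample identifiers present in `expr`. When `NULL`, labels
#'   are derived from the clinical table via [assign_labels()] if time to
#'   progression is available.
#'
#' @return An object of class `ipre_cohort`: a list with elements `expr`,
#'   `clinical` and `labels`.
#' @export
#' @examples
#' expr <- matrix(runif(12), 3, 4,
#'                dimnames = list(c("g1", "g2", "g3"), paste0("s", 1:4)))
#' clin <- data.frame(sample_id = paste0("s", 1:4),
#'                    ttp_years = c(2, 8, 3, 9),
#'                    event = c(TRUE, FALSE, TRUE, FALSE),
#'                    cohort_id = "demo")
#' cohort(expr, clin)
cohort <- function(expr, clinical = NULL, labels = NULL) {
  if (!is.matrix(expr) || !is.numeric(expr))
    stop("`expr` must be a numeric matrix (genes x samples)")
  if (is.null(rownames(expr)) || is.null(colnames(expr)))
    stop("`expr` must have gene row names and sample column names")
  if (anyDuplicated(rownames(expr)))
    stop("duplicate gene ids in expression matrix: ",
         paste(unique(rownames(expr)[duplicated(rownames(expr))]), collapse = ", "))
  if (anyDuplicated(colnames(expr)))
    stop("duplicate sample ids in expression matrix: ",
         paste(unique(colnames(expr)[duplicated(colnames(expr))]), collapse = ", "))
  if (!is.null(clinical)) {
    clinical <- as.data.frame(clinical)
    if (!"sample_id" %in% names(clinical))
      stop("clinical table needs a `sample_id` column")
    if (anyDuplicated(clinical$sample_id))
      stop("duplicate sample ids in clinical table")
    clinical <- clinical[clinical$sample_id %in% colnames(expr), , drop = FALSE]
    rownames(clinical) <- NULL
  }
  if (is.null(labels) && !is.null(clinical) && "ttp_years" %in% names(clinical)) {
    labels <- suppressWarnings(assign_labels(clinical))
  }
  if (!is.null(labels)) {
    if (is.null(names(labels)) || !all(names(labels) %in% colnames(expr)))
      stop("labels must be named by sample ids present in `expr`")
    bad <- setdiff(unique(labels), c("poor", "good"))
    if (length(bad))
      stop("labels must be 'poor' or 'good'; found: ", paste(bad, collapse = ", "))
  }
  structure(list(expr = expr, clinical = clinical, labels = labels),
            class = "ipre_cohort")
}

#' @export
print.ipre_cohort <- function(x, ...) {
  cat("ipre_cohort:", nrow(x$expr), "genes x", ncol(x$expr), "samples\n")
  if (!is.null(x$labels)) {
    tab <- table(factor(x$labels, levels = c("poor", "good")))
    cat("  labeled:", sum(tab), "(", tab[["poor"]], "poor /", tab[["good"]], "good )\n")
  }
  if (!is.null(x$clinical) && "cohort_id" %in% names(x$clinical))
    cat("  cohorts:", paste(unique(x$clinical$cohort_id), collapse = ", "), "\n")
  invisible(x)
}

#' Read and write expression matrices
#'
#' Tab-separated text: first column holds gene (or probe) identifiers, the
#' header row holds sample identifiers, remaining cells are expression values.
#'
#' @param path File path.
#' @return `read_expression_tsv()` returns a numeric matrix with gene row
#'   names and sample column names.
#' @export
read_expression_tsv <- function(path) {
  d <- utils::read.delim(path, header = TRUE, sep = "\t", check.names = FALSE,
                         stringsAsFactors = FALSE)
  ids <- as.character(d[[1L]])
  m <- as.matrix(d[, -1L, drop = FALSE])
  storage.mode(m) <- "double"
  rownames(m) <- ids
  if (anyDuplicated(ids))
    stop("duplicate row identifiers in ", path)
  m
}

#' @rdname read_expression_tsv
#' @param expr Numeric matrix as returned by [read_expression_tsv()].
#' @param id_col Name for the identifier column in the written file.
#' @export
write_expression_tsv <- function(expr, path, id_col = "gene_id") {
  d <- data.frame(rownames(expr), expr, check.names = FALSE,
                  stringsAsFactors = FALSE)
  names(d)[1L] <- id_col
  utils::write.table(d, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a clinical table
#'
#' Tab-separated with columns `sample_id`, `ttp_years` (time to progression,
#' years), `event` (metastasis/recurrence observed), `er`, `pr`, `her2`
#' (status `positive`/`negative`), `grade` (`I`/`II`/`III`), `size_cm`
#' (tumour size, cm) and `cohort_id`; missing values encoded as `NA`.
#' Event flags may be `0/1`, `TRUE/FALSE` or `yes/no`.
#'
#' @param path File path.
#' @return A data frame, one row per sample.
#' @export
read_clinical_tsv <- function(path) {
  d <- utils::read.delim(path, header = TRUE, sep = "\t", check.names = FALSE,
                         stringsAsFactors = FALSE, na.strings = c("NA", ""))
  if (!"sample_id" %in% names(d))
    stop("clinical table ", path, " needs a `sample_id` column")
  d$sample_id <- as.character(d$sample_id)
  if ("event" %in% names(d) && !is.logical(d$event)) {
    ev <- tolower(as.character(d$event))
    d$event <- ev %in% c("1", "true", "yes", "y")
    d$event[is.na(ev)] <- NA
  }
  for (col in c("ttp_years", "size_cm"))
    if (col %in% names(d)) d[[col]] <- as.numeric(d[[col]])
  d
}

#' @rdname read_clinical_tsv
#' @param clinical Data frame as returned by [read_clinical_tsv()].
#' @export
write_clinical_tsv <- function(clinical, path) {
  utils::write.table(clinical, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "NA")
  invisible(path)
}
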