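#' Rank genes by virtual-chromosome score
#'
#' Sorts genes by VC descending; exact ties are broken lexicographically by
#' gene id so the ranking is deterministic and independent of input order.
#'
#' @param vc Data frame as returned by [score_genes()] (columns `gene`, `vc`).
#' @return `vc` reordered, with a `rank` column added.
#' @export
rank_genes <- function(vc) {
  if (nrow(vc) < 1L) stop("need at least one gene")
  ord <- order(-vc$vc, vc$gene)
  out <- vc[ord, , drop = FALSE]
  out$rank <- seq_len(nrow(out))
  rownames(out) <- NULL
  out
}

#' Robustness-score profile of a ranked gene list
#'
#' For genes sorted by VC descending, the robustness score of the length-`m`
#' prefix is the weighted prefix sum `R_m = m^(-exponent) * sum(VC_1..VC_m)`,
#' with the inverse square root (`exponent = 0.5`) as the default weight.
#' The profile rises while high-scoring genes are added and falls once the
#' tail dominates; its argmax sets the signature size (first index on exact
#' ties, giving the smaller signature).
#'
#' @param vc_sorted Numeric vector of VC scores sorted non-increasing.
#' @param exponent Weight exponent; `0.5` gives the inverse-square-root
#'   weight, `1` the plain running mean.
#' @return List with `r_scores` (one per prefix length) and `m_star`
#'   (argmax index).
#' @export
#' @examples
#' robustness_profile(c(0.9, 0.8, 0.1))  # m_star = 2
robustness_profile <- function(vc_sorted, exponent = 0.5) {
  if (length(vc_sorted) < 1L) stop("need at least one score")
  if (any(diff(vc_sorted) > 0))
    stop("`vc_sorted` must be sorted non-increasing")
  m <- seq_along(vc_sorted)
  r <- cumsum(vc_sorted) / m^exponent
  list(r_scores = r, m_star = which.max(r))
}

#' Extract the prognostic gene signature
#'
#' Ranks genes by VC, computes the robustness profile over all genes, and
#' returns the prefix of ranked genes up to the profile maximum.
#'
#' @param vc Data frame from [score_genes()].
#' @inheritParams robustness_profile
#' @return An `ipre_signature`: list with `genes` (ordered ids), `size`,
#'   `ranked` (the ranked score table) and `r_scores`.
#' @export
select_signature <- function(vc, exponent = 0.5) {
  ranked <- rank_genes(vc)
  prof <- robustness_profile(ranked$vc, exponent)
  structure(list(genes = ranked$gene[seq_len(prof$m_star)],
                 size = prof$m_star,
                 ranked = ranked,
                 r_scores = prof$r_scores),
            class = "ipre_signature")
}

#' @export
print.ipre_signature <- function(x, ...) {
  cat("ipre_signature:", x$size, "genes\n")
  cat(" ", paste(utils::head(x$genes, 10L), collapse = ", "),
      if (x$size > 10L) "...\n" else "\n")
  invisible(x)
}

#' Per-sample signature mean expression (mScore)
#'
#' The mScore of a sample is the arithmetic mean of its normalized
#' expression over the signature genes; it summarizes the signature in one
#' number in `[0, 1]` and enters the risk model as the X6 covariate.
#' Signature genes absent from the matrix (e.g. on another platform) are
#' dropped with a warning and the mean is taken over the genes present.
#'
#' @param expr Normalized expression matrix (genes x samples).
#' @param signature An `ipre_signature` or character vector of gene ids.
#' @return Named numeric vector of mScores, one per sample.
#' @export
mscore <- function(expr, signature) {
  genes <- if (inherits(signature, "ipre_signature")) signature$genes
           else as.character(signature)
  present <- genes[genes %in% rownames(expr)]
  if (length(present) == 0L)
    stop("no signature gene present in the expression matrix")
  if (length(present) < length(genes))
    warning(length(genes) - length(present),
            " signature gene(s) absent from the expression matrix: ",
            paste(setdiff(genes, present), collapse = ", "))
  colMeans(expr[present, , drop = FALSE])
}

#' Read and write gene signatures
#'
#' Plain text holds one gene id per line; GMT holds a single tab-separated
#' record `name <tab> description <tab> gene...`.
#'
#' @param signature An `ipre_signature` or character vector of gene ids.
#' @param path File path.
#' @param name,description GMT set name and description.
#' @export
write_signature <- function(signature, path) {
  genes <- if (inherits(signature, "ipre_signature")) signature$genes
           else as.character(signature)
  writeLines(genes, path)
  invisible(path)
}

#' @rdname write_signature
#' @export
write_signature_gmt <- function(signature, path, name = "ipre_signature",
                                description = "prognostic gene signature") {
  genes <- if (inherits(signature, "ipre_signature")) signature$genes
           else as.character(signature)
  writeLines(paste(c(name, description, genes), collapse = "\t"), path)
  invisible(path)
}

#' @rdname write_signature
#' @export
read_signature <- function(path) {
  lines <- readLines(path)
  lines <- trimws(lines)
  lines[nzchar(lines)]
}
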