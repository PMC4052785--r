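#' Collapse probe-level expression to gene level
#'
#' Maps probe rows to gene rows using a probe-to-gene table. When several
#' probes map to the same gene the gene value is the arithmetic mean of its
#' probes. Affymetrix control probes (identifiers starting with `"AFFX"`)
#' and probes absent from the map are dropped; the drop log is attached as
#' attributes `dropped_affx` and `dropped_unmapped`.
#'
#' @param probe_matrix Numeric matrix, probes in rows (unique row names),
#'   samples in columns.
#' @param probe_map Data frame with columns `probe_id` and `gene_symbol`
#'   (extra columns ignored), or a two-column data frame in that order.
#' @return Gene-level numeric matrix with attributes `dropped_affx` and
#'   `dropped_unmapped` (character vectors of dropped probe ids).
#' @export
#' @examples
#' m <- matrix(c(0.2, 0.4), 2, 1, dimnames = list(c("p1", "p2"), "s1"))
#' map <- data.frame(probe_id = c("p1", "p2"), gene_symbol = "G")
#' collapse_probes(m, map)  # G = 0.3
collapse_probes <- function(probe_matrix, probe_map) {
  if (is.null(rownames(probe_matrix)))
    stop("`probe_matrix` must have probe row names")
  if (anyDuplicated(rownames(probe_matrix)))
    stop("probe ids must be unique")
  probe_map <- as.data.frame(probe_map)
  if (all(c("probe_id", "gene_symbol") %in% names(probe_map))) {
    map <- stats::setNames(as.character(probe_map$gene_symbol),
                           as.character(probe_map$probe_id))
  } else if (ncol(probe_map) >= 2L) {
    map <- stats::setNames(as.character(probe_map[[2L]]),
                           as.character(probe_map[[1L]]))
  } else {
    stop("`probe_map` needs columns probe_id and gene_symbol")
  }
  map <- map[!is.na(map) & nzchar(map)]

  probes <- rownames(probe_matrix)
  is_affx <- startsWith(probes, "AFFX")
  mapped <- probes %in% names(map) & !is_affx
  dropped_affx <- probes[is_affx]
  dropped_unmapped <- probes[!is_affx & !mapped]
  if (!any(mapped))
    stop("no probe maps to any gene after dropping AFFX/unmapped probes")

  kept <- probe_matrix[mapped, , drop = FALSE]
  genes <- map[rownames(kept)]
  sums <- rowsum(kept, group = genes, reorder = TRUE)
  counts <- as.vector(table(genes)[rownames(sums)])
  out <- sums / counts
  attr(out, "dropped_affx") <- dropped_affx
  attr(out, "dropped_unmapped") <- dropped_unmapped
  out
}

#' Min-max normalize expression per gene
#'
#' Rescales each gene row to `[0, 1]` by `(e - min) / (max - min)`, computed
#' within the given matrix (i.e. within one cohort; cohorts are normalized
#' separately before integration). Genes whose expression is constant across
#' all samples are set to 0 everywhere and flagged in the `constant_genes`
#' attribute so downstream steps can exclude them.
#'
#' @param expr Numeric matrix, genes in rows.
#' @return The normalized matrix with attribute `constant_genes`.
#' @export
minmax_normalize <- function(expr) {
  if (ncol(expr) < 1L) stop("need at least one sample")
  if (any(!is.finite(expr))) {
    idx <- which(!is.finite(expr), arr.ind = TRUE)[1L, ]
    stop("non-finite expression value for gene '", rownames(expr)[idx[1L]],
         "', sample '", colnames(expr)[idx[2L]], "'")
  }
  lo <- apply(expr, 1L, min)
  hi <- apply(expr, 1L, max)
  rng <- hi - lo
  const <- rng == 0
  rng[const] <- 1  # avoid 0/0; constant rows overwritten below
  out <- (expr - lo) / rng
  out[const, ] <- 0
  attr(out, "constant_genes") <- rownames(expr)[const]
  out
}

#' Assign good/poor prognosis labels from follow-up
#'
#' A sample is poor prognosis when metastasis/recurrence was observed within
#' the horizon (event with `ttp_years <= horizon`) and good prognosis when it
#' remained progression-free beyond the horizon (`ttp_years > horizon`).
#' Samples censored before the horizon carry no 5-year information and are
#' excluded, as are samples with missing follow-up time; exclusions are
#' reported via warnings and the `excluded` attribute.
#'
#' @param clinical Data frame with `sample_id`, `ttp_years` and `event`.
#' @param horizon Follow-up horizon in years (default 5).
#' @return Named character vector (`"poor"`/`"good"`) over the labelable
#'   samples, with attribute `excluded` listing the dropped sample ids.
#' @export
assign_labels <- function(clinical, horizon = 5) {
  clinical <- as.data.frame(clinical)
  ttp <- clinical$ttp_years
  event <- clinical$event
  ids <- as.character(clinical$sample_id)

  missing_ttp <- is.na(ttp)
  if (any(missing_ttp))
    warning(sum(missing_ttp), " sample(s) excluded: missing follow-up time")
  censored <- !missing_ttp & ttp <= horizon & !(!is.na(event) & event)
  if (any(censored))
    warning(sum(censored), " sample(s) excluded: censored before the ",
            horizon, "-year horizon")

  poor <- !missing_ttp & !is.na(event) & event & ttp <= horizon
  good <- !missing_ttp & ttp > horizon
  keep <- poor | good
  labels <- stats::setNames(ifelse(poor[keep], "poor", "good"), ids[keep])
  attr(labels, "excluded") <- ids[!keep]
  labels
}

#' Integrate normalized cohorts on their common genes
#'
#' Restricts every cohort to the intersection of all gene sets (sorted
#' lexicographically so the result does not depend on platform gene order)
#' and concatenates the samples. Sample ids are made globally unique by
#' prefixing the cohort id; clinical rows and labels are carried along.
#'
#' @param cohorts List of [cohort()] objects, each already normalized.
#' @param exclude Optional character vector of sample ids (unprefixed) to
#'   drop, e.g. samples known to overlap between series.
#' @return A single integrated [cohort()].
#' @export
integrate_cohorts <- function(cohorts, exclude = NULL) {
  if (length(cohorts) < 1L) stop("need at least one cohort")
  gene_sets <- lapply(cohorts, function(co) rownames(co$expr))
  common <- sort(Reduce(intersect, gene_sets))
  if (length(common) == 0L)
    stop("gene intersection across cohorts is empty")

  pieces <- vector("list", length(cohorts))
  clin <- vector("list", length(cohorts))
  labs <- vector("list", length(cohorts))
  for (i in seq_along(cohorts)) {
    co <- cohorts[[i]]
    cid <- if (!is.null(co$clinical) && "cohort_id" %in% names(co$clinical) &&
               nrow(co$clinical) > 0L) {
      as.character(co$clinical$cohort_id[1L])
    } else {
      paste0("cohort", i)
    }
    keep <- colnames(co$expr)
    if (!is.null(exclude)) keep <- setdiff(keep, exclude)
    ex <- co$expr[common, keep, drop = FALSE]
    colnames(ex) <- paste(cid, keep, sep = ":")
    pieces[[i]] <- ex
    if (!is.null(co$clinical)) {
      cl <- co$clinical[co$clinical$sample_id %in% keep, , drop = FALSE]
      cl$cohort_id <- cid
      cl$sample_id <- paste(cid, cl$sample_id, sep = ":")
      clin[[i]] <- cl
    }
    if (!is.null(co$labels)) {
      lb <- co$labels[names(co$labels) %in% keep]
      names(lb) <- paste(cid, names(lb), sep = ":")
      labs[[i]] <- lb
    }
  }
  expr <- do.call(cbind, pieces)
  clinical <- if (any(!vapply(clin, is.null, logical(1L))))
    do.call(rbind, clin) else NULL
  labels <- if (any(!vapply(labs, is.null, logical(1L))))
    do.call(c, labs) else NULL
  if (!is.null(labels)) attr(labels, "excluded") <- NULL
  cohort(expr, clinical, labels)
}

#' Balance prognosis groups by undersampling
#'
#' Keeps the minority class whole and draws a uniform subsample without
#' replacement of the majority class down to the minority size, so both
#' prognosis groups contribute equally to training (e.g. 897 poor and 1,371
#' good samples become 897 + 897 = 1,794).
#'
#' @param x A labeled [cohort()].
#' @param seed Integer seed making the subsample reproducible.
#' @return The balanced [cohort()] (equal class counts).
#' @export
balance_cohort <- function(x, seed = 1L) {
  if (is.null(x$labels)) stop("cohort has no labels")
  poor <- names(x$labels)[x$labels == "poor"]
  good <- names(x$labels)[x$labels == "good"]
  if (length(poor) == 0L || length(good) == 0L)
    stop("both prognosis groups must be non-empty")
  n <- min(length(poor), length(good))
  set.seed(seed)
  if (length(poor) > n) poor <- sort(sample(poor, n))
  if (length(good) > n) good <- sort(sample(good, n))
  keep <- colnames(x$expr)[colnames(x$expr) %in% c(poor, good)]
  clinical <- if (!is.null(x$clinical))
    x$clinical[x$clinical$sample_id %in% keep, , drop = FALSE] else NULL
  cohort(x$expr[, keep, drop = FALSE], clinical, x$labels[keep])
}
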