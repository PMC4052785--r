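#' Virtual-chromosome gene scoring
#'
#' The virtual chromosome (VC) scores each gene for prognostic value by
#' combining two components computed over the labeled samples of an
#' integrated, normalized cohort:
#'
#' * the correlation factor `alpha = (p - q) / N`, where `p` counts samples
#'   whose dichotomized expression is concordant with their dichotomized
#'   outcome (underexpressed, `e < 0.5`, in samples progressing within the
#'   horizon; overexpressed, `e >= 0.5`, in samples progression-free beyond
#'   it) and `q = N - p` counts the discordant samples;
#' * the penalized factor `beta = 1 - |mean(poor group) - mean(good group)|`
#'   of the normalized expression, so a large between-group separation means
#'   a small penalty.
#'
#' The combined score is `VC = tau1 * alpha + tau2 * beta`; with the default
#' weights (`tau1 = 1`, `tau2 = -1.0011`) well-separated concordant genes
#' score highest.
#'
#' @param ttp Time to progression in years, one value per sample.
#' @param e Normalized expression in `[0, 1]`, one value per sample.
#' @param horizon Outcome dichotomization horizon in years (default 5).
#' @param threshold Expression dichotomization threshold (default 0.5).
#' @return `correlation_coefficient()` returns `+1`/`-1` per sample.
#' @name vc_scoring
#' @export
correlation_coefficient <- function(ttp, e, horizon = 5, threshold = 0.5) {
  ifelse((ttp <= horizon & e < threshold) | (ttp > horizon & e >= threshold),
         1, -1)
}

#' @rdname vc_scoring
#' @return `correlation_factor()` returns a list with `alpha`, `p`, `q`.
#' @export
correlation_factor <- function(e, ttp, horizon = 5, threshold = 0.5) {
  if (length(e) == 0L) stop("empty expression vector")
  if (length(e) != length(ttp)) stop("`e` and `ttp` lengths differ")
  cc <- correlation_coefficient(ttp, e, horizon, threshold)
  p <- sum(cc == 1)
  q <- sum(cc == -1)
  list(alpha = (p - q) / length(cc), p = p, q = q)
}

#' @rdname vc_scoring
#' @param labels Character vector of `"poor"`/`"good"` labels per sample.
#' @return `penalized_factor()` returns `beta` in `[0, 1]`.
#' @export
penalized_factor <- function(e, labels) {
  g1 <- e[labels == "poor"]
  g2 <- e[labels == "good"]
  if (length(g1) == 0L || length(g2) == 0L)
    stop("both prognosis groups must be non-empty")
  1 - abs(mean(g1) - mean(g2))
}

#' @rdname vc_scoring
#' @param alpha,beta The two VC components.
#' @param tau1,tau2 Component weights (defaults 1 and -1.0011).
#' @return `vc_score()` returns the weighted combination.
#' @export
vc_score <- function(alpha, beta, tau1 = 1, tau2 = -1.0011) {
  tau1 * alpha + tau2 * beta
}

#' Score every gene of a labeled cohort
#'
#' Applies the virtual-chromosome statistic gene by gene over the labeled
#' samples of `x`. Genes flagged constant by [minmax_normalize()] are
#' excluded by default because their zero-filled rows make the concordance
#' pattern an artifact.
#'
#' @param x A labeled, normalized [cohort()].
#' @inheritParams vc_scoring
#' @param exclude_constant Drop constant-flagged genes before scoring.
#' @return Data frame with one row per gene: `gene`, `alpha`, `beta`, `vc`,
#'   `p`, `q`.
#' @export
score_genes <- function(x, tau1 = 1, tau2 = -1.0011, horizon = 5,
                        threshold = 0.5, exclude_constant = TRUE) {
  if (is.null(x$labels)) stop("cohort has no labels")
  ids <- names(x$labels)
  expr <- x$expr[, ids, drop = FALSE]
  clin <- x$clinical
  ttp <- clin$ttp_years[match(ids, clin$sample_id)]
  if (anyNA(ttp)) stop("missing ttp_years for labeled sample(s)")
  labels <- as.character(x$labels)

  genes <- rownames(expr)
  if (exclude_constant) {
    const <- attr(x$expr, "constant_genes")
    if (!is.null(const)) genes <- setdiff(genes, const)
  }
  n <- length(genes)
  alpha <- beta <- numeric(n)
  p <- q <- integer(n)
  for (i in seq_len(n)) {
    e <- expr[genes[i], ]
    cf <- correlation_factor(e, ttp, horizon, threshold)
    alpha[i] <- cf$alpha
    p[i] <- cf$p
    q[i] <- cf$q
    beta[i] <- penalized_factor(e, labels)
  }
  data.frame(gene = genes, alpha = alpha, beta = beta,
             vc = vc_score(alpha, beta, tau1, tau2),
             p = p, q = q, stringsAsFactors = FALSE)
}
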