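#' Confusion-matrix cells with poor prognosis as the positive class
#'
#' @param predictions,truths Character vectors of `"poor"`/`"good"`.
#' @return List with integer cells `tp`, `tn`, `fp`, `fn`.
#' @export
confusion <- function(predictions, truths) {
  if (length(predictions) == 0L) stop("empty input")
  if (length(predictions) != length(truths)) stop("length mismatch")
  bad <- setdiff(unique(c(predictions, truths)), c("poor", "good"))
  if (length(bad))
    stop("labels must be 'poor' or 'good'; found: ", paste(bad, collapse = ", "))
  list(tp = sum(predictions == "poor" & truths == "poor"),
       tn = sum(predictions == "good" & truths == "good"),
       fp = sum(predictions == "poor" & truths == "good"),
       fn = sum(predictions == "good" & truths == "poor"))
}

#' Wald confidence interval for a proportion
#'
#' `p_hat +/- z * sqrt(p_hat * (1 - p_hat) / n)`, the normal approximation
#' without continuity correction. Bounds are reported as computed, not
#' clipped to `[0, 1]` (a near-zero proportion can print a slightly
#' negative lower bound, and an estimate of exactly 0 or 1 prints a
#' degenerate interval).
#'
#' @param p_hat Estimated proportion in `[0, 1]`.
#' @param n Number of trials (>= 1).
#' @param level Confidence level (default 0.95).
#' @return Numeric vector `c(lo, hi)`.
#' @export
wald_ci <- function(p_hat, n, level = 0.95) {
  if (n < 1L) stop("`n` must be >= 1")
  if (p_hat < 0 || p_hat > 1) stop("`p_hat` must lie in [0, 1]")
  z <- stats::qnorm((1 + level) / 2)
  half <- z * sqrt(p_hat * (1 - p_hat) / n)
  c(lo = p_hat - half, hi = p_hat + half)
}

#' Classification metrics from confusion cells
#'
#' Sensitivity `tp/(tp+fn)` (poor identified as poor), specificity
#' `tn/(tn+fp)` (good identified as good), accuracy `(tp+tn)/(tp+tn+fp+fn)`
#' (the denominator is the cell sum), and the F-value (F1, harmonic mean of
#' precision and sensitivity). Each proportion carries a Wald confidence
#' interval. A metric with a zero denominator is reported as `NA`
#' (undefined), never as 0.
#'
#' @param cells List with `tp`, `tn`, `fp`, `fn` (see [confusion()]).
#' @param level Confidence level for the intervals.
#' @return List with `sensitivity`, `specificity`, `accuracy`, `f_value`
#'   and intervals `sensitivity_ci`, `specificity_ci`, `accuracy_ci`.
#' @export
prognosis_metrics <- function(cells, level = 0.95) {
  tp <- cells$tp; tn <- cells$tn; fp <- cells$fp; fn <- cells$fn
  stopifnot(tp >= 0, tn >= 0, fp >= 0, fn >= 0)
  n <- tp + tn + fp + fn
  if (n < 1L) stop("empty confusion matrix")
  ratio <- function(num, den) if (den > 0) num / den else NA_real_
  se <- ratio(tp, tp + fn)
  sp <- ratio(tn, tn + fp)
  acc <- ratio(tp + tn, n)
  f <- if (2 * tp + fp + fn > 0) 2 * tp / (2 * tp + fp + fn) else NA_real_
  ci <- function(p, den) if (is.na(p)) c(lo = NA_real_, hi = NA_real_)
                         else wald_ci(p, den, level)
  list(sensitivity = se, specificity = sp, accuracy = acc, f_value = f,
       sensitivity_ci = ci(se, tp + fn),
       specificity_ci = ci(sp, tn + fp),
       accuracy_ci = ci(acc, n))
}

#' ROC curve and AUC
#'
#' The AUC is the rank-sum (concordance) statistic with ties counted one
#' half: the probability that a random poor-prognosis sample scores above a
#' random good-prognosis sample. ROC points (false positive rate, true
#' positive rate) are returned for every distinct threshold, classifying
#' poor when the score is at or above the threshold; the trapezoidal area
#' over these points equals the concordance.
#'
#' @param scores Numeric scores; higher means more poor-like.
#' @param labels True labels, `"poor"`/`"good"`; both must be present.
#' @return List with `auc` and `roc` (data frame `fpr`, `tpr`, `threshold`).
#' @export
roc_auc <- function(scores, labels) {
  y <- labels == "poor"
  n1 <- sum(y); n0 <- sum(!y)
  if (n1 == 0L || n0 == 0L) stop("both prognosis classes must be present")
  r <- rank(scores)  # midranks: ties counted 1/2
  auc <- (sum(r[y]) - n1 * (n1 + 1) / 2) / (n1 * n0)

  thr <- c(Inf, sort(unique(scores), decreasing = TRUE))
  tpr <- vapply(thr, function(t) sum(y & scores >= t) / n1, numeric(1L))
  fpr <- vapply(thr, function(t) sum(!y & scores >= t) / n0, numeric(1L))
  list(auc = auc, roc = data.frame(fpr = fpr, tpr = tpr, threshold = thr))
}

#' Kaplan-Meier curves and log-rank test for two prognosis groups
#'
#' Product-limit survival estimate per group and the unstratified two-sided
#' log-rank test (chi-squared, 1 df). With no events anywhere the curves
#' are flat at 1 and the test is undefined (`p = NA`).
#'
#' @param times Positive follow-up times (years).
#' @param events Event indicator (metastasis/recurrence observed).
#' @param groups Two-level group label per sample (e.g. predicted
#'   `"poor"`/`"good"`).
#' @return List with `fit` (a [survival::survfit] object), `chisq` and
#'   `p_value`.
#' @export
km_logrank <- function(times, events, groups) {
  groups <- as.factor(groups)
  if (nlevels(droplevels(groups)) != 2L)
    stop("need exactly two non-empty groups")
  if (any(times <= 0)) stop("times must be positive")
  events <- as.integer(events)
  fit <- survival::survfit(survival::Surv(times, events) ~ groups)
  if (sum(events) == 0L)
    return(list(fit = fit, chisq = NA_real_, p_value = NA_real_))
  sd <- survival::survdiff(survival::Surv(times, events) ~ groups)
  list(fit = fit, chisq = unname(sd$chisq),
       p_value = stats::pchisq(sd$chisq, df = 1L, lower.tail = FALSE))
}

#' Hazard ratio between two groups
#'
#' Cox proportional-hazards fit of a binary group indicator;
#' `HR = exp(coef)` with a Wald confidence interval. The indicator is coded
#' 1 for the `"poor"` level (or the second factor level), so HR > 1 means
#' the poor group progresses faster.
#'
#' @inheritParams km_logrank
#' @param level Confidence level (default 0.95).
#' @return List with `hr`, `ci` (`lo`, `hi`), `p_value`.
#' @export
hazard_ratio <- function(times, events, groups, level = 0.95) {
  events <- as.integer(events)
  if (sum(events) == 0L) stop("no events: hazard ratio is inestimable")
  g <- as.factor(groups)
  if (nlevels(droplevels(g)) != 2L)
    stop("group indicator must have exactly two non-empty levels")
  ind <- if ("poor" %in% levels(g)) as.integer(g == "poor")
         else as.integer(g == levels(g)[2L])
  fit <- survival::coxph(survival::Surv(times, events) ~ ind)
  beta <- unname(stats::coef(fit))
  se <- sqrt(unname(stats::vcov(fit)[1L, 1L]))
  z <- stats::qnorm((1 + level) / 2)
  list(hr = exp(beta),
       ci = c(lo = exp(beta - z * se), hi = exp(beta + z * se)),
       p_value = 2 * stats::pnorm(-abs(beta / se)))
}

#' Random-gene-signature null distribution (RAND)
#'
#' Draws `k` gene sets of the same size as the signature uniformly without
#' replacement from the cohort's genes and evaluates each with a
#' user-supplied function, giving the null distribution against which a
#' signature's outcome association is benchmarked (the convention of
#' comparing against 1,000 random signatures of identical size).
#'
#' @param x A [cohort()] or expression matrix supplying the gene universe.
#' @param signature_size Number of genes per random signature.
#' @param evaluator Function taking a character vector of gene ids and
#'   returning a single number (e.g. a log-rank p value or an accuracy).
#' @param k Number of random signatures (default 1000).
#' @param seed Integer seed.
#' @return List with `values` (length `k`), `median`, `quantiles`
#'   (2.5/5/50/95/97.5 percentiles) and `signatures`.
#' @export
random_signature_null <- function(x, signature_size, evaluator, k = 1000,
                                  seed = 1L) {
  genes <- if (inherits(x, "ipre_cohort")) rownames(x$expr) else rownames(x)
  if (signature_size > length(genes))
    stop("signature_size exceeds the number of genes")
  set.seed(seed)
  sigs <- replicate(k, sample(genes, signature_size), simplify = FALSE)
  values <- vapply(sigs, function(g) as.numeric(evaluator(g)), numeric(1L))
  list(values = values, median = stats::median(values),
       quantiles = stats::quantile(values, c(0.025, 0.05, 0.5, 0.95, 0.975),
                                   na.rm = TRUE),
       signatures = sigs)
}
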