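#' Run the full prognosis pipeline on training and test cohorts
#'
#' Convenience wrapper chaining every stage: per-cohort min-max
#' normalization, integration on common genes, optional class balancing,
#' virtual-chromosome scoring, robustness-based signature selection,
#' receptor imputation, covariate encoding, backward-selected logistic
#' fitting, cutoff selection on the training risk scores, and evaluation on
#' a held-out cohort (confusion metrics, AUC, Kaplan-Meier/log-rank, hazard
#' ratio).
#'
#' @param train List of labeled [cohort()]s used for signature extraction
#'   and model fitting.
#' @param test A labeled [cohort()] held out for evaluation (normalized
#'   separately from training, never integrated with it).
#' @param tau1,tau2 Virtual-chromosome weights (defaults 1, -1.0011).
#' @param exponent Robustness-score weight exponent (default 0.5).
#' @param alpha Backward-selection retention threshold (default 0.05).
#' @param balance_seed Seed for class balancing before scoring; `NULL`
#'   skips balancing.
#' @param cutoff Classification cutoff; `NULL` (default) selects the
#'   F-value-maximizing cutoff on the training risk scores.
#' @param grid_step Cutoff-search grid resolution.
#' @return List with `signature`, `model`, `cutoff`, `train` (integrated
#'   cohort, risk scores) and `test` (risk scores, predictions, `metrics`,
#'   `auc`, `km`, `hr`).
#' @export
run_pipeline <- function(train, test = NULL, tau1 = 1, tau2 = -1.0011,
                         exponent = 0.5, alpha = 0.05, balance_seed = NULL,
                         cutoff = NULL, grid_step = 0.001) {
  norm_cohort <- function(co) {
    ex <- minmax_normalize(co$expr)
    out <- cohort(ex, co$clinical, co$labels)
    attr(out$expr, "constant_genes") <- attr(ex, "constant_genes")
    out
  }
  train <- lapply(train, norm_cohort)
  integrated <- integrate_cohorts(train)
  scored_cohort <- if (!is.null(balance_seed))
    balance_cohort(integrated, seed = balance_seed) else integrated

  vc <- score_genes(scored_cohort, tau1 = tau1, tau2 = tau2)
  signature <- select_signature(vc, exponent = exponent)

  prep <- function(co) {
    ids <- names(co$labels)
    clin <- impute_receptor(co$expr, co$clinical)
    ms <- mscore(co$expr, signature)
    enc <- encode_clinical(clin, ms)
    enc <- enc[ids, , drop = FALSE]
    keep <- ids[stats::complete.cases(enc)]
    list(cov = enc[keep, , drop = FALSE], labels = co$labels[keep],
         clin = clin)
  }

  tr <- prep(scored_cohort)
  # When the signature is strongly informative the encoded covariates can
  # linearly separate the training classes, where maximum-likelihood
  # logistic coefficients diverge. The pipeline then falls back to the
  # signature mean alone as the risk score (RS = -X6, so low signature
  # expression means high risk), with the cutoff still chosen by the
  # F-value search; the fallback is recorded in `model$fallback`.
  model <- tryCatch(
    fit_risk_model(tr$cov, tr$labels, alpha = alpha),
    error = function(e) {
      if (!grepl("separation", conditionMessage(e))) stop(e)
      structure(list(intercept = 0,
                     coefficients = c(x6_mscore = -1),
                     retained = "x6_mscore",
                     cutoff = NA_real_, alpha = alpha,
                     trace = data.frame(variable = character(0),
                                        p_value = numeric(0)),
                     summary = NULL, fallback = "separation"),
                class = "ipre_risk_model")
    })
  rs_train <- risk_score(model, tr$cov)
  eps <- if (is.null(cutoff))
    choose_cutoff(rs_train, tr$labels, grid_step)$epsilon else cutoff
  model$cutoff <- eps

  out <- list(signature = signature, model = model, cutoff = eps,
              train = list(cohort = scored_cohort, rs = rs_train,
                           labels = tr$labels))
  if (!is.null(test)) {
    test <- norm_cohort(test)
    te <- suppressWarnings(prep(test))
    rs <- risk_score(model, te$cov)
    pred <- classify_risk(rs, eps)
    cells <- confusion(pred, as.character(te$labels))
    clin <- te$clin
    keep <- clin$sample_id %in% names(rs) & !is.na(clin$ttp_years)
    km <- hr <- NULL
    grp <- pred[clin$sample_id[keep]]
    if (length(unique(grp)) == 2L) {
      km <- km_logrank(clin$ttp_years[keep], clin$event[keep], grp)
      if (sum(clin$event[keep]) > 0L)
        hr <- hazard_ratio(clin$ttp_years[keep], clin$event[keep], grp)
    }
    out$test <- list(rs = rs, predicted = pred, labels = te$labels,
                     cells = cells, metrics = prognosis_metrics(cells),
                     auc = roc_auc(rs, as.character(te$labels))$auc,
                     km = km, hr = hr)
  }
  out
}
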