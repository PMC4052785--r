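#' Encode clinical covariates for the risk model
#'
#' Encodes the clinical variables used by the multivariate logistic risk
#' model:
#'
#' | variable | characteristic | code |
#' |----------|----------------|------|
#' | `x1_grade` | tumour grade I-II / III | 0 / 1 |
#' | `x2_size`  | tumour size < 2 cm / 2 to < 4 cm / >= 4 cm | 0 / 0.55 / 1 |
#' | `x3_er`    | estrogen receptor - / + | -1 / +1 |
#' | `x4_pr`    | progesterone receptor - / + | -1 / +1 |
#' | `x5_her2`  | HER2 - / + | -1 / +1 |
#' | `x6_mscore`| signature mean expression | value in \[0, 1\] |
#'
#' The middle size bin absorbs the 3 to 4 cm range so the coding is total.
#' Missing values propagate as `NA`; a sample with a missing covariate is
#' usable only by models that do not retain that variable.
#'
#' @param clinical Data frame with columns `grade`, `size_cm`, `er`, `pr`,
#'   `her2` (statuses `positive`/`negative`, grades `I`/`II`/`III`).
#' @param mscore Numeric vector of mScores in `[0, 1]`, one per row of
#'   `clinical` (or named by `sample_id`).
#' @return Data frame with columns `x1_grade`, `x2_size`, `x3_er`, `x4_pr`,
#'   `x5_her2`, `x6_mscore` and row names from `sample_id` when present.
#' @export
encode_clinical <- function(clinical, mscore = NULL) {
  clinical <- as.data.frame(clinical)
  n <- nrow(clinical)
  grab <- function(col) if (col %in% names(clinical)) clinical[[col]] else rep(NA, n)

  grade <- toupper(trimws(as.character(grab("grade"))))
  x1 <- ifelse(grade %in% c("I", "II"), 0, ifelse(grade == "III", 1, NA))

  size <- as.numeric(grab("size_cm"))
  x2 <- ifelse(size < 2, 0, ifelse(size < 4, 0.55, 1))

  code_status <- function(s) {
    s <- tolower(trimws(as.character(s)))
    ifelse(s %in% c("positive", "+", "pos", "1"), 1,
           ifelse(s %in% c("negative", "-", "neg", "0"), -1, NA))
  }
  x6 <- if (is.null(mscore)) rep(NA_real_, n) else {
    if (!is.null(names(mscore)) && "sample_id" %in% names(clinical))
      unname(mscore[as.character(clinical$sample_id)])
    else as.numeric(mscore)
  }
  if (any(!is.na(x6) & (x6 < 0 | x6 > 1)))
    stop("mscore values must lie in [0, 1]")

  out <- data.frame(x1_grade = x1, x2_size = x2,
                    x3_er = code_status(grab("er")),
                    x4_pr = code_status(grab("pr")),
                    x5_her2 = code_status(grab("her2")),
                    x6_mscore = x6)
  if ("sample_id" %in% names(clinical))
    rownames(out) <- as.character(clinical$sample_id)
  out
}

#' Impute missing ER/PR status from receptor gene expression
#'
#' When immunohistochemistry status is missing, the dichotomized mRNA level
#' of the receptor gene stands in: normalized ESR1 expression at or above
#' the threshold means ER positive (below means negative), and likewise PGR
#' for PR. Recorded statuses are never overridden. When the status is
#' missing and the receptor gene is absent from the matrix the status stays
#' missing and the sample is flagged in the `unimputable` attribute.
#'
#' @param expr Normalized expression matrix containing `ESR1` and/or `PGR`.
#' @param clinical Clinical data frame with `sample_id`, `er`, `pr`.
#' @param threshold Dichotomization threshold on the normalized scale
#'   (default 0.5, the over/under-expression convention).
#' @param genes Named character vector mapping status columns to gene ids.
#' @return The clinical table with missing `er`/`pr` filled where possible.
#' @export
impute_receptor <- function(expr, clinical, threshold = 0.5,
                            genes = c(er = "ESR1", pr = "PGR")) {
  clinical <- as.data.frame(clinical)
  ids <- as.character(clinical$sample_id)
  unimputable <- character(0)
  for (status in names(genes)) {
    if (!status %in% names(clinical)) clinical[[status]] <- NA_character_
    miss <- is.na(clinical[[status]])
    if (!any(miss)) next
    gene <- genes[[status]]
    if (!gene %in% rownames(expr)) {
      unimputable <- c(unimputable, ids[miss])
      next
    }
    e <- expr[gene, ]
    have <- miss & ids %in% colnames(expr)
    clinical[[status]][have] <-
      ifelse(e[ids[have]] >= threshold, "positive", "negative")
    unimputable <- c(unimputable, ids[miss & !have])
  }
  attr(clinical, "unimputable") <- unique(unimputable)
  clinical
}

#' Fit the logistic risk model with backward elimination
#'
#' Fits a maximum-likelihood logistic regression of prognosis (poor = 1) on
#' all candidate covariates, then repeatedly removes the covariate with the
#' largest Wald P value above `alpha` and refits, until every retained
#' covariate has P <= `alpha`. The elimination trace is recorded.
#'
#' @param covariates Data frame of encoded covariates (see
#'   [encode_clinical()]); no missing values allowed.
#' @param labels Character vector of `"poor"`/`"good"`, one per row.
#' @param alpha Retention threshold on the Wald P value (default 0.05).
#' @param cutoff Classification cutoff stored with the model (default
#'   -1.480; see [choose_cutoff()] to refit it).
#' @return An `ipre_risk_model`: list with `intercept`, `coefficients`
#'   (named, retained covariates only), `cutoff`, `alpha`, `trace`
#'   (data frame of removals) and `summary` (coefficient table of the final
#'   fit: estimate, std. error, z, P).
#' @export
fit_risk_model <- function(covariates, labels, alpha = 0.05,
                           cutoff = -1.480) {
  covariates <- as.data.frame(covariates)
  if (anyNA(covariates))
    stop("missing values among candidate covariates; impute or drop first")
  y <- as.integer(labels == "poor")
  if (sum(y) < 2L || sum(1 - y) < 2L)
    stop("need at least 2 samples per prognosis class")

  # collinearity check on the candidate design
  x <- as.matrix(covariates)
  cons <- apply(x, 2L, function(col) max(col) == min(col))
  if (any(cons))
    stop("constant covariate(s): ", paste(names(covariates)[cons], collapse = ", "))
  cm <- suppressWarnings(stats::cor(x))
  diag(cm) <- 0
  if (any(abs(cm) > 1 - 1e-10, na.rm = TRUE)) {
    idx <- which(abs(cm) > 1 - 1e-10, arr.ind = TRUE)[1L, ]
    stop("collinear covariates: ", colnames(cm)[idx[1L]], " and ",
         colnames(cm)[idx[2L]])
  }

  vars <- names(covariates)
  trace <- data.frame(variable = character(0), p_value = numeric(0),
                      stringsAsFactors = FALSE)
  repeat {
    dat <- data.frame(.y = y, covariates[, vars, drop = FALSE])
    fml <- if (length(vars)) stats::as.formula(
      paste(".y ~", paste(vars, collapse = " + "))) else stats::as.formula(".y ~ 1")
    fit <- suppressWarnings(stats::glm(fml, family = stats::binomial(),
                                       data = dat))
    if (length(vars) && fit$deviance < 1e-6)
      stop("perfect separation detected: the maximum-likelihood coefficients ",
           "diverge; reduce covariates or use more samples")
    coefs <- summary(fit)$coefficients
    pv_rows <- setdiff(rownames(coefs), "(Intercept)")
    pvals <- stats::setNames(coefs[pv_rows, 4L], pv_rows)
    if (length(vars) == 0L || all(pvals <= alpha)) break
    worst <- names(which.max(pvals))
    trace <- rbind(trace, data.frame(variable = worst,
                                     p_value = unname(max(pvals)),
                                     stringsAsFactors = FALSE))
    vars <- setdiff(vars, worst)
  }

  beta <- stats::coef(fit)
  structure(list(intercept = unname(beta["(Intercept)"]),
                 coefficients = beta[setdiff(names(beta), "(Intercept)")],
                 retained = vars,
                 cutoff = cutoff,
                 alpha = alpha,
                 trace = trace,
                 summary = coefs),
            class = "ipre_risk_model")
}

#' The published risk-score preset
#'
#' The risk-score formula of the published model, fitted on 1,794 balanced
#' training samples: `RS = -0.99475 - 0.34534 X2 - 0.19854 X3 - 0.21123 X4 -
#' 1.13115 X6` (tumour size, ER, PR and mScore retained; grade and HER2
#' eliminated), classified at the cutoff -1.480.
#'
#' @return An `ipre_risk_model` ready for [risk_score()] and
#'   [classify_risk()].
#' @export
#' @examples
#' m <- ipre_2014()
#' rs <- risk_score(m, data.frame(x2_size = 0, x3_er = 1, x4_pr = 1,
#'                                x6_mscore = 1))
#' classify_risk(rs, m$cutoff)  # "good"
ipre_2014 <- function() {
  structure(list(intercept = -0.99475,
                 coefficients = c(x2_size = -0.34534, x3_er = -0.19854,
                                  x4_pr = -0.21123, x6_mscore = -1.13115),
                 retained = c("x2_size", "x3_er", "x4_pr", "x6_mscore"),
                 cutoff = -1.480,
                 alpha = 0.05,
                 trace = data.frame(variable = c("x1_grade", "x5_her2"),
                                    p_value = c(0.50, 0.08),
                                    stringsAsFactors = FALSE),
                 summary = NULL),
            class = "ipre_risk_model")
}

#' @export
print.ipre_risk_model <- function(x, ...) {
  cat("ipre_risk_model: RS =", format(x$intercept))
  for (v in names(x$coefficients))
    cat(sprintf(" %s %s*%s", ifelse(x$coefficients[[v]] < 0, "-", "+"),
                format(abs(x$coefficients[[v]])), v))
  cat("\n  cutoff:", x$cutoff, "(RS >= cutoff => poor)\n")
  invisible(x)
}

#' Risk score of encoded samples
#'
#' `RS = beta0 + sum(beta_n * X_n)` over the model's retained covariates.
#'
#' @param model An `ipre_risk_model`.
#' @param covariates Data frame of encoded covariates containing every
#'   retained variable (extra columns ignored).
#' @return Numeric vector of risk scores, one per row.
#' @export
risk_score <- function(model, covariates) {
  covariates <- as.data.frame(covariates)
  need <- names(model$coefficients)
  missing_vars <- setdiff(need, names(covariates))
  if (length(missing_vars))
    stop("missing retained covariate(s): ", paste(missing_vars, collapse = ", "))
  x <- as.matrix(covariates[, need, drop = FALSE])
  if (anyNA(x))
    stop("missing values in retained covariate(s)")
  rs <- as.vector(model$intercept + x %*% model$coefficients)
  names(rs) <- rownames(covariates)
  rs
}

#' Classify risk scores at a cutoff
#'
#' Poor prognosis if and only if `rs >= epsilon` (the boundary value itself
#' is poor).
#'
#' @param rs Numeric risk scores.
#' @param epsilon Cutoff (default -1.480, the published value).
#' @return Character vector of `"poor"`/`"good"`.
#' @export
classify_risk <- function(rs, epsilon = -1.480) {
  out <- ifelse(rs >= epsilon, "poor", "good")
  names(out) <- names(rs)
  out
}

#' Choose the risk-score cutoff maximizing the F-value
#'
#' Scans candidate cutoffs over `[min(rs), max(rs)]` on a regular grid and
#' returns the one maximizing the F-value (the F1 score, the harmonic mean
#' of precision and sensitivity, with poor prognosis as the positive
#' class). Ties go to the cutoff with higher specificity, then to the
#' smaller cutoff.
#'
#' @param rs Numeric risk scores.
#' @param labels True labels, `"poor"`/`"good"`.
#' @param grid_step Grid resolution (default 0.001).
#' @return List with `epsilon`, `f_value`, `sensitivity`, `specificity`.
#' @export
choose_cutoff <- function(rs, labels, grid_step = 0.001) {
  y <- labels == "poor"
  if (all(y) || !any(y)) stop("both prognosis classes must be present")
  grid <- seq(min(rs), max(rs), by = grid_step)
  if (grid[length(grid)] < max(rs)) grid <- c(grid, max(rs))
  best <- NULL
  for (eps in grid) {
    pred <- rs >= eps
    tp <- sum(pred & y); fp <- sum(pred & !y); fn <- sum(!pred & y)
    tn <- sum(!pred & !y)
    f <- if (tp == 0) 0 else 2 * tp / (2 * tp + fp + fn)
    sp <- tn / (tn + fp)
    if (is.null(best) || f > best$f_value + 1e-12 ||
        (abs(f - best$f_value) <= 1e-12 && sp > best$specificity + 1e-12)) {
      best <- list(epsilon = eps, f_value = f,
                   sensitivity = tp / (tp + fn), specificity = sp)
    }
  }
  best
}

#' Serialize a risk model to JSON and back
#'
#' The JSON file holds the intercept, retained coefficients, cutoff,
#' retention threshold and elimination trace, so a fitted model is reusable
#' as a preset.
#'
#' @param model An `ipre_risk_model`.
#' @param path File path.
#' @export
write_risk_model <- function(model, path) {
  obj <- list(intercept = model$intercept,
              coefficients = as.list(model$coefficients),
              cutoff = model$cutoff,
              alpha = model$alpha,
              trace = model$trace)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       dataframe = "rows", pretty = TRUE)
  invisible(path)
}

#' @rdname write_risk_model
#' @export
read_risk_model <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  structure(list(intercept = obj$intercept,
                 coefficients = unlist(obj$coefficients),
                 retained = names(unlist(obj$coefficients)),
                 cutoff = obj$cutoff,
                 alpha = obj$alpha,
                 trace = if (length(obj$trace)) as.data.frame(obj$trace)
                         else data.frame(variable = character(0),
                                         p_value = numeric(0)),
                 summary = NULL),
            class = "ipre_risk_model")
}
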