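#' Configuration for synthetic multi-platform cohorts
#'
#' Describes the simulated study: a number of cohorts ("platforms") carrying
#' overlapping but unequal gene subsets, a block of planted prognostic genes
#' whose expression shifts between prognosis groups on the normalized scale,
#' clinical covariates whose encoded values drive the outcome through a
#' logistic model, and the receptor reporter genes `ESR1`/`PGR` so that
#' missing ER/PR statuses can be imputed from expression.
#'
#' @param n_cohorts Number of cohorts (default 3).
#' @param n_samples Samples per cohort (default 300).
#' @param n_genes Genes in the universe, including the planted block and
#'   the two receptor reporters (default 1000).
#' @param n_prognostic Planted prognostic genes (default 50).
#' @param effect Between-group mean shift of planted genes on the
#'   normalized scale, in `[0, 1)`: poor-group mean `0.5 - effect/2`,
#'   good-group mean `0.5 + effect/2` (default 0.3).
#' @param noise_sd Within-group standard deviation before clipping to
#'   `[0, 1]` (default 0.15).
#' @param poor_fraction Target fraction of poor-prognosis samples; the
#'   logistic intercept is solved so the expected fraction matches
#'   (default 0.4).
#' @param clinical_effects Named log-odds contributions of the encoded
#'   clinical covariates to the poor outcome. The default leaves grade at 0
#'   (a deliberately null covariate for elimination tests).
#' @param missing_rate Fraction of samples with ER and PR status masked to
#'   missing (default 0.1).
#' @param censored_fraction Extra censored decoy samples (follow-up ending
#'   before 5 years without an event) as a fraction of `n_samples`; they
#'   exercise label exclusion (default 0.05).
#' @param dropout_fraction Fraction of null genes absent from each cohort
#'   (disjoint slices), so gene-set intersection is exercised (default 0.05).
#' @param seed Integer seed; the whole simulation is reproducible under it.
#' @return A validated `ipre_sim_config` list.
#' @export
sim_config <- function(n_cohorts = 3, n_samples = 300, n_genes = 1000,
                       n_prognostic = 50, effect = 0.3, noise_sd = 0.15,
                       poor_fraction = 0.4,
                       clinical_effects = c(grade = 0, size = 0.8,
                                            er = -0.5, pr = -0.4,
                                            her2 = 0.3),
                       missing_rate = 0.1, censored_fraction = 0.05,
                       dropout_fraction = 0.05, seed = 20140514) {
  cfg <- list(n_cohorts = as.integer(n_cohorts),
              n_samples = as.integer(n_samples),
              n_genes = as.integer(n_genes),
              n_prognostic = as.integer(n_prognostic),
              effect = effect, noise_sd = noise_sd,
              poor_fraction = poor_fraction,
              clinical_effects = clinical_effects,
              missing_rate = missing_rate,
              censored_fraction = censored_fraction,
              dropout_fraction = dropout_fraction,
              seed = as.integer(seed))
  if (cfg$n_cohorts < 1L || cfg$n_samples < 10L)
    stop("need at least one cohort of at least 10 samples")
  if (cfg$n_prognostic > cfg$n_genes - 2L)
    stop("n_prognostic must leave room for null genes and the receptor reporters")
  if (cfg$poor_fraction <= 0 || cfg$poor_fraction >= 1)
    stop("poor_fraction must lie strictly between 0 and 1")
  if (cfg$effect < 0 || cfg$effect >= 1)
    stop("effect must lie in [0, 1)")
  if (cfg$noise_sd <= 0 || cfg$effect + 2 * cfg$noise_sd > 1)
    stop("infeasible effect/noise: effect + 2*noise_sd must stay within [0, 1]")
  if (!all(c("grade", "size", "er", "pr", "her2") %in% names(cfg$clinical_effects)))
    stop("clinical_effects needs entries grade, size, er, pr, her2")
  structure(cfg, class = "ipre_sim_config")
}

#' Simulate labeled multi-platform cohorts with planted prognostic genes
#'
#' For each cohort, clinical covariates are drawn from realistic breast
#' cancer marginals (grade I/II/III at 0.30/0.45/0.25; tumour size
#' log-normal around 2.2 cm; ER+/PR+/HER2+ at 0.70/0.60/0.20), the poor
#' outcome is drawn from a logistic model on the encoded covariates with
#' the intercept solved numerically to hit `poor_fraction`, time to
#' progression is drawn uniform on `(0, 5]` with an event for poor samples
#' and uniform on `(5, 12]` for good samples (with a late event with
#' probability 0.25 so both survival arms carry events), and expression is
#' drawn as Gaussian around the group means with clipping to `[0, 1]`.
#' Receptor reporter genes track the true ER/PR status so masked statuses
#' are imputable. Each cohort omits a disjoint slice of the null genes so
#' the gene sets overlap without being equal.
#'
#' @param cfg An [sim_config()].
#' @return List with `cohorts` (list of labeled [cohort()]s) and `truth`:
#'   `prognostic_genes`, `coefficients` (the generating log-odds),
#'   `intercepts` (solved per cohort), `labels` (named by integrated
#'   `cohort:sample` ids), `clip_rate`.
#' @export
simulate_cohorts <- function(cfg = sim_config()) {
  if (!inherits(cfg, "ipre_sim_config")) cfg <- do.call(sim_config, cfg)
  set.seed(cfg$seed)

  n_null <- cfg$n_genes - cfg$n_prognostic - 2L
  sig_genes <- sprintf("SIG%04d", seq_len(cfg$n_prognostic))
  null_genes <- sprintf("G%05d", seq_len(n_null))
  eff <- cfg$clinical_effects

  cohorts <- vector("list", cfg$n_cohorts)
  truth_labels <- character(0)
  intercepts <- numeric(cfg$n_cohorts)
  clipped <- total <- 0

  for (ci in seq_len(cfg$n_cohorts)) {
    cid <- sprintf("cohort%d", ci)
    n_cens <- round(cfg$censored_fraction * cfg$n_samples)
    n <- cfg$n_samples + n_cens

    grade <- sample(c("I", "II", "III"), n, TRUE, prob = c(0.30, 0.45, 0.25))
    size_cm <- round(stats::rlnorm(n, log(2.2), 0.45), 1)
    er <- ifelse(stats::runif(n) < 0.70, "positive", "negative")
    pr <- ifelse(stats::runif(n) < 0.60, "positive", "negative")
    her2 <- ifelse(stats::runif(n) < 0.20, "positive", "negative")

    enc <- encode_clinical(data.frame(grade = grade, size_cm = size_cm,
                                      er = er, pr = pr, her2 = her2))
    lp <- eff[["grade"]] * enc$x1_grade + eff[["size"]] * enc$x2_size +
      eff[["er"]] * enc$x3_er + eff[["pr"]] * enc$x4_pr +
      eff[["her2"]] * enc$x5_her2
    b0 <- stats::uniroot(function(b) mean(stats::plogis(b + lp)) - cfg$poor_fraction,
                         c(-20, 20))$root
    intercepts[ci] <- b0
    poor <- stats::runif(n) < stats::plogis(b0 + lp)

    ttp <- ifelse(poor, stats::runif(n, 0.02, 5), stats::runif(n, 5.02, 12))
    event <- ifelse(poor, TRUE, stats::runif(n) < 0.25)
    # censored decoys: follow-up ends before the horizon, no event
    if (n_cens > 0L) {
      idx <- seq.int(cfg$n_samples + 1L, n)
      ttp[idx] <- stats::runif(n_cens, 0.1, 4.9)
      event[idx] <- FALSE
    }

    # overlapping but unequal gene subsets: drop a disjoint null-gene slice
    n_drop <- round(cfg$dropout_fraction * n_null)
    drop_idx <- if (n_drop > 0L)
      ((ci - 1L) * n_drop + seq_len(n_drop) - 1L) %% n_null + 1L
    else integer(0)
    genes <- c("ESR1", "PGR", sig_genes, null_genes[setdiff(seq_len(n_null), drop_idx)])

    mu <- matrix(0.5, length(genes), n, dimnames = list(genes, NULL))
    shift <- cfg$effect / 2
    mu[sig_genes, ] <- rep(ifelse(poor, 0.5 - shift, 0.5 + shift),
                           each = length(sig_genes))
    mu["ESR1", ] <- ifelse(er == "positive", 0.65, 0.35)
    mu["PGR", ] <- ifelse(pr == "positive", 0.65, 0.35)
    raw <- mu + stats::rnorm(length(mu), 0, cfg$noise_sd)
    clipped <- clipped + sum(raw < 0 | raw > 1)
    total <- total + length(raw)
    expr <- pmin(1, pmax(0, raw))
    dim(expr) <- dim(mu)
    rownames(expr) <- genes
    colnames(expr) <- sprintf("s%03d", seq_len(n))

    miss <- stats::runif(n) < cfg$missing_rate
    er_obs <- ifelse(miss, NA_character_, er)
    pr_obs <- ifelse(miss, NA_character_, pr)

    clin <- data.frame(sample_id = colnames(expr), ttp_years = ttp,
                       event = event, er = er_obs, pr = pr_obs,
                       her2 = her2, grade = grade, size_cm = size_cm,
                       cohort_id = cid, stringsAsFactors = FALSE)
    cohorts[[ci]] <- suppressWarnings(cohort(expr, clin))
    lab <- ifelse(poor, "poor", "good")[seq_len(cfg$n_samples)]
    truth_labels <- c(truth_labels, stats::setNames(
      lab, paste(cid, colnames(expr)[seq_len(cfg$n_samples)], sep = ":")))
  }

  list(cohorts = cohorts,
       truth = list(prognostic_genes = sig_genes,
                    coefficients = eff,
                    intercepts = intercepts,
                    labels = truth_labels,
                    clip_rate = clipped / total))
}
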