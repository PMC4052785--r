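# Shared fixtures and independent oracles for the test suite.

# Tiny labeled cohort built by hand: 3 genes x 6 samples, 3 poor / 3 good.
make_toy_cohort <- function() {
  expr <- rbind(
    gA = c(0.1, 0.2, 0.3, 0.8, 0.9, 0.7),  # concordant with outcome
    gB = c(0.9, 0.8, 0.6, 0.2, 0.1, 0.3),  # anti-concordant
    gC = c(0.4, 0.6, 0.5, 0.5, 0.4, 0.6)   # uninformative
  )
  colnames(expr) <- paste0("s", 1:6)
  clin <- data.frame(sample_id = paste0("s", 1:6),
                     ttp_years = c(2, 3, 4, 7, 8, 9),
                     event = c(TRUE, TRUE, TRUE, FALSE, FALSE, FALSE),
                     er = "positive", pr = "positive", her2 = "negative",
                     grade = "II", size_cm = 2.5, cohort_id = "toy",
                     stringsAsFactors = FALSE)
  cohort(expr, clin)
}

# Random labeled cohort with expression already in [0, 1].
random_cohort <- function(n_genes, n_samples, seed, cohort_id = "rnd") {
  set.seed(seed)
  n_poor <- max(1L, rbinom(1L, n_samples - 2L, 0.5) + 1L)
  poor <- seq_len(n_samples) <= n_poor
  expr <- matrix(runif(n_genes * n_samples), n_genes, n_samples,
                 dimnames = list(sprintf("g%03d", seq_len(n_genes)),
                                 sprintf("%s_s%03d", cohort_id, seq_len(n_samples))))
  clin <- data.frame(sample_id = colnames(expr),
                     ttp_years = ifelse(poor, runif(n_samples, 0.1, 5),
                                        runif(n_samples, 5.1, 12)),
                     event = poor | runif(n_samples) < 0.3,
                     cohort_id = cohort_id, stringsAsFactors = FALSE)
  cohort(expr, clin)
}

# Straight-from-the-formula VC scoring oracle: plain loops, no shared code
# with score_genes beyond the published formulas.
oracle_vc <- function(expr, ttp, labels, tau1 = 1, tau2 = -1.0011) {
  out <- data.frame(gene = rownames(expr), alpha = NA_real_, beta = NA_real_,
                    vc = NA_real_, stringsAsFactors = FALSE)
  for (i in seq_len(nrow(expr))) {
    p <- 0L; q <- 0L
    for (j in seq_len(ncol(expr))) {
      e <- expr[i, j]
      cc <- if ((ttp[j] <= 5 && e < 0.5) || (ttp[j] > 5 && e >= 0.5)) 1L else -1L
      if (cc == 1L) p <- p + 1L else q <- q + 1L
    }
    a <- (p - q) / ncol(expr)
    m1 <- mean(expr[i, labels == "poor"])
    m2 <- mean(expr[i, labels == "good"])
    b <- 1 - abs(m1 - m2)
    out$alpha[i] <- a; out$beta[i] <- b
    out$vc[i] <- tau1 * a + tau2 * b
  }
  out
}

# Exhaustive prefix oracle for signature selection.
oracle_best_prefix <- function(vc_values, exponent = 0.5) {
  best_m <- 1L; best_r <- -Inf
  srt <- sort(vc_values, decreasing = TRUE)
  for (m in seq_along(srt)) {
    r <- sum(srt[1:m]) / m^exponent
    if (r > best_r) { best_r <- r; best_m <- m }
  }
  list(m_star = best_m, r_max = best_r)
}

# Exhaustive threshold oracle for the F-value-maximizing cutoff.
oracle_best_f <- function(rs, labels) {
  y <- labels == "poor"
  srt <- sort(unique(rs))
  cands <- c(srt[1] - 1, (srt[-1] + srt[-length(srt)]) / 2, srt,
             srt[length(srt)] + 1)
  best <- -Inf
  for (eps in cands) {
    tp <- sum(rs >= eps & y); fp <- sum(rs >= eps & !y); fn <- sum(rs < eps & y)
    f <- if (tp == 0) 0 else 2 * tp / (2 * tp + fp + fn)
    if (f > best) best <- f
  }
  best
}

# O(n^2) pairwise concordance oracle for the AUC.
oracle_auc <- function(scores, labels) {
  pos <- scores[labels == "poor"]; neg <- scores[labels == "good"]
  tot <- 0
  for (a in pos) for (b in neg)
    tot <- tot + if (a > b) 1 else if (a == b) 0.5 else 0
  tot / (length(pos) * length(neg))
}

# Round half away from zero at d decimals (printed-table convention).
round_half_away <- function(x, d) sign(x) * floor(abs(x) * 10^d + 0.5) / 10^d

# Two-decimal print of the benchmark tables: values pass through a
# three-decimal representation before the final two-decimal rounding.
round_printed_ci <- function(x) round_half_away(round_half_away(x, 3), 2)
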