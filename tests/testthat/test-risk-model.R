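test_that("clinical variables encode to the model's codes", {
  clin <- data.frame(sample_id = "s1", grade = "III", size_cm = 2.5,
                     er = "positive", pr = "positive", her2 = "negative")
  enc <- encode_clinical(clin, c(s1 = 0.6))
  expect_equal(unlist(enc),
               c(x1_grade = 1, x2_size = 0.55, x3_er = 1, x4_pr = 1,
                 x5_her2 = -1, x6_mscore = 0.6))

  # size bins: < 2 -> 0; [2, 4) -> 0.55 (the middle bin absorbs 3-4 cm); >= 4 -> 1
  sizes <- data.frame(size_cm = c(1.9, 2.0, 3.0, 3.5, 3.99, 4.0, 7.5))
  expect_equal(encode_clinical(sizes)$x2_size,
               c(0, 0.55, 0.55, 0.55, 0.55, 1, 1))

  # grade I and II share code 0
  grades <- data.frame(grade = c("I", "II", "III", NA))
  expect_equal(encode_clinical(grades)$x1_grade, c(0, 0, 1, NA))

  # missing values propagate as NA
  enc <- encode_clinical(data.frame(er = NA, size_cm = NA))
  expect_true(is.na(enc$x3_er) && is.na(enc$x2_size))

  expect_error(encode_clinical(data.frame(grade = "I"), mscore = 1.2), "\\[0, 1\\]")
})

test_that("missing receptor statuses are imputed from dichotomized expression", {
  expr <- rbind(ESR1 = c(0.8, 0.9, 0.5, 0.2), PGR = c(0.3, 0.6, 0.7, 0.4))
  colnames(expr) <- paste0("s", 1:4)
  clin <- data.frame(sample_id = paste0("s", 1:4),
                     er = c(NA, "negative", NA, NA),
                     pr = c(NA, NA, "positive", NA),
                     stringsAsFactors = FALSE)
  out <- impute_receptor(expr, clin)
  expect_equal(out$er, c("positive",   # ESR1 = 0.8 >= 0.5
                         "negative",   # recorded status never overridden
                         "positive",   # boundary 0.5 counts as overexpressed
                         "negative"))  # ESR1 = 0.2
  expect_equal(out$pr, c("negative", "positive", "positive", "negative"))

  # receptor gene absent: status stays missing, sample flagged
  out2 <- impute_receptor(expr[2L, , drop = FALSE], clin)
  expect_true(is.na(out2$er[1L]))
  expect_true("s1" %in% attr(out2, "unimputable"))
})

test_that("the published preset reproduces the printed risk-score arithmetic", {
  m <- ipre_2014()
  rs1 <- risk_score(m, data.frame(x2_size = 0, x3_er = 1, x4_pr = 1, x6_mscore = 1))
  expect_equal(unname(rs1), -2.53567)
  expect_equal(unname(classify_risk(rs1)), "good")

  rs2 <- risk_score(m, data.frame(x2_size = 1, x3_er = -1, x4_pr = -1, x6_mscore = 0))
  expect_equal(unname(rs2), -0.93032)
  expect_equal(unname(classify_risk(rs2)), "poor")

  # all-zero covariates give the intercept; the cutoff boundary is poor
  rs0 <- risk_score(m, data.frame(x2_size = 0, x3_er = 0, x4_pr = 0, x6_mscore = 0))
  expect_equal(unname(rs0), m$intercept)
  expect_equal(unname(classify_risk(-1.480)), "poor")
  expect_equal(unname(classify_risk(-1.4801)), "good")

  # lower signature expression means higher risk (mScore coefficient < 0)
  lo <- risk_score(m, data.frame(x2_size = 0.55, x3_er = 1, x4_pr = 1, x6_mscore = 0.2))
  hi <- risk_score(m, data.frame(x2_size = 0.55, x3_er = 1, x4_pr = 1, x6_mscore = 0.8))
  expect_gt(lo, hi)

  expect_error(risk_score(m, data.frame(x2_size = 0)), "missing retained")
})

test_that("backward elimination drops noise covariates and keeps significant ones", {
  set.seed(42)
  n <- 2000
  cov <- data.frame(x1_grade = rbinom(n, 1, 0.4),
                    x2_size = sample(c(0, 0.55, 1), n, TRUE),
                    x3_er = sample(c(-1, 1), n, TRUE),
                    x6_mscore = runif(n))
  lp <- -0.3 + 0 * cov$x1_grade + 0.9 * cov$x2_size - 0.6 * cov$x3_er -
    1.5 * cov$x6_mscore
  labels <- ifelse(runif(n) < plogis(lp), "poor", "good")
  model <- fit_risk_model(cov, labels)
  expect_true("x1_grade" %in% model$trace$variable)   # pure-noise covariate removed
  expect_setequal(model$retained, c("x2_size", "x3_er", "x6_mscore"))
  expect_true(all(model$summary[model$retained, 4L] <= 0.05))
  expect_lte(nrow(model$trace), ncol(cov))
})

test_that("coefficients of a known generating model are recovered within 3 SE", {
  set.seed(7)
  n <- 5000
  truth <- c(x1_grade = 0.6, x2_size = -0.7, x3_er = 0.35, x4_pr = -0.45,
             x6_mscore = -1.2)
  cov <- data.frame(x1_grade = rbinom(n, 1, 0.35),
                    x2_size = sample(c(0, 0.55, 1), n, TRUE),
                    x3_er = sample(c(-1, 1), n, TRUE, prob = c(0.3, 0.7)),
                    x4_pr = sample(c(-1, 1), n, TRUE, prob = c(0.4, 0.6)),
                    x6_mscore = runif(n))
  lp <- -0.4 + as.matrix(cov) %*% truth
  labels <- ifelse(runif(n) < plogis(lp), "poor", "good")
  model <- fit_risk_model(cov, labels)
  expect_setequal(model$retained, names(truth))
  for (v in names(truth)) {
    est <- model$coefficients[[v]]
    se <- model$summary[v, 2L]
    expect_lt(abs(est - truth[[v]]), 3 * se)
  }
})

test_that("labels independent of all covariates leave an intercept-only model", {
  set.seed(11)
  n <- 600
  cov <- data.frame(x2_size = sample(c(0, 0.55, 1), n, TRUE),
                    x3_er = sample(c(-1, 1), n, TRUE),
                    x6_mscore = runif(n))
  labels <- sample(c("poor", "good"), n, TRUE)
  model <- fit_risk_model(cov, labels)
  expect_length(model$retained, 0L)
  expect_length(model$coefficients, 0L)
  expect_equal(sort(model$trace$variable), sort(names(cov)))
})

test_that("degenerate fits fail loudly", {
  # perfect separation
  cov <- data.frame(x6_mscore = c(0.1, 0.2, 0.3, 0.7, 0.8, 0.9))
  labels <- c("poor", "poor", "poor", "good", "good", "good")
  expect_error(fit_risk_model(cov, labels), "separation")

  # collinear pair named in the error
  set.seed(3)
  cov <- data.frame(x3_er = sample(c(-1, 1), 50, TRUE), x6_mscore = runif(50))
  cov$x4_pr <- cov$x3_er
  labels <- sample(c("poor", "good"), 50, TRUE)
  err <- tryCatch(fit_risk_model(cov, labels), error = conditionMessage)
  expect_match(err, "collinear")
  expect_match(err, "x3_er"); expect_match(err, "x4_pr")

  expect_error(fit_risk_model(data.frame(x6_mscore = c(NA, 1)), c("poor", "good")),
               "missing")
})

test_that("the cutoff search maximizes the F-value with the stated tie rules", {
  # separable scores reach F = 1
  rs <- c(-2, -1.5, -1.2, 0.3, 0.8, 1.1)
  labels <- c("good", "good", "good", "poor", "poor", "poor")
  best <- choose_cutoff(rs, labels)
  expect_equal(best$f_value, 1)
  expect_gt(best$epsilon, -1.2); expect_lte(best$epsilon, 0.3)

  # identical scores: F equals the all-poor prediction
  rs_const <- rep(0.4, 6)
  best <- choose_cutoff(rs_const, labels)
  tp <- 3; fp <- 3; fn <- 0
  expect_equal(best$f_value, 2 * tp / (2 * tp + fp + fn))

  # exhaustive midpoint oracle on random instances (n <= 50)
  for (seed in 301:305) {
    set.seed(seed)
    n <- sample(8:50, 1)
    rs <- round(rnorm(n), 2)
    labels <- ifelse(runif(n) < plogis(rs), "poor", "good")
    if (length(unique(labels)) < 2L) next
    best <- choose_cutoff(rs, labels, grid_step = 0.001)
    expect_equal(best$f_value, oracle_best_f(rs, labels), tolerance = 1e-9)
  }

  expect_error(choose_cutoff(c(1, 2), c("poor", "poor")), "both")
})

test_that("fitted models survive a JSON round trip", {
  dir <- withr::local_tempdir()
  set.seed(5)
  n <- 400
  cov <- data.frame(x2_size = sample(c(0, 0.55, 1), n, TRUE),
                    x6_mscore = runif(n))
  lp <- -0.2 + 0.9 * cov$x2_size - 1.4 * cov$x6_mscore
  labels <- ifelse(runif(n) < plogis(lp), "poor", "good")
  model <- fit_risk_model(cov, labels)
  path <- file.path(dir, "model.json")
  write_risk_model(model, path)
  back <- read_risk_model(path)
  expect_equal(back$intercept, model$intercept)
  expect_equal(back$coefficients, model$coefficients)
  expect_equal(back$cutoff, model$cutoff)
  expect_equal(risk_score(back, cov), risk_score(model, cov))

  # the shipped preset also round-trips
  write_risk_model(ipre_2014(), path)
  pre <- read_risk_model(path)
  expect_equal(pre$coefficients, ipre_2014()$coefficients)
})
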