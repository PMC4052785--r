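test_that("probe collapsing averages multi-probe genes and drops controls", {
  m <- rbind(p1 = c(0.2, 0.6), p2 = c(0.4, 0.8), p3 = c(0.5, 0.5),
             "AFFX-ctrl" = c(9, 9), orphan = c(1, 1))
  colnames(m) <- c("s1", "s2")
  map <- data.frame(probe_id = c("p1", "p2", "p3"),
                    gene_symbol = c("G1", "G1", "G2"))
  out <- collapse_probes(m, map)

  expect_equal(sort(rownames(out)), c("G1", "G2"))
  expect_equal(unname(out["G1", ]), c(0.3, 0.7))          # mean of p1, p2
  expect_equal(unname(out["G2", ]), c(0.5, 0.5))          # single probe passthrough
  expect_equal(attr(out, "dropped_affx"), "AFFX-ctrl")
  expect_equal(attr(out, "dropped_unmapped"), "orphan")

  only_ctrl <- m[4L, , drop = FALSE]
  expect_error(collapse_probes(only_ctrl, map), "no probe maps")
})

test_that("min-max normalization maps rows onto [0,1] and flags constants", {
  m <- rbind(a = c(1, 3, 5), b = c(2, 2, 2), c = c(0, 1, 0.5))
  colnames(m) <- c("s1", "s2", "s3")
  out <- minmax_normalize(m)
  expect_equal(unname(out["a", ]), c(0, 0.5, 1))
  expect_equal(unname(out["b", ]), c(0, 0, 0))
  expect_equal(attr(out, "constant_genes"), "b")
  expect_equal(unname(out["c", ]), c(0, 1, 0.5))  # already normalized row unchanged

  bad <- m; bad["a", "s2"] <- NA
  expect_error(minmax_normalize(bad), "gene 'a'.*sample 's2'")
})

test_that("normalization is idempotent on non-constant matrices", {
  for (seed in 1:5) {
    set.seed(seed)
    m <- matrix(rnorm(60), 6, 10,
                dimnames = list(paste0("g", 1:6), paste0("s", 1:10)))
    once <- minmax_normalize(m)
    twice <- minmax_normalize(once)
    expect_equal(unclass(twice), unclass(once), tolerance = 1e-12)
    expect_true(all(apply(once, 1, min) == 0) && all(apply(once, 1, max) == 1))
  }
})

test_that("prognosis labels follow the 5-year rule and exclude early-censored samples", {
  clin <- data.frame(sample_id = c("a", "b", "c", "d", "e"),
                     ttp_years = c(3, 7, 4, 5, NA),
                     event = c(TRUE, FALSE, FALSE, TRUE, TRUE))
  expect_warning(expect_warning(assign_labels(clin), "censored"), "missing")
  labels <- suppressWarnings(assign_labels(clin))
  expect_equal(labels[["a"]], "poor")          # event within horizon
  expect_equal(labels[["b"]], "good")          # progression-free beyond horizon
  expect_equal(labels[["d"]], "poor")          # ttp = 5 boundary counts as poor
  expect_setequal(attr(labels, "excluded"), c("c", "e"))

  # partition: every retained sample gets exactly one label
  for (seed in 1:3) {
    co <- random_cohort(3, 40, seed)
    lab <- suppressWarnings(assign_labels(co$clinical))
    expect_true(all(lab %in% c("poor", "good")))
    expect_equal(sort(c(names(lab), attr(lab, "excluded"))),
                 sort(co$clinical$sample_id))
  }
})

test_that("integration intersects genes, keeps values and prefixes sample ids", {
  co1 <- random_cohort(6, 4, 11, "c1")
  co2 <- random_cohort(6, 3, 12, "c2")
  rownames(co2$expr)[1L] <- "zzz"   # gene unique to cohort 2
  out <- integrate_cohorts(list(co1, co2))

  common <- sort(intersect(rownames(co1$expr), rownames(co2$expr)))
  expect_equal(rownames(out$expr), common)
  expect_equal(ncol(out$expr), 7L)
  expect_true(all(startsWith(colnames(out$expr)[1:4], "c1:")))
  expect_true(all(startsWith(colnames(out$expr)[5:7], "c2:")))
  # per-sample values preserved exactly
  for (g in common) {
    expect_identical(unname(out$expr[g, paste0("c1:", colnames(co1$expr))]),
                     unname(co1$expr[g, ]))
    expect_identical(unname(out$expr[g, paste0("c2:", colnames(co2$expr))]),
                     unname(co2$expr[g, ]))
  }
  # labels carried over
  expect_equal(unname(out$labels[paste0("c1:", names(co1$labels))]),
               unname(co1$labels), ignore_attr = TRUE)

  # single cohort is an identity apart from the id prefix
  solo <- integrate_cohorts(list(co1))
  expect_equal(rownames(solo$expr), sort(rownames(co1$expr)))
  expect_equal(unname(solo$expr[rownames(co1$expr), ]), unname(co1$expr))

  rownames(co2$expr) <- paste0("other", seq_len(nrow(co2$expr)))
  expect_error(integrate_cohorts(list(co1, co2)), "empty")
})

test_that("integration honours an exclusion list of overlapping samples", {
  co1 <- random_cohort(5, 4, 21, "c1")
  out <- integrate_cohorts(list(co1), exclude = colnames(co1$expr)[1L])
  expect_equal(ncol(out$expr), 3L)
  expect_false(paste0("c1:", colnames(co1$expr)[1L]) %in% colnames(out$expr))
})

test_that("balancing equalizes classes, keeps the minority whole, and is seeded", {
  n_poor <- 10L; n_good <- 50L; n <- n_poor + n_good
  ids <- sprintf("s%02d", seq_len(n))
  expr <- matrix(runif(4 * n), 4, n, dimnames = list(paste0("g", 1:4), ids))
  clin <- data.frame(sample_id = ids,
                     ttp_years = c(runif(n_poor, 1, 5), runif(n_good, 5.1, 12)),
                     event = c(rep(TRUE, n_poor), rep(FALSE, n_good)),
                     cohort_id = "b", stringsAsFactors = FALSE)
  co <- cohort(expr, clin)
  minority <- names(co$labels)[co$labels == "poor"]

  b1 <- balance_cohort(co, seed = 5L)
  expect_equal(sum(b1$labels == "poor"), sum(b1$labels == "good"))
  expect_equal(length(b1$labels), 2L * n_poor)
  expect_true(all(minority %in% names(b1$labels)))

  b2 <- balance_cohort(co, seed = 5L)
  expect_identical(colnames(b1$expr), colnames(b2$expr))
  b3 <- balance_cohort(co, seed = 6L)
  expect_false(identical(colnames(b1$expr), colnames(b3$expr)))

  # already balanced cohort passes through unchanged
  ids <- c(names(co$labels)[co$labels == "poor"][1:5],
           names(co$labels)[co$labels == "good"][1:5])
  small <- cohort(co$expr[, ids], co$clinical[co$clinical$sample_id %in% ids, ])
  expect_setequal(colnames(balance_cohort(small, 1L)$expr), ids)
})

test_that("expression and clinical tables round-trip through TSV", {
  dir <- withr::local_tempdir()
  co <- random_cohort(5, 4, 41)
  ep <- file.path(dir, "e.tsv"); cp <- file.path(dir, "c.tsv")
  write_expression_tsv(co$expr, ep)
  write_clinical_tsv(co$clinical, cp)
  expect_equal(read_expression_tsv(ep), co$expr, tolerance = 1e-12)
  clin <- read_clinical_tsv(cp)
  expect_equal(clin$sample_id, co$clinical$sample_id)
  expect_equal(clin$ttp_years, co$clinical$ttp_years, tolerance = 1e-12)
  expect_equal(clin$event, co$clinical$event)
})
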