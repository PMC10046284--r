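make_scores <- function(patient, tumor, bg, biomarker = "TEM1", sd = 30) {
  tibble::tibble(
    sample_id = paste0("s", seq_along(patient)), patient_id = patient,
    biomarker = biomarker, tumor_mean = tumor, tumor_sd = sd,
    tumor_n = 100L, bg_mean = bg, bg_sd = sd / 2, bg_n = 100L,
    tbr = tumor / bg
  )
}

test_that("patient aggregation averages means and recomputes TBR", {
  single <- make_scores(1, 80, 40)
  agg <- aggregate_patient(single)
  expect_equal(agg$tumor_mean, 80)
  expect_equal(agg$tbr, 2)

  multi <- make_scores(c(1, 1), c(80, 90), c(40, 40))
  expect_equal(aggregate_patient(multi)$tumor_mean, 85)

  two <- make_scores(c(1, 1), c(60, 90), c(30, 30))
  expect_equal(aggregate_patient(two)$tbr, 2.5)

  # TBR is recomputed from averaged means, not averaged per-sample TBRs
  uneven <- make_scores(c(1, 1), c(60, 90), c(20, 60))
  expect_equal(aggregate_patient(uneven)$tbr, 75 / 40)
  expect_false(isTRUE(all.equal(aggregate_patient(uneven)$tbr,
                                mean(c(60 / 20, 90 / 60)))))

  mixed <- make_scores(c(1, 1), c(60, 90), c(30, 30),
                       biomarker = c("TEM1", "VEGFA"))
  expect_error(aggregate_patient(mixed), "across biomarkers")
})

test_that("aggregation is invariant to sample order", {
  sc <- make_scores(c(1, 1, 1, 2), c(60, 70, 95, 50), c(30, 25, 40, 20))
  a1 <- aggregate_patients(sc)
  a2 <- aggregate_patients(sc[c(3, 1, 4, 2), ])
  expect_equal(a1, a2)
})

test_that("biomarker summary counts TBR<1 cases and expression calls", {
  pats <- aggregate_patients(make_scores(1:3, c(45, 55, 80), c(50, 50, 40)))
  s <- summarize_biomarkers(pats)
  expect_equal(s$n_tbr_below_1, 1L)
  expect_equal(s$fraction_expressed, 1)
  expect_equal(s$mean_tumor_intensity, 60)

  one <- aggregate_patients(make_scores(1, 81, 81 / 3.1, sd = 39))
  s1 <- summarize_biomarkers(one)
  expect_equal(s1$mean_tumor_intensity, 81)
  expect_equal(s1$mean_tbr, 3.1)
  expect_equal(s1$mean_within_roi_sd, 39)

  low <- aggregate_patients(make_scores(1:4, c(5, 8, 12, 40), rep(10, 4)))
  expect_equal(summarize_biomarkers(low)$fraction_expressed, 0.5)
  expect_equal(summarize_biomarkers(low, expression_threshold = 4)$fraction_expressed, 1)
})

test_that("paired t-test matches the explicit-sum reference to 1e-10", {
  tum <- c(10, 12, 14, 16); bg <- c(8, 9, 11, 12)
  res <- paired_t(tum, bg)
  ref <- brute_paired_t(tum, bg)
  expect_lt(abs(res$statistic - ref$t), 1e-10)
  expect_lt(abs(res$p - ref$p), 1e-10)

  sym <- paired_t(c(1, -1), c(0, 0))
  expect_equal(sym$statistic, 0)
  expect_equal(sym$p, 1)

  set.seed(21)
  for (i in 1:20) {
    n <- sample(3:30, 1)
    x <- rnorm(n, 50, 20); y <- rnorm(n, 40, 15)
    res <- paired_t(x, y)
    ref <- brute_paired_t(x, y)
    expect_lt(abs(res$statistic - ref$t), 1e-10)
    expect_lt(abs(res$p - ref$p), 1e-10)
  }

  expect_error(paired_t(c(5, 6, 7), c(1, 2, 3)), "degenerate")
  expect_error(paired_t(5, 1), "at least 2")
  expect_error(paired_t(1:3, 1:2), "equal-length")
})

test_that("unpaired t-test matches the pooled-variance reference to 1e-10", {
  expect_equal(unpaired_t(c(1, 2, 3), c(1, 2, 3))$p, 1)
  expect_equal(unpaired_t(c(1, 2, 3), c(1, 2, 3))$statistic, 0)

  set.seed(22)
  for (i in 1:20) {
    a <- rnorm(sample(2:20, 1), 60, 25)
    b <- rnorm(sample(2:20, 1), 50, 25)
    res <- unpaired_t(a, b)
    ref <- brute_unpaired_t(a, b)
    expect_lt(abs(res$statistic - ref$t), 1e-10)
    expect_lt(abs(res$p - ref$p), 1e-10)
  }
  # Welch variant differs from the pooled test when variances differ
  a <- c(1, 2, 3, 10); b <- c(4, 4.5, 5)
  expect_false(isTRUE(all.equal(unpaired_t(a, b, equal_var = FALSE)$p,
                                unpaired_t(a, b)$p)))
  expect_error(unpaired_t(1, c(1, 2)), "at least 2")
})

test_that("t-test objects expose tidy() and glance() summaries", {
  res <- paired_t(c(10, 12, 15, 9), c(5, 6, 9, 4))
  td <- tidy(res)
  expect_s3_class(td, "tbl_df")
  expect_equal(td$p_value, res$p)
  expect_true(td$significant == (res$p <= 0.05))
  gl <- glance(unpaired_t(c(1, 5, 3), c(2, 2, 8)))
  expect_equal(gl$n, 6)
  expect_equal(gl$alpha, 0.05)
})

test_that("preoperative subgroup report has one row per biomarker and metric", {
  pats <- dplyr::bind_rows(
    aggregate_patients(make_scores(1:8, c(80, 90, 85, 75, 70, 65, 95, 60),
                                   rep(30, 8))),
    aggregate_patients(make_scores(1:8, c(70, 72, 74, 60, 62, 64, 66, 68),
                                   rep(40, 8), biomarker = "VEGFA"))
  )
  pats$preop_therapy <- rep(c(TRUE, TRUE, TRUE, TRUE, TRUE, FALSE, FALSE, FALSE), 2)
  rep_tbl <- preop_subgroup_report(pats)
  expect_equal(nrow(rep_tbl), 4)  # 2 biomarkers x 2 metrics
  expect_setequal(unique(rep_tbl$metric), c("tumor_intensity", "tbr"))
  expect_true(all(is.finite(rep_tbl$p_value)))

  # identical subgroups: p = 1
  pats2 <- aggregate_patients(make_scores(1:4, c(80, 90, 80, 90),
                                          c(40, 30, 40, 30)))
  pats2$preop_therapy <- c(TRUE, TRUE, FALSE, FALSE)
  expect_equal(preop_subgroup_report(pats2)$p_value, c(1, 1))

  # one subgroup empty: report emitted, p not computable
  pats2$preop_therapy <- TRUE
  rep_na <- preop_subgroup_report(pats2)
  expect_equal(nrow(rep_na), 2)
  expect_true(all(is.na(rep_na$p_value)))
  expect_equal(rep_na$n_none, c(0, 0))
})
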