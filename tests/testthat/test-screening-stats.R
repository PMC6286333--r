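test_that("screening metrics follow the standard definitions and infinity convention", {
  m <- screening_metrics(tp = 32, fp = 5, tn = 38, fn = 1)
  expect_equal(round(m$sensitivity, 2), 0.97)
  expect_equal(round(m$specificity, 2), 0.88)
  expect_equal(m$plr, m$sensitivity / (1 - m$specificity), tolerance = 1e-12)
  expect_equal(m$nlr, (1 - m$sensitivity) / m$specificity, tolerance = 1e-12)

  perfect_spec <- screening_metrics(tp = 10, fp = 0, tn = 20, fn = 2)
  expect_identical(perfect_spec$plr, Inf)

  ones <- screening_metrics(tp = 1, fp = 0, tn = 1, fn = 0)
  expect_equal(ones$sensitivity, 1)
  expect_equal(ones$specificity, 1)
  expect_equal(ones$accuracy, 1)
  expect_equal(ones$nlr, 0)
  expect_true(is.na(screening_metrics(0, 0, 5, 0)$sensitivity))
  expect_error(screening_metrics(-1, 0, 0, 0), ">= 0")
})

test_that("ROC/AUC equals the Mann-Whitney U statistic and pROC on random data", {
  for (seed in 1:5) {
    set.seed(seed)
    n <- sample(20:500, 1)
    cobb <- stats::runif(n, 0, 60)
    score <- 0.1 * cobb + stats::rnorm(n, sd = sample(c(0.5, 2, 5), 1))
    data <- data.frame(i_asym = score - min(score), cobb = cobb)
    res <- roc_with_youden(data, 25)
    labels <- cobb > 25
    expect_equal(res$auc, auc_mann_whitney(data$i_asym, labels),
                 tolerance = 1e-12)
    # brute-force U statistic
    u <- 0
    for (a in data$i_asym[labels])
      u <- u + sum(a > data$i_asym[!labels]) +
        0.5 * sum(a == data$i_asym[!labels])
    expect_equal(res$auc, u / (sum(labels) * sum(!labels)), tolerance = 1e-12)
    expect_equal(res$auc,
                 as.numeric(pROC::auc(pROC::roc(labels, data$i_asym,
                                                quiet = TRUE))),
                 tolerance = 1e-9)
  }
})

test_that("ROC handles separation, chance-level scores and degenerate classes", {
  sep <- data.frame(i_asym = c(1:10 / 10, 3 + 1:10 / 10),
                    cobb = c(rep(0, 10), rep(40, 10)))
  res <- roc_with_youden(sep, 25)
  expect_equal(res$auc, 1)
  expect_equal(res$sensitivity, 1)
  expect_equal(res$specificity, 1)
  expect_equal(res$nlr, 0)
  expect_identical(res$discrimination_category, "outstanding discrimination")
  expect_true(res$cutoff > 1 && res$cutoff <= 3.1)

  set.seed(42)
  chance <- data.frame(i_asym = stats::runif(2000),
                       cobb = sample(c(0, 40), 2000, replace = TRUE))
  expect_lt(abs(roc_with_youden(chance, 25)$auc - 0.5), 0.03)

  expect_error(roc_with_youden(data.frame(i_asym = 1:5, cobb = rep(0, 5)), 25),
               "non-empty")
})

test_that("the Youden cut-off is invariant to monotone score transforms", {
  set.seed(7)
  data <- data.frame(i_asym = stats::rgamma(120, 2, 1),
                     cobb = stats::runif(120, 0, 60))
  r1 <- roc_with_youden(data, 20)
  data2 <- data
  data2$i_asym <- log1p(data$i_asym) * 3
  r2 <- roc_with_youden(data2, 20)
  expect_equal(r1$sensitivity, r2$sensitivity, tolerance = 1e-12)
  expect_equal(r1$specificity, r2$specificity, tolerance = 1e-12)
  expect_equal(r1$auc, r2$auc, tolerance = 1e-12)
  expect_equal(log1p(r1$cutoff) * 3, r2$cutoff, tolerance = 0.3)
  # DeLong and bootstrap CIs both bracket the point estimate
  expect_true(r1$auc_ci_95[1] <= r1$auc && r1$auc <= r1$auc_ci_95[2])
  rb <- roc_with_youden(data, 20, ci_method = "bootstrap", boot_n = 200)
  expect_true(rb$auc_ci_95[1] <= rb$auc && rb$auc <= rb$auc_ci_95[2])
})

test_that("CV reproduces published phantom worked examples and grades correctly", {
  # front-view phantom repeatability cells: mean 2.13 sd 0.04 -> 2%,
  # mean 2.10 sd 0.09 -> 4%, mean 2.89 sd 0.02 -> 1%
  expect_identical(round(cv_from_summary(2.13, 0.04)$cv_percent), 2)
  expect_identical(round(cv_from_summary(2.10, 0.09)$cv_percent), 4)
  expect_identical(round(cv_from_summary(2.89, 0.02)$cv_percent), 1)
  expect_identical(cv_from_summary(2.13, 0.04)$grade, "very good")

  expect_equal(coefficient_of_variation(rep(3.3, 5))$cv_percent, 0)
  v <- c(2, 2.2, 1.9, 2.1)
  expect_equal(coefficient_of_variation(v)$cv_percent,
               100 * stats::sd(v) / mean(v), tolerance = 1e-12)
  expect_error(coefficient_of_variation(c(-5, 1)), "positive")
  expect_error(coefficient_of_variation(2), "at least 2")

  expect_identical(cv_from_summary(1, 0.15)$grade, "good")
  expect_identical(cv_from_summary(1, 0.25)$grade, "fair/moderate")
  expect_identical(cv_from_summary(1, 0.40)$grade, "poor")
})

test_that("ICC(A,1) recovers designed variance structure", {
  ident <- matrix(rep(1:10, 2), ncol = 2)
  r <- icc_two_way(ident)
  expect_equal(r$icc, 1, tolerance = 1e-12)
  expect_identical(r$grade, "excellent")

  # subject sd 10x error sd: reliability must land in the excellent band
  set.seed(11)
  subj <- stats::rnorm(30, sd = 10)
  mm <- outer(subj, c(0, 0), "+") + stats::rnorm(60, sd = 1)
  sim <- icc_two_way(mm)
  expect_gt(sim$icc, 0.9)
  expect_identical(sim$grade, "excellent")
  expect_true(sim$icc_ci_95[1] <= sim$icc && sim$icc <= sim$icc_ci_95[2])

  # shuffling repeats destroys the subject structure
  set.seed(12)
  shuf <- apply(mm, 2, sample)
  expect_lt(abs(icc_two_way(shuf)$icc), 0.35)

  expect_error(icc_two_way(matrix(c(1, NA, 2, 3), 2, 2)), "missing")
  expect_error(icc_two_way(matrix(1:3, 3, 1)), "at least 2")
  expect_true(icc_two_way(matrix(5, 4, 2))$degenerate)
})

test_that("Fisher r-to-z comparison matches its closed form and flags boundaries", {
  set.seed(13)
  x <- stats::rnorm(20)
  y <- x + stats::rnorm(20)
  same <- pearson_with_fisher_comparison(x, y, x, y)
  expect_equal(same$z, 0)
  expect_equal(same$p, 1)

  exact <- pearson_with_fisher_comparison(x, x, x, y)
  expect_true(exact$boundary)
  expect_true(is.na(exact$p))

  # published worked example: r1 = 0.92 (n = 18) vs r2 = 0.86 (n = 58);
  # the formula gives p = 0.310 (frozen from direct evaluation), in the
  # reported non-significant region
  ref <- fisher_r_to_z_test(0.92, 18, 0.86, 58)
  expect_equal(ref$z, 1.015087, tolerance = 1e-5)
  expect_equal(ref$p, 0.310064, tolerance = 1e-5)
  expect_gt(ref$p, 0.05)

  expect_error(pearson_with_fisher_comparison(x, y, rep(1, 20), y),
               "zero variance")
  expect_error(pearson_with_fisher_comparison(x[1:3], y[1:3], x, y),
               "n >= 4")
})

test_that("screening report stratifies by threshold and curve type", {
  set.seed(17)
  coh <- data.frame(id = sprintf("S%02d", 1:40),
                    cobb = stats::runif(40, 0, 60),
                    curve_type = rep(c("single_thoracic", "double"), 20))
  coh$i_asym <- 0.1 * coh$cobb + stats::rnorm(40, sd = 0.4)
  coh$i_asym <- coh$i_asym - min(coh$i_asym)
  rep_ <- screening_report(coh)
  expect_identical(nrow(rep_), 9L)   # 3 strata x 3 thresholds
  expect_true(all(c("total", "single_thoracic", "double") %in% rep_$stratum))
  one_class <- coh[coh$cobb > 30, ]
  rep2 <- screening_report(one_class, cobb_thresholds = 25,
                           by_curve_type = FALSE)
  expect_true(!is.na(rep2$error[1]))
})
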