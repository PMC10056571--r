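test_that("empirical AUC matches the Mann-Whitney pair count", {
  expect_equal(roc_auc(c(2, 3, 0, 1), c(1, 1, 0, 0))$auc, 1.0)
  expect_equal(roc_auc(c(1, 3, 0, 2), c(1, 1, 0, 0))$auc, 0.75)
  expect_equal(roc_auc(c(1, 2, 3, 1, 2, 3), c(1, 1, 1, 0, 0, 0))$auc, 0.5)
  set.seed(101)
  for (i in 1:50) {
    n <- sample(4:40, 1)
    labels <- c(1, 0, rbinom(n - 2, 1, 0.4))
    markers <- sample(0:8, n, replace = TRUE)  # plenty of ties
    r <- roc_auc(markers, labels)
    expect_equal(r$auc, oracle_auc(markers, labels))
    # monotone transform invariance
    expect_equal(roc_auc(exp(markers / 3), labels)$auc, r$auc)
  }
})

test_that("DeLong SE and CI behave sensibly", {
  set.seed(7)
  markers <- c(rnorm(30, 1), rnorm(50))
  labels <- rep(c(1, 0), c(30, 50))
  r <- roc_auc(markers, labels)
  expect_gt(r$se_delong, 0)
  expect_true(r$ci95[1] >= 0 && r$ci95[2] <= 1)
  expect_true(r$ci95[1] < r$auc && r$auc < r$ci95[2])
  # curve is monotone: sensitivity non-increasing in the threshold
  expect_true(all(diff(r$curve$sensitivity) <= 0))
  expect_error(roc_auc(1:4, c(1, 1, 1, 1)), "negative")
  # agreement with pROC on the same data
  pr <- pROC::roc(labels, markers, direction = "<", quiet = TRUE)
  expect_equal(r$auc, as.numeric(pROC::auc(pr)))
  expect_equal(r$ci95, as.numeric(pROC::ci.auc(pr, method = "delong"))[c(1, 3)],
               tolerance = 1e-9)
})

test_that("paired DeLong comparison is calibrated against oracles", {
  set.seed(13)
  labels <- rep(c(1, 0), each = 10)
  a <- rnorm(20, labels)
  b <- rnorm(20, 0.8 * labels)
  expect_equal(delong_compare(a, a, labels)$p_two_sided, 1)
  expect_equal(delong_compare(a, a, labels)$delta, 0)
  cmp <- delong_compare(a, b, labels)
  expect_equal(cmp$delta, cmp$auc_a - cmp$auc_b)
  # SE within 10% of a stratified bootstrap oracle
  se_boot <- oracle_bootstrap_se_delta(a, b, labels, reps = 10000)
  expect_lt(abs(cmp$se_delta - se_boot) / se_boot, 0.10)
  # agreement with pROC's paired DeLong test
  pr <- pROC::roc.test(pROC::roc(labels, a, direction = "<", quiet = TRUE),
                       pROC::roc(labels, b, direction = "<", quiet = TRUE),
                       method = "delong", paired = TRUE)
  expect_equal(cmp$p_two_sided, pr$p.value, tolerance = 1e-9)
  expect_error(delong_compare(a[-1], b, labels), "length")
})

test_that("Youden scan matches exhaustive search and its worked example", {
  y <- youden_cut(c(1, 3, 3, 0, 2), c(1, 1, 1, 0, 0))
  expect_equal(y$best_threshold, 2.5)
  expect_equal(y$J, 2 / 3, tolerance = 1e-12)
  expect_equal(y$sensitivity, 2 / 3, tolerance = 1e-12)
  expect_equal(y$specificity, 1.0)
  expect_equal(youden_cut(c(5, 6, 1, 2), c(1, 1, 0, 0))$J, 1.0)
  set.seed(23)
  for (i in 1:50) {
    n <- sample(4:30, 1)
    labels <- c(1, 0, rbinom(n - 2, 1, 0.5))
    markers <- sample(0:6, n, replace = TRUE)
    got <- youden_cut(markers, labels)
    want <- oracle_youden(markers, labels)
    expect_equal(got$best_threshold, want$threshold)
    expect_equal(got$J, want$J)
    # J invariant under monotone transforms
    expect_equal(youden_cut(2 * markers + 1, labels)$J, got$J)
  }
})

test_that("sensitivity and specificity come from the confusion counts", {
  p <- c(rep(1, 9), 0, rep(1, 17), rep(0, 83))
  y <- c(rep(1, 10), rep(0, 100))
  ss <- sens_spec(p, y)
  expect_equal(ss$sensitivity, 0.90)
  expect_equal(ss$specificity, 0.83)
  expect_equal(ss[c("tp", "fn", "fp", "tn")], list(tp = 9, fn = 1, fp = 17,
                                                   tn = 83))
  expect_equal(sens_spec(y, y)$sensitivity, 1.0)
  expect_equal(sens_spec(y, y)$specificity, 1.0)
  all_pos <- sens_spec(rep(1, 110), y)
  expect_equal(all_pos$sensitivity, 1.0)
  expect_equal(all_pos$specificity, 0.0)
  expect_warning(sens_spec(c(1, 0), c(0, 0)), "sensitivity undefined")
})

test_that("McNemar uses the exact binomial below 25 discordant pairs", {
  m <- mcnemar(c(rep(1, 5), rep(0, 1), rep(1, 10)),
               c(rep(0, 5), rep(1, 1), rep(1, 10)))
  expect_equal(m$b, 5)
  expect_equal(m$c, 1)
  expect_equal(m$method, "exact")
  expect_equal(m$statistic, 1.5)          # (|5-1|-1)^2 / 6
  expect_equal(m$p, 0.21875)              # 2 * P(X <= 1 | n = 6)
  sym <- mcnemar(c(1, 1, 1, 0, 0, 0), c(0, 0, 0, 1, 1, 1))
  expect_equal(sym$p, 1.0)
  one <- mcnemar(rep(1, 5), rep(0, 5))
  expect_equal(one$p, 0.0625)             # 2 * 0.5^5
  agree <- mcnemar(c(1, 0, 1), c(1, 0, 1))
  expect_equal(agree$p, 1)
  expect_equal(agree$statistic, 0)
  for (b in c(0, 2, 7, 11)) for (cc in c(0, 3, 9)) {
    if (b + cc == 0) next
    got <- mcnemar(c(rep(1, b), rep(0, cc)), c(rep(0, b), rep(1, cc)))
    expect_equal(got$p, oracle_mcnemar_exact(b, cc))
  }
  # large-sample path: continuity-corrected chi-squared, as in base R
  big <- mcnemar(rep(c(1, 0), c(20, 15)), rep(c(0, 1), c(20, 15)))
  expect_equal(big$method, "chi2_cc")
  ref <- mcnemar.test(matrix(c(0, 15, 20, 0), 2))
  expect_equal(big$p, ref$p.value)
})

test_that("ICC(A,1) matches the ANOVA oracle and its boundary cases", {
  set.seed(31)
  subj <- rnorm(30, 50, 10)
  ratings <- cbind(subj + rnorm(30, 0, 1), subj + rnorm(30, 0, 1))
  r <- icc_agreement(ratings)
  expect_equal(r$icc, oracle_icc_a1(ratings), tolerance = 1e-9)
  expect_true(r$ci95[1] < r$icc && r$icc <= r$ci95[2])
  expect_gt(r$icc, 0.9)
  # identical raters agree perfectly
  expect_equal(icc_agreement(cbind(subj, subj))$icc, 1.0)
  # independent raters have ICC near zero
  ind <- icc_agreement(cbind(rnorm(30), rnorm(30)))
  expect_lt(abs(ind$icc), 0.2)
  expect_error(icc_agreement(ratings[1:3, ]), "5 subjects")
  expect_error(icc_agreement(ratings[, 1, drop = FALSE]), "2 raters")
})
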