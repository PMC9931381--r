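test_that("confusion counts partition the sample and match an elementwise tally", {
  truth <- c(rep("submaximal", 6), rep("maximal", 4))
  expect_equal(confusion(truth, truth)$fn, 0)
  expect_equal(confusion(truth, truth)$fp, 0)

  all_pos <- rep("submaximal", 10)
  cm <- confusion(truth, all_pos)
  expect_equal(cm$tn, 0)
  expect_equal(cm$fn, 0)
  expect_equal(cm$fp, 4)

  set.seed(51)
  for (rep in 1:10) {
    t <- sample(c(TRUE, FALSE), 30, replace = TRUE)
    p <- sample(c(TRUE, FALSE), 30, replace = TRUE)
    cm <- confusion(t, p)
    expect_equal(cm$tp, sum(t & p))
    expect_equal(cm$fn, sum(t & !p))
    expect_equal(cm$tn, sum(!t & !p))
    expect_equal(cm$fp, sum(!t & p))
    expect_equal(cm$tp + cm$fn + cm$tn + cm$fp, 30)
  }
  expect_error(confusion(truth, truth[-1]), "equal")
  expect_error(confusion(c("a", "b"), c("a", "b")), "binary")
})

test_that("metrics_report computes the documented rates on constructed counts", {
  # tp = 91, fn = 6, tn = 286, fp = 4
  truth <- c(rep("submaximal", 97), rep("maximal", 290))
  pred <- c(rep("submaximal", 91), rep("maximal", 6),
            rep("maximal", 286), rep("submaximal", 4))
  scores <- ifelse(pred == "submaximal", 0.9, 0.1) +
    stats::runif(387, -0.05, 0.05)
  rep <- metrics_report(truth, scores, predicted = pred)
  expect_equal(rep$sensitivity, 91 / 97)
  expect_equal(rep$specificity, 286 / 290)
  expect_equal(rep$accuracy, 377 / 387)
  expect_equal(round(rep$sensitivity, 4), 0.9381)
  expect_equal(round(rep$specificity, 4), 0.9862)
  expect_true(rep$accuracy_ci[1] <= rep$accuracy &&
                rep$accuracy <= rep$accuracy_ci[2])

  # a perfect classifier: all rates 1, accuracy CI upper bound 1
  t2 <- c(rep("submaximal", 50), rep("maximal", 50))
  s2 <- c(rep(1, 50), rep(0, 50))
  rep2 <- metrics_report(t2, s2, predicted = t2)
  expect_equal(rep2$accuracy, 1)
  expect_equal(rep2$accuracy_ci[2], 1)
  expect_equal(rep2$auc, 1)
  expect_true(rep2$auc_ci_degenerate)
})

test_that("Clopper-Pearson bounds match beta quantiles and the reference implementation", {
  set.seed(61)
  for (rep in 1:20) {
    n <- sample(5:200, 1)
    k <- sample(0:n, 1)
    ci <- clopper_pearson(k, n)
    lo <- if (k == 0) 0 else stats::qbeta(0.025, k, n - k + 1)
    hi <- if (k == n) 1 else stats::qbeta(0.975, k + 1, n - k)
    expect_equal(ci, c(lo, hi))
    ref <- stats::binom.test(k, n)$conf.int
    expect_equal(ci, as.numeric(ref), tolerance = 1e-9)
  }
})

test_that("Clopper-Pearson intervals reach nominal coverage on simulated binomials", {
  set.seed(71)
  for (p in c(0.1, 0.5, 0.9)) {
    k <- stats::rbinom(2000, 30, p)
    covered <- vapply(k, function(ki) {
      ci <- clopper_pearson(ki, 30)
      ci[1] <= p && p <= ci[2]
    }, logical(1))
    expect_gte(mean(covered), 0.95 - 0.015)
  }
})

test_that("roc_from_scores: trivial cases and the U-statistic oracle", {
  truth <- c(rep("submaximal", 5), rep("maximal", 5))
  expect_equal(roc_from_scores(c(6:10, 1:5), truth)$auc, 1)
  expect_equal(roc_from_scores(rep(1, 10), truth)$auc, 0.5)
  expect_error(roc_from_scores(1:5, rep("maximal", 5)), "both classes")

  set.seed(81)
  for (rep in 1:10) {
    n <- sample(10:60, 1)
    is_pos <- c(TRUE, FALSE, sample(c(TRUE, FALSE), n - 2, replace = TRUE))
    scores <- round(stats::rnorm(n, mean = is_pos), 1)  # induces ties
    roc <- roc_from_scores(scores, is_pos)
    expect_equal(roc$auc, u_auc(scores, is_pos), tolerance = 1e-12)
  }
})

test_that("ROC points are sorted and the curve is componentwise non-decreasing", {
  set.seed(82)
  is_pos <- sample(c(TRUE, FALSE), 50, replace = TRUE)
  is_pos[1:2] <- c(TRUE, FALSE)
  roc <- roc_from_scores(stats::rnorm(50), is_pos)
  expect_true(all(diff(roc$points$fpr) >= 0))
  expect_true(all(diff(roc$points$tpr) >= 0))
  expect_equal(roc$points$fpr[1], 0)
  expect_equal(roc$points$tpr[nrow(roc$points)], 1)
})

test_that("AUC is invariant under monotone score transforms; label swap flips it", {
  set.seed(91)
  is_pos <- c(TRUE, FALSE, sample(c(TRUE, FALSE), 38, replace = TRUE))
  scores <- stats::rnorm(40)
  auc <- roc_from_scores(scores, is_pos)$auc
  expect_equal(roc_from_scores(exp(scores), is_pos)$auc, auc)
  expect_equal(roc_from_scores(5 * scores - 2, is_pos)$auc, auc)
  expect_equal(roc_from_scores(scores, !is_pos)$auc, 1 - auc,
               tolerance = 1e-12)
  swapped <- metrics_report(!is_pos, -scores,
                            predicted = !(scores > 0))
  direct <- metrics_report(is_pos, scores, predicted = scores > 0)
  expect_equal(swapped$sensitivity, direct$specificity)
  expect_equal(swapped$specificity, direct$sensitivity)
})

test_that("DeLong CI: degeneracy, symmetry, and agreement with pROC", {
  sep <- delong_ci(c(5:8, 1:4), c(rep(TRUE, 4), rep(FALSE, 4)))
  expect_equal(sep$variance, 0)
  expect_equal(c(sep$lo, sep$hi), c(1, 1))
  expect_true(sep$degenerate)

  # interleaved scores with AUC exactly 0.5: interval symmetric about 0.5
  inter <- delong_ci(c(1, 2, 3, 4, 1, 2, 3, 4),
                     c(rep(TRUE, 4), rep(FALSE, 4)))
  expect_equal(inter$auc, 0.5)
  expect_equal(inter$hi - 0.5, 0.5 - inter$lo, tolerance = 1e-12)

  skip_if_not_installed("pROC")
  set.seed(101)
  for (rep in 1:5) {
    is_pos <- c(TRUE, FALSE, sample(c(TRUE, FALSE), 78, replace = TRUE))
    scores <- stats::rnorm(80, mean = 0.8 * is_pos)
    dl <- delong_ci(scores, is_pos)
    ref <- suppressMessages(pROC::ci.auc(
      pROC::roc(response = as.integer(is_pos), predictor = scores,
                quiet = TRUE), method = "delong"))
    expect_equal(dl$lo, max(0, as.numeric(ref)[1]), tolerance = 1e-6)
    expect_equal(dl$hi, min(1, as.numeric(ref)[3]), tolerance = 1e-6)
  }
})

test_that("comparison table lays out one column per method with 4-decimal cells", {
  set.seed(111)
  truth <- c(rep("submaximal", 40), rep("maximal", 40))
  mk <- function(label, noise) {
    s <- ifelse(truth == "submaximal", 0.8, 0.2) + stats::rnorm(80, 0, noise)
    metrics_report(truth, s, method_label = label)
  }
  tab <- comparison_table(list(mk("XGBoost", 0.1), mk("Thresholds", 0.5)))
  expect_equal(names(tab), c("metric", "XGBoost", "Thresholds"))
  expect_equal(tab$metric, c("Sensitivity", "Specificity", "Accuracy",
                             "(95% CI)", "AUC", "(95% CI deLong)"))
  expect_match(tab$XGBoost[1], "^0\\.\\d{4}$")
  csv <- withr::local_tempfile(fileext = ".csv")
  txt <- withr::local_tempfile(fileext = ".txt")
  write_comparison(tab, csv, txt)
  expect_true(file.exists(csv) && file.exists(txt))
  expect_equal(nrow(utils::read.csv(csv)), 6)
})
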