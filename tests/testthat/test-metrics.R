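test_that("AUC equals the pairwise Mann-Whitney probability", {
  # events {0.9, 0.4}, nonevents {0.6, 0.2}: 3 of 4 pairs concordant
  r <- roc_auc(c(0.9, 0.4, 0.6, 0.2), c(TRUE, TRUE, FALSE, FALSE))
  expect_equal(r$auc, 0.75)
  # perfectly separated scores
  expect_equal(roc_auc(c(5, 6, 7, 1, 2), c(TRUE, TRUE, TRUE, FALSE, FALSE))$auc, 1)
  expect_error(roc_auc(1:5, rep(TRUE, 5)), class = "glycrisk_input_error")
})

test_that("AUC of an uninformative score approaches one half", {
  set.seed(51)
  r <- roc_auc(rnorm(2000), runif(2000) < 0.4)
  expect_lt(abs(r$auc - 0.5), 0.03)
  expect_true(r$ci[1] <= r$auc && r$auc <= r$ci[2])
})

test_that("ROC curve is monotone and AUC is rank-invariant", {
  set.seed(52)
  score <- rnorm(200)
  y <- runif(200) < plogis(score)
  r <- roc_auc(score, y)
  expect_true(all(diff(r$sensitivity) <= 1e-12))
  expect_true(all(diff(r$specificity) >= -1e-12))
  r2 <- roc_auc(exp(score), y)
  expect_equal(r2$auc, r$auc, tolerance = 1e-12)
})

test_that("AUC and De Long variance agree with the pROC reference", {
  skip_if_not_installed("pROC")
  set.seed(53)
  score <- rnorm(150)
  y <- runif(150) < plogis(1.2 * score)
  r <- roc_auc(score, y)
  pr <- pROC::roc(y, score, quiet = TRUE, direction = "<")
  expect_equal(r$auc, as.numeric(pROC::auc(pr)), tolerance = 1e-10)
  expect_equal(r$auc_se, sqrt(pROC::var(pr)), tolerance = 1e-8)
})

test_that("paired De Long test is null on identical or rank-equivalent scores", {
  set.seed(54)
  a <- rnorm(60)
  y <- runif(60) < plogis(a)
  same <- delong_compare(a, a, y)
  expect_identical(same$difference, 0)
  expect_equal(same$p_value, 1)
  mono <- delong_compare(a, qlogis(plogis(a)^3), y)  # monotone transform
  expect_equal(mono$difference, 0, tolerance = 1e-12)
  expect_equal(mono$p_value, 1)
  expect_error(delong_compare(a, a[-1], y[-1]), class = "glycrisk_input_error")
})

test_that("paired De Long statistic matches the pROC reference", {
  skip_if_not_installed("pROC")
  set.seed(55)
  x <- rnorm(120); noise <- rnorm(120)
  y <- runif(120) < plogis(1.5 * x)
  a <- x + 0.5 * noise; b <- 0.4 * x + noise
  ours <- delong_compare(a, b, y)
  ref <- pROC::roc.test(pROC::roc(y, a, quiet = TRUE, direction = "<"),
                        pROC::roc(y, b, quiet = TRUE, direction = "<"),
                        method = "delong", paired = TRUE)
  expect_equal(ours$z, unname(ref$statistic), tolerance = 1e-8)
  expect_equal(ours$p_value, ref$p.value, tolerance = 1e-8)
})

test_that("confusion metrics follow the standard formulas", {
  # TP=2 FP=1 FN=1 TN=2 -> MCC = (4-1)/sqrt(81) = 1/3
  rep_ <- confusion_metrics(c(T, T, T, F, F, F), c(T, T, F, T, F, F))
  expect_equal(c(rep_$TP, rep_$FP, rep_$FN, rep_$TN), c(2, 1, 1, 2))
  expect_equal(rep_$mcc, 1 / 3)
  expect_equal(rep_$youden_j, rep_$sensitivity + rep_$specificity - 1)

  perfect <- confusion_metrics(c(T, T, F, F), c(T, T, F, F))
  expect_equal(perfect$sensitivity, 1)
  expect_equal(perfect$specificity, 1)
  expect_equal(perfect$accuracy, 1)
  expect_equal(perfect$mcc, 1)
  expect_equal(perfect$lr_positive, Inf)

  allneg <- confusion_metrics(rep(FALSE, 6), c(T, T, T, F, F, F))
  expect_equal(allneg$sensitivity, 0)
  expect_equal(allneg$specificity, 1)
  expect_equal(allneg$mcc, 0)
})

test_that("confusion counts conserve n on random inputs", {
  set.seed(56)
  for (i in 1:200) {
    n <- sample(1:50, 1)
    rep_ <- confusion_metrics(runif(n) < 0.5, runif(n) < 0.5)
    expect_equal(rep_$TP + rep_$FP + rep_$FN + rep_$TN, n)
  }
})

test_that("Youden optimum equals an exhaustive threshold sweep", {
  score <- c(0.1, 0.3, 0.35, 0.5, 0.55, 0.7, 0.8, 0.9)
  y <- c(F, F, T, F, T, T, F, T)
  r <- roc_auc(score, y)
  yo <- youden_optimal(r)
  sweep <- vapply(r$thresholds, function(t) {
    cm <- confusion_metrics(score >= t, y)
    cm$sensitivity + cm$specificity - 1
  }, numeric(1))
  expect_equal(yo$youden_j, max(sweep), tolerance = 1e-12)
  # separated data reach J = 1 at the separating threshold
  ysep <- youden_optimal(roc_auc(c(1, 2, 3, 7, 8, 9), rep(c(F, T), each = 3)))
  expect_equal(ysep$youden_j, 1)
  expect_equal(ysep$report$accuracy, 1)
  # constant score: J = 0 (degenerate)
  ycon <- youden_optimal(roc_auc(rep(1, 10), rep(c(T, F), 5)))
  expect_equal(ycon$youden_j, 0)
})

test_that("Youden ties break toward higher specificity", {
  # two thresholds reach the same J; the larger (more specific) one wins
  score <- c(1, 2, 3, 4)
  y <- c(F, T, F, T)
  yo <- youden_optimal(roc_auc(score, y))
  expect_equal(yo$report$specificity, 1)
})

test_that("Hosmer-Lemeshow equals hand-computed group sums on a toy case", {
  set.seed(57)
  p <- seq(0.05, 0.95, length.out = 40)
  y <- runif(40) < p
  hl <- hosmer_lemeshow(p, y, g = 4)
  bins <- rep(1:4, each = 10)
  obs <- tapply(y, bins, sum); expc <- tapply(p, bins, sum)
  stat <- sum((obs - expc)^2 / (expc * (1 - expc / 10)))
  expect_equal(hl$statistic, stat, tolerance = 1e-12)
  expect_equal(hl$df, 2)
  expect_equal(hl$p_value, pchisq(stat, 2, lower.tail = FALSE))
  expect_error(hosmer_lemeshow(p, y, g = 30), class = "glycrisk_input_error")
})

test_that("Hosmer-Lemeshow is zero when observed equals expected", {
  # constant probability within each bin, observed count set to expected
  p <- rep(c(0.2, 0.4, 0.6, 0.8), each = 10)
  y <- unlist(lapply(c(0.2, 0.4, 0.6, 0.8), function(q)
    rep(c(TRUE, FALSE), c(round(10 * q), 10 - round(10 * q)))))
  hl <- hosmer_lemeshow(p, y, g = 4)
  expect_equal(hl$statistic, 0, tolerance = 1e-12)
})
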