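test_that("logistic fit on a null covariate covers OR = 1", {
  set.seed(31)
  x <- rnorm(2000)
  y <- runif(2000) < 0.4
  fit <- fit_logistic(y, cbind(x = x))
  row <- fit$coefficients[fit$coefficients$term == "x", ]
  expect_true(row$or_low <= 1 && 1 <= row$or_high)
  expect_true(fit$converged)
  expect_length(fit$predicted_probabilities, 2000)
  expect_true(all(fit$predicted_probabilities > 0 &
                  fit$predicted_probabilities < 1))
})

test_that("tiny-data MLE matches a brute-force log-likelihood grid search", {
  y <- c(TRUE, FALSE, TRUE, TRUE, FALSE, FALSE, TRUE, FALSE)
  x <- c(2.1, 0.4, 1.8, 0.5, 1.0, 2.2, 1.4, 0.9)  # overlapping classes
  fit <- fit_logistic(y, cbind(x = x))
  ll <- function(b0, b1) sum(dbinom(y, 1, plogis(b0 + b1 * x), log = TRUE))
  # nested grid refinement around the coarse optimum
  grid <- expand.grid(b0 = seq(-10, 10, 0.1), b1 = seq(-10, 10, 0.1))
  vals <- mapply(ll, grid$b0, grid$b1)
  best <- grid[which.max(vals), ]
  fine <- expand.grid(b0 = seq(best$b0 - 0.2, best$b0 + 0.2, 0.0005),
                      b1 = seq(best$b1 - 0.2, best$b1 + 0.2, 0.0005))
  fvals <- mapply(ll, fine$b0, fine$b1)
  fbest <- fine[which.max(fvals), ]
  expect_equal(fit$coefficients$estimate[1], fbest$b0, tolerance = 1e-3)
  expect_equal(fit$coefficients$estimate[2], fbest$b1, tolerance = 1e-3)
})

test_that("logistic estimates are invariant to row permutation and errors are raised", {
  set.seed(13)
  x <- matrix(rnorm(300), ncol = 2, dimnames = list(NULL, c("a", "b")))
  y <- runif(150) < plogis(x[, 1])
  f1 <- fit_logistic(y, x)
  perm <- sample(150)
  f2 <- fit_logistic(y[perm], x[perm, ])
  expect_equal(f1$coefficients$estimate, f2$coefficients$estimate,
               tolerance = 1e-9)
  expect_error(fit_logistic(rep(TRUE, 50), cbind(rnorm(50))),
               class = "glycrisk_input_error")
})

test_that("complete separation is flagged, never a silent huge OR", {
  x <- c(1:10)
  y <- x > 5
  fit <- fit_logistic(y, cbind(x = x))
  expect_true(fit$separation)
  expect_false(fit$converged)
})

test_that("spearman matrix is exact under monotone transforms and reversal", {
  set.seed(41)
  x <- rnorm(30)
  cm <- spearman_matrix(cbind(x = x, ex = exp(x), neg = -x))
  expect_equal(cm$r["x", "ex"], 1)
  expect_equal(cm$r["x", "neg"], -1)
  expect_true(isSymmetric(cm$r))
  expect_equal(diag(cm$r), c(x = 1, ex = 1, neg = 1))
})

test_that("tied data equal the Pearson-on-midranks oracle, constants give NA", {
  x <- c(1, 2, 2, 3, 3, 3, 4, 5, 5, 6)
  y <- c(2, 1, 3, 3, 5, 4, 4, 6, 7, 7)
  cm <- spearman_matrix(cbind(x = x, y = y))
  oracle <- cor(rank(x), rank(y))  # midranks then product-moment
  expect_equal(cm$r["x", "y"], oracle, tolerance = 1e-12)
  t_or <- oracle * sqrt(8 / (1 - oracle^2))
  expect_equal(cm$p["x", "y"], 2 * pt(-abs(t_or), 8), tolerance = 1e-12)
  cm2 <- spearman_matrix(cbind(x = x, const = rep(1, 10)))
  expect_true(is.na(cm2$r["x", "const"]))
})

test_that("missing values are handled pairwise-complete", {
  x <- c(1:10, NA, NA)
  y <- c(NA, 2:10, 5, 6)
  z <- 12:1
  cm <- spearman_matrix(cbind(x = x, y = y, z = z))
  expect_equal(cm$n["x", "y"], 9)
  expect_equal(cm$n["x", "z"], 10)
  ok <- complete.cases(x, y)
  expect_equal(cm$r["x", "y"], cor(rank(x[ok]), rank(y[ok])),
               tolerance = 1e-12)
})

test_that("two-group comparison enumerates exactly for tiny samples", {
  res <- group_compare(c(1, 2, 3, 4, 5, 6),
                       rep(c("a", "b"), each = 3))
  expect_match(res$method, "exact")
  expect_equal(res$p_value, 0.1)  # 2/20 rank arrangements as extreme
})

test_that("group comparisons are invariant to label renaming", {
  set.seed(17)
  v <- rnorm(60)
  g <- rep(c("x", "y", "z"), each = 20)
  r1 <- group_compare(v, g)
  r2 <- group_compare(v, c(x = "grp1", y = "grp2", z = "grp3")[g])
  expect_equal(r1$statistic, r2$statistic)
  expect_equal(r1$p_value, r2$p_value)
  expect_equal(r1$posthoc$z, r2$posthoc$z)
})

test_that("Dunn-Bonferroni p-values dominate unadjusted ones and cap at 1", {
  set.seed(19)
  v <- c(rnorm(30), rnorm(30, 1), rnorm(30, 2))
  g <- rep(c("a", "b", "c"), each = 30)
  res <- group_compare(v, g)
  expect_true(all(res$posthoc$p_adjusted >= res$posthoc$p_unadjusted))
  expect_true(all(res$posthoc$p_adjusted <= 1))
  expect_error(group_compare(c(1, 2, 3), c("a", "a", "b")),
               class = "glycrisk_input_error")
})

test_that("Kruskal-Wallis holds its type-I error on null groups", {
  set.seed(23)
  rejections <- sum(vapply(1:500, function(i) {
    v <- rlnorm(600)
    group_compare(v, rep(c("a", "b", "c"), each = 200))$p_value < 0.05
  }, logical(1)))
  # binomial 99% band around 5% of 500
  band <- qbinom(c(0.005, 0.995), 500, 0.05)
  expect_gte(rejections, band[1])
  expect_lte(rejections, band[2])
})
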