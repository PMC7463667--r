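test_that("NRI equals direct enumeration of movements on a toy table", {
  # events: 2 up, 1 down, 1 unchanged; nonevents: 1 down, 0 up
  p_old <- c(0.3, 0.3, 0.3, 0.3,  0.2, 0.2, 0.2, 0.2)
  p_new <- c(0.5, 0.4, 0.1, 0.3,  0.1, 0.2, 0.2, 0.2)
  y <- rep(c(TRUE, FALSE), each = 4)
  res <- nri(p_old, p_new, y)
  expect_equal(res$nri_events, 0.25)     # (2 - 1) / 4
  expect_equal(res$nri_nonevents, 0.25)  # (1 - 0) / 4
  expect_equal(res$nri, 0.5)
})

test_that("NRI is zero on identical models and antisymmetric in labels", {
  set.seed(61)
  p <- runif(40); y <- rep(c(TRUE, FALSE), 20)
  expect_equal(nri(p, p, y)$nri, 0)
  p2 <- pmin(0.99, p + rnorm(40, 0, 0.1))
  expect_equal(nri(p, p2, y)$nri, -nri(p, p2, !y)$nri, tolerance = 1e-12)
})

test_that("categorical NRI counts category crossings only", {
  cuts <- c(0.05, 0.10)
  p_old <- c(0.04, 0.08, 0.12, 0.06)
  p_new <- c(0.06, 0.09, 0.11, 0.04)   # up, none, none, down
  y <- c(TRUE, TRUE, FALSE, FALSE)
  res <- nri(p_old, p_new, y, variant = "categorical", categories = cuts)
  expect_equal(res$nri_events, 0.5)     # 1 up of 2 events
  expect_equal(res$nri_nonevents, 0.5)  # 1 down of 2 nonevents
  expect_error(nri(p_old, p_new, y, variant = "categorical"),
               class = "glycrisk_input_error")
  # a single category admits no movement
  res1 <- nri(p_old, p_new, y, variant = "categorical",
              categories = numeric(0))
  expect_equal(res1$nri, 0)
})

test_that("IDI matches hand arithmetic and is antisymmetric under model swap", {
  # event means 0.6 -> 0.7, nonevent means 0.4 -> 0.3  =>  IDI = 0.2
  p_old <- c(0.5, 0.7, 0.3, 0.5)
  p_new <- c(0.6, 0.8, 0.2, 0.4)
  y <- c(TRUE, TRUE, FALSE, FALSE)
  expect_equal(idi(p_old, p_new, y)$idi, 0.2)
  expect_equal(idi(p_old, p_old, y)$idi, 0)
  expect_equal(idi(p_new, p_old, y)$idi, -0.2)
})

test_that("NRI and IDI are invariant to subject ordering", {
  set.seed(62)
  p_old <- runif(50); p_new <- runif(50); y <- runif(50) < 0.5
  y[1:2] <- c(TRUE, FALSE)
  perm <- sample(50)
  expect_equal(nri(p_old, p_new, y)$nri,
               nri(p_old[perm], p_new[perm], y[perm])$nri)
  expect_equal(idi(p_old, p_new, y)$idi,
               idi(p_old[perm], p_new[perm], y[perm])$idi, tolerance = 1e-12)
})

test_that("bootstrap CI is deterministic per seed and collapses for constants", {
  set.seed(63)
  dat <- data.frame(x = rnorm(80))
  b1 <- bootstrap_ci(function(d) mean(d$x), dat, B = 300, seed = 5)
  b2 <- bootstrap_ci(function(d) mean(d$x), dat, B = 300, seed = 5)
  expect_identical(b1$ci, b2$ci)
  expect_identical(b1$replicates, b2$replicates)
  const <- bootstrap_ci(function(d) 0.7, dat, B = 200, seed = 1)
  expect_equal(diff(const$ci), 0)
  expect_equal(const$p_value, 0)  # nonzero constant: infinitely precise
  zero <- bootstrap_ci(function(d) 0, dat, B = 200, seed = 1)
  expect_equal(zero$p_value, 1)
})

test_that("degenerate resamples are redrawn and counted", {
  # 1 event among 6 subjects: many resamples drop the event class
  dat <- data.frame(p_old = runif(6), p_new = runif(6),
                    outcome = c(TRUE, rep(FALSE, 5)))
  b <- bootstrap_ci(function(d) idi(d$p_old, d$p_new, d$outcome)$idi,
                    dat, B = 150, seed = 2)
  expect_gt(b$n_redrawn, 0)
  expect_equal(b$B, 150L)
  expect_true(all(is.finite(b$replicates)))
})

test_that("bootstrap CI width shrinks roughly as one over sqrt(n)", {
  set.seed(64)
  make <- function(n) {
    x <- rnorm(n)
    data.frame(p_old = plogis(0.3 * x), p_new = plogis(0.8 * x),
               outcome = runif(n) < plogis(x))
  }
  w <- vapply(c(200, 800), function(n) {
    b <- bootstrap_ci(function(d) idi(d$p_old, d$p_new, d$outcome)$idi,
                      make(n), B = 400, seed = 9)
    diff(b$ci)
  }, numeric(1))
  expect_gt(w[1] / w[2], 1.6)
  expect_lt(w[1] / w[2], 2.5)
})

test_that("a true-null IDI is covered by the bootstrap CI at the nominal rate", {
  # both models equal the true model plus independent noise of the same
  # size, so the population IDI is 0
  set.seed(65)
  covered <- vapply(1:60, function(i) {
    x <- rnorm(300)
    y <- runif(300) < plogis(x)
    d <- data.frame(p_old = plogis(x + rnorm(300, 0, 0.4)),
                    p_new = plogis(x + rnorm(300, 0, 0.4)),
                    outcome = y)
    b <- bootstrap_ci(function(dd) idi(dd$p_old, dd$p_new, dd$outcome)$idi,
                      d, B = 300, seed = i)
    b$ci[1] <= 0 && 0 <= b$ci[2]
  }, logical(1))
  # binomial 99% band around 95% of 60 replicates
  expect_gte(sum(covered), qbinom(0.005, 60, 0.95))
})

test_that("nri_idi bundles point estimates with reproducible bootstrap CIs", {
  set.seed(66)
  x <- rnorm(200)
  y <- runif(200) < plogis(1.2 * x)
  p_old <- plogis(0.4 * x); p_new <- plogis(1.1 * x)
  res <- nri_idi(p_old, p_new, y, B = 200, seed = 3)
  expect_equal(res$nri$nri, nri(p_old, p_new, y)$nri)
  expect_equal(res$idi$idi, idi(p_old, p_new, y)$idi)
  expect_true(res$bootstrap$nri$ci[1] <= res$bootstrap$nri$ci[2])
  expect_identical(nri_idi(p_old, p_new, y, B = 200, seed = 3)$bootstrap$idi$ci,
                   res$bootstrap$idi$ci)
  expect_true(abs(res$nri$nri) <= 2)
  expect_true(abs(res$nri$nri_events) <= 1 && abs(res$nri$nri_nonevents) <= 1)
})
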