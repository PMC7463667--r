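#' @title Association statistics: logistic models, Spearman matrices,
#'   non-parametric group comparisons
#' @name model-fitting
NULL

#' Logistic regression with odds ratios and Wald intervals
#'
#' Maximum-likelihood fit (IRLS via `stats::glm`), reporting per-term
#' coefficients, standard errors from the observed information, odds
#' ratios `exp(coef)` with Wald 95% CIs, p-values, log-likelihood and
#' per-subject predicted probabilities. Quasi-complete separation is
#' detected (non-convergence or any |coefficient| > 15 on the logit scale)
#' and flagged rather than silently returning an enormous OR.
#'
#' @param outcome logical (or 0/1) response with both classes present.
#' @param covariates numeric matrix or data.frame of predictors.
#' @param labels optional covariate names.
#' @return object of class `logistic_fit` with `coefficients` (a per-term
#'   data.frame), `log_likelihood`, `converged`, `separation`, `n` and
#'   `predicted_probabilities`.
#' @export
fit_logistic <- function(outcome, covariates, labels = NULL) {
  y <- as.logical(outcome)
  if (any(is.na(y))) stop_input("outcome must not contain missing values")
  if (length(unique(y)) < 2)
    stop_input("outcome must contain both classes")
  X <- as.matrix(covariates)
  storage.mode(X) <- "double"
  if (nrow(X) != length(y)) stop_input("outcome and covariates must be paired")
  if (length(y) <= ncol(X) + 1)
    stop_input("need more observations than model terms")
  colnames(X) <- labels %||% colnames(X) %||% paste0("x", seq_len(ncol(X)))
  df <- data.frame(.y = y, X, check.names = FALSE)
  fit <- suppressWarnings(
    stats::glm(.y ~ ., data = df, family = stats::binomial(),
               control = stats::glm.control(epsilon = 1e-8, maxit = 100)))
  sm <- summary(fit)
  co <- sm$coefficients
  z <- stats::qnorm(0.975)
  coefs <- data.frame(
    term = rownames(co),
    estimate = co[, 1],
    std_error = co[, 2],
    odds_ratio = exp(co[, 1]),
    or_low = exp(co[, 1] - z * co[, 2]),
    or_high = exp(co[, 1] + z * co[, 2]),
    p_value = co[, 4],
    row.names = NULL)
  separation <- !fit$converged || any(abs(co[, 1]) > 15)
  structure(list(coefficients = coefs,
                 log_likelihood = as.numeric(stats::logLik(fit)),
                 converged = fit$converged && !separation,
                 separation = separation,
                 n = length(y),
                 predicted_probabilities = unname(stats::fitted(fit)),
                 glm = fit),
            class = "logistic_fit")
}

#' @export
print.logistic_fit <- function(x, ...) {
  cat(sprintf("Logistic fit (n = %d, logLik = %.3f%s)\n", x$n,
              x$log_likelihood,
              if (x$separation) ", SEPARATION FLAGGED" else ""))
  print(x$coefficients, row.names = FALSE, digits = 4)
  invisible(x)
}

#' Pairwise Spearman correlation matrix
#'
#' Rank correlations (average ranks for ties) with pairwise-complete
#' handling of missing values; p-values from the t approximation
#' `t = r * sqrt((n - 2) / (1 - r^2))` on n - 2 degrees of freedom.
#' Constant columns give undefined (NA) correlations, not zero.
#'
#' @param table numeric matrix or data.frame.
#' @param labels optional variable names.
#' @return object of class `correlation_matrix` with `r`, `p` and `n`
#'   matrices.
#' @export
spearman_matrix <- function(table, labels = NULL) {
  X <- as.matrix(table)
  storage.mode(X) <- "double"
  vars <- labels %||% colnames(X) %||% paste0("v", seq_len(ncol(X)))
  k <- ncol(X)
  r <- p <- n <- matrix(NA_real_, k, k, dimnames = list(vars, vars))
  diag(r) <- 1; diag(p) <- 0
  diag(n) <- colSums(!is.na(X))
  for (i in seq_len(k - 1)) for (j in (i + 1):k) {
    ok <- stats::complete.cases(X[, i], X[, j])
    m <- sum(ok)
    n[i, j] <- n[j, i] <- m
    if (m < 4) next
    xi <- X[ok, i]; xj <- X[ok, j]
    if (stats::var(xi) == 0 || stats::var(xj) == 0) next  # undefined
    rho <- stats::cor(rank(xi), rank(xj))
    r[i, j] <- r[j, i] <- rho
    pv <- if (abs(rho) >= 1) 0 else {
      tt <- rho * sqrt((m - 2) / (1 - rho^2))
      2 * stats::pt(-abs(tt), df = m - 2)
    }
    p[i, j] <- p[j, i] <- pv
  }
  structure(list(variables = vars, r = r, p = p, n = n),
            class = "correlation_matrix")
}

#' Non-parametric comparison of a biomarker across groups
#'
#' Two groups: Mann-Whitney U (exact enumeration when total n <= 10 and no
#' ties, otherwise the normal approximation with the midrank tie
#' correction). Three or more: Kruskal-Wallis chi-square followed by Dunn
#' z-tests with Bonferroni-multiplied p-values capped at 1.
#'
#' @param values numeric vector.
#' @param groups group labels, >= 2 groups with >= 2 observations each.
#' @return object of class `group_comparison`: `method`, `statistic`,
#'   `p_value`, and for >= 3 groups a `posthoc` data.frame of pairwise
#'   Dunn tests (`z`, `p_unadjusted`, `p_adjusted`).
#' @export
group_compare <- function(values, groups) {
  ok <- !is.na(values) & !is.na(groups)
  values <- values[ok]; groups <- factor(as.character(groups[ok]))
  sizes <- table(groups)
  if (length(sizes) < 2) stop_input("need >= 2 groups")
  if (any(sizes < 2)) stop_input("every group needs >= 2 observations")
  if (length(sizes) == 2) {
    lv <- levels(groups)
    exact <- length(values) <= 10 && !any(duplicated(values))
    wt <- suppressWarnings(
      stats::wilcox.test(values[groups == lv[1]], values[groups == lv[2]],
                         exact = exact, correct = !exact))
    out <- list(method = if (exact) "mann-whitney (exact)" else
                  "mann-whitney (normal approximation)",
                statistic = unname(wt$statistic), p_value = wt$p.value,
                groups = lv)
  } else {
    kw <- stats::kruskal.test(values, groups)
    out <- list(method = "kruskal-wallis + dunn-bonferroni",
                statistic = unname(kw$statistic),
                df = unname(kw$parameter), p_value = kw$p.value,
                posthoc = dunn_posthoc(values, groups))
  }
  structure(out, class = "group_comparison")
}

# Dunn pairwise z-tests on the pooled midranks, with the tie-corrected
# variance N(N+1)/12 - sum(t^3 - t)/(12 (N - 1)), Bonferroni-multiplied
# over the k(k-1)/2 comparisons.
dunn_posthoc <- function(values, groups) {
  N <- length(values)
  rk <- rank(values)
  tie <- table(values)
  tiecor <- sum(tie^3 - tie) / (12 * (N - 1))
  v0 <- N * (N + 1) / 12 - tiecor
  lv <- levels(groups)
  m <- length(lv) * (length(lv) - 1) / 2
  res <- do.call(rbind, utils::combn(lv, 2, simplify = FALSE, FUN = function(pr) {
    ni <- sum(groups == pr[1]); nj <- sum(groups == pr[2])
    zi <- mean(rk[groups == pr[1]]) - mean(rk[groups == pr[2]])
    z <- zi / sqrt(v0 * (1 / ni + 1 / nj))
    p <- 2 * stats::pnorm(-abs(z))
    data.frame(group1 = pr[1], group2 = pr[2], z = z,
               p_unadjusted = p, p_adjusted = min(1, p * m))
  }))
  res
}

#' @export
print.group_comparison <- function(x, ...) {
  cat(sprintf("%s: statistic = %.4g, p = %.4g\n",
              x$method, x$statistic, x$p_value))
  if (!is.null(x$posthoc)) print(x$posthoc, row.names = FALSE, digits = 4)
  invisible(x)
}
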