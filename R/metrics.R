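#' @title Discrimination and calibration metrics
#'
#' @description Empirical ROC curves with the Mann-Whitney AUC and De Long
#' structural-component variance, paired De Long comparison of two scores
#' on the same subjects, confusion-matrix classification measures, the
#' Youden optimal cut-off, and the Hosmer-Lemeshow deciles-of-risk
#' calibration test.
#' @name classifier-metrics
NULL

# midrank placement value psi: 1 if event score > nonevent, 1/2 on ties.
# De Long structural components computed via midranks (O(n log n)).
delong_components <- function(score, outcome) {
  x <- score[outcome]   # events
  y <- score[!outcome]  # nonevents
  m <- length(x); n <- length(y)
  rall <- rank(c(x, y), ties.method = "average")
  rx <- rank(x, ties.method = "average")
  ry <- rank(y, ties.method = "average")
  v10 <- (rall[seq_len(m)] - rx) / n              # per-event components
  v01 <- 1 - (rall[m + seq_len(n)] - ry) / m      # per-nonevent components
  list(auc = sum(rall[seq_len(m)]) / (m * n) - (m + 1) / (2 * n),
       v10 = v10, v01 = v01, m = m, n = n)
}

#' Empirical ROC curve with De Long AUC confidence interval
#'
#' Thresholds are the midpoints between distinct sorted scores plus
#' infinite endpoints; a subject is called positive when its score is at
#' or above the threshold. The AUC equals the Mann-Whitney probability
#' with ties counted 1/2; its standard error comes from the De Long
#' structural components and the Wald CI is clipped to [0, 1].
#'
#' @param score numeric risk score (higher = more likely event).
#' @param outcome logical event indicator, both classes present.
#' @return object of class `roc_result`: `thresholds`, `sensitivity`,
#'   `specificity`, `auc`, `auc_se`, `ci` and the class counts.
#' @export
roc_auc <- function(score, outcome) {
  outcome <- as.logical(outcome)
  ok <- !is.na(score) & !is.na(outcome)
  score <- score[ok]; outcome <- outcome[ok]
  if (length(unique(outcome)) < 2)
    stop_input("outcome must contain both classes")
  s <- sort(unique(score))
  thr <- c(-Inf, if (length(s) > 1) (s[-1] + s[-length(s)]) / 2, Inf)
  m <- sum(outcome); n <- sum(!outcome)
  sens <- vapply(thr, function(t) sum(score[outcome] >= t) / m, numeric(1))
  spec <- vapply(thr, function(t) sum(score[!outcome] < t) / n, numeric(1))
  dc <- delong_components(score, outcome)
  se <- sqrt(stats::var(dc$v10) / dc$m + stats::var(dc$v01) / dc$n)
  ci <- pmin(1, pmax(0, dc$auc + c(-1, 1) * stats::qnorm(0.975) * se))
  structure(list(thresholds = thr, sensitivity = sens, specificity = spec,
                 auc = dc$auc, auc_se = se, ci = ci,
                 n_events = m, n_nonevents = n,
                 score = score, outcome = outcome),
            class = "roc_result")
}

#' @export
print.roc_result <- function(x, ...) {
  cat(sprintf("AUC = %.3f (95%% CI %.3f-%.3f), %d events / %d nonevents\n",
              x$auc, x$ci[1], x$ci[2], x$n_events, x$n_nonevents))
  invisible(x)
}

#' De Long paired comparison of two correlated AUCs
#'
#' Both scores are evaluated on the same subjects; the variance of the AUC
#' difference includes the covariance of the paired structural components.
#'
#' @param score_a,score_b paired numeric scores.
#' @param outcome logical event indicator.
#' @return list with `auc_a`, `auc_b`, `difference`, `se`, `z`, `p_value`
#'   and the 95% `ci` of the difference.
#' @export
delong_compare <- function(score_a, score_b, outcome) {
  outcome <- as.logical(outcome)
  if (length(score_a) != length(score_b) ||
      length(score_a) != length(outcome))
    stop_input("scores and outcome must be paired vectors of equal length")
  ok <- !is.na(score_a) & !is.na(score_b) & !is.na(outcome)
  score_a <- score_a[ok]; score_b <- score_b[ok]; outcome <- outcome[ok]
  if (length(unique(outcome)) < 2)
    stop_input("outcome must contain both classes")
  da <- delong_components(score_a, outcome)
  db <- delong_components(score_b, outcome)
  s10 <- stats::cov(cbind(da$v10, db$v10))
  s01 <- stats::cov(cbind(da$v01, db$v01))
  S <- s10 / da$m + s01 / da$n
  d <- da$auc - db$auc
  se <- sqrt(S[1, 1] + S[2, 2] - 2 * S[1, 2])
  if (se < .Machine$double.eps^0.5) {
    z <- 0; p <- 1
    if (abs(d) > 0) { z <- sign(d) * Inf; p <- 0 }
  } else {
    z <- d / se
    p <- 2 * stats::pnorm(-abs(z))
  }
  list(auc_a = da$auc, auc_b = db$auc, difference = d, se = se,
       z = z, p_value = p,
       ci = d + c(-1, 1) * stats::qnorm(0.975) * se)
}

#' Confusion-matrix classification measures
#'
#' Sensitivity, specificity, accuracy (% correctly classified), positive
#' and negative likelihood ratios, the Matthews correlation coefficient
#' and the Youden J. Likelihood ratios with a zero denominator report Inf;
#' MCC is 0 when any margin of the table is empty.
#'
#' @param predicted_positive logical predicted class.
#' @param outcome logical true class.
#' @param threshold optional threshold to record alongside the metrics.
#' @return object of class `classification_report`.
#' @export
confusion_metrics <- function(predicted_positive, outcome, threshold = NA) {
  if (length(predicted_positive) != length(outcome) || !length(outcome))
    stop_input("paired non-empty vectors required")
  pp <- as.logical(predicted_positive); y <- as.logical(outcome)
  tp <- sum(pp & y); fp <- sum(pp & !y)
  fn <- sum(!pp & y); tn <- sum(!pp & !y)
  sens <- if (tp + fn > 0) tp / (tp + fn) else NA_real_
  spec <- if (tn + fp > 0) tn / (tn + fp) else NA_real_
  acc <- (tp + tn) / length(y)
  lr_pos <- if (is.na(spec)) NA_real_ else if (spec == 1) Inf else sens / (1 - spec)
  lr_neg <- if (is.na(spec)) NA_real_ else if (spec == 0) Inf else (1 - sens) / spec
  denom <- sqrt(prod(c(tp + fp, tp + fn, tn + fp, tn + fn)))
  mcc <- if (denom == 0) 0 else (tp * tn - fp * fn) / denom
  structure(list(TP = tp, FP = fp, FN = fn, TN = tn,
                 sensitivity = sens, specificity = spec, accuracy = acc,
                 lr_positive = lr_pos, lr_negative = lr_neg,
                 mcc = mcc, youden_j = sens + spec - 1,
                 threshold = threshold),
            class = "classification_report")
}

#' @export
print.classification_report <- function(x, ...) {
  cat(sprintf("TP %d FP %d FN %d TN %d | sens %.1f%% spec %.1f%% acc %.1f%% MCC %.3f J %.3f\n",
              x$TP, x$FP, x$FN, x$TN, 100 * x$sensitivity,
              100 * x$specificity, 100 * x$accuracy, x$mcc, x$youden_j))
  invisible(x)
}

#' Youden-optimal cut-off of an ROC curve
#'
#' The threshold maximizing J = sensitivity + specificity - 1; ties are
#' broken toward the higher-specificity (larger) threshold.
#'
#' @param roc a `roc_result`.
#' @return list with `threshold`, `youden_j` and the full
#'   `classification_report` at that cut-off.
#' @export
youden_optimal <- function(roc) {
  stopifnot(inherits(roc, "roc_result"))
  j <- roc$sensitivity + roc$specificity - 1
  best <- which(j >= max(j) - 1e-12)
  pick <- best[which.max(roc$thresholds[best])]
  thr <- roc$thresholds[pick]
  rep <- confusion_metrics(roc$score >= thr, roc$outcome, threshold = thr)
  list(threshold = thr, youden_j = j[pick], report = rep)
}

#' Hosmer-Lemeshow deciles-of-risk calibration test
#'
#' Subjects are grouped into g equal-count bins of predicted probability
#' (ties assigned to the lower bin); the statistic sums
#' `(O - E)^2 / (E * (1 - E / n_k))` over bins and is referred to a
#' chi-square with g - 2 degrees of freedom.
#'
#' @param predicted_prob probabilities in (0, 1).
#' @param outcome logical events.
#' @param g number of groups (default 10); requires `n >= 2 * g`.
#' @return list with `statistic`, `df`, `p_value` and the per-group table.
#' @export
hosmer_lemeshow <- function(predicted_prob, outcome, g = 10) {
  p <- as.numeric(predicted_prob); y <- as.logical(outcome)
  if (length(p) != length(y)) stop_input("paired vectors required")
  if (any(p <= 0 | p >= 1)) stop_input("probabilities must lie in (0, 1)")
  if (length(p) < 2 * g)
    stop_input(sprintf("n = %d too small for g = %d groups; reduce g",
                       length(p), g))
  # equal-count bins on the sort order; tied probabilities fall in the
  # lower bin (ties.method = "first" after an ordering by p)
  ord <- order(p)
  bin <- integer(length(p))
  bin[ord] <- ceiling(seq_along(p) / (length(p) / g))
  obs <- tapply(y, bin, sum)
  exp <- tapply(p, bin, sum)
  nk <- tabulate(bin, nbins = g)
  stat <- sum((obs - exp)^2 / (exp * (1 - exp / nk)))
  df <- g - 2
  list(statistic = stat, df = df,
       p_value = stats::pchisq(stat, df, lower.tail = FALSE),
       groups = data.frame(bin = seq_len(g), n = nk,
                           observed = as.numeric(obs),
                           expected = as.numeric(exp)))
}
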