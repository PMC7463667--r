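#' @title Net reclassification improvement and integrated discrimination
#'   improvement
#'
#' @description NRI and IDI quantify the gain of a new risk model over an
#' old one from their predicted probabilities. The event NRI component is
#' P(up | event) - P(down | event), the nonevent component
#' P(down | nonevent) - P(up | nonevent), and the overall NRI their sum;
#' the continuous variant counts any change of predicted probability, the
#' categorical variant counts risk-category crossings. IDI is the change
#' in the discrimination slope: the gain in mean predicted probability for
#' events minus the gain for nonevents. Confidence intervals come from a
#' subject-level percentile bootstrap.
#' @name reclassification-stats
NULL

classify_movement <- function(p_old, p_new, variant, categories) {
  if (variant == "continuous") {
    up <- p_new > p_old; down <- p_new < p_old
  } else {
    co <- findInterval(p_old, categories)
    cn <- findInterval(p_new, categories)
    up <- cn > co; down <- cn < co
  }
  list(up = up, down = down)
}

#' Net reclassification improvement
#'
#' @param p_old,p_new paired predicted probabilities (or risk scores) from
#'   the old and new models.
#' @param outcome logical event indicator, both classes present.
#' @param variant `"continuous"` (default; any probability change counts)
#'   or `"categorical"` (movement across `categories` cut points).
#' @param categories cut points defining the risk categories; required for
#'   the categorical variant.
#' @return object of class `nri_result` with `nri` (overall),
#'   `nri_events`, `nri_nonevents`, the movement counts, and the variant.
#' @examples
#' nri(c(.2, .2, .2, .2), c(.4, .4, .1, .2), outcome = rep(TRUE, 4))
#' @export
nri <- function(p_old, p_new, outcome,
                variant = c("continuous", "categorical"),
                categories = NULL) {
  variant <- match.arg(variant)
  outcome <- as.logical(outcome)
  if (length(p_old) != length(p_new) || length(p_old) != length(outcome))
    stop_input("p_old, p_new and outcome must be paired")
  if (length(unique(outcome)) < 2)
    stop_input("outcome must contain both classes")
  if (variant == "categorical" && is.null(categories))
    stop_input("categorical NRI requires category cut points")
  mv <- classify_movement(p_old, p_new, variant, categories)
  ev <- outcome; ne <- !outcome
  nri_ev <- mean(mv$up[ev]) - mean(mv$down[ev])
  nri_ne <- mean(mv$down[ne]) - mean(mv$up[ne])
  structure(list(nri = nri_ev + nri_ne,
                 nri_events = nri_ev, nri_nonevents = nri_ne,
                 n_events = sum(ev), n_nonevents = sum(ne),
                 movements = data.frame(
                   class = c("event", "nonevent"),
                   up = c(sum(mv$up[ev]), sum(mv$up[ne])),
                   down = c(sum(mv$down[ev]), sum(mv$down[ne]))),
                 variant = variant),
            class = "nri_result")
}

#' Integrated discrimination improvement
#'
#' `idi = (mean p_new - mean p_old | events) -
#'        (mean p_new - mean p_old | nonevents)`.
#'
#' @inheritParams nri
#' @return list with `idi` and the four class-wise means.
#' @export
idi <- function(p_old, p_new, outcome) {
  outcome <- as.logical(outcome)
  if (length(p_old) != length(p_new) || length(p_old) != length(outcome))
    stop_input("p_old, p_new and outcome must be paired")
  if (length(unique(outcome)) < 2)
    stop_input("outcome must contain both classes")
  m_new_ev <- mean(p_new[outcome]); m_old_ev <- mean(p_old[outcome])
  m_new_ne <- mean(p_new[!outcome]); m_old_ne <- mean(p_old[!outcome])
  list(idi = (m_new_ev - m_old_ev) - (m_new_ne - m_old_ne),
       mean_new_events = m_new_ev, mean_old_events = m_old_ev,
       mean_new_nonevents = m_new_ne, mean_old_nonevents = m_old_ne)
}

#' Percentile bootstrap confidence interval for a paired-data statistic
#'
#' Subject-level resampling with replacement. A resample on which the
#' statistic is undefined (e.g. a single-class outcome draw) is redrawn
#' and counted. The p-value uses the normal approximation with the
#' bootstrap standard error; a (numerically) constant statistic yields a
#' zero-width CI and p = 0 for a nonzero value, p = 1 at zero.
#'
#' @param statistic function taking a data.frame (a resample of `data`)
#'   and returning a scalar; `NA`/errors mark the resample degenerate.
#' @param data data.frame of paired subject-level rows.
#' @param B number of bootstrap replicates (>= 100 for reported CIs).
#' @param seed integer seed; results are reproducible per seed.
#' @param conf confidence level.
#' @return object of class `bootstrap_ci`: `estimate`, `ci`, `se`,
#'   `p_value`, `B`, `seed` and `n_redrawn`.
#' @export
bootstrap_ci <- function(statistic, data, B = 1000L, seed = 1L,
                         conf = 0.95) {
  if (B < 1) stop_input("B must be >= 1")
  if (B < 100) warning("B < 100: reported CI is unreliable")
  est <- statistic(data)
  if (!is.finite(est)) stop_input("statistic undefined on the full data")
  set.seed(seed)
  n <- nrow(data)
  stats_b <- numeric(B)
  redrawn <- 0L
  for (b in seq_len(B)) {
    repeat {
      idx <- sample.int(n, n, replace = TRUE)
      val <- tryCatch(statistic(data[idx, , drop = FALSE]),
                      error = function(e) NA_real_)
      if (is.finite(val)) break
      redrawn <- redrawn + 1L
      if (redrawn > 100L * B)
        stop_input("statistic undefined on virtually every resample")
    }
    stats_b[b] <- val
  }
  alpha <- (1 - conf) / 2
  ci <- unname(stats::quantile(stats_b, c(alpha, 1 - alpha), type = 7))
  se <- stats::sd(stats_b)
  p <- if (se < .Machine$double.eps^0.5) {
    if (abs(est) < .Machine$double.eps^0.5) 1 else 0
  } else 2 * stats::pnorm(-abs(est / se))
  structure(list(estimate = est, ci = ci, se = se, p_value = p,
                 B = as.integer(B), seed = as.integer(seed),
                 n_redrawn = redrawn, replicates = stats_b),
            class = "bootstrap_ci")
}

#' @export
print.bootstrap_ci <- function(x, ...) {
  cat(sprintf("estimate %.4f (bootstrap %d reps, 95%% CI %.4f-%.4f, p = %.4g)\n",
              x$estimate, x$B, x$ci[1], x$ci[2], x$p_value))
  invisible(x)
}

#' NRI and IDI of a new model over an old one, with bootstrap CIs
#'
#' Convenience wrapper combining [nri()], [idi()] and [bootstrap_ci()] on
#' the same subject table.
#'
#' @inheritParams nri
#' @param B,seed bootstrap replicates and seed.
#' @return object of class `nri_idi_result` with the point estimates and
#'   a `bootstrap` list of `bootstrap_ci` objects for nri, its components
#'   and idi.
#' @export
nri_idi <- function(p_old, p_new, outcome,
                    variant = c("continuous", "categorical"),
                    categories = NULL, B = 1000L, seed = 1L) {
  variant <- match.arg(variant)
  dat <- data.frame(p_old = p_old, p_new = p_new,
                    outcome = as.logical(outcome))
  point_nri <- nri(p_old, p_new, outcome, variant, categories)
  point_idi <- idi(p_old, p_new, outcome)
  boots <- list(
    nri = bootstrap_ci(function(d)
      nri(d$p_old, d$p_new, d$outcome, variant, categories)$nri,
      dat, B = B, seed = seed),
    nri_events = bootstrap_ci(function(d)
      nri(d$p_old, d$p_new, d$outcome, variant, categories)$nri_events,
      dat, B = B, seed = seed),
    nri_nonevents = bootstrap_ci(function(d)
      nri(d$p_old, d$p_new, d$outcome, variant, categories)$nri_nonevents,
      dat, B = B, seed = seed),
    idi = bootstrap_ci(function(d) idi(d$p_old, d$p_new, d$outcome)$idi,
                       dat, B = B, seed = seed))
  structure(list(nri = point_nri, idi = point_idi,
                 bootstrap = boots, variant = variant,
                 B = as.integer(B), seed = as.integer(seed)),
            class = "nri_idi_result")
}

#' @export
print.nri_idi_result <- function(x, ...) {
  b <- x$bootstrap
  cat(sprintf("NRI (%s): %.3f (95%% CI %.3f-%.3f, p = %.4g)\n",
              x$variant, x$nri$nri, b$nri$ci[1], b$nri$ci[2], b$nri$p_value))
  cat(sprintf("  events %.3f, nonevents %.3f\n",
              x$nri$nri_events, x$nri$nri_nonevents))
  cat(sprintf("IDI: %.3f (95%% CI %.3f-%.3f, p = %.4g)\n",
              x$idi$idi, b$idi$ci[1], b$idi$ci[2], b$idi$p_value))
  invisible(x)
}
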