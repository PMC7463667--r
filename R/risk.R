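#' @title GlycA-augmented mSCORE risk scoring
#'
#' @description The augmentation rule bins a subject's serum GlycA against
#' quartiles of a healthy-reference population and adds integer points to
#' the mSCORE 10-year risk percentage: Q1 (below the 25th percentile) -1,
#' Q2 +0, Q3 +1, Q4 (at or above the 75th percentile) +2. The combined
#' percentage is mapped back to the ESC risk categories (low < 1%,
#' moderate 1 to < 5%, high 5 to < 10%, very high >= 10%).
#' @name risk-scoring
NULL

GLYCA_POINTS_MAP <- c(Q1 = -1L, Q2 = 0L, Q3 = 1L, Q4 = 2L)

RISK_CATEGORIES <- c("low", "moderate", "high", "very_high")

#' Reference quartiles for GlycA point assignment
#'
#' Build the cut-point object either directly from three concentrations or
#' from a healthy-control sample via [compute_reference_quartiles()].
#'
#' @param q25,q50,q75 strictly increasing GlycA concentrations (umol/L).
#' @param source_n size of the population the cut points came from.
#' @return an object of class `reference_quartiles`.
#' @examples
#' reference_quartiles(618.83, 734.55, 822.36)
#' @export
reference_quartiles <- function(q25, q50, q75, source_n = NA_integer_) {
  if (!(is.finite(q25) && is.finite(q50) && is.finite(q75)) ||
      !(q25 < q50 && q50 < q75) || q25 <= 0)
    stop_input("quartiles must be positive and strictly increasing")
  structure(list(q25 = q25, q50 = q50, q75 = q75,
                 points_map = GLYCA_POINTS_MAP,
                 source_n = source_n),
            class = "reference_quartiles")
}

#' @export
print.reference_quartiles <- function(x, ...) {
  cat(sprintf("GlycA reference quartiles (n = %s): %.2f / %.2f / %.2f umol/L\n",
              x$source_n, x$q25, x$q50, x$q75))
  cat("  points: Q1 -1, Q2 +0, Q3 +1, Q4 +2\n")
  invisible(x)
}

#' Derive reference quartiles from a healthy-control GlycA sample
#'
#' 25th/50th/75th percentiles by linear interpolation between order
#' statistics (the `quantile()` type-7 default).
#'
#' @param hc_glyca numeric vector of >= 4 finite positive concentrations.
#' @return a `reference_quartiles`.
#' @examples
#' compute_reference_quartiles(1:7)   # 2.5 / 4 / 5.5
#' @export
compute_reference_quartiles <- function(hc_glyca) {
  hc_glyca <- hc_glyca[is.finite(hc_glyca)]
  if (length(hc_glyca) < 4)
    stop_input("need >= 4 finite GlycA values to define quartiles")
  if (any(hc_glyca <= 0))
    stop_input("GlycA concentrations must be positive")
  q <- unname(stats::quantile(hc_glyca, c(0.25, 0.50, 0.75), type = 7))
  if (any(diff(q) <= 0))
    stop_input("degenerate quartiles: sample has too little spread")
  reference_quartiles(q[1], q[2], q[3], source_n = length(hc_glyca))
}

#' GlycA points for the mSCORE augmentation
#'
#' Vectorised quartile lookup: -1 below q25, 0 in [q25, q50), +1 in
#' [q50, q75), +2 at or above q75. Boundaries are left-closed on the upper
#' category: a value equal to a cut point takes the higher category.
#'
#' @param glyca GlycA concentration(s), umol/L, finite and >= 0.
#' @param ref a `reference_quartiles`.
#' @return integer points in {-1, 0, 1, 2}.
#' @examples
#' ref <- reference_quartiles(618.83, 734.55, 822.36)
#' glyca_points(c(500, 700, 800, 900), ref)  # -1 0 1 2
#' @export
glyca_points <- function(glyca, ref) {
  stopifnot(inherits(ref, "reference_quartiles"))
  if (any(!is.finite(glyca)) || any(glyca < 0))
    stop_input("GlycA values must be finite and non-negative")
  pts <- findInterval(glyca, c(ref$q25, ref$q50, ref$q75)) - 1L
  as.integer(pts)
}

#' ESC risk category of a 10-year risk percentage
#'
#' low < 1, moderate 1 to < 5, high 5 to < 10, very_high >= 10 (left-closed
#' boundaries; thresholds configurable).
#'
#' @param score risk percentage(s), >= 0.
#' @param thresholds upper-open cut points of the low/moderate/high bands.
#' @return factor with levels low < moderate < high < very_high.
#' @export
categorize_mscore <- function(score, thresholds = c(1, 5, 10)) {
  if (any(!is.finite(score)) || any(score < 0))
    stop_input("risk score must be finite and >= 0")
  idx <- findInterval(score, thresholds) + 1L
  factor(RISK_CATEGORIES[idx], levels = RISK_CATEGORIES, ordered = TRUE)
}

#' Combine mSCORE and GlycA points into an augmented risk assessment
#'
#' combined = max(0, mscore + points), clamped because a -1 point can push
#' a sub-1% mSCORE negative; both the original and combined percentages are
#' categorised.
#'
#' @param mscore 10-year risk percentage(s), >= 0.
#' @param points integer GlycA points from [glyca_points()].
#' @return data.frame with mscore, mscore_category, glyca_points,
#'   combined_score and combined_category.
#' @export
combine_score <- function(mscore, points) {
  if (length(mscore) != length(points))
    stop_input("mscore and points must be paired")
  combined <- pmax(0, mscore + points)
  data.frame(mscore = mscore,
             mscore_category = categorize_mscore(mscore),
             glyca_points = as.integer(points),
             combined_score = combined,
             combined_category = categorize_mscore(combined))
}

#' Score a cohort table with the GlycA-augmented mSCORE
#'
#' Derives reference quartiles from the cohort's own HC rows (or accepts
#' fixed cut points), assigns points to every subject and appends the
#' scoring columns.
#'
#' @param cohort cohort data.frame with `glyca` and `mscore` columns (and
#'   a `group` column when `ref` is derived from HC rows).
#' @param ref optional `reference_quartiles`; default derives them from
#'   `cohort$glyca[cohort$group == ref_group]`.
#' @param ref_group group label of the reference population.
#' @return the cohort with `glyca_points`, `combined_score`,
#'   `mscore_category`, `combined_category` appended; the quartiles are
#'   attached as attribute `"reference_quartiles"`.
#' @export
score_cohort <- function(cohort, ref = NULL, ref_group = "HC") {
  if (is.null(ref)) {
    if (!"group" %in% names(cohort))
      stop_input("cohort needs a 'group' column to derive reference quartiles")
    ref <- compute_reference_quartiles(cohort$glyca[cohort$group == ref_group])
  }
  sc <- combine_score(cohort$mscore, glyca_points(cohort$glyca, ref))
  out <- cbind(cohort, sc[, c("mscore_category", "glyca_points",
                              "combined_score", "combined_category")])
  attr(out, "reference_quartiles") <- ref
  out
}

#' Cross-tabulate risk categories before and after GlycA augmentation
#'
#' 4x4 table of original (rows) against augmented (columns) categories,
#' with upward/downward reclassification counts; optionally stratified by
#' subclinical CV disease status.
#'
#' @param assessments data.frame with `mscore_category` and
#'   `combined_category` (e.g. from [combine_score()] or [score_cohort()]).
#' @param cvd_status optional logical vector aligned with `assessments`.
#' @return an object of class `reclassification_table`: `counts` (4x4),
#'   `n`, `upward`, `downward`, and per-stratum tables under `strata` when
#'   `cvd_status` is given.
#' @export
reclassification_table <- function(assessments, cvd_status = NULL) {
  need <- c("mscore_category", "combined_category")
  if (!all(need %in% names(assessments)) || nrow(assessments) == 0)
    stop_input("assessments must be non-empty with mscore_category and combined_category")
  if (!is.null(cvd_status) && length(cvd_status) != nrow(assessments))
    stop_input("cvd_status length must match assessments")
  f <- function(df) {
    old <- factor(df$mscore_category, levels = RISK_CATEGORIES)
    new <- factor(df$combined_category, levels = RISK_CATEGORIES)
    counts <- table(original = old, augmented = new)
    io <- as.integer(old); in_ <- as.integer(new)
    list(counts = counts, n = nrow(df),
         upward = sum(in_ > io), downward = sum(in_ < io))
  }
  out <- f(assessments)
  if (!is.null(cvd_status)) {
    keep <- !is.na(cvd_status)
    out$strata <- list(
      cvd = f(assessments[keep & cvd_status, , drop = FALSE]),
      no_cvd = f(assessments[keep & !cvd_status, , drop = FALSE]))
  }
  class(out) <- "reclassification_table"
  out
}

#' @export
print.reclassification_table <- function(x, ...) {
  cat(sprintf("Risk reclassification (n = %d): %d upward, %d downward\n",
              x$n, x$upward, x$downward))
  print(x$counts)
  invisible(x)
}
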