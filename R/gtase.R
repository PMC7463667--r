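#' @title Serum glycosyltransferase activity from a colorimetric assay
#'
#' @description The coupled assay releases inorganic phosphate from the
#' leaving nucleotide diphosphate; malachite-green absorbance at 620 nm is
#' converted to phosphate concentration through a standard curve, each
#' sample is read with and without the coupling phosphatase so the paired
#' difference cancels serum phosphatase background, and activity is the
#' phosphate released per minute of reaction (uM P/min).
#' @name gtase-assay
NULL

#' Fit a phosphate standard curve
#'
#' Ordinary least-squares line of absorbance on known inorganic-phosphate
#' concentration (a serial dilution, typically 100 down to 1.56 uM).
#'
#' @param concentration known phosphate concentrations (uM), >= 3 distinct.
#' @param absorbance matched absorbances.
#' @return an object of class `gtase_curve`: slope (absorbance per uM),
#'   intercept, `r_squared`, and the points.
#' @examples
#' conc <- 100 / 2^(0:6)
#' fit_standard_curve(conc, 0.002 * conc + 0.05)
#' @export
fit_standard_curve <- function(concentration, absorbance) {
  if (length(concentration) != length(absorbance))
    stop_input("concentration and absorbance must be paired")
  if (length(unique(concentration)) < 3)
    stop_input("standard curve needs >= 3 distinct concentrations")
  if (stats::var(concentration) == 0)
    stop_input("standard concentrations have zero variance")
  fit <- stats::lm(absorbance ~ concentration)
  sst <- sum((absorbance - mean(absorbance))^2)
  r2 <- if (sst == 0) 1 else 1 - sum(stats::residuals(fit)^2) / sst
  structure(list(slope = unname(stats::coef(fit)[2]),
                 intercept = unname(stats::coef(fit)[1]),
                 r_squared = r2,
                 points = data.frame(concentration, absorbance)),
            class = "gtase_curve")
}

#' Compute glycosyltransferase activity from paired wells
#'
#' The with-phosphatase minus without-phosphatase absorbance difference is
#' converted to phosphate through the standard-curve slope (the intercept
#' cancels in the difference) and divided by the reaction time. Negative
#' differences — serum phosphatase background exceeding the signal — clamp
#' to zero activity and raise a flag rather than an error.
#'
#' @param abs_with,abs_without absorbances with/without the coupling
#'   phosphatase (vectors are processed element-wise).
#' @param curve a `gtase_curve` with positive slope.
#' @param minutes reaction time (> 0); default 30.
#' @param sample_id optional identifiers.
#' @return a data.frame with `sample_id`, `phosphate_released` (uM),
#'   `reaction_minutes`, `activity` (uM P/min) and `clamped`.
#' @export
compute_activity <- function(abs_with, abs_without, curve, minutes = 30,
                             sample_id = NULL) {
  if (!inherits(curve, "gtase_curve") || !is.finite(curve$slope))
    stop_input("a fitted gtase_curve is required")
  if (curve$slope <= 0) stop_input("assay error: standard-curve slope <= 0")
  if (minutes <= 0) stop_input("reaction_minutes must be positive")
  if (length(abs_with) != length(abs_without))
    stop_input("paired wells required: abs_with/abs_without lengths differ")
  delta <- abs_with - abs_without
  clamped <- delta < 0
  if (any(clamped))
    warning(sprintf("%d well(s) with negative paired difference clamped to 0",
                    sum(clamped)))
  phosphate <- pmax(delta, 0) / curve$slope
  data.frame(
    sample_id = sample_id %||% paste0("S", seq_along(delta)),
    phosphate_released = phosphate,
    reaction_minutes = minutes,
    activity = phosphate / minutes,
    clamped = clamped)
}

#' Process a plate of paired readings against a standards table
#'
#' @param plate data.frame with columns `sample_id`, `abs_with`,
#'   `abs_without` (e.g. from `read.csv`).
#' @param standards data.frame with columns `concentration`, `absorbance`.
#' @param minutes reaction time.
#' @return the [compute_activity()] results with the curve attached as an
#'   attribute.
#' @export
gtase_plate <- function(plate, standards, minutes = 30) {
  curve <- fit_standard_curve(standards$concentration, standards$absorbance)
  out <- compute_activity(plate$abs_with, plate$abs_without, curve,
                          minutes = minutes, sample_id = plate$sample_id)
  attr(out, "curve") <- curve
  out
}
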