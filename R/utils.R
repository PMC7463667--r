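`%||%` <- function(a, b) if (is.null(a)) b else a

#' Solve a lognormal sdlog from a median and interquartile range
#'
#' For X ~ lognormal(meanlog = log(median), sdlog = s), the IQR is
#' 2 * median * sinh(z * s) with z = qnorm(0.75), which inverts in closed
#' form.
#'
#' @param median,iqr positive scalars on the natural scale.
#' @return sdlog.
#' @keywords internal
#' @noRd
lnorm_sdlog_from_iqr <- function(median, iqr) {
  stopifnot(median > 0, iqr > 0)
  asinh(iqr / (2 * median)) / stats::qnorm(0.75)
}

# Truncated-normal sampler via inverse-CDF; vectorised over n.
rtruncnorm <- function(n, mean, sd, lower = -Inf, upper = Inf) {
  pl <- stats::pnorm(lower, mean, sd)
  pu <- stats::pnorm(upper, mean, sd)
  stats::qnorm(pl + stats::runif(n) * (pu - pl), mean, sd)
}

#' Solve the intercept of a logistic outcome link for a target prevalence
#'
#' Given a linear predictor offset `slope * x` per subject, finds the
#' intercept `a` such that `mean(plogis(a + slope * x))` equals the target
#' marginal prevalence on this sample.
#'
#' @param x numeric covariate vector.
#' @param slope coefficient on the logit scale.
#' @param target prevalence in (0, 1).
#' @return the intercept (scalar).
#' @export
solve_logistic_intercept <- function(x, slope, target) {
  stopifnot(is.numeric(x), length(x) > 0, target > 0, target < 1)
  f <- function(a) mean(stats::plogis(a + slope * x)) - target
  stats::uniroot(f, lower = -80, upper = 80, tol = 1e-12)$root
}

# Stop with a classed condition so callers/tests can distinguish user
# errors from internal ones.
stop_input <- function(msg, class = "glycrisk_input_error") {
  stop(structure(class = c(class, "error", "condition"),
                 list(message = msg, call = sys.call(-1))))
}
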