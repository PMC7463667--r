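#' Default rank-correlation targets for the arthritis cohort generator
#'
#' Named vector of Spearman correlations imposed (via a Gaussian copula)
#' between biomarker columns of generated RA subjects. Names are
#' `"var1:var2"` pairs. The glycoprotein-inflammation entries reproduce the
#' associations reported for early RA serum (GlycA/GlycB against CRP, ESR,
#' DAS28, SDAI, HAQ, glycosyltransferase activity and cIMT); the remaining
#' entries (acute-phase cross-correlations, DAS28-SDAI agreement, the weak
#' GlycA-mSCORE link reflecting independence from traditional risk factors)
#' are structural defaults chosen once for plausibility.
#'
#' @return named numeric vector.
#' @export
default_spearman_targets <- function() {
  c("glyca:crp"    = 0.480,
    "glyca:esr"    = 0.331,
    "glyca:das28"  = 0.306,
    "glyca:sdai"   = 0.221,
    "glyca:haq"    = 0.179,
    "glyca:gtase"  = 0.405,
    "glyca:cimt"   = 0.312,
    "glyca:glycb"  = 0.600,
    "glycb:crp"    = 0.531,
    "glycb:esr"    = 0.440,
    "glycb:das28"  = 0.376,
    "glycb:sdai"   = 0.279,
    "glycb:haq"    = 0.239,
    "glycb:gtase"  = 0.327,
    "crp:esr"      = 0.550,
    "das28:sdai"   = 0.850,
    "das28:crp"    = 0.450,
    "das28:esr"    = 0.450,
    "sdai:crp"     = 0.400,
    "sdai:esr"     = 0.400,
    "mscore:cimt"  = 0.450,
    "mscore:glyca" = 0.100)
}

#' Configuration for the synthetic arthritis cohort generator
#'
#' Captures the study conditions the generator emulates: group sizes,
#' the healthy-control GlycA reference quartiles, the RA GlycA location and
#' spread, the rank-correlation structure among biomarkers, and the logistic
#' links tying GlycA to subclinical cardiovascular disease and to 6-month
#' DAS28 remission.
#'
#' @param n_hc,n_csa,n_ra group sizes (healthy controls, clinically suspect
#'   arthralgia, early RA). Defaults are the study's 28/14/82.
#' @param glyca_ref_quartiles healthy-control GlycA 25th/50th/75th
#'   percentiles in umol/L, strictly increasing.
#' @param ra_glyca_median,ra_glyca_iqr RA GlycA location/spread (umol/L).
#' @param spearman_targets named vector `"a:b" = rho` of Spearman targets
#'   for RA biomarker pairs; see [default_spearman_targets()].
#' @param or_cvd_per_unit odds ratio for subclinical CV disease per umol/L
#'   GlycA (logistic link slope `log(or)`).
#' @param cvd_prevalence target marginal prevalence of subclinical CV
#'   disease among RA subjects.
#' @param or_remission_per_unit odds ratio for 6-month DAS28 remission per
#'   umol/L GlycA.
#' @param remission_rate6 target marginal 6-month remission rate among RA.
#' @param remission12_followup fraction of RA subjects with an observed
#'   12-month remission status (the remainder is missing completely at
#'   random).
#' @param seed integer RNG seed; every draw of the generator is a
#'   deterministic function of the configuration including this seed.
#' @return an object of class `glycrisk_config` (a validated list).
#' @export
generator_config <- function(n_hc = 28L, n_csa = 14L, n_ra = 82L,
                             glyca_ref_quartiles = c(618.83, 734.55, 822.36),
                             ra_glyca_median = 882,
                             ra_glyca_iqr = 200,
                             spearman_targets = default_spearman_targets(),
                             or_cvd_per_unit = 1.004,
                             cvd_prevalence = 0.596,
                             or_remission_per_unit = 0.993,
                             remission_rate6 = 0.54,
                             remission12_followup = 0.84,
                             seed = 1L) {
  cfg <- list(n_hc = as.integer(n_hc), n_csa = as.integer(n_csa),
              n_ra = as.integer(n_ra),
              glyca_ref_quartiles = as.numeric(glyca_ref_quartiles),
              ra_glyca_median = ra_glyca_median,
              ra_glyca_iqr = ra_glyca_iqr,
              spearman_targets = spearman_targets,
              or_cvd_per_unit = or_cvd_per_unit,
              cvd_prevalence = cvd_prevalence,
              or_remission_per_unit = or_remission_per_unit,
              remission_rate6 = remission_rate6,
              remission12_followup = remission12_followup,
              seed = as.integer(seed))
  validate_generator_config(cfg)
  class(cfg) <- "glycrisk_config"
  cfg
}

validate_generator_config <- function(cfg) {
  with(cfg, {
    if (any(c(n_hc, n_csa, n_ra) <= 0))
      stop_input("all group sizes must be positive",
                 "glycrisk_config_error")
    q <- glyca_ref_quartiles
    if (length(q) != 3 || any(!is.finite(q)) || any(q <= 0) ||
        !all(diff(q) > 0))
      stop_input("glyca_ref_quartiles must be 3 strictly increasing positive values",
                 "glycrisk_config_error")
    if (ra_glyca_median <= 0 || ra_glyca_iqr <= 0)
      stop_input("RA GlycA median and IQR must be positive",
                 "glycrisk_config_error")
    if (any(abs(spearman_targets) > 1))
      stop_input("spearman targets must lie in [-1, 1]",
                 "glycrisk_config_error")
    if (cvd_prevalence <= 0 || cvd_prevalence >= 1 ||
        remission_rate6 <= 0 || remission_rate6 >= 1)
      stop_input("prevalences must lie in (0, 1)", "glycrisk_config_error")
    if (or_cvd_per_unit <= 0 || or_remission_per_unit <= 0)
      stop_input("odds ratios must be positive", "glycrisk_config_error")
    if (remission12_followup < 0 || remission12_followup > 1)
      stop_input("remission12_followup must lie in [0, 1]",
                 "glycrisk_config_error")
  })
  invisible(cfg)
}

#' Read a generator configuration from JSON or YAML
#'
#' The file holds a flat mapping of [generator_config()] arguments;
#' `spearman_targets` is a mapping from `"a:b"` pair names to correlations.
#' Absent fields fall back to the defaults.
#'
#' @param path path to a `.json`, `.yaml` or `.yml` file.
#' @return a `glycrisk_config`.
#' @export
read_generator_config <- function(path) {
  ext <- tolower(tools::file_ext(path))
  raw <- if (ext %in% c("yaml", "yml")) {
    if (!requireNamespace("yaml", quietly = TRUE))
      stop_input("reading YAML configs requires the 'yaml' package")
    yaml::read_yaml(path)
  } else {
    jsonlite::read_json(path, simplifyVector = TRUE)
  }
  if (!is.null(raw$spearman_targets))
    raw$spearman_targets <- unlist(raw$spearman_targets)
  do.call(generator_config, raw)
}
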