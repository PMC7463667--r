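# glycrisk

Cardiovascular (CV) risk stratification in early rheumatoid arthritis (RA)
is known to underestimate risk because conventional scores do not capture
systemic inflammation. **glycrisk** implements, end to end, an analysis in
which the serum glycoprotein NMR signal **GlycA** is used to augment the
EULAR-modified SCORE estimate (**mSCORE**, a 10-year fatal-CVD risk
percentage) and the augmented score is evaluated against subclinical
atherosclerosis with a full discrimination / calibration / reclassification
statistic suite. It is aimed at biostatisticians and rheumatology /
cardiometabolic researchers who want a tested, reproducible implementation
of every stage of such an analysis.

## What it computes

* **NMR glycoprotein deconvolution** — the 1.90–2.15 ppm region of a 1D
  ¹H-NMR serum spectrum is modelled as two Lorentzian lines (GlycA ≈ 2.00
  ppm, GlycB ≈ 2.07 ppm) over a linear baseline. For each signal the fit
  reports position, height above baseline *h*, full width at half height
  *w*, area *A* = π·h·w/2 (proportional to the number of protein–sugar
  bonds), the mobility proxy H/W = *h*/*w*, and the calibrated
  concentration *c* = *A*·f (μmol/L).
* **GlycA-augmented mSCORE** — healthy-reference GlycA quartile boundaries
  (defaults 618.83 / 734.55 / 822.36 μmol/L) map a concentration to integer
  points (Q1: −1, Q2: +0, Q3: +1, Q4: +2) which are added to the mSCORE
  percentage; both scores are mapped to the ESC risk categories
  (low < 1%, moderate 1–<5%, high 5–<10%, very high ≥ 10%) and
  cross-tabulated into a reclassification table.
* **Evaluation suite** — ROC/AUC with De Long structural-component
  variance, paired De Long comparison of two scores, confusion-matrix
  metrics (sensitivity, specificity, accuracy, likelihood ratios, MCC),
  Youden-optimal cut-offs, Hosmer–Lemeshow deciles-of-risk calibration,
  and continuous/categorical **NRI** and **IDI** with subject-level
  percentile-bootstrap confidence intervals.
* **Supporting stages** — logistic regression with odds ratios and Wald
  CIs (separation detected and flagged), Spearman correlation matrices
  with network export, Kruskal–Wallis / Mann–Whitney group comparisons
  with Dunn–Bonferroni post hocs, and a colorimetric glycosyltransferase
  activity assay (phosphate standard curve + paired background
  subtraction, μM P/min).
* **Synthetic cohort generator** — a Gaussian-copula generator that
  reproduces the statistical structure of an early-RA study population
  (HC reference quartiles, RA GlycA elevation, biomarker rank
  correlations, logistic outcome links for subclinical CV disease and
  treatment response), so the whole pipeline runs and is tested without
  patient data.

## Worked example

```r
library(glycrisk)

cfg    <- generator_config(seed = 7)      # 28 HC, 14 CSA, 82 RA
cohort <- generate_cohort(cfg)
scored <- score_cohort(cohort)            # quartiles from the HC rows
attr(scored, "reference_quartiles")
#> GlycA reference quartiles (n = 28): 615.52 / 728.33 / 828.63 umol/L
#>   points: Q1 -1, Q2 +0, Q3 +1, Q4 +2

ra <- scored[scored$group == "RA", ]
reclassification_table(ra, cvd_status = ra$subclinical_cvd)
#> Risk reclassification (n = 82): 31 upward, 1 downward
#>            augmented
#> original    low moderate high very_high
#>   low         1       15    0         0
#>   moderate    1       34   14         0
#>   high        0        0   13         2
#>   very_high   0        0    0         2

dl <- delong_compare(ra$combined_score, ra$mscore, ra$subclinical_cvd)
# Delta AUC = 0.062 (95% CI 0.004-0.119), p = 0.037

f_old <- fit_logistic(ra$subclinical_cvd, ra[, "mscore", drop = FALSE])
f_new <- fit_logistic(ra$subclinical_cvd, ra[, c("mscore", "glyca_points")])
nri_idi(f_old$predicted_probabilities, f_new$predicted_probabilities,
        ra$subclinical_cvd, B = 1000, seed = 7)
#> NRI (continuous): 0.360 (95% CI -0.074-0.768, p = 0.1012)
#>   events 0.360, nonevents 0.000
#> IDI: 0.045 (95% CI 0.001-0.091, p = 0.05381)
```

Reading the numbers: the 28 generated healthy controls put the quartile
boundaries close to the reference values; adding GlycA points moves 31 of
82 RA patients into higher ESC risk categories; the augmented score has a
significantly larger AUC than mSCORE alone (paired De Long p = 0.037); and
the continuous NRI of 0.36 is carried entirely by the events (patients with
subclinical atherosclerosis move to higher predicted risk).

The NMR stage works the same way from a spectrum:

```r
sp  <- simulate_spectrum(880, 420, noise_sd = 0.5, seed = 7)
fit <- calibrate_concentration(fit_glyco_region(sp), 50)
fit$signals[, c("signal", "position", "hw_ratio", "concentration")]
#>  signal position hw_ratio concentration
#>   glyca     2.00    77834         879.7
#>   glycb     2.07    53496         419.8
```

`run_pipeline(cfg, out_dir)` chains every stage (simulate → deconvolve →
score → fit → evaluate → reclassify → network) into a CSV/JSON report
bundle with a digest manifest; identical configuration and seed reproduce
identical digests. A thin command-line wrapper with the same verbs lives
in `inst/scripts/glycrisk.R`.

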