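---
title: "Methods behind glycrisk: glycoprotein quantification, GlycA-augmented risk scoring, and reclassification statistics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods behind glycrisk}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(glycrisk)
```

This vignette documents the statistical models implemented in glycrisk,
the parameters that matter, the assumptions behind the synthetic cohort
generator, and the numerical choices made where the design was genuinely
open. Nothing here states an empirical result beyond what the package's
own tests and scripts compute.

## 1. Glycoprotein signal model (1.90–2.15 ppm)

GlycA and GlycB are composite ¹H-NMR signals from the mobile N-acetyl
sugar groups of circulating acute-phase glycoproteins (GlycA from
N-acetylglucosamine/-galactosamine, GlycB from N-acetylneuraminic acid).
The package models the 1.90–2.15 ppm region as

$$ y(\delta) = a + b\,\delta
   + \sum_{k \in \{A,B\}} \frac{h_k\, (w_k/2)^2}{(\delta-\delta_k)^2 + (w_k/2)^2}
   + \varepsilon, $$

two Lorentzian lines over a first-degree baseline. Lorentzian is the
default line shape because an exponentially decaying FID yields Lorentzian
lines after Fourier transform; the closed-form area is
$A_k = \pi h_k w_k / 2$. Height is defined as the distance from the fitted
baseline to the line maximum and width as the full width at half height,
so the mobility proxy is simply $H/W = h_k / w_k$. Areas are converted to
protein–sugar bond concentrations by internal calibration,
$c_k = A_k \cdot f$ with $f$ in μmol/L per (a.u.·ppm).

**Defaults.** Line centres 2.00 ppm (GlycA) and 2.07 ppm (GlycB) — the
window is fixed by the chemistry but the centres are starting values only
and configurable, since published pipelines differ in the exact GlycB
position and in how many functions they place in the window. Initial FWHM
0.01 ppm; initial heights from the local maximum near each starting
centre after an edge-based baseline guess.

**Optimisation.** Levenberg–Marquardt least squares (`minpack.lm`),
maximum 500 iterations, `ftol = ptol = 1e-10`; heights and widths are
optimised on the log scale, which enforces positivity without
constraints. Non-convergence returns a result with `converged = FALSE`
and diagnostics rather than an error, and calibration refuses
non-converged fits. On noiseless input the squared residual norm is below
$10^{-6}$ of the total signal energy (tested), fitted areas are invariant
to any linear baseline added to the input within 0.5%, and doubling the
simulated concentration doubles the fitted area within 1%.

The simulator draws the same model forward (grid of 512 points, additive
Gaussian noise, deterministic per seed), so generator truth serves as the
oracle for recovery tests: areas within 1% noiseless, median relative
area error under 5% across 50 seeds at noise of 1% of peak height.

## 2. Glycosyltransferase assay

The coupled colorimetric assay measures the inorganic phosphate released
from the leaving nucleotide diphosphate. The standard curve is an
unweighted OLS line of absorbance on known phosphate concentration (a
two-fold serial dilution, 100 → 1.56 μM, read as the natural
interpretation of the kit's stated range); no log transform is applied
because the malachite-green response is linear over this range. Each
sample is read with and without the coupling phosphatase and the paired
difference is used, so any common additive background cancels exactly
(tested as an invariance). Activity is phosphate released per minute,
$\mathrm{activity} = \Delta\mathrm{abs} / (\mathrm{slope} \cdot t)$ in
μM P/min with $t$ = 30 min by default. A negative paired difference —
serum phosphatase background exceeding the signal — is clamped to zero
with a flag rather than raised as an error, because it is an expected
physical outcome of the background-compensation design, not a data error.

## 3. The GlycA-augmented mSCORE

mSCORE (the EULAR-modified SCORE 10-year fatal-CVD risk, in %) is an
*input* to this package; the SCORE equations themselves are out of scope.
The augmentation rule is:

| GlycA quartile (vs healthy reference) | points |
|---|---|
| Q1 (below the 25th percentile) | −1 |
| Q2 | +0 |
| Q3 | +1 |
| Q4 (at or above the 75th percentile) | +2 |

with default reference boundaries 618.83 / 734.55 / 822.36 μmol/L, and
combined score = max(0, mSCORE + points).

Three boundary conventions had to be fixed:

* **Quartile inclusivity.** A value exactly on a cut point takes the
  *higher* category (left-closed upward). Published descriptions of such
  rules mix strict and non-strict signs; one consistent convention is
  required and monotonicity is preserved either way.
* **Percentile definition.** Linear interpolation between order
  statistics (`quantile()` type 7). Recorded explicitly because reference
  boundaries are typically derived from small control samples (n ≈ 28),
  where percentile definitions genuinely differ.
* **Negative combined scores.** −1 point applied to a sub-1% mSCORE is
  clamped at 0 rather than re-categorised specially; a negative 10-year
  risk is meaningless and the clamp keeps the low category.

ESC category thresholds are fixed constants (<1, 1–<5, 5–<10, ≥10%),
configurable in `categorize_mscore()`. The reclassification table is the
4×4 cross-tabulation of original against augmented categories, overall
and stratified by subclinical CV disease status (plaque present or
carotid intima–media thickness > 0.90 mm).

## 4. Evaluation statistics

* **ROC / AUC.** Thresholds at midpoints between distinct sorted scores
  plus ±∞; AUC is the Mann–Whitney probability with ties counted 1/2,
  computed via midranks. The AUC standard error uses De Long structural
  components; the paired comparison of two scores on the same subjects
  includes the covariance of the components. Both are cross-checked
  against pROC in the test suite; the paired test is additionally checked
  against a within-subject score-swap permutation oracle on a small
  frozen dataset.
* **Classification metrics.** Standard 2×2 formulas; likelihood ratios
  report `Inf` at specificity 1; MCC is defined as 0 when a table margin
  is empty. The Youden cut-off maximises J = sensitivity + specificity − 1
  with ties broken toward the higher-specificity threshold — chosen
  deliberately so that when J is flat the reported cut-off errs the same
  way a specificity-skewed conventional score does; accuracy is reported
  alongside because "maximum accuracy" and maximum J are formally
  different criteria.
* **Hosmer–Lemeshow.** Equal-count quantile bins of predicted probability
  (default g = 10, ties to the lower bin), statistic
  $\sum_k (O_k-E_k)^2 / (E_k(1-E_k/n_k))$ against $\chi^2_{g-2}$. The
  g − 2 reference distribution is the classical one for probabilities
  *fitted* by the model under evaluation; for externally fixed, known
  probabilities the statistic is approximately $\chi^2_g$ instead. The
  package's calibration simulation therefore fits a correctly specified
  logistic model per replicate before applying the test, which is the
  setting in which the test is used in the pipeline (probabilities always
  come from a logistic fit).
* **NRI / IDI.** Event component P(up|event) − P(down|event), nonevent
  component P(down|nonevent) − P(up|nonevent), overall NRI their sum; IDI
  is the change in discrimination slope. The default variant is
  *continuous* (any probability movement counts), because the pipeline
  computes NRI from logistic predicted probabilities; the categorical
  variant over the four risk categories is available via
  `variant = "categorical"`. Whether a published NRI of this design is
  continuous or categorical is often unstated, so both are provided and
  neither is asserted as "the" published variant.
* **Bootstrap.** Subject-level resampling with replacement, percentile
  2.5/97.5 CI, B = 1000 by default, fully seeded. A resample on which the
  statistic is undefined (e.g. a single-class outcome draw) is redrawn
  and the redraw count reported. The p-value uses the normal
  approximation with the bootstrap SE — a pragmatic choice matching how
  such p-values are usually reported next to percentile CIs; it is
  approximate and the CI is the primary inference.

## 5. The synthetic cohort generator

The generator exists so that every downstream stage can be exercised and
tested without patient data. It emulates the *statistical structure* of an
early-RA CV-risk study — not any individual patient.

**Marginals.** HC GlycA is log-normal with the median pinned to the
reference 50th percentile (734.55 μmol/L) and sdlog the least-squares
compromise of the two outer log-quartiles,
$\sigma = (\log q_{75} - \log q_{25}) / (2 z_{0.75})$: a two-parameter
family cannot match an asymmetric quartile triplet exactly, and this
choice leaves the implied outer quartiles about 3% from the printed
values while keeping the distribution positive and right-skewed. RA GlycA
is log-normal with median 882 and IQR 200 μmol/L. Inflammatory markers
and disease indices use log-normal or truncated-normal marginals with
location/spread set to the cohort medians and IQRs of the study
population (CRP 0.80 (2.20) mg/dL, ESR 24 (27) mm/h, DAS28 5.40 (1.78),
SDAI 24.22 (16.90), HAQ 1.11 (1.00), cIMT normal (0.67, 0.10) mm
truncated at 0.3 mm). Quantities with no published summary —
GlycB medians by group, glycosyltransferase activity scale (RA median 55,
IQR 30 μM P/min), the mSCORE distribution (discretised gamma over 0–15%,
shape 1.5, scale 2 — putting roughly a fifth of RA patients at high/very
high baseline risk), and the lipoprotein panel levels — were chosen once
as field-plausible values and are documented here rather than revisited.

**Dependence.** A Gaussian copula: Spearman targets $\rho_s$ are
converted to latent Pearson parameters by $2\sin(\pi\rho_s/6)$, the
latent normal is sampled and mapped through each marginal's quantile
function. This preserves marginals exactly and rank correlations
asymptotically. The default targets reproduce the reported RA biomarker
correlations (e.g. GlycA–CRP 0.48, GlycA–GTase 0.405, GlycB–ESR 0.44);
pairs not reported get structural defaults (e.g. DAS28–SDAI 0.85,
GlycA–mSCORE 0.10 — deliberately weak, since GlycA was reported
independent of traditional CV risk factors). A non-positive-semi-definite
target matrix raises a configuration error naming the pair whose removal
most repairs the spectrum.

**Outcome links.** Subclinical CV disease is Bernoulli with
$\mathrm{logit}\,p = a + \log(\mathrm{OR}) \cdot \mathrm{GlycA}$, OR
1.004 per μmol/L by default, with the intercept solved numerically
(`uniroot`) on the realised sample so the marginal prevalence hits the
target (59.6% in RA; HC/CSA use fixed plausible prevalences 0.15/0.31).
Affected subjects are then given at least one carotid plaque (plus a
GlycA-dependent Poisson count) and unaffected subjects have cIMT redrawn
below 0.90 mm, so the imaging definition
`subclinical_cvd == (plaque_count > 0 | cIMT > 0.90)` holds row by row.
Six-month remission is the analogous link with OR 0.993 and a 54%
marginal rate; the 12-month flag agrees with the 6-month one for 80% of
subjects, is redrawn from the same link otherwise, and is missing
completely at random for the non-followed fraction (default 16%,
mirroring 42 of 50 followed).

**What passing tests do and do not show.** The generator produces clean
copula dependence, exactly log-normal marginals, and an outcome that
depends on GlycA alone. Real cohorts have messier marginals, confounding
between mSCORE components and inflammation, and measurement error in
every assay. In particular, because the generated mSCORE predicts disease
only through its weak correlation with GlycA, the baseline (mSCORE-alone)
discrimination is near null and the absolute AUC gain of the augmented
score is smaller than in a real cohort where the base score itself is
informative; tests on this generator validate the *statistical machinery*
(estimators, intervals, invariances), not clinical effect sizes.

## 6. Problem sizes and numerical tolerances

The test suite uses n = 5000 draws for distributional checks (quartile
convergence within 3–5%, Spearman targets within ±0.05, prevalence within
±3 points), 100 seeded cohorts of n = 2000 for logistic
parameter-recovery coverage, 200 replicates of n = 5000 for
Hosmer–Lemeshow size, 500 replicates for Kruskal–Wallis size, a 10⁵-rep
permutation oracle for the paired De Long test, and 50 seeds for noisy
NMR recovery — sizes chosen to make Monte-Carlo bands (binomial 99%)
decisively tighter than the properties being checked while keeping the
suite fast. Logistic IRLS runs to relative tolerance 1e−8 (max 100
iterations) with |coefficient| > 15 at failure flagged as separation;
the NMR optimiser and bootstrap settings are given above.

## 7. Known limitations

* The deconvolution fits exactly two lines; shoulders from adjacent
  resonances are absorbed by the linear baseline and would bias areas if
  they fall inside the window. Gaussian/Voigt line-shape options and >2
  components would be the natural extension.
* The generator's lipoprotein panel is a set of plausibly scaled
  log-normal columns with a shared GlycA loading — enough to exercise the
  reclassification subgroup analyses structurally, but it does not model
  lipoprotein physics.
* Continuous NRI is known to overstate improvement relative to the
  categorical variant; both are reported by the same interface and users
  should prefer the categorical variant when fixed risk categories are
  the clinical decision tool.
* Bootstrap p-values are normal approximations; for small cohorts the
  percentile CI is the more trustworthy summary.
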