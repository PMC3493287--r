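---
title: "Methods: biomarker quartile patterns, MCID classification, and the calibrated synthetic cohort"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: biomarker quartile patterns, MCID classification, and the calibrated synthetic cohort}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(oscarpanel)
```

This vignette is the package's own account of its statistical content: the
model behind each stage, the tunable parameters and why their defaults are
what they are, what the synthetic cohort generator does and does not emulate,
and the numerical conventions adopted where the underlying analysis left the
choice open. It states no empirical result that the test suite or
`scripts/acceptance.R` does not itself compute.

## 1. The analysis model

For each serum biomarker the cohort is split into quartiles and the extreme
groups are contrasted:

* **Cut-points.** Empirical 25th/50th/75th percentiles with linear
  interpolation between order statistics (R's type-7 default). Any
  interpolation rule would do; this one is stated so results are
  reproducible. Values tied with a cut-point take the *lower* label, so the
  upper quartile contains strictly-high concentrations. Fewer than 8
  non-missing values, or ties spanning a cut-point, abort the split rather
  than return degenerate groups.
* **Contrast.** Q4 − Q1, difference of means for continuous outcomes
  (matching a mean-difference convention, not medians), difference of
  proportions in percentage points for binary ones. Each biomarker × outcome
  cell uses the records complete for that pair (pairwise deletion), matching
  the cell-wise structure of the heatmap.
* **Classification.** Outcomes with an established minimal clinically
  important difference are classified directly: |Δ| < MCID → yellow,
  otherwise green/red by whether the signed difference favors the
  upper-biomarker group given the outcome's direction of benefit. The strict
  inequality means a difference exactly at the MCID counts as clinically
  important. Outcomes without an MCID fall back to a significance test at
  α = 0.05: χ² without continuity correction for binary outcomes (switching
  to an exact conditional 2×2 test when any expected count is below 1, the
  regime where the χ² approximation is untrustworthy), Wilcoxon rank-sum for
  continuous ones. Two true invariants are tested: flipping only the
  direction-of-benefit flag swaps green and red; negating the outcome *and*
  flipping the flag (re-expressing survival as death) leaves the color
  unchanged. The engine therefore carries a single internal orientation —
  death-by-3-years, lower is better — and a published "survival −21%" is its
  death +21 points.

**MCID defaults** (units of the outcome): FEV₁ 100 mL, 6MWD 37 m (the
conservative lower bound of the published 37–71 m range — using the lower
bound can only make the classifier *more* willing to call a difference
important, an intentional sensitivity choice), SGRQ 4 points, mMRC 1 grade,
BODE 1 point. DLCO has no established MCID and uses the rank-sum fallback.
IC/TLC is special: the published 0.25 figure is a prognostic *threshold*, not
a difference, so the cell compares the proportion of patients below 0.25
between groups via the χ² fallback (a patient below threshold is
hyperinflated, hence worse). No multiple-testing correction is applied across
cells by default (none was applied in the source analysis); a Bonferroni
toggle exists.

The composite panel score (opt-in `mode = "panel"`) is the mean of
within-cohort fractional ranks across the panel's markers — unit-free, robust
to the 10³-fold scale differences between analytes, and reducing to the
single marker's ranks when the panel has one member. Whether the original
panel-level claim used a formal composite or a verbal reading of per-marker
plots is unknowable from the source; per-biomarker mode is therefore the
default and the composite is provided, not asserted, as "the" method.

## 2. Mortality model and concordance

The data model carries a binary death-by-3-years flag and no event times, so
the concordance statistic is the ROC-area form for binary outcomes:
C = P(score_case > score_control) + ½·P(tie), computed by the rank identity.
This is a stated limitation — it is *not* a time-to-event concordance, and
censoring is not modeled. The risk score comes from logistic regression fit
by IRLS with a small ridge penalty (default 10⁻⁶ on standardized
coefficients, intercept unpenalized) whose only purpose is to keep the fit
finite under complete separation; at that magnitude it is numerically
invisible in well-posed problems (the test suite checks agreement with an
unpenalized `glm` to 10⁻⁴). Biomarkers enter log-transformed: they are
right-skewed, and the detection-limit floor makes the log scale the natural
one. Predictors are standardized so coefficients are log-odds per SD.
Convergence is declared on the penalized gradient norm (tolerance 10⁻⁸, cap
100 iterations with step halving; non-convergence is an error reporting the
gradient norm, never a silent partial fit).

## 3. The synthetic cohort: a stated world

The generator's purpose is to make every downstream stage runnable and
testable offline with the statistical structure the analysis assumes. Its
defaults *are* the published conditions; none is a tuning knob.

**Stage mixture.** GOLD I–IV weights are the exact published per-stage counts
(18/73/105/57)/253 — not the rounded 7/29/42/23% — so the closed-form
stage-weighted mortality reproduces the published overall 35% (89/253 =
35.2%) after integer rounding, which the rounded weights would not (35.95%).

**Clinical variables.** Per-stage truncated normals at the published means
(SD), with physiologic bounds: FEV₁% [10, 150], IC/TLC [0.05, 0.7], 6MWD
[0, 800], SGRQ [0, 100], DLCO% [10, 150], BMI [12, 50], age [30, 95],
FEV₁(L) [0.2, 6]. SGRQ is published as median [IQR]; the generator treats the
median as the mean and IQR/1.349 as the SD, a stated normal approximation.
mMRC is published only as P(mMRC ≥ 2); the indicator is drawn Bernoulli and
expanded uniformly to grades {0, 1} below and {2, 3, 4} above the threshold —
grades only matter for BODE points, which depend on the grade bin, not the
grade. Death-by-3-years is Bernoulli per stage; no event times exist in this
world (see §2). FEV₁(L) and FEV₁% are drawn independently within stage (their
within-stage coupling is not published); generated FEV₁% can therefore
disagree with the drawn GOLD label at the cut-points, which the validator
flags as informative, not fatal.

**DLCO stand-in.** No published stage-stratified DLCO summary exists in the
calibration source, yet DLCO is a required outcome. The stage profiles
75/62/48/35 %predicted (SD 20/18/16/13) are *synthetic* stand-ins following
the usual decline of diffusing capacity with GOLD stage; they are labelled
synthetic in `inst/extdata/copd_calibration.json` and excluded from every
calibration-recovery claim.

**Biomarker panel.** Each marginal is log-normal, fitted to the published
median [IQR]: μ = ln(median), σ = (ln q3 − ln q1)/(2·z₀.₇₅) with
z₀.₇₅ = Φ⁻¹(0.75) ≈ 0.67449. Pinning μ to the median is deliberate: the
median is the most robust of the three published statistics and every
recovery check is median-based. A two-parameter family cannot also match
strongly log-asymmetric quartiles (e.g. a GOLD I IL-6 of 4.0 [0.4–17.5]);
such fits are *flagged* at a 15% tolerance on the implied quartiles rather
than traded off against the median — the median-preserving least-squares
solution over the two quantile equations is algebraically identical to the
closed form (minimizing (b−μ+zσ)² + (c−μ−zσ)² in σ with μ fixed gives
σ = (c−b)/2z), so no separate refit path exists.

**Dependence.** The published 8×8 Spearman matrix is converted entrywise to
the Gaussian-copula Pearson scale by ρ_P = 2·sin(πρ_S/6). The converted
matrix is already positive-definite (smallest eigenvalue ≈ 0.36); had it not
been, eigenvalue clipping at 10⁻⁸ followed by re-normalization to unit
diagonal repairs it, and an irreparable matrix errors with its smallest
eigenvalue. Sampling uses *restricted pairing* in the Iman–Conover
tradition: (i) draw i.i.d. normal scores; (ii) linearly adjust them so their
*sample* Pearson correlation equals the target exactly (whiten by the sample
Cholesky factor, recolor by the target's); (iii) map each column's ranks to
the stratified uniform grid (rank − ½)/n; (iv) apply the log-normal quantile
function. This was chosen a priori because the module's contract demands
tight recovery at n = 5000: marginal quantiles are recovered to O(1/n)
instead of O(1/√n) (sample medians land on the fitted medians essentially
exactly), and the sample Spearman matrix concentrates within ~0.01 of target.
The cost, stated plainly: within a stratum the marginal values form a
permuted quantile grid, not an i.i.d. sample, so the sampler under-disperses
marginal summary statistics relative to true sampling noise. Rank-based
downstream machinery (quartile groups, Spearman, rank tests) is unaffected —
group membership is still a uniformly random partition — but the generator
should not be used to study the *sampling variability* of marginal summaries.
For n < k + 2 the exact-correlation adjustment is rank-deficient and plain
Cholesky coloring is used.

**Coupling modes.** `stage_linked` (default) draws each patient's panel from
their own stage's marginals under the shared copula: biomarkers gain outcome
association *only through stage*. This reproduces the published direction
signs (IL-6/TNF-α up with severity, MMP-9/VEGF down) but is deliberately the
weakest coupling consistent with the published tables — within-stage
biomarker–outcome association is not published and is not invented. Observed
consequences (computed by the test suite, not asserted here): upper-vs-lower
quartile contrasts at n = 253 are often inside the MCID, and the
biomarker-only mortality C in this world is smaller than the published 0.78.
Those published magnitudes depend on the unreleased patient-level data and
are treated as classification fixtures, not reproduction targets.
`independent` draws everyone's panel from the pooled marginals — the null
world used for fallback-test calibration checks (non-yellow rate ≈ α,
verified over 200 seeds with the seed as the independent replication unit).

**Detection limits.** Published ELISA lower limits (IL-6 0.70, IL-8 3.50,
IL-16 6.20, TNF-α 1.6, MCP-1 5.0, PARC 10, VEGF 5 pg/mL; MMP-9 0.156 ng/mL
carried as 156 on the pg scale of its as-printed marginals). Default policy
floors sub-LOD draws at the LOD; `half_lod` substitutes LOD/2 and `none`
disables censoring. Floor-at-LOD is the default because published summaries
themselves contain sub-LOD quartiles (GOLD I IL-6 q1 = 0.4 < 0.70), so the
uncensored world must remain reachable — hence a policy, not a constant.
Medians sit far above every LOD, so censoring does not move the
recovery targets.

**Known transcription quirks carried as-is.** The overall "current smoker"
figure in the source table (69%) is inconsistent with its per-stage values
(≤ 53%); smoking status is generated from the per-stage values and excluded
from all calibration checks and analyses. A PARC quartile printed with a
European decimal separator ("35.640") is transcribed as 35640 pg/mL,
consistent with its neighbors. MMP-9 units are carried "as printed".

**Seeds.** One integer master seed; per-stage panel substreams are drawn from
it deterministically, and all generator entry points restore the caller's RNG
state. Identical configs give bit-identical tables.

## 4. Rendering

The OSCAR heatmap and stage box plots are written as hand-built SVG text
rather than through a graphics device: the rendering contract is
byte-determinism (identical matrix and spec ⇒ identical bytes), which a text
writer guarantees and device back-ends do not. The default palette replaces
pure green/red with colorblind-safe substitutes (#009E73 / #D55E00), with a
`classic = TRUE` escape hatch; gray marks insufficient-data cells, a case the
original display had no convention for, and triggers a footnote. Box plots
use median/IQR boxes with 1.5·IQR whiskers on a log₁₀ axis, since the panel
spans four orders of magnitude.

## 5. What a green test establishes — and what it does not

The test suite establishes: the marginal fits invert the published quantile
summaries (within the asymmetry tolerance); the copula sampler recovers the
published rank-correlation matrix to ±0.03 at n = 5000 and every calibrated
median to ±5%; the MCID engine reproduces the published red/green calls when
fed the published quartile differences; the fallback tests hold their nominal
size on the null simulator; and the hand-rolled statistics (concordance,
Spearman matrix, exact 2×2) agree with independent oracles (O(n²) pair
counting, explicit rank-Pearson sums, hypergeometric enumeration /
`fisher.test`) to 10⁻¹⁰ or better.

It does **not** establish: that real COPD cohorts have log-normal biomarker
marginals (heavier tails are plausible); that within-stage biomarker–outcome
coupling is zero (certainly false in patients, unknowable from the published
tables); that the published effect *magnitudes* (quartile differences,
C = 0.78/0.85) are reproducible — they depend on unreleased patient-level
data; or anything about longitudinal trajectories, exacerbations, site
effects or censoring, all out of scope.
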