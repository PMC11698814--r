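---
title: "Equivalent-Score norming for the EAR test: models, calibration, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Equivalent-Score norming for the EAR test}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(earnorms)
```

## The problem

The EAR test measures two social-cognitive abilities with one 60-item
protocol: identifying which of the six basic emotions a dynamic facial
expression conveys (ER index) and judging whether the expression is
authentic or posed (EA index).  Both indices decline with age and vary
with education and sex, so a raw score is clinically meaningless without
demographic standardization.  This package implements the Equivalent
Scores (ES) pipeline — the standardization framework of Italian
neuropsychological norming — end to end, together with a synthetic
normative-cohort generator calibrated to the published summary statistics
of the test's validation sample (n = 522, ages 17–88, education 5–24
years).

## Demographic adjustment

Raw scores are adjusted by the negated fitted effect of significant
background predictors:

$$\text{adjusted} = \text{raw} + b\,( \text{age}^2 - c ) + s \cdot
\mathbb{1}[\text{male}] - s \cdot \mathbb{1}[\text{female}]$$

For the published EAR norms, $b = 0.002$, $c = 1811.257$ (the normative
cohort's mean squared age) and $s = 0.818$ (ER) or $0.420$ (EA).  Two
conventions deserve explicit statement:

* **Sign.**  The published equation footnote prints a minus sign on the
  age term, but the printed correction grids — 26 independently checkable
  numbers per index — have corrections *increasing* with age, which is
  the only direction consistent with an age-related decline.  The grids
  are treated as canonical; `adjust_score()` adds
  $b(\text{age}^2 - c)$.

* **Display rounding.**  The printed grid entries are reproduced exactly
  by rounding the exact correction to three decimals and then to two,
  halves away from zero at both steps (e.g. $-1.5545 \to -1.555 \to
  -1.56$); a single rounding to two decimals disagrees with three
  printed cells.  `display_round()` implements this convention; all
  internal arithmetic keeps full precision, and grids are rounded for
  display only.

`select_model()` re-derives adjustment equations from data.  Candidate
predictors are transforms of age (`age`, `age^2`, `log(age)`) and
education (`education`, `log(education)`) plus deviation-coded sex
($\pm\tfrac12$, so the fitted coefficient is the male−female gap and the
correction offsets are symmetric).  Within a family the transforms are
nearly collinear (r > 0.97 here), so only the best-fitting single
transform per family — the one maximising the $R^2$ of the multiple model
containing it — enters; predictors are then retained at $p < 0.05$ and
the model refit once, with no further stepwise iteration.  A condition
number guard refuses user-supplied candidate sets that remain
ill-conditioned.  The original `log(age − 17.5)` variant sometimes seen
in candidate pools is undefined at this sample's minimum age (17), so
`log(age)` is used.

## Tolerance limits and Equivalent Scores

The clinical cut-off is the **outer tolerance limit** (oTL): the largest
order statistic $x_{(r)}$ such that, with confidence $\gamma = 0.95$, at
most a fraction $p = 0.05$ of the population lies below it.  The rank is
the largest $r$ with $\Pr\{\mathrm{Bin}(n, p) \le r - 1\} \le 1 -
\gamma$; the inner limit (iTL) uses the smallest rank with that CDF at
least $\gamma$.  Both are computed by exact binomial summation
(`pbinom`), with a $10^{-12}$ guard for CDF values that are
mathematically equal to the bound (for $p = 0.05, \gamma = 0.95$ the
margins are many orders of magnitude larger).  The smallest feasible
sample is $n = 59$, where $0.95^{59} \approx 0.0485 \le 0.05$ puts the
oTL at the sample minimum.

Equivalent Scores band adjusted scores into five levels: ES 0
("abnormal") at or below the oTL; ES 4 ("normal") strictly above the
sample median — defined as the lower middle order statistic for even $n$,
so "above the median" has an exact sample meaning; ES 1–3 between.  The
published account of the method states only that the inner bands lie
between the oTL and the median, so their placement was a genuinely open
choice:

* the default **rank method** splits the ranks strictly between the outer
  rank and the median rank into three equal-count bins (remainders to the
  lower bins) — distribution-free and reproducible from the data alone;
* a **z-score method** (equal spacing on the standardized scale between
  oTL and median) is available via `es_bands(..., method = "zscore")`,
  since some ES implementations band on z-scores.

Neither is asserted to reproduce the published inner thresholds exactly,
which would require the original participant records.  Ties are kept in
the sorted multiset; if tied data collapse an inner band the package
warns rather than silently shifting thresholds.  Boundary values always
resolve to the lower band, matching the half-open interval layout of the
published threshold table (printed two-decimal edges read as inclusive
upper bounds).

## The synthetic cohort generator

The generator exists so that every stage — model selection, tolerance
limits, banding, association analyses — can be exercised on data with
known ground truth.  Its defaults are calibrated once to the published
summary structure and are not tuning knobs.

**Demographics.**  Participants are drawn from the published age-band ×
education-band × sex stratification grid (the printed cells total 520;
they are used verbatim as weights), uniformly within band.  Uniformity
within band is an assumption — the within-band distributions are
unpublished — and it inflates the education SD relative to the published
value (the real distribution peaks at typical degree durations); the
banded marginals and the published correlations are what the generator
guarantees.

**Scores.**  Each index is a Gaussian latent
$\mu + \beta_{a^2}(\text{age}^2 - \overline{\text{age}^2}) +
\beta_e(\text{edu} - \overline{\text{edu}}) + \beta_s \cdot
\text{sexcode} + \varepsilon$, rounded and truncated to 0–60.  Age enters
through age² so the generator and the norming stage share one functional
form and parameter recovery is well-posed.  Coefficients are solved in
closed form from the target means, SDs, age/education correlations and
sex gaps, using exact moments of the stratified demographic distribution;
three refinement passes (n = 50 000 each, fixed internal seed, so the
default configuration is deterministic) absorb the bias that rounding and
truncation introduce.  The sex-gap target is the *partial* coefficient —
the sexes differ in age and education distribution, so matching the
marginal gap would bias $\beta_s$.  Education keeps a (small) generating
effect even though the published adjustment retains only age and sex:
most of the published education correlation (r = .142 for ER) is
age-mediated, which is exactly why a p < 0.05 selection drops education
— and the model-selection tests exercise that behaviour realistically.

**Items.**  Per-emotion success probabilities are the calibrated base
difficulties tilted on the logit scale until their sum equals the
participant's stored ER score; Bernoulli draws are then repaired by a
minimal weighted step to the exact total, so scoring the generated
responses reproduces the stored indices *exactly* (a structural identity,
tested as such).  Base difficulties are fixed-point calibrated so
aggregate per-emotion means match the published values (fear hardest at
6.54/10, surprise easiest).  Wrong answers on fear items choose
"surprise" with probability 0.6, reflecting the fear→surprise confusion
asymmetry of facial-emotion data; other errors are uniform.  Authenticity
correctness uses a single per-participant accuracy `ea_raw/60` with the
same exact-total repair.

**Covariates.**  MoCA (ages ≥ 50 only, 0–30) and the four IRI subscales
(0–28 each; total = their exact sum) are Gaussian covariates loaded on
the standardized indices and scaled to the published moments.  The
subscale loadings place the ER association on Fantasy and most of the EA
association on Perspective Taking, so the published qualitative pattern
(EA relates to both cognitive-empathy subscales, ER to Fantasy only at
study-size samples) emerges; a common factor spreads the remaining shared
variance.  These are plumbing for the association analyses, not
calibration-critical.

**Randomness.**  Everything flows from one master seed through
counter-based substreams (demographics, scores, covariates, items), so
stages are independently reproducible and adding item simulation does not
perturb the scores.

What the generator does *not* emulate: the raw-data records deposited by
the validation study, non-Italian demographic structures, within-band
demographic shape, retest structure, or item-level covariance beyond the
per-emotion difficulty profile.  Passing tests therefore demonstrate the
pipeline's correctness and calibration to the published summaries, not
equivalence to the original raw data.

## Power analysis

`required_n_f2()` solves the smallest denominator df $v$ for which the
level-$\alpha$ F test with $u$ numerator df and noncentrality $\lambda =
f^2 (u + v + 1)$ (Cohen's convention, as in the standard power tools)
reaches the target power.  Two bookkeeping conventions convert $v$ to a
total N: the default quotes $N = u + v$ rounded — the convention under
which norming studies in this family report their planned minimum (it
gives N = 286 for $u = 3$, $f^2 = 0.05$, $\alpha = 0.05$, power 0.90) —
while `count_intercept = TRUE` applies the textbook $N = u + v + 1$ with
$v$ rounded up (288 for the same inputs).  The alternative $\lambda = f^2
v$ convention is available behind `lambda_convention = "error"`.  An
independent noncentral-t formulation cross-checks the $u = 1$ case in the
test suite.

## Numerical and scale choices

* Simulation sizes: moment checks use n = 20 000 (correlation Monte-Carlo
  SE ≈ 0.006, well inside the ±0.03 bands); parameter recovery uses 20
  cohorts of the normative size 522; tolerance-limit coverage uses 200
  replicates of 522 against a 100 000-participant reference population.
* Calibration warns (rather than fails) when more than 20% of latent
  scores truncate at the 0–60 bounds, and refuses targets whose implied
  residual variance is negative, naming the offending index.
* The norms resource is versioned JSON with a checksum over all constants;
  export/reload reproduces reports bit for bit.
* Scored protocols must be complete (all 60 items exactly once): the
  norms assume the 0–60 scale, so partial protocols are rejected, never
  prorated.

## Known limitations

* The published inner ES thresholds cannot be reproduced without the raw
  normative data; the banding *procedure* is validated on synthetic data
  instead.
* Ages above 65 are sparsely represented in the normative sample; the
  scorer attaches a standing caution to such reports, and ages outside
  17–88 get no Equivalent Score at all.
* The generator's truncated-Gaussian score model is a choice; the
  published report establishes only that raw distributions passed
  skewness/kurtosis screening.
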