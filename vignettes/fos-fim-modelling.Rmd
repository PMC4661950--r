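---
title: "Predicting functional independence from sensorimotor biomarkers with Fast Orthogonal Search"
author: "fosbio authors"
output: rmarkdown::html_document
vignette: >
  %\VignetteIndexEntry{FOS modelling of FIM scores}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fosbio)
```

## Scope and data model

fosbio estimates clinical outcome scales — the Functional Independence
Measure (FIM-Total on 18–126, FIM-Motor on 13–91) at two weeks and three
months post-stroke — from a subjects × metrics panel of robotic and
clinical biomarkers. The panel is held in a `BiomarkerExperiment`
(a `SummarizedExperiment`: assay `metrics` = metrics × subjects, per-metric
task-group labels in `rowData`, outcome columns in `colData`). Task groups
follow the standard robotic batteries — visually guided reaching for the
affected (`RA1`–`RA13`), unaffected (`RU`) arm and their interlimb
difference (`RI`), arm-position matching (`M1`–`M9`), object-hit
(`OH1`–`OH14`) — plus clinical scores. Named dataset unions (e.g.
`All-Robotic = RA ∪ RU ∪ RI ∪ M ∪ OH`, `Clinical-All`) select the candidate
pool for one analysis.

Subjects with a missing value in any selected metric are removed listwise,
with the exclusion count reported; downstream fitting requires finite
values throughout.

## Normalization

Every candidate metric is min-max scaled, $z(x) = (x - x_\min)/(x_\max -
x_\min)$, using the observed extremes, so all transforms share the bounded
domain $[0, 1]$. Clinical scores are scaled identically to robotic metrics;
the log and trigonometric transforms need a common bounded domain, and the
fitted model is invariant to the affine part of the scaling anyway. Values
outside the fitted range (only possible at prediction time on new data) are
clipped into $[0, 1]$ so the transforms stay defined.

Two scopes are supported and stamped into every result. `global` fits the
normalization once on the whole table, matching a single normalization pass
over a fixed study cohort; it is the default. `train_fold` refits the
extremes inside every cross-validation training fold, so no statistic of
held-out subjects can reach training; the test suite verifies this by
corrupting a held-out subject and asserting unchanged predictions for its
fold peers. With ~10% held out, the two differ only through the sample
extremes and in practice give very similar validation R.

## Candidate basis and its degeneracies

Each normalized metric contributes six candidates — $z$, $z^2$, $z^3$,
$\sin z$, $\cos z$, $\ln(z + \varepsilon)$ — in a fixed order, giving
$6P$ candidates for $P$ metrics. Choices made here:

- $\varepsilon = 10^{-6}$ (configurable) makes the log total at $z = 0$
  without distorting the upper range; the logarithm is natural, as usual in
  system identification.
- sin/cos take the raw normalized value in radians, with no frequency
  scaling — the simplest reading when only the function families are named.
- The untransformed metric is itself a candidate (excludable via
  `includeIdentity = FALSE`); the additive model is generic in its basis
  functions and the identity is the most interpretable member.
- No interaction terms: the basis is univariate by design.

On $[0, 1]$ some transforms are *nearly collinear*: $\sin z \approx z$
(correlation ≈ 0.99995 under a uniform design) and $\cos z \approx 1 -
z^2/2$. Consequently the fitted transform label for a given metric is not
identifiable — any selection rule may return `identity(M3)` where `sin(M3)`
generated the data, at negligible MSE cost. This is why repeat-rate
reports collapse transforms and count *metrics*, and why exact-recovery
tests use well-separated transforms (cube, log). Near-duplicate columns are
handled inside the fit: a candidate whose orthogonalized squared norm falls
below $10^{-10}$ times its raw squared norm is skipped as collinear.

## Fast Orthogonal Search

The model is $S = \sum_{m=1}^{M} a_m p_m(n) + e(n)$. Term 1 is always the
constant. At each later step the remaining candidates are orthogonalized
(modified Gram-Schmidt) against the selected terms, and the candidate whose
orthogonal component explains the most residual variance — equivalently,
yields the largest training-MSE reduction — is selected and removed from
the pool. Exact ties (within $10^{-12}$ relative) resolve to the lowest
candidate index, making the fit deterministic. Final coefficients are the
ordinary least squares solution on the selected columns, so `trainMsePath`
is non-increasing by construction.

Because greedy orthogonal selection is algebraically equivalent to "refit
OLS with each remaining candidate and keep the best", the package also
ships `greedyForwardOLS()`, a deliberately naive implementation used as an
independent oracle: the acceptance suite checks selection sequences, MSE
paths and coefficients agree on hundreds of randomized instances, including
rank-deficient pools. Requesting more terms than the pool's rank raises an
error reporting the achievable order; there is no internal stopping rule,
since the order is chosen externally by cross-validation.

## Cross-validated order selection and the R convention

Subjects are partitioned uniformly at random (seeded, unstratified) into 10
folds; models of order 1–15 are fit per fold (one greedy path per fold —
the order-$m$ model is the path prefix) and evaluated on the held-out fold
after clipping predictions into the target's valid range (e.g. a predicted
130 becomes 126 on FIM-Total). Performance is the Pearson correlation
between actual and predicted held-out scores, clamped below at 0 and
defined as 0 for constant vectors, so R lies in $[0, 1]$ and $R^2$ reads as
explained variance; the signed raw correlations are kept as diagnostics.
The chosen order maximizes the across-fold mean R, ties going to the
smaller order. The pooled out-of-fold R is reported alongside as a
diagnostic and feeds the between-dataset comparisons.

At realistic signal strengths the mean-R curve is nearly flat past the true
order, so argmax order selection has a heavy right tail: adding a term
costs held-out performance only ~noise, and in a minority of replicates a
higher order wins by a hair. The parsimony tie-break applies only to exact
ties; a one-standard-error rule would stabilize the choice but would be a
different selector, so it is not the default behavior.

Two panels predicting the same target on the same subjects are compared
with a Steiger-type z-test on Fisher-transformed correlations, using the
correlation between the two pooled prediction vectors; unrelated samples
use the two-sample Fisher z. The method used is stamped into the report.

## Repeat-rate stability

`repeatRates()` refits the model of fixed order on `nRepeats = 100` random
90% subject subsets (without replacement — subsampling, not bootstrap) and
tabulates, per selection rank, how often each metric is picked, collapsing
transforms. Counts per rank sum exactly to the number of repeats; all picks
are retained, with a display-only threshold available when writing the
CSV. The order is fixed to the full-data CV choice by default;
`reselectOrder = TRUE` re-runs CV inside every repeat for a costlier,
fully honest resampling of the whole procedure.

One caveat documented by the null-control simulations: within a *single*
pure-noise cohort, the spuriously best candidate tends to repeat across
90%-overlap subsamples, so a high repeat rate in one dataset is evidence of
stability *given these data*, not of a population-level effect. Across
independent noise realizations no metric is systematically preferred; the
acceptance checks therefore aggregate the null control across 50 seeds.

## The synthetic cohort generator

No patient-level data are distributed, so analyses and benchmarks run on
seeded synthetic cohorts built to the same shape: 85 subjects by default,
with the full metric inventory (13 RA, 13 RU, 13 RI, 9 M, 14 OH, plus
Purdue, BIT, Chedoke and Modified Ashworth scores). Structure and defaults:

- A latent severity factor $u$ drives all task groups: group factor
  $f_g = \sqrt{a}\,u + \sqrt{1-a}\,\eta_g$ with `severityLoading`
  $a = 0.5$, and each metric in group $g$ is
  $\sqrt{\rho} f_g + \sqrt{1-\rho}\,\epsilon$. Within-group correlations
  equal $\rho$ (`withinGroupCorrelation`, default 0.3 — a moderate value in
  the plausible 0–0.6 range for task batteries; recovery benchmarks can
  sweep it), between-group correlations $\rho a$. Equicorrelated Gaussian
  blocks are the simplest structure matching mutually correlated task
  parameters.
- Ordinal clinical scores are produced by binning the Gaussian latent at
  fixed cut-points (Chedoke 1–7; Modified Ashworth 0, 1, 1+, 2, 3, 4 with
  1+ recoded as 1.5), preserving a monotone association with severity. The
  unaffected-arm Ashworth frequencies are kept just non-degenerate (a few
  non-zero subjects) so that 90% subsamples cannot yield constant columns,
  which min-max normalization rejects by contract.
- The target is `intercept + Σ coefficient × transform(z(metric)) + noise`
  for a configurable sparse `trueModel` (default: three nonlinear terms on
  `M3`, `M5`, `OH11` — matching/object-hit metrics, echoing the kinds of
  biomarkers that dominate real FIM models). The noise SD is set directly
  or derived from a requested generative R (default 0.85, in the range of
  published FIM prediction performance). The raw target is affinely
  rescaled to the configured moments (FIM-Total-2w: mean 96.3, sd 24.3, per
  typical cohort tables) and clipped into the valid FIM range; the returned
  ground truth (rescaled terms, intercept, noise realization, normalization
  parameters) reconstructs the targets from the table exactly.

What the generator deliberately does **not** emulate: non-Gaussian and
floor/ceiling-laden score distributions beyond clipping, missing data,
longitudinal recovery between the two FIM time points, and any
biomechanical structure inside the robotic tasks. Passing recovery
benchmarks on these cohorts shows the pipeline recovers sparse nonlinear
structure under correlated Gaussian designs of realistic size — not that
real stroke data contain such structure.

## Numerical choices

- Collinearity skip: orthogonalized squared norm $< 10^{-10} \times$ raw
  squared norm; selected-once rule keeps the model well-posed.
- Tie-break on MSE reduction: lowest candidate index within $10^{-12}$
  relative; candidate-order permutations change nothing else.
- Order choice: smallest order within $10^{-9}$ of the maximal mean
  validation R.
- Every stochastic operation (fold assignment, subsampling, cohort
  generation, the pipeline's per-analysis child seeds) takes an explicit
  integer seed and restores the caller's RNG state, so identical seeds
  reproduce results bit-identically, including report files.
- Problem sizes used by the shipped benchmarks: 200 random instances
  (10–50 subjects, 5–40 candidates) for oracle equivalence; 50 seeds at
  n = 500 for parameter recovery and 50 at n = 200 for the null control —
  sizes at which the Monte-Carlo rates are stable to a few percent while a
  full run stays in the minutes range on one CPU.

## Known limitations

- Greedy selection is not best-subset: with strongly correlated metrics a
  sibling can substitute for a planted metric; repeat rates quantify, not
  remove, that ambiguity.
- Transform labels within a metric are partly interchangeable (see the
  basis section); interpret selected terms at metric level.
- CV order selection by plain argmax is noisy in the flat region past the
  true order; inspect the full `meanValidationR()` curve
  (`plotOrderCurve()`) rather than the chosen order alone.
- With `scope = "global"` the normalization sees all subjects, a mild,
  deliberate leak matching a one-pass study design; use `train_fold` for
  strict separation.
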