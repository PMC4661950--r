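# fosbio

Predictive modelling of clinical outcome scales from panels of sensorimotor
biomarkers, built around **Fast Orthogonal Search (FOS)** — a greedy
orthogonal-least-squares regression over nonlinear transforms of normalized
metrics.

## The problem

After stroke, the ability to perform daily activities is scored with the
Functional Independence Measure (FIM; 18 items on 1–7, total range 18–126,
motor subscale 13–91). Robotic assessments (visually guided reaching,
arm-position matching, bimanual object-hit) and standard clinical tests
(Chedoke-McMaster, Purdue Pegboard, Modified Ashworth, BIT) yield dozens of
candidate biomarkers per subject. The question this package addresses: which
few biomarkers, possibly through nonlinear relationships, best estimate a
subject's present and future FIM scores — and how stable is that selection?

## The model

Each metric `x` is min-max normalized, `z(x) = (x − x_min)/(x_max − x_min)`,
and expanded into six candidate basis functions: `z`, `z²`, `z³`, `sin z`,
`cos z`, `ln(z + ε)`. The outcome `S` is modelled as

    S = Σ_{m=1..M} a_m p_m(n) + e(n)

where the `p_m` are chosen greedily from the candidate pool: the first term
is always the constant, and each subsequent term is the candidate whose
Gram-Schmidt-orthogonalized component against the current model yields the
largest reduction in training MSE; the coefficients `a_m` are the OLS
solution on the selected columns. Around the core selection routine the
package provides:

- **`fosFit()` / `greedyForwardOLS()`** — the orthogonal-search fit and an
  independent brute-force oracle that refits a full OLS model per candidate
  per step; both produce identical selections, which the test suite checks
  on hundreds of randomized instances.
- **`crossValidate()`** — 10-fold cross-validated selection of the model
  order over 1–15 terms. Performance is the R value: the Pearson correlation
  between actual and range-clipped predicted scores on held-out subjects
  (clamped at 0), averaged over folds.
- **`repeatRates()`** — stability analysis: refit on 100 random 90% subject
  subsets and count, per selection rank, how often each metric is picked
  (whatever transform carried it).
- **`compareR()`** — Steiger's z-test for dependent overlapping
  correlations (or two-sample Fisher z) to compare R values between
  biomarker panels.
- **`generateCohort()`** — a seeded synthetic-cohort generator with
  correlated within-task metric blocks, ordinal-like clinical scores and a
  known sparse nonlinear ground-truth model, standing in for clinical data
  and powering the recovery benchmarks.
- **`runAnalysis()`** — end-to-end orchestration over (dataset, target)
  pairs with CSV/JSON report output; `inst/cli/fosbio.R` exposes it on the
  shell.

## Worked example

```r
library(fosbio)

cohort <- generateCohort(syntheticCohortConfig(seed = 7))
be <- cohort$experiment
realizedGenerativeR(cohort)
#> [1] 0.811

cols <- metricsForDataset(be, "All-Robotic")
cv <- crossValidate(be, cols, cohort$target, maxOrder = 15, folds = 10,
                    seed = 42)
cv
#> CVResult 'FIM-Total-2w': 10 folds x 15 orders (scope global, seed 42)
#> chosen order 4, overall R 0.736 (pooled R 0.737)

params <- fitNormalization(be, cols)
cs <- expandCandidates(normalizeValues(metricMatrix(be)[, cols], params))
fosFit(cs, cohort$target@values, order = chosenOrder(cv),
       targetName = "FIM-Total-2w")
#> FOSModel for 'FIM-Total-2w': 4 term(s), training MSE 175.9
#>       kind metric      label coefficient trainMSE
#> 1 constant   <NA>   constant      24.051    526.4
#> 2   square     M3 square(M3)     -54.088    273.0
#> 3      cos     M5    cos(M5)      97.768    202.8
#> 4      log   OH11  log(OH11)      -3.545    175.9

repeatRates(be, cols, cohort$target, order = chosenOrder(cv),
            nRepeats = 100, seed = 42)
#> RepeatRateReport: order 4, 100 repeats on 90% subsets (seed 42)
#>   rank 1: M3 98%, M5 2%
#>   rank 2: M5 98%, M3 2%
#>   rank 3: OH11 79%, RU7 7%, OH6 6%
```

Reading the output: this 85-subject synthetic cohort was generated from a
3-term nonlinear model of `M3`, `M5` and `OH11` with noise giving a
generative R of 0.81. Cross-validation picks a 4-term model (constant plus
three candidates) whose held-out R of 0.74 approaches that ceiling, and the
repeat-rate table shows the three planted metrics dominating the first
three ranks. Note that the fitted transforms (`square(M3)` for a planted
`cube(M3)`) may differ from the planted ones — several transforms are
nearly collinear on `[0, 1]`, which is exactly why repeat rates are
reported per metric, not per transform.

## Vignette

`vignettes/fos-fim-modelling.Rmd` documents the model, its assumptions, the
tunable parameters, the synthetic-cohort design and the numerical choices
in detail.
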