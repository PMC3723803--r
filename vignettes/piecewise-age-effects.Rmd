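---
title: "Testing the flattened-slope prediction with piecewise regression"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Testing the flattened-slope prediction with piecewise regression}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(aoabreak)
```

## The scientific question

The critical period hypothesis (CPH) for second language acquisition, in
its most testable form, predicts that ultimate attainment (UA) declines
steeply with age of onset of acquisition (AOA) up to the end of a critical
period and much more shallowly — or not at all — afterwards. The
prediction concerns the *slope* of the AOA–UA function, not its strength:
a strong negative correlation across the whole lifespan is compatible with
a perfectly linear age effect and is therefore not evidence for a critical
period.

Two analysis traditions in this literature cannot address the prediction:

* **Group comparisons.** Discretising AOA into bins and reading a
  non-significant difference between two bins as "no difference" mistakes
  absence of evidence for evidence of absence. With the group sizes
  typical of these studies, the power to detect even a medium effect
  (Cohen's d = 0.5) can be very low: `t2n_power(7, 23, 0.5)` is about
  0.20, and holding power at 0.95 before accepting a null would require
  about `solve_n_for_power(0.5, target_power = 0.95)` = 105 participants
  per group.
* **Correlation comparisons.** A larger AOA–UA correlation in younger
  than in older arrivals does not show the slope differs: the slope b and
  the correlation r are linked by b = r·s_y/s_x, so the older group's
  correlation shrinks whenever its outcome variance grows — which it
  systematically does, for reasons (exposure, education, motivation)
  unrelated to any critical period. Likewise, "significant in group A but
  not in group B" does not imply A and B differ; the correct comparison
  is Fisher's r-to-z difference test (`compare_correlations()`), and
  partial correlations inherit an additional artefact: they shrink
  mechanically as the correlation between the conditioning variable and
  the predictor grows (`partial_correlation()`).

The valid instrument is a regression model in which the slope may change:
joined piecewise (segmented) regression.

## The model

For a breakpoint at age b, the mean score is modelled as

    E[y | x] = beta0 + beta1 * (x - b) + beta2 * I(x <= b) * (x - b)

where I(.) is the segment indicator. Centring the predictor at the
breakpoint makes the two segments meet there by construction (the
hypothesised patterns involve changes of slope, never jumps), makes the
intercept the predicted score at the breakpoint, and gives the two
reported per-segment slopes as beta1 (after) and beta1 + beta2 (before).
Records exactly at the breakpoint belong to the "before" segment
(`aoa <= b`); the source tables this package reproduces label segments
both as `<=` and `<` in different places, and we fix the convention at
`<=` throughout.

Model selection proceeds in three steps:

1. **Fixed breakpoint.** Fit the model at a theoretically motivated age
   (the conventional cut-off 18) and compare it with the simple linear
   model by an F-test on the residual sums of squares. The test asks only
   whether the extra term reduces the deviance, so it is one-tailed by
   construction; halving its p-value "because the direction was
   predicted" is unsound.
2. **Breakpoint scan.** Refit at every integer candidate age on a grid
   (default 5–19: later breakpoints would not indicate a critical period
   ending before maturity, and earlier ones leave too few records to fit)
   and take the deviance-minimising candidate (`scan_breakpoints()`).
   Exact ties go to the smallest candidate so the result is
   deterministic. Candidates leaving fewer than two observations in a
   segment are dropped; a segment whose records share a single age leaves
   that segment's slope unidentified (aliased), which is tolerated — the
   fitted mean and deviance are still defined, matching the behaviour of
   the linear-model fitters this analysis style grew up with.
3. **Selection-aware reading.** The p-value of the comparison at the
   *scanned* optimum is reported nominally, as is conventional, but the
   scan is itself a selection step: testing the best of fifteen
   candidates inflates the type-I error, so a borderline p at the optimum
   is weaker evidence than its nominal value suggests. The documentation
   of `compare_nested()` repeats this caveat.

AIC and BIC are computed from the full Gaussian log-likelihood (with the
2π constant) counting the residual variance as a parameter — the
`stats::AIC()` convention — because the published values this package
reproduces (642.3 vs 644.4, 651.6 vs 651.4 for the North America data at
breakpoint 16) are on that scale. An exact fit has no defined Gaussian
likelihood; `information_criteria()` raises an error rather than
returning infinities.

## Robustness battery

Attainment variance typically grows with AOA, so three sensitivity checks
accompany every reanalysis:

* **Huber M-estimation** (`fit_robust()`): IRLS with Huber's psi, tuning
  constant 1.345 (95% Gaussian efficiency) and MAD residual scale —
  standard defaults, since the method family alone is specified in this
  literature. Convergence is declared by the IRLS coefficient-change
  criterion (tolerance 1e-8, at most 100 iterations) and non-convergence
  is flagged on the returned object, never silent.
* **Heteroscedastic GLS** (`fit_gls_linear_variance()`): residual
  variance sigma^2 * (1 + gamma * aoa), increasing linearly in the
  covariate — the most literal reading of "variance increasing linearly
  with AOA". No installed variance-function family matches this form, so
  the model is estimated directly by profile maximum likelihood: for
  fixed gamma the coefficients are weighted least squares and sigma^2 its
  ML estimate; gamma is optimised on
  (-1/max(aoa) + 1e-6, 100), the lower bound keeping every record's
  variance positive. ML rather than REML is used so likelihoods of
  nested mean structures remain comparable, and the returned optimum is
  explicitly guaranteed to be at least as good as gamma = 0 (which
  recovers OLS exactly).
* **Outlier-excluded refits** (`refit_without_outliers()`): records with
  internally studentized residuals (leverage-adjusted, the influence
  convention of standard linear-model tooling) above 2.5 in absolute
  value in *both* the simple and the breakpoint model are removed and
  both models refitted.

## The synthetic-data generator

`generate_aoa_data()` draws integer AOAs uniformly on a range and adds
Gaussian noise around a continuous piecewise-linear mean. Its four shapes
are the canonical candidate age functions: `linear`, `decline_then_flat`
("stretched L"), `flat_then_decline` ("stretched 7"), and
`flat_decline_floor` (ceiling, decline, floor with final slope exactly
0). The `intercept` is anchored at the `anchor` age (defaulting to the
first breakpoint, else 18) so that published fits — e.g. a slope of
−1.22 with predicted score 168.5 at age 18 — translate directly into
generator settings. `var_slope` > 0 scales the noise SD by
sqrt(1 + var_slope·aoa), emulating the variance growth seen in real
data. Default conditions mirror the studies the package is designed
around: n = 76, AOA 5–71, noise SD 5 where the mean structure is under
study and ≈16 score points (the residual SD implied by a GJT SD of 27.3
and R² = 0.65) where realistic totals matter.

With `clip_to_scale = FALSE` (the default) scores are *not* truncated to
the 0–204 GJT scale, so estimator validation is free of censoring bias;
the trade-off is that such datasets can carry scores outside the
physical scale, which the `aoa_data()` constructor permits only on this
explicitly unchecked path. `generate_mimic()` instead produces
realistic, clipped, integer datasets whose AOA distribution is a
moment-matched discretised beta on the published range (uniform sampling
cannot reproduce the published AOA mean 32.5 / SD 18.0) and whose mean
structure and residual SD come from the published linear fits.

What passing tests on these data do **not** show: real AOA distributions
are not beta-shaped, real noise is bounded and integer-valued, and real
studies carry covariates (aptitude, age at testing, length of residence)
the generator deliberately omits. Recovery and calibration results here
validate the estimators under the stated model, not the model itself.

## Validation problem sizes

The test suite validates the machinery at sizes chosen to make the
statistical properties sharp while keeping every check quick to run:
breakpoint recovery uses 200 replicates of n = 500 (kink at 18, slopes 0
and −1.5, noise SD 5), where the scanned optimum falls within ±1 year of
the truth in well over 95% of replicates; the nested F-test's size is
checked with 2000 replicates under a pure linear null at n = 76; GLS
variance-slope recovery uses 100 replicates at n = 500. Breakpoint
*location* is intrinsically fuzzy at moderate noise — adjacent candidates
differ by small deviance margins — so end-to-end pipeline fixtures assert
recovery to within a couple of years, while the dedicated recovery study
above pins down the ±1-year behaviour under its stated conditions.

## Known limitations

* The scan-then-test p-value is nominal; a formal correction (e.g.
  supremum-type tests over the grid) is out of scope.
* One breakpoint at most; discontinuous (jump) and smooth-transition
  models are out of scope.
* Fisher z comparisons assume independent samples; comparing overlapping
  or dependent correlations needs different machinery.
* The extracted source-study datasets are not redistributed; analyses of
  the real data require obtaining the original supplementary CSVs
  (schema `aoa,gjt`) and passing them to `read_aoa_csv()`. All package
  examples run on synthetic data.
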