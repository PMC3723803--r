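# aoabreak

Piecewise (breakpoint) regression and correct inference for age-of-onset
effects on second-language ultimate attainment.

## The problem

The critical period hypothesis (CPH) predicts, in its testable
"flattened slope" form, that ultimate attainment (UA) in a second
language declines steeply with age of onset of acquisition (AOA) up to
the end of a critical period and much more shallowly afterwards. That is
a claim about the **slope** of the AOA–UA function — yet the literature
standardly addresses it with tools that cannot answer it: t-tests and
ANOVAs across AOA bins (which read low-powered non-significance as "no
difference") and comparisons of subgroup correlation coefficients (which
confuse the correlation r with the slope b; the two are linked by
b = r·s_y/s_x, so the older group's r shrinks whenever its outcome
variance grows, critical period or not).

`aoabreak` is for researchers who want to test the prediction properly
on AOA–UA data (here: grammaticality-judgement-task scores on a 0–204
scale). It provides:

* **joined piecewise regression** — E[y|x] = β₀ + β₁(x−b) + β₂·I(x≤b)·(x−b),
  segments constrained to meet at the breakpoint b — with a deviance-
  minimising scan over candidate breakpoints (integer ages 5–19 by
  default) and nested-model selection by one-tailed F-test, AIC and BIC;
* the **correctly-used inferential tools** the piecewise approach
  replaces: Fisher r-to-z comparison of independent correlations,
  partial correlations from zero-order correlations, significance of r,
  and exact noncentral-t power for two-sample designs with unequal n;
* a **robustness battery**: Huber M-estimation, GLS with residual
  variance σ²(1 + γ·aoa), and refits excluding records with
  |studentized residual| > 2.5 in both models;
* a **synthetic-data generator** for the canonical critical-period mean
  shapes (linear, decline-then-flat, flat-then-decline,
  ceiling–decline–floor), plus an end-to-end `run_reanalysis()` pipeline
  and an `exec/aoabreak` command-line interface.

## Worked example

```r
library(aoabreak)

d <- generate_mimic("north_america", seed = 42)  # synthetic stand-in
fit <- fit_ols(d, center_at = 18)
fit
#> simple linear model fit [ols], study 'synthetic_mimic:north_america'
#>       term estimate   se
#>  intercept   164.55 2.15
#>      slope    -1.09 0.10
#> R2 = 0.62, F(1,74) = 123.0, p = 2.14e-17, deviance = 16099.2

bp <- fit_breakpoint(d, breakpoint = 18)
bp
#> breakpoint model (breakpoint at aoa 18) fit [ols], study 'synthetic_mimic:north_america'
#>               term estimate   se
#>          intercept   165.50 2.93
#>  slope (aoa <= 18)    -0.82 0.57
#>   slope (aoa > 18)    -1.13 0.12
#> R2 = 0.63, F(2,73) = 61.0, p = 2.68e-16, deviance = 16048.1

compare_nested(fit, bp)
#> Simple vs breakpoint (aoa 18): F(1,73) = 0.23, one-tailed p = 0.631
#> delta AIC = 1.8, delta BIC = 4.1 (breakpoint - simple)
#> preferred at alpha = 0.05: simple model
```

The intercept is the predicted score at the centring age (18); the
breakpoint model reports one slope per segment, joined at 18. Here the
data were generated linear, and parsimony correctly rejects the
breakpoint term: the slope before 18 (−0.82 ± 0.57) does not differ
detectably from the slope after (−1.13 ± 0.12), the F-test is far from
significance, and both information criteria prefer the simple model.

The misused tools, used correctly:

```r
compare_correlations(-0.37, 17, 0.45, 32)
#> r1 = -0.37 (n = 17) vs r2 = 0.45 (n = 32)
#> Fisher z difference: z = -2.68, one-tailed p = 0.0036, two-tailed p = 0.0073

t2n_power(7, 23, d = 0.5)   # power of a typical bin comparison: 0.20
solve_n_for_power(0.5, target_power = 0.95)   # 105 per group
```

A power of 0.20 means a medium true effect goes undetected four times
out of five — a non-significant bin comparison at these sizes says
nothing about the shape of the age function.

See the vignette (`vignettes/piecewise-age-effects.Rmd`) for the model,
its conventions, and the robustness battery in detail.

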