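# zblnaft

Parametric survival modelling of cause-specific lung-cancer mortality with a
**Zografos–Balakrishnan log-normal (ZBLN) accelerated failure time model**,
alongside the standard comparison arms — log-normal AFT, Weibull AFT and Cox
proportional hazards — and the selection, fit and validation machinery
around them.

## The problem

Lung and bronchus cancer with bone or brain metastases has a median
cause-specific survival of only a few months, and registry cohorts are
heavily tied (month granularity) and administratively censored at fixed
follow-up horizons (3 or 5 years).  Covariates in such cohorts routinely
violate the proportional-hazards assumption, which undermines the Cox
model; accelerated failure time models act on the time scale instead and do
not require it.  The package is for biostatisticians and epidemiologists
who want to fit and validate AFT survival models on cohorts of this shape —
and, because registry extracts sit behind data-use agreements, it ships a
synthetic cohort generator that emulates the published cohort composition
so every stage of the analysis is runnable and testable out of the box.

## The model

The ZBLN distribution is the gamma-generated extension of the log-normal:
with log-normal density *g* and distribution function *G*,

    f(t) = g(t) · [−log(1 − G(t))]^(a−1) / Γ(a),    t > 0,

with distribution function `F(t) = P(a, −log(1 − G(t)))` (regularized lower
incomplete gamma).  The extra shape `a > 0` tilts the tails; `a = 1`
recovers the log-normal exactly, so the log-normal AFT model is nested.

The AFT regression places the linear predictor on log-time: the location of
log *T* is `μ₀ + x'β`, i.e. `T = T₀ · exp(x'β)`.  Each coefficient
exponentiates to an **acceleration factor** `AF = exp(β)`: AF > 1 means the
level is associated with longer survival than its reference level, AF < 1
with shorter.  Right-censored maximum likelihood
`Σ δᵢ log f(tᵢ) + (1−δᵢ) log S(tᵢ)` is maximized by BFGS with analytic
gradients in unconstrained coordinates, with a deterministic multi-start
over the generator shape.  Model fit is compared by AIC/BIC; held-out
performance by Harrell's C-index, RMSE of predicted median survival, and
decile calibration against the Kaplan–Meier estimate.

## Worked example

```r
library(zblnaft)

scenario <- default_scenario(horizon = 36, n = 4000, seed = 7)
cohort   <- generate_cohort(scenario)
parts    <- split_cohort(cohort, 0.7, seed = 7)

fit <- fit_aft(parts$train, aft_model_spec("zbln"), seed = 7)
print(fit)
#> zbln AFT fit: n = 2800, logLik = -7776.65, AIC = 15601.3, BIC = 15743.8
#>                          term     estimate    AF            p
#>                           age -0.003476441 0.997 2.023245e-01
#>                    race=Asian  0.297166496 1.346 4.949778e-01
#>     treatment=Bimodal Therapy  1.248047158 3.484 1.289875e-77
#>    treatment=Trimodal Therapy  1.581743419 4.863 4.803700e-39
#>     metastases=Bone and Brain -0.447965977 0.639 9.071375e-08
#>     ...                       (one row per non-reference level)

validate_model(fit, parts$test)
#> validation (n = 1200, horizon 36): C-index = 0.634, RMSE = 7.796
```

Reading the output: bimodal therapy has AF ≈ 3.5, i.e. treated patients'
survival times are stretched about 3.5-fold relative to untreated ones;
bone-and-brain metastases have AF ≈ 0.64, i.e. shorter survival than
bone-only disease.  The C-index of 0.63 says the fitted model orders
held-out patients' survival times correctly in about 63% of usable pairs.

The end-to-end study — split, proportional-hazards screen, LASSO screen,
four models, AIC/BIC table, validation and calibration tables — is one
call, or can be followed step by step through the numbered drivers under
`analysis/`:

```r
res <- run_study(default_scenario(60, n = 20412, seed = 1),
                 horizons = c(36, 60), seed = 1, out_dir = "results")
```

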