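# dipetkin

Dual-input liver FDG kinetic modelling with gravitational search fitters.

`dipetkin` is for researchers analysing short (five-minute) dynamic
^18^F-FDG PET of the liver at the time-activity-curve level: it
implements the dual-input reversible two-tissue-compartment model,
three interchangeable parameter-estimation engines, a synthetic
two-group cohort generator (hepatocellular carcinoma vs background
liver), and the statistical layer needed to compare estimation methods
(AIC/BIC fit quality, Student t-tests, ROC/AUC with DeLong comparison).

## The model

The liver's blood input is the HPI-weighted mixture of the hepatic
arterial and portal-vein curves,

    C_B(t) = HPI * A(t) + (1 - HPI) * P(t),

and the tissue curve is the convolution of C_B with the two-exponential
impulse response of the reversible two-tissue compartment model,

    C_T(t) = k1/(a2 - a1) * [ (k3 + k4 - a1) e^(-a1 t)
                            + (a2 - k3 - k4) e^(-a2 t) ] (x) C_B(t),

where `a1 <= a2` are the roots of `x^2 - (k2+k3+k4) x + k2 k4 = 0`.
All five parameters — `k1` (ml/min/ml, influx), `k2`, `k3`, `k4`
(1/min; efflux, phosphorylation, dephosphorylation) and `HPI` (the
arterial fraction) — are estimated jointly from a 16-frame TAC
(12 x 5 s + 4 x 60 s) by minimising the per-frame sum of squared
residuals with one of:

* `nlls` — bounded Levenberg–Marquardt least squares with multi-start;
* `gsa` — the canonical gravitational search algorithm;
* `dcgsa` — its dynamic chaotic variant (randomised dynamic
  gravitational constant, linear inertia weight, logistic chaotic step).

## Worked example

Simulate a small two-group cohort on the 16-frame schedule, fit every
subject, and build the group comparison table:

```r
library(dipetkin)

coh  <- generate_cohort(cohort_spec(n_per_group = 10, noise_level = 0.02), seed = 1)
fits <- fit_cohort(coh, methods = "nlls", seed = 1)
rep  <- cohort_report(fits, positive_group = "HCC")
rep$parameters[, 1:9]
#> # A tibble: 5 x 9
#>   method parameter mean_pos sd_pos mean_neg sd_neg statistic       p_value   auc
#>   <chr>  <chr>        <dbl>  <dbl>    <dbl>  <dbl>     <dbl>         <dbl> <dbl>
#> 1 nlls   k1           0.677 0.0860    0.644 0.0461    1.06   0.301          0.41
#> 2 nlls   k2           0.661 0.219     0.664 0.0917   -0.0361 0.972          0.61
#> 3 nlls   k3           0.192 0.168     0.155 0.0876    0.622  0.542          0.48
#> 4 nlls   k4           0.112 0.194     0.3   0.258    -1.84   0.0819         0.69
#> 5 nlls   hpi          0.746 0.0962    0.308 0.0980   10.1    0.00000000791  1
```

Each row compares one kinetic parameter between the tumour (`mean_pos`)
and background-liver (`mean_neg`) groups: the arterial fraction `hpi`
separates the groups essentially perfectly (mean 0.75 vs 0.31,
p ≈ 8e-9, AUC = 1 — hepatocellular carcinoma is arterially supplied,
background liver portal-dominated), while `k3` does not reach
significance at this sample size because phosphorylation is only weakly
identified from 300 s of data (see the methods vignette). The AIC/BIC
block and pairwise DeLong AUC comparisons live in `rep$fit_quality` and
`rep$auc_comparisons`.

Single fits work tibble-first as well:

```r
a  <- arterial_input()
p  <- portal_from_arterial(a)
tc <- coh$tissue[[1]]
fit <- fit_tac(tc, a, p, method = "dcgsa", seed = 1)
tidy(fit)      # term/estimate table
glance(fit)    # rss, aic, bic, iterations
autoplot(fit, tc, a, p)
```

A command-line front end (`inst/cli/dipetkin.R`) exposes the pipeline as
`simulate`, `fit`, `evaluate` and `benchmark` subcommands over CSV/JSON
files; see `?run_simulate` and friends.

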