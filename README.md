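# necrokinetics

Kinetic modelling of active neuronal necrosis, with the statistical toolkit
used to evaluate a necrosis-released CSF biomarker.

In amyloid-driven neurodegeneration, single-neuron necrosis events can be
counted in cortical microscopy fields (143 um x 143 um). Their frequency
rises during the preclinical stage, peaks around the onset of cognitive
impairment, and then declines — because each death removes a neuron from the
population that can still die. `necrokinetics` is for researchers who want to
fit, simulate and interrogate that time course, and to analyse the
accompanying fluid-biomarker group comparisons, from reproducible, seeded
code.

## The model

A cycle of fixed period `p` (days) kills a constant fraction `r` of the
residual neurons. With `N` neurons per field initially, the population
entering cycle `k` and the deaths during cycle `k` are

```
N_k = N (1 - r)^(k - 1)
D_k = N r (1 - r)^(k - 1) = N_k - N_{k+1}
```

Calendar time maps to a continuous cycle index `k(t) = (t - t0)/p + 1` for
`t >= t0`, where `t0` is the onset of detectable necrosis; the model is zero
before `t0`. Fitting is deterministic grid-search least squares on
per-time-point mean counts, with coordinate refinement, percentile bootstrap
intervals, and seeded Poisson / negative-binomial count generators. The
biomarker toolkit implements the Wilcoxon rank-sum test (exact enumeration or
tie-corrected normal approximation), Bonferroni adjustment, empirical
ROC/AUC, Pearson correlation and 1.5-IQR box summaries from scratch, each
verified against independent oracles.

One caution worth knowing up front (detailed in the methods vignette): for
observations at or after onset the curve is exactly `A exp(-lambda t)`, so
only the amplitude and daily decay rate are identified — the four raw
parameters share an exactly flat least-squares ridge. Fitted *curves* and
predictions are reliable; individual parameter estimates from a single
post-onset time course are not, unless period/onset are anchored externally.

## Worked example

```r
library(necrokinetics)

## the published fitted parameter set for 5xFAD occipital cortex
p <- fittedParams5xFAD()
activeNecrosisAt(p, 60)
#> [1] 3.706068          # predicted necrosis events/field at day 60
                         # (the observed value at 2 months was 3.766)

## a synthetic time course at that parameter set: 30 Poisson fields at
## days 31, 92, 184, 368, 552
tc <- generateNecrosisCounts(seed = 1)

## fit with period and onset anchored at one month (the identified sub-model)
g <- ParameterGrid(n0 = seq(15, 55, by = 2.5), r = seq(0.02, 0.4, by = 0.01),
                   periodDays = 31, onsetDays = 31, refine = TRUE)
fit <- fitModel(tc, g)
fit
#> FitResult
#>   n0 = 30.42, r = 0.1445, period = 31 d, onset = 31 d
#>   SSE = 0.00993933 over 5 time points (1582 evaluations)
```

The estimate (n0 = 30.4, r = 0.145) sits next to the generating values
(30.3, 0.141); `fittedCurve(fit)` shows the per-time-point observed means
against the fitted curve, and `bootstrapCI(tc, g, B = 200, seed = 1)` gives
percentile intervals.

```r
## synthetic four-group CSF cohort (nc/dc/MCI/AD, n = 19/11/21/56)
d <- as.data.frame(generateBiomarkerGroups(seed = 1))
rankSumTest(d$value_pg_ml[d$group == "MCI"], d$value_pg_ml[d$group == "nc"],
            comparisons = 6)
#> RankSumResult: U = 363, p = 1.432e-06 (exact), adjusted p = 8.591e-06 (m = 6)

keep <- d$group %in% c("MCI", "nc", "dc")
rocPoints(d$value_pg_ml[keep], d$group[keep] == "MCI")
#> RocCurve: 52 operating points, AUC = 0.9397
```

The MCI group separates from the pooled controls with AUC 0.94 in this draw;
the generating population AUC is 0.89 (the default cohort is calibrated
through the binormal closed form, `binormalAUC()`).

Config-driven pipelines (`runSimulate()`, `runFit()`, `runPredict()`,
`runBiomarker()`) write delimited tables plus JSON reports and a manifest
echoing the resolved configuration and seed; a thin CLI wrapper lives at
`inst/scripts/necrokinetics-cli.R`.

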