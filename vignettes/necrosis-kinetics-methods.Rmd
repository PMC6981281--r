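---
title: "Methods: discrete-cycle necrosis kinetics and biomarker discrimination"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: discrete-cycle necrosis kinetics and biomarker discrimination}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(necrokinetics)
```

## The model

Active neuronal necrosis in amyloid-driven neurodegeneration is a rare,
asynchronous event counted in small microscopy fields (143 um x 143 um).
`necrokinetics` models its time course as a *discrete-cycle geometric decay*:
a cycle of fixed period $p$ (days) removes a constant fraction $r$ of the
residual neuron population. With $N$ neurons per field at the start, the
population entering cycle $k$ is

$$N_k = N\,(1-r)^{k-1},$$

and the expected number of deaths (observable necrotic events) during cycle
$k$ is

$$D_k = N\,r\,(1-r)^{k-1} = N_k - N_{k+1}.$$

Note the telescoping identity on the right: deaths during cycle $k$ are the
difference between the populations entering cycles $k$ and $k+1$. This is the
convention the package uses throughout; it is consistent with the closed form
$N\,r\,(1-r)^{k-1}$ and is property-tested (`deathsInCycle(k)` equals
`residualNeurons(k) - residualNeurons(k + 1)` for random parameters, and
cumulative deaths equal $N(1-(1-r)^K)$).

Calendar time $t$ (days) maps to a **continuous** cycle index

$$k(t) = \frac{t - t_0}{p} + 1 \qquad (t \ge t_0),$$

where $t_0$ is the onset of detectable necrosis; before $t_0$ the model
returns exactly zero. Fractional cycles make the post-onset curve a smooth
exponential rather than a staircase. This convention is adopted because it
reproduces the published prediction to three decimals: with the published
fitted set ($N = 30.3$ cells/field, $r = 0.141$, $p = 31$ d, $t_0 = 31$ d),

```{r}
activeNecrosisAt(fittedParams5xFAD(), 60)
```

gives 3.706 cells/field at day 60; integer-stepped cycles do not. Whether
onset is a free parameter or tied to the period (detection beginning one
period after death initiation) is left open by the model description; both
modes are provided (`fitModel(..., onsetTied = TRUE)`), with the free mode as
the default.

### Parameters

| parameter    | meaning                              | units       | domain        | default (published fit) |
|--------------|--------------------------------------|-------------|---------------|-------------------------|
| `n0`         | initial neurons per field            | cells/field | $> 0$, real   | 30.3                    |
| `r`          | per-cycle death ratio                | —           | $[0, 1)$      | 0.141                   |
| `periodDays` | cycle period                         | days        | $> 0$         | 31                      |
| `onsetDays`  | start of detectable necrosis         | days        | $\ge 0$       | 31                      |

`n0` is real-valued: it is the *expected* neuron count per field, not a count
in one particular field.

## Fitting

`fitModel()` minimises the unweighted sum of squared differences between the
per-time-point **mean** count and the model curve (weighting by fields per
time point is available but off by default, since the standard design is
balanced). The optimiser is a deterministic exhaustive sweep of a Cartesian
parameter grid followed by coordinate-wise line search (Brent's method on
each coordinate, windows starting at the grid spacing and shrinking until the
relative change falls below `tol`). A grid search is preferred to gradient
methods because the objective is cheap, the landscape is multimodal in
(period, onset), and determinism simplifies verification: on small grids the
optimum is tested against an independent brute-force re-evaluation.

The default grid spans $n_0 \in [5, 60]$ (step 2.5), $r \in [0.01, 0.6]$
(step 0.01), $p \in [5, 90]$ d (step 5) and $t_0 \in [0, 90]$ d (step 5) —
about $4.7\times10^5$ combinations — with refinement enabled, so the final
estimate is not limited to the coarse steps. These steps were chosen so an
exhaustive sweep stays around a quarter of a second; a much finer grid adds
nothing once refinement polishes the optimum within the hull.

Numerical conventions:

* **Ties.** Exactly equal SSE values are broken by the lexicographically
  smallest $(r, p, t_0, n_0)$, so fits are reproducible.
* **Degenerate data.** All-zero counts cannot identify anything; the fit
  returns the grid's lower bounds with `isDegenerate(fit) = TRUE` instead of
  pretending to estimate.
* **Refinement never increases the SSE** (improvements only are accepted) and
  the polished estimate is clamped to the grid hull.

### Identifiability: what the data can and cannot determine

For observation times at or after onset the model curve is exactly

$$f(t) = n_0\,r\,(1-r)^{(t-t_0)/p} = A\,e^{-\lambda t},
\qquad A = n_0\,r\,e^{\lambda t_0},\quad \lambda = -\log(1-r)/p .$$

Only the two functionals $(A, \lambda)$ — amplitude and daily decay rate —
are identified by post-onset data. Every $(n_0, r, p, t_0)$ on the preimage
of a given $(A, \lambda)$ produces the *identical* curve at the observed
times, hence the identical SSE: the objective has an exactly flat ridge, and
which ridge point a grid search returns is decided by noise and grid
alignment, not by the data. Tying onset to the period truncates the ridge
(candidates with onset after the first positive observation are excluded) but
does not remove it.

Consequences, documented rather than hidden:

* Individual parameter estimates from a single post-onset time course are
  **not** trustworthy, and confidence intervals for them in the free model
  are ridge-width artefacts. The *fitted curve* (equivalently $(A, \lambda)$)
  is estimated consistently — the package's tests verify that the fitted
  curve converges to the generating curve as fields per time point grow,
  while the raw parameters need not.
* Unique parameter recovery requires external anchoring — e.g. fixing the
  period and onset from prior knowledge (monthly cycles, detection onset at
  the first month), after which $(n_0, r)$ are identified through $(A,
  \lambda)$. The bootstrap-coverage study below therefore works in that
  identified sub-model.
* `predictAt()` is unaffected: prediction needs only the curve, and the
  day-60 prediction from the published parameter set is exact.

### Bootstrap

`bootstrapCI()` resamples **fields within each time point** with replacement
(fields are the replicate unit of the count data; mouse identity is not part
of the data structure, so mouse-level clustering is not modelled), refits on
each resample, and reports percentile intervals. All resampling is scoped to
the given seed, so results are bit-reproducible. The coverage check in the
test suite runs 200 repeated experiments with $B = 200$ replicates each, with
period and onset grids fixed at the generating values and refinement off
(grid step 0.002 in $r$): this isolates the bootstrap machinery in the
identified sub-model and keeps each fit to a single vectorised sweep.
Measured coverage of the nominal 95% interval for $r$ is asserted within
$\pm 5$ points.

## Synthetic data

The generators reproduce the *statistical structure* of the study's inputs so
the full analysis runs without any external data:

* `generateNecrosisCounts()` draws per-field counts with mean
  `activeNecrosisAt(params, t)` at times 31, 92, 184, 368, 552 days (five
  sampling ages spanning 1–18 months), 30 fields per time point — the
  published design. Noise is Poisson by default (rare events in small
  fields); a negative binomial (`NoiseSpec("negative_binomial", dispersion)`,
  variance $\mu + \mu^2/\theta$) is offered because mouse-to-mouse variation
  plausibly overdisperses. Fields are generated independently; correlation of
  fields within one mouse is *not* modelled, because the count-table schema
  does not expose mouse identity.
* `generateBiomarkerGroups()` draws log-normal concentrations per group.
  Concentrations are positive and right-skewed, which the log-normal captures
  with two parameters; no assay-level effects (calibration curves, detection
  limits, CV%) are simulated. The default cohort mirrors the reference
  four-group structure (nc 19, dc 11, MCI 21, AD 56 subjects) with a common
  log-SD of 0.5, an nc median near 400 pg/mL, and log-means calibrated
  through the binormal closed form `binormalAUC()` so the population AUCs
  equal the reported discriminations (MCI vs nc 0.861, MCI vs dc 0.931, MCI
  vs AD 0.809).
* `generateCorrelatedPair()` draws standard bivariate normal pairs at a
  target Pearson correlation for exercising `pearsonR()`.

All generators are pure functions of their arguments and seed. Passing tests
on these inputs demonstrate correctness of the *computations*; they do not
validate the Poisson or log-normal assumptions against real microscopy or
ELISA data.

## Biomarker statistics

* **Rank-sum test** (`rankSumTest()`): midranks for ties; the statistic is
  the Mann–Whitney $U$ of the first sample. For $n\,m \le 400$ the two-sided
  p-value is computed by exact enumeration of all $\binom{n+m}{n}$ rank
  assignments (a subset-sum dynamic program over doubled midranks — exact
  with ties, no sampling); above that, a normal approximation with
  tie-corrected variance and 0.5 continuity correction. Both are available
  explicitly via `method=`. The exact path is tested against brute-force
  enumeration, the approximate path is identical to the standard one and is
  within 0.02 of exact for untied samples at $n, m \ge 8$ (heavily tied small
  samples can deviate slightly more — an inherent property of the
  approximation).
* **Bonferroni** (`bonferroniAdjust()`): $\min(1, m\,p)$; in the pipeline,
  $m$ defaults to the number of pairwise group comparisons actually
  performed and is recorded in the report.
* **ROC / AUC** (`rocPoints()`, `aucStat()`): empirical curve over all
  distinct thresholds, cases score higher by convention, endpoints $(0,0)$
  and $(1,1)$ always present; tied scores give diagonal segments. The
  trapezoidal area equals the pairwise concordance probability (ties counted
  half) *exactly*, and equals $U/(nm)$ — both identities are
  property-tested. An AUC below 0.5 is reported as-is, never flipped.
* **Pearson correlation** (`pearsonR()`, `pearsonRTest()`): product-moment
  estimate; optional two-sided p via the $t$ transform on $n-2$ degrees of
  freedom; errors on constant input rather than returning `NaN`.
* **Box summaries** (`boxSummary()`): quartiles by linear interpolation of
  order statistics (R's default type-7 convention, fixed and documented);
  whiskers at the most extreme observations within $1.5\times$IQR of the
  quartiles.

## Pipeline

`runSimulate()`, `runFit()`, `runPredict()` and `runBiomarker()` are
config-driven (flat key-value lists or a YAML file; `showConfig(task)` prints
the defaults). Every run writes a `manifest.json` echoing the fully resolved
configuration and seed; outputs contain no timestamps, so identical config +
seed reproduces byte-identical files. Count tables are long-format delimited
text (`time_days, field_id, count`), biomarker tables
(`subject_id, group, value_pg_ml`); the delimiter is auto-detected among
comma and tab, and schema violations fail with the offending row number
before any output is written. A thin command-line wrapper over these
functions ships in `inst/scripts/necrokinetics-cli.R`.

## Problem sizes used in the test suite

The suite is sized for a single CPU: recovery experiments use the published
design (30 fields x 5 time points) over 10 seeds; oracle equivalences run on
1,000 random small datasets (AUC) and 25 exhaustive enumerations (rank-sum);
generator calibration uses $10^5$ subjects per group; the coverage study runs
200 experiments x 200 bootstrap replicates in the identified sub-model. These
are the package's own choices of scale and are stated here so they can be
grown if heavier evidence is wanted.

## Known limitations

* The discrete-cycle model is phenomenological: no spatial structure, no
  distinction between morphological necrosis classes, no mechanistic content.
* Parameter-level inference from post-onset data alone is ill-posed (see the
  identifiability section); report and compare fitted curves, or anchor the
  period/onset externally.
* Counts are treated as independent across fields and time points
  (cross-sectional sampling); longitudinal within-animal correlation is out
  of scope.
* The least-squares objective is not a count likelihood; Poisson or
  negative-binomial regression alternatives are deliberately out of scope.
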