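---
title: "Methods: the comprehensive workload index and its analysis pipeline"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: the comprehensive workload index and its analysis pipeline}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pcwload)
```

## The model

`pcwload` implements an integrated index of physician workload in
outpatient practice. The premise is that neither objective workload (how
many patients a physician sees) nor subjective mental workload alone
describes the burden of outpatient work; the index combines both, at the
level of the two task groups that outpatient work decomposes into:
physician–patient **communication** tasks (direct interaction) and
**non-communication** tasks (paperwork and everything else).

For respondent $i$, each task group $g$ gets a mental workload score from a
six-dimension, twelve-item hybrid NASA-TLX/SWAT instrument. The dimensions
are mental demands (MD), physical demands (PD), temporal demands (TD),
perceived risk (PR), frustration level (FL) and performance (Pe). Items are
rated on a 0–100 scale; a dimension score is the mean of its items, and the
respondent also completes all $\binom{6}{2} = 15$ pairwise comparisons of
the dimensions, once per task group. The weight of dimension $d$ is the
number of comparisons $d$ won divided by 15, so the weights are a convex
combination by construction, and the mental workload score is

$$\mathrm{PMW}_{g,i} = \sum_{d} S_{d,g,i}\, W_{d,g,i} \in [0, 100].$$

Task workload multiplies mental resources by time resources:
$\mathrm{PW}_{g,i} = \mathrm{PMW}_{g,i}\, T_{g,i}$, with $T_{g,i}$ the
per-visit minutes spent on task group $g$. The comprehensive index is

$$\mathrm{PCW}_i = (\mathrm{PW}_{\mathrm{comm},i} +
\mathrm{PW}_{\mathrm{noncomm},i}) \cdot R_{ov,i} \cdot R_{pc,i} \cdot
R_{ps,i},$$

where the three multiplicative coefficients adjust for objective workload
(outpatients served per day), served patient complexity (the ratio of
outpatients admitted for further care to outpatients seen) and service
quality (self-rated outpatient satisfaction).

### Coefficient scaling

The instrument fixes which observable drives each coefficient but not its
scale, and the absolute scale of the index depends directly on that choice.
The package's defaults, all configurable via `adjustment_scheme()`:

* `r_ov = "sample_mean"` — outpatients per day divided by the sample mean,
  so the average practice maps to 1;
* `r_pc = "minmax1"` — the admitted ratio min–max normalised over the
  analysis sample, plus 1. This keeps the coefficient in $[1, 2]$ and maps
  a physician who admits no one exactly to the reference value 1, which is
  the property the construction exists for (a raw zero ratio would zero the
  whole index);
* `r_ps = "scale_max"` — satisfaction divided by its scale maximum 100.

Raw-value alternatives are provided for each coefficient; every report
records the scheme used. Because the scale of the index is a modelling
choice, absolute index values are only comparable within one scheme, and
the package makes no claim to reproduce any particular published absolute
index level. All relative quantities — group classification, regressions,
cross-tab tests — are invariant to a global rescaling of the index.

### Classification

The four workload groups cut the index at $M - SD$, $M$ and $M + SD$
computed from the analysed sample: I/low ($\mathrm{PCW} \le M - SD$),
II/medium, III/high, IV/very high ($\mathrm{PCW} > M + SD$), with each cut
inclusive on its left side. The SD is the sample standard deviation
($n - 1$ denominator), the usual survey convention. For a heavily
right-skewed index $M - SD$ can fall below the data minimum (or below
zero), leaving the low group legitimately empty; the pipeline tolerates
this and downstream tests then operate on the observed groups. A
zero-spread sample is classified entirely as medium, with a warning.

## Inference stages

`ln(PCW)` is the regression response because the index, a product of
positive factors, is approximately log-normal; records with a zero index
have no logarithm and are excluded from the regression with a warning
rather than floored (the `r_pc` "+1" construction exists precisely to make
zeros rare, so a zero is treated as a degenerate record, not a value to
transform). Predictors are indicator-coded categorical characteristics with
explicit reference levels; variance inflation factors are computed per
indicator term as $1/(1 - R^2_j)$ from auxiliary regressions, matching
per-term reporting for dummy-coded designs.

Group differences across characteristics use the Pearson chi-square
statistic with no continuity correction, with the asymptotic p-value kept
even when expected cells fall below 5 (a warning is emitted; published
analyses of this design do the same). Where a category row is so sparse
that it dominates the statistic while carrying almost no observations, the
convention adopted here — matching the published analyses the reference
tables come from — is to exclude that row from the test; the package leaves
this to the caller by operating on whatever table it is given.

Determinants of group membership use maximum-likelihood multinomial logit
(`nnet::multinom`) with the very-high group as base outcome, reporting
relative risk ratios $\exp(\beta)$ with Wald 95% intervals exponentiated
from the log scale. A predictor level with an empty outcome cell is
reported as not estimable (`NA`) rather than fitted, since its
quasi-separated coefficient would diverge.

Significance is flagged at $p < 0.10$ and $p < 0.05$, the thresholds the
reporting convention uses; no multiple-testing correction is applied
because the analysis is descriptive, not confirmatory.

## The synthetic survey generator

The respondent-level data of the motivating nationwide survey
($N = 1{,}934$ physicians) are not public, so the package ships a generator
(`pcw_sim_config()`, `sample_population()`) that emulates its *marginal*
structure: the published category frequencies of fourteen characteristics,
outpatients served per day (negative binomial matched to mean 43.20, SD
24.81, floored at 1), admissions per day (binomial given outpatients, rate
matched to mean 4.22), satisfaction (truncated normal, mean 80.59, SD
14.75, rounded to steps of 5) and per-visit communication /
non-communication times (zero-truncated normals, means 6.02 / 3.95
minutes). Item ratings honour the 10-point bipolar format by rounding to
steps of 10.

Covariate effects are injected through a latent log-workload
$\eta_i = \sum \text{effects} + \varepsilon_i$,
$\varepsilon_i \sim N(0, \sigma)$, whose exponential scales all dimension
rating means, so an effect of size $b$ shifts $\ln(\mathrm{PCW})$ by
approximately $b$ and the full pipeline can be validated by parameter
recovery. This generative construction is an artifact choice — the survey
design specifies the regression it fits, not a data-generating process —
and three of its parameters deserve comment:

* **Noise SD** $\sigma$ (default 0.7): no residual spread is published for
  the log-scale regression, so this is a free, unanchored parameter.
* **Baseline rating level** (default $\exp(\log 25) = 25$): placed in the
  lower half of the 0–100 scale so that the multiplicative spread
  $e^{\eta}$ rarely saturates the scale ceiling. Saturation and rounding
  attenuate injected effects; at the default baseline the attenuation is
  negligible for small effects (order 0.1 on the log scale) and mild but
  visible for large ones (order 0.5), which the recovery tests document.
* **Pairwise picks**: drawn from a logistic (Bradley–Terry-like) comparison
  of the record's dimension means (scale 8 rating points), so weights
  concentrate on genuinely higher-scoring dimensions without being
  deterministic.

What the generator does **not** emulate: any joint dependence among
characteristics (region × hospital level, say), within-respondent
correlation between the two task-group assessments beyond the shared
latent, or the real instrument's item-level psychometrics. Passing recovery
tests therefore demonstrate that the pipeline's arithmetic and inference
are correct under a plausible data-generating process, not that the
generator reproduces the real survey's joint distribution.

Determinism is per `(config, seed)`: one seed initialises the generator and
all draws are vectorised field by field, so two calls with the same
arguments are identical, but growing `n` re-randomises earlier records.
Replicated experiments (`recovery_experiment()`) derive replicate seeds as
`seed + r`.

## Numerical choices

* **Boundary tolerance.** Classification cuts carry a $10^{-9}$ relative
  tolerance so a score printed equal to a cut point lands on the $\le$
  side regardless of floating-point representation (e.g. $811.30 - 494.98$
  is not exactly $316.32$ in doubles).
* **Distribution bins** are left-open right-closed, 0 to 1,800 in steps of
  200 with a final right-open tail interval; a score outside all bins is an
  error by default, and `include_lowest = TRUE` admits a score exactly at
  the lower edge (used by the pipeline, whose index can in principle be 0).
* **Weights** are exact multiples of $1/15$; validation requires all 15
  pairs present exactly once and each pick a member of its pair. Ties are
  not representable — the instrument forces a choice.
* **Eligibility** is complete-case: at least 4 months in the outpatient
  clinic, at least 1 year employed in the current institution, and no
  missing or malformed field among those the pipeline uses. Malformed rows
  are retained at read time with a problem log, then rejected explicitly at
  screening, so nothing is silently dropped.
* **Degenerate inputs**: constant admitted ratio collapses `r_pc` to 1
  with a warning; zero outpatients per day flags the record and floors its
  ratio at 0; an exactly collinear regression design is an error naming
  the aliased terms; an infinite VIF is reported with an aliasing warning.

## Problem sizes

The shipped tests validate scale scoring against a brute-force oracle on
hundreds of random assessments, the chi-square statistic against a two-loop
oracle on 500 random tables, marginal emulation at $n = 20{,}000$–$50{,}000$,
and effect recovery with 200 replicate surveys of $n = 2{,}000$ (mean
recovered effect within 0.01 of the injected 0.115, interval coverage in
the nominal band). These sizes give Monte-Carlo standard errors comfortably
inside the asserted tolerances.

## Interface notes

The package is organised around one fitting function: `pcw()` takes a
survey data frame and returns a classed fit with `print`, `summary`,
`plot` and `as.data.frame` methods; `fit_lnpcw()` and `fit_pcw_multinom()`
consume the fit for the inference stages, and `run_pipeline()` /
`render_reports()` execute and serialise the whole analysis. Simulation,
scoring, classification and reporting are all reachable as plain functions,
which is the intended scripting interface.

## Limitations

Self-rated satisfaction is a coarse proxy for service quality, and a single
admitted-ratio indicator is a coarse proxy for patient complexity; both are
inherited from the instrument. The absolute index scale is scheme-dependent
(see above). The generator's independence assumptions mean
characteristic-by-characteristic analyses of synthetic data are realistic,
but joint analyses (interactions, confounding structure) are not. And the
classification is relative to the analysed sample: a physician's group
label changes when the sample around them changes, which is intended — the
index discriminates *within* a surveyed population rather than against an
absolute threshold.
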