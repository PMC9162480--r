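# pcwload

Integrated evaluation of physician comprehensive workload (PCW) tethered to
outpatient practice.

## The problem

Outpatient physicians carry two kinds of burden at once: *objective*
workload (how many patients they see per day) and *mental* workload (the
cognitive cost of the work itself). Either one alone misclassifies people —
a physician with a moderate patient count and punishing cognitive load, or
vice versa, is invisible to a single-axis measure. `pcwload` implements a
composite index that combines both, for researchers and hospital-management
analysts who want to score survey data, stratify physicians into workload
groups, and model which characteristics drive the index.

## The model

Each respondent rates a six-dimension, twelve-item hybrid NASA-TLX/SWAT
mental workload instrument twice — once for physician–patient
**communication** tasks, once for **non-communication** (paperwork-type)
tasks — and completes all 15 pairwise comparisons of the six dimensions
(mental, physical and temporal demands; perceived risk; frustration;
performance). With dimension scores *S* (item means, 0–100) and weights
*W* (pairwise win counts / 15):

    PMW_g = Σ_d S_d W_d                      (per task group g, in [0, 100])
    PW_g  = PMW_g × T_g                      (T_g: minutes per visit on g)
    PCW   = (PW_comm + PW_noncomm) × R_ov × R_pc × R_ps

where the adjustment coefficients are driven by outpatients served per day
(`R_ov`, objective workload), the admitted-to-seen patient ratio (`R_pc`,
patient complexity, min–max normalised + 1 so "admits nobody" is the
reference value 1) and self-rated outpatient satisfaction (`R_ps`, service
quality). Scores are stratified at M − SD, M, M + SD into four groups
(low / medium / high / very high), cross-tabulated against characteristics
with Pearson chi-square tests, and modelled by OLS on ln(PCW) (with
per-term variance inflation factors) and by multinomial logistic regression
reporting relative risk ratios against the very-high group.

Because the raw survey behind the design is not public, the package
includes a synthetic generator that emulates its published marginal
structure and supports parameter-recovery validation of the entire
pipeline.

## Worked example

```r
library(pcwload)

# a synthetic survey of 1,000 physicians with a gender effect of 0.115
# on the log-workload scale
cfg <- pcw_sim_config(n = 1000, effects = list(gender = c(Female = 0.115)))
dat <- sample_population(cfg, seed = 3)

fit <- pcw(dat)
fit
#> Physician comprehensive workload fit
#>   respondents: 1000
#>   PCW: mean 363.68, SD 415.36, range [1.54, 5276.49]
#>   coefficient scheme: r_ov = sample_mean | r_pc = minmax1 | r_ps = scale_max
#>   groups: low 0 (0.0%), medium 685 (68.5%), high 207 (20.7%), very high 108 (10.8%)
```

The index is a product of positive factors, hence right-skewed: here
M − SD falls below the data minimum, so the low group is empty and most
respondents sit in the medium band — the classification always describes
the analysed sample. The log-scale regression recovers the injected
effect:

```r
fit_lnpcw(fit, c("gender", "area"),
          references = list(gender = "Male", area = "Central"))
#> ln(PCW) linear regression (n = 1000 , residual df = 996 )
#> Reference levels: gender = Male; area = Central
#>
#>          term      beta      se     t p_value  vif sig
#>   (Intercept)  5.278000 0.06558 80.47  0.0000   NA ***
#>  genderFemale  0.134400 0.06706  2.00  0.0453 1.00  **
#>   areaEastern -0.005428 0.07884 -0.07  0.9450 1.31
#>   areaWestern  0.189700 0.08569  2.21  0.0271 1.31  **
#> Significance: * p < 0.10, ** p < 0.05, *** p < 0.01
```

`genderFemale = 0.134` estimates the injected 0.115 (one draw; the shipped
recovery experiment averages 200 replicates and lands within 0.01). The
published cross-tabulations bundled with the package reproduce their
chi-square statistics exactly:

```r
chisq_pearson(reference_crosstabs("gender"))
#> Pearson chi-square: X2 = 36.523, df = 3, p < 0.001

pcw_classification(811.30, 494.98)
#> Workload classification: M = 811.30, SD = 494.98
#>   I/low        score <= 316.32
#>   II/medium    316.32 < score <= 811.30
#>   III/high     811.30 < score <= 1306.28
#>   IV/very high score > 1306.28
```

A whole analysis — generate or read, screen eligibility, score, classify,
tabulate, test, regress — runs as one call and serialises to CSV + JSON:

```r
rep <- run_pipeline(pipeline_config(generator = cfg, seed = 1))
render_reports(rep, "out/")
```

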