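# bhindex

Construction and modelling of a composite **brain-health index** for
two-timepoint training studies, written for biostatisticians and
psychometricians analysing multi-domain assessment batteries.

A single 0–100 index summarizes a 20-measure online battery spanning four
domains — cognition, well-being, social interaction and daily life. Each
raw instrument score *z<sub>i</sub>* is converted to a percentile through a
reference CDF, *P<sub>i</sub> = 100 Φ(z<sub>i</sub>)*, and combined as the
weighted average

&nbsp;&nbsp;&nbsp;&nbsp;BHI = Σ<sub>i</sub> w<sub>i</sub> P<sub>i</sub>,&nbsp;&nbsp;Σ<sub>i</sub> w<sub>i</sub> = 1,

with half of the weight on cognition (clinician-consensus scheme) and
reverse-scored measures (depression, anxiety, stress, sleep) inverted at
the transform stage. Reference CDFs are empirical (midrank convention),
moment-matched parametric (Gaussian / gamma / negative binomial, closed
form), or bootstrap-based for the model-derived metabolic-equivalents
score.

On top of the index the package provides, for pre/post change:

- **gain summaries** — mean change, Cohen's *d* = mean/sd with a
  noncentral-*t* confidence interval, proportion above a gain threshold;
- an **exploratory factor model of change scores** — maximum-likelihood
  extraction (profiled Λ, quasi-Newton Ψ, Heywood bounding), varimax
  rotation, Horn's parallel analysis with 95th-percentile random-reference
  eigenvalues for factor retention, and a full fit panel (Bartlett-corrected
  χ², TLI, RMSEA with CI, RMS residual, off-diagonal fit), plus normalized
  loadings with the 0.200 salience cutoff and regression-method construct
  scores;
- a **spline dose–response analysis** — index change regressed on a 3-df
  natural cubic spline of training modules completed, with dose contrasts,
  a tail-flatness check and demographic-independence tests;
- a **calibrated synthetic-cohort generator** with a latent three-factor
  change structure and a piecewise dose-effect profile, emitting ground
  truth for parameter-recovery testing.

## Worked example

```r
library(bhindex)

cohort <- generate_cohort(cohort_config(seed = 1))   # n = 180, 80% retention
report <- bhi_report(cohort$assessments, cohort$battery, seed = 1)
report
#> <bhi_report>
#>   completers: 142; mean gain 11.13 points (sd 10.29), d = 1.08 [0.87, 1.29]
#>   74% with >= 5-point gain
#>   factors: <bhi_factor_solution> m = 3 (parallel analysis retained 3 )
#>   chi-square 114.96 on 133 df (p = 0.868), TLI 1.040, RMSEA 0.000
#>   RMS residual 0.040, off-diagonal fit 0.970
#>   dose contrasts: 4 vs 0 = 8.44, 7 vs 4 = 2.59; tail flat
```

Reading the output: 142 of 180 simulated participants completed the second
assessment; their index rose 11.1 points on average (a standardized gain
near 1), and 74% gained at least 5 points. Parallel analysis retained
three latent change constructs, and the factor solution reproduces the
change correlations closely (133 df for 20 measures and 3 factors). The
spline curve rises ≈ 8 points over the first four training modules and
flattens past seven — single-cohort contrast estimates are noisy (the
zero-dose group is small by design), which is why recovery checks average
many replicate cohorts. The median baseline index in this cohort is 54.3.

Individual records can be scored directly:

```r
battery <- default_battery()
scores  <- score_assessments(cohort$assessments, battery)
deltas  <- delta_table(cohort$assessments, battery, scores)
gain_summary(deltas)
fit <- fit_dose_response(deltas)
dose_contrast(fit, 4, 0)
```

A thin CLI wraps the same functions:

```sh
Rscript inst/cli/bhi.R simulate --seed 7 --n 180 --out cohort.csv
Rscript inst/cli/bhi.R report --input cohort.csv --seed 7 --out report.json
```

## Package layout

- `R/battery.R` — measure registry, battery config I/O
- `R/reference.R` — reference distributions and percentile transform
- `R/index.R` — composite index, change table, gain summaries
- `R/factor.R` — ML EFA, varimax, parallel analysis, fit statistics
- `R/dose.R` — spline dose–response and demographic tests
- `R/cohort.R` — synthetic-cohort generator and its calibration
- `R/report.R`, `inst/cli/bhi.R` — report assembly and CLI
- `vignettes/brain-health-index.Rmd` — methods and design notes
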