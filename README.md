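# apcpolish

Multiphase age–period–cohort (APC) analysis for epidemiologists: estimate
birth-cohort effects from an age × period contingency table of event rates
without confronting the classical APC identifiability problem.

Age, period and cohort are linearly dependent (age + cohort = period), so
the linear effects of the model

    log λ_ij = μ + α_i + β_j + γ_k,   k = j − i + I

cannot be jointly identified.  The multiphase approach instead treats the
cohort effect as the age × period *interaction*: **Tukey median polish**
iteratively subtracts row (age) and column (period) medians from the log
rates until residual row/column medians vanish, and the residuals are then
regressed on the K = I + J − 1 cohort indicator variables (no intercept),
optionally **weighted by death counts** (WLS), giving per-cohort rate
ratios `RR_k = exp(γ_k − γ_ref)` with 95% confidence intervals against a
reference cohort chosen automatically as the one whose rates change least
when the cohort influence is removed.

The package ships the Taiwan 1976–2010 hepatocellular-carcinoma (HCC)
mortality rate tables (10 five-year age groups 40–44 … 85+, 7 five-year
periods, 16 birth cohorts 1891 … 1966) as worked fixtures, plus direct age
standardization (WHO 2000 World Standard), Poisson deviance diagnostics for
the null → age → age-period → APC model sequence, a Poisson simulator with
known truth, a Monte-Carlo recovery study, and a CLI.

## Worked example

```r
library(apcpolish)
tab <- hcc_mortality("males")
dec <- apc_median_polish(tab)
dec
#> Median polish decomposition (19 iterations, converged)
#>   constant mu = -6.7388 (log rate per person-year)
#>   age effects:    -1.37 -0.83 -0.41 -0.09 0.12 0.32 0.45 0.54 0.62 0.67
#>   period effects: -0.25 -0.1 -0.08 0.04 0.11 0.16 0.13

sel <- select_reference(tab, dec)   # cohort least changed by removing
sel$label                           # its residual factor
#> [1] 1946

rr <- rate_ratios(fit_cohort_effects(residual_observations(dec)), sel$label)
rr
#> Cohort rate ratios (unweighted, reference 1946, 95% CI)
#>  cohort effect        ci
#>    1891   0.75 0.62-0.90
#>    ...
#>    1936   1.13 1.03-1.25
#>    1946   1.00       REF
#>    1966   0.68 0.57-0.82
```

The constant −6.74 is the overall log mortality rate per person-year
(≈118 deaths per 100,000); age effects rise monotonically with age and
period effects peak in 2001–2005.  The rate ratios say that, relative to
men born around 1946, the 1936 cohort's HCC mortality is 13% higher and
the 1966 cohort's 32% lower — the cohort-driven reversal that a naive
extrapolation of the still-rising age-standardized trend would miss:

```r
round(age_adjust(tab), 1)
#> 1976-1980 1981-1985 1986-1990 1991-1995 1996-2000 2001-2005 2006-2010
#>      78.6      90.9      92.3     105.3     113.0     113.6     109.1
```

With death counts attached (`apc_table(..., deaths =, population =)` or
synthetic tables), `cohort_weights(obs, "per_cell_deaths")` turns the fit
into weighted least squares with narrower intervals, and
`deviance_summary()` checks model fitness.  `recovery_study()` measures
bias/RMSE/coverage of either estimator on simulated worlds with known
cohort effects; see the vignette (`vignettes/multiphase-apc.Rmd`) for the
design of the tie-free recovery benchmark.

## Command line

```sh
Rscript -e 'quit(status = apcpolish::apc_cli())' \
  cohort-effects --fixture hcc_males --weighting uniform --reference auto \
  --out results/
```

Subcommands: `decompose`, `cohort-effects`, `select-reference`,
`standardize`, `diagnose`, `simulate`, `recover`.  Every run writes plain
CSV outputs plus a JSON manifest of inputs and options; exit codes are 0
(success), 1 (validation error), 2 (usage error).

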