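# no2burden

Comparative risk assessment of the disease burden attributable to nitrogen
dioxide (NO₂) in urban populations, resolved by source. Urban residents
inhale NO₂ from three places: ambient (outdoor-originated) air, household
gas cooking, and secondhand smoke (SHS). This package estimates, for
stratified populations (city × age band × sex), the disability-adjusted
life years (DALYs) from lung cancer (LC), chronic obstructive pulmonary
disease (COPD) and diabetes mellitus (DM) attributable to that exposure,
the economic losses they imply, and the burden avoided under counterfactual
control scenarios — an indoor smoking ban, switching households from gas to
electric cooking, and capping ambient NO₂ at the WHO interim targets and
air quality guideline.

It is written for environmental-health researchers and policy analysts who
want a reproducible, testable implementation of this class of burden
pipeline. Because city-level exposure, baseline-rate and census inputs of
this kind are rarely deposited, the package ships a calibrated synthetic
cohort generator; all tables are plain CSV, so real inputs can be dropped
in with the same schemas.

## The model

Relative risk follows a capped log-linear concentration–response function
(CRF) per disease *d*:

```
RR_d(C) = RR0_d ^ ( min(C, MaxC_d) / ΔC0 ),     C = C_ambient + C_cooking + C_SHS
```

with `RR0_d` the meta-analytic relative risk per ΔC0 = 10 µg/m³ and
`MaxC_d` the highest exposure supported by the epidemiology (RR is held
constant beyond it). Defaults: LC 1.055 (1.010–1.101), MaxC 54.0; COPD
1.016 (1.012–1.020), MaxC 60.7; DM 1.019 (1.009–1.029), MaxC 44.0.

For each population stratum *g*, individual exposures are drawn from
moment-matched lognormal distributions per source and averaged after
applying the CRF:

```
PAF_dg   = (RR̄ − 1) / RR̄                        population attributable fraction
PAF_sdg  = (C̄_s / C̄_exp) · PAF_dg               source apportionment
DALY_sdg = PAF_sdg · DALYrate_dg / 1e5 · N_g
PIF_idg  = (RR̄_S0 − RR̄_Si) / RR̄_S0              potential impact fraction
RDALY    = PIF · DALYrate / 1e5 · N
EL       = GDP_pc · DALY                          human capital approach
```

Uncertainty is propagated with a two-stage Monte Carlo: stage 1 draws
individual exposures (intra-population variability, default 2,000 per
stratum), stage 2 draws CRF and baseline-rate parameters (default 1,000
iterations); results are reported as mean and 95% uncertainty interval
(2.5th–97.5th percentile). See `vignettes/no2-burden-methods.Rmd` for the
full account of assumptions and numerical choices.

## Worked example

```r
library(no2burden)

cohort <- generate_cohort(synthetic_config(n_cities = 30, seed = 2019))
population_weighted_exposure(cohort$exposure, cohort$baseline,
                             interval = FALSE)$mean
#> [1] 26.7

mc <- run_two_stage(cohort, config = uncertainty_config(
  n_variability = 500, n_uncertainty = 200, seed = 2019))
bt <- burden_table(mc)   # DALYs in thousands, losses in billions CNY
format_burden_table(bt)[bt$disease == "total", ]
#>  scenario  source disease          dalys economic_losses
#>        S0 ambient   total    82 (38-123)   5.7 (2.6-8.6)
#>        S0 cooking   total     42 (19-63)   2.9 (1.3-4.4)
#>        S0     shs   total  1.3 (0.6-2.0)   0.1 (0.0-0.1)
#>        S0   total   total   126 (58-189)    8.7 (4.0-13)
#>        S1    <NA>   total  1.3 (0.6-2.0)   0.1 (0.0-0.1)
#>        S2    <NA>   total     42 (19-65)   2.9 (1.3-4.5)
#>        S3    <NA>   total  2.5 (1.2-3.8)   0.2 (0.1-0.2)
#>        S4    <NA>   total 6.5 (3.0-10.0)   0.4 (0.2-0.6)
#>        S5    <NA>   total    18 (8.2-28)   1.2 (0.6-1.9)
#>        S6    <NA>   total     49 (22-75)   3.4 (1.5-5.2)

sr <- shares_and_reductions(bt)
sr$disease_share_pct
#> COPD   DM   LC
#>   22   16   62
sr$reduction_pct_el
#> S1 S2 S3 S4 S5 S6
#>  1 33  1  4 13 38
```

Reading: in this 30-city synthetic cohort, 126 (58–189) thousand DALYs are
attributable to NO₂, about two-thirds from ambient air and one-third from
gas cooking, with SHS near 1%. Lung cancer carries ~62% of the burden.
Switching every household to electric cooking (S2) removes 33% of the
economic losses — more than meeting the WHO interim target 3 (S5, 13%) and
approaching the full air-quality-guideline scenario (S6, 38%).

The same pipeline is scriptable from a shell:

```sh
Rscript inst/cli/no2burden.R simulate --config cfg.yaml --out run/
Rscript inst/cli/no2burden.R estimate --inputs run/ --out run/ --seed 1
Rscript inst/cli/no2burden.R report   --inputs run/ --out run/
```

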