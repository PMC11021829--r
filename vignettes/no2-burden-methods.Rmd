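---
title: "Methods: source-resolved NO2-attributable burden estimation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: source-resolved NO2-attributable burden estimation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(no2burden)
```

## The estimation problem

Urban residents are exposed to NO₂ from ambient (outdoor-originated) air,
household gas cooking, and secondhand smoke (SHS). The package estimates,
per population stratum (city × ten age bands × two sexes), the DALYs from
lung cancer, COPD and diabetes mellitus attributable to that exposure, the
associated economic losses, and the burden avoided in counterfactual
scenarios. The pipeline is the standard comparative-risk-assessment chain —
exposure distribution → relative risk → attributable fraction → burden —
with two specific features: burden is *apportioned across sources*, and
scenario effects are computed as *potential impact fractions* against a
common baseline.

## Concentration–response model

Relative risk is a capped power law of annual NO₂ exposure:

$$RR_d(C) = RR_{0,d}^{\min(C,\,MaxC_d)/\Delta C_0}$$

* `RR0` (dimensionless) is the meta-analytic relative risk per
  ΔC₀ = 10 µg/m³; shipped defaults (`default_crfs()`): LC 1.055
  (1.010–1.101), COPD 1.016 (1.012–1.020), DM 1.019 (1.009–1.029).
* `MaxC` (µg/m³; 54.0 / 60.7 / 44.0) is the highest exposure level in the
  underlying epidemiology. Holding RR constant beyond it is a conservative
  choice: extrapolating a log-linear CRF produces unrealistically large
  risks at high concentrations.

The cap is applied **per individual before averaging**. Averaging first and
capping after is not the same operation (the cap is convex-breaking), and
the per-individual order is the one consistent with defining the population
average relative risk over simulated individuals.

Attributable and impact fractions:

$$PAF = \frac{\bar{RR}-1}{\bar{RR}}, \qquad
  PAF_s = \frac{\bar{C}_s}{\bar{C}_{exp}}\,PAF, \qquad
  PIF_i = \frac{\bar{RR}_{S0}-\bar{RR}_{Si}}{\bar{RR}_{S0}}$$

The proportional-to-mean-concentration apportionment is the convention used
to split PM₂.₅ burden between household and ambient air pollution. It is
applied exactly as stated even when some individuals sit at the RR cap;
apportionment under capping has no established alternative convention. When
the total mean exposure is zero the attributable burden is zero and all
source PAFs are set to 0 (the 0/0 case is fixed by convention). Protective
CRFs (RR₀ < 1) are out of scope; `paf()`/`pif()` reject average RRs below 1,
and a PIF that would come out negative (a "control" scenario that raises
exposure) is rejected rather than clipped, to surface configuration errors.

Burden and monetization:

$$DALY_{s,d,g} = PAF_{s,d,g}\cdot \frac{DALYrate_{d,g}}{10^5}\cdot N_g,
  \qquad EL = GDP_{pc}\cdot DALY$$

One DALY is valued at one GDP per capita (human capital approach), using
the city's GDP per capita for all its strata; age-specific productivity
weights are deliberately not modeled, as defensible coefficients are hard
to establish and vary strongly across regions.

## Scenarios

`scenario_suite()` ships seven counterfactuals: S0 the 2019 baseline; S1 an
indoor smoking ban (C_SHS = 0); S2 electric instead of gas cooking
(C_cooking = 0); S3–S6 ambient caps at the WHO interim targets 1–3 and air
quality guideline (40/30/20/10 µg/m³ annual outdoor NO₂).

The cap rule compares the city's *monitored outdoor* concentration — not
the exposure concentration — to the target; ties take the unchanged branch.
For a capped city the ambient exposure becomes `target × f_exp`, where the
exposure factor `f_exp ≤ 1` is the ratio of inhaled outdoor-originated
concentration to the outdoor concentration (below 1 because of indoor
surface removal).

Taken literally, the cap rule assigns a single value. The package instead
**rescales the individual-level ambient distribution by
`target / outdoor_no2`**, which reproduces the rule in the mean while
preserving within-population variability — the rest of the pipeline treats
exposure as a distribution over individuals, and collapsing it only for
capped cities would make scenario contrasts incoherent. A strict-literal
mode (`cap_mode = "literal"`, sd → 0) is available for sensitivity checks.

Scenario counterfactuals are implemented as transforms of one common
baseline sample (common random numbers): removal zeroes a column, caps
rescale one. Whether the original analyses redrew exposures per scenario is
not documented in this literature; the common-sample choice is made
deliberately because it reduces variance in scenario contrasts and makes
cell-wise monotonicity (nested caps ⇒ ordered reductions) hold per
iteration, not just in expectation. Redrawing is available via
`uncertainty_config(redraw_per_iteration = TRUE)`.

## Two-stage Monte Carlo

* **Stage 1 — variability**: `n_variability` (default 2,000) individuals
  per stratum drawn from moment-matched lognormals per source
  (`mean`, `sd` → `meanlog`, `sdlog`; concentrations are positive and
  right-skewed, and only the first two moments are available). Sources are
  sampled independently within an individual; no correlation structure is
  reported for them. Degenerate inputs collapse exactly: sd = 0 yields the
  mean, mean = 0 yields zeros.
* **Stage 2 — uncertainty**: `n_uncertainty` (default 1,000) iterations
  draw, per disease, an RR₀ and, per stratum × disease, a baseline DALY
  rate. The default 2,000 × 1,000 grid gives 2,000,000 total iterations.
* RR₀ draws: lognormal with median at the central estimate and log-scale sd
  `(ln U − ln L) / (2 × 1.959964)` — meta-analytic RR intervals are close
  to log-symmetric (1.010–1.101 around 1.055). Draws are **floored at 1**:
  the fitted lognormal has a small tail below 1 even when the CI is
  entirely above it, and a protective draw would produce negative
  attributable burden, which is out of scope. The floor affects well under
  1% of draws for the shipped CRFs and keeps every per-iteration fraction
  in [0, 1).
* Rate draws: lognormal fitted to the 95% UI by default (rates are
  positive); a zero-truncated normal is available
  (`rate_distribution = "normal_truncated"`). Draws are mapped through a
  common quantile so correlation is a configuration choice.
* Correlation structure: RR₀ draws are shared across strata and sources
  within an iteration (CRF uncertainty is systematic/global); rate draws
  are independent across strata (baseline-rate uncertainty is local). Both
  are configurable (`rr0_shared`, `rate_shared`). These are documented
  defaults, not claims about any original study; the distribution families
  are likewise not specified in the source literature.
* Summaries: arithmetic mean plus empirical 2.5th/97.5th percentiles with
  linear interpolation on order statistics (R's quantile type 7) — stated
  explicitly because percentile definitions differ across ecosystems.
* Aggregation sums cells **per iteration** and then summarizes; percentiles
  are never added across cells.

## Synthetic cohort generator

`generate_cohort()` emulates the input tables the pipeline needs for urban
China in 2019: 330 cities across 31 provinces, ten age bands, two sexes.
What it reproduces, by construction:

* national population-weighted total exposure = 26.7 µg/m³, indoor-source
  share 34.5% (middle of the reported 30–40% band), SHS share 1% of total —
  enforced by an exact global rescale of the drawn ambient/cooking/SHS
  levels (the calibration targets are configuration fields);
* ambient stratum mean ≡ `outdoor_no2 × f_exp` for every stratum;
* higher outdoor NO₂, populations and GDP in first-tier and new first-tier
  cities; cooking exposure ×1.5 for women in adult age bands (they cook
  more frequently); near-zero baseline LC/COPD/DM rates below age 18;
* baseline-rate uncertainty intervals default to central × {0.8, 1.25},
  since the source UIs are not published at this granularity.

What it does **not** reproduce: the true spatial distribution of Chinese
cities, real GBD rates, any micro-environmental exposure modeling, or
correlations between exposure and baseline rates beyond the tier structure.
Passing tests on this cohort therefore demonstrate correctness of the
estimation machinery and calibration of national exposure summaries — not
agreement of absolute burden totals with any published national estimate,
which depend on undeposited city-level inputs.

Other generator defaults chosen once as field-realistic values: outdoor
city means 24/32/38 µg/m³ (other/new-tier-1/tier-1) with CV 0.35 before
calibration; `f_exp` uniform on 0.55–0.85 by province; city populations
lognormal around 1.8 M (×3 / ×6 tier multipliers); GDP per capita
lognormal around 70,000 CNY; within-stratum exposure CVs 0.55 (ambient)
and 0.9 (indoor sources), which yield an individual-level 95% population
spread of roughly 9–65 µg/m³ around the 26.7 mean.

## Numerical choices

* All computation in double precision; sums and means use R's long-double
  accumulators (`sum`, `colMeans`, `rowsum`), so national totals are stable
  to summation order.
* The degenerate limit (all sds zero, CIs and UIs collapsed) reproduces the
  deterministic single-pass pipeline (`estimate_burden()`) iteration by
  iteration; the scenario-total arithmetic is written in the same
  association order in both paths so the agreement is at machine level.
* `relative_risk()` evaluates `exp(log(rr0) · e)` rather than `rr0^e` so
  the deterministic and Monte Carlo paths share one code path.
* Ties in the ambient cap (`outdoor == target`) take the unchanged branch.
* Rounding is applied only at the presentation layer
  (`format_burden_table()`, shares): DALYs to table units, shares to whole
  percent (round-half-even), scenario reduction percentages floored —
  a conservative whole-percent convention. Re-running the reporting step on
  the same estimates is idempotent. Recomputing printed-style row totals
  from independently rounded cells can differ by ±1 in the last digit;
  consistency checks allow exactly that slack.

## Problem sizes

Tests and the acceptance script run reduced-replication configurations
chosen as the package's desk-scale defaults: the cross-seed stability check
uses 20 cities at 500 × 200 iterations, and `scripts/acceptance.R` runs the
full 330-city cohort at 400 × 150. A full 330-city run at the default
2,000 × 1,000 replication is a single-CPU job of roughly one to two hours
and is intended for production use, not routine testing.

## Known limitations

* Only LC, COPD and DM are modeled; asthma and cardiovascular outcomes are
  excluded, so totals are conservative.
* The capped CRF understates risk above `MaxC` by construction.
* Apportionment by mean concentration ignores non-linearity of the CRF
  across sources; no alternative convention is established.
* A small-source removal scenario's PIF does not converge to the source's
  apportioned PAF exactly but to it times
  $\beta \bar{C} / (1 - e^{-\beta \bar{C}})$ (β = ln RR₀ / ΔC₀) as the
  source vanishes — a few percent for realistic exposures, which is why a
  smoking ban's reduction approximately (not exactly) equals the
  SHS-attributed burden.
* The economic valuation is a human capital approach with a single national
  assumption (1 DALY = 1 GDP per capita); no currency conversion,
  discounting, or age-productivity weighting.
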