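# Deterministic core math: capped power-law relative risk, population
# attributable fraction with source apportionment, potential impact
# fraction, DALYs and human-capital monetization.

crf_row <- function(crf, disease = NULL) {
  if (is.data.frame(crf)) {
    if (!is.null(disease)) crf <- crf[crf$disease == disease, , drop = FALSE]
    if (nrow(crf) != 1L)
      stop_input("expected a single CRF row; got %d", nrow(crf))
    return(as.list(crf[1, ]))
  }
  as.list(crf)
}

#' Relative risk at a given NO2 exposure concentration
#'
#' Capped power law: `RR = rr0 ^ (min(c_exp, max_c) / delta_c0)`. The cap at
#' `max_c` is a conservative choice: above the highest concentration
#' supported by the epidemiology, the RR is held constant rather than
#' extrapolated.
#'
#' @param c_exp exposure concentration(s), ug/m3, >= 0.
#' @param crf a single CRF row (see [default_crfs()]) or the full table with
#'   `disease` naming the row.
#' @param rr0 the RR0 value to use; defaults to the central estimate. Pass a
#'   draw from [sample_rr0()] for uncertainty propagation.
#' @param disease disease code when `crf` is a multi-row table.
#' @return Relative risk(s), dimensionless, >= 1 for rr0 >= 1.
#' @examples
#' relative_risk(10, default_crfs(), disease = "LC")  # 1.055
#' @export
relative_risk <- function(c_exp, crf, rr0 = NULL, disease = NULL) {
  cr <- crf_row(crf, disease)
  if (any(c_exp < 0)) stop_input("exposure concentrations must be >= 0")
  if (is.null(rr0)) rr0 <- cr$rr0_central
  exp(log(rr0) * (pmin(c_exp, cr$max_c) / cr$delta_c0))
}

#' Population-average relative risk over an individual sample
#'
#' Averages per-individual relative risks (the cap is applied per individual
#' before averaging) over a sample of total exposure concentrations.
#'
#' @param sample an `no2_exposure_sample` from [sample_individuals()], or a
#'   numeric vector of total exposure concentrations.
#' @inheritParams relative_risk
#' @return The mean relative risk (scalar).
#' @export
mean_rr <- function(sample, crf, rr0 = NULL, disease = NULL) {
  totals <- if (inherits(sample, "no2_exposure_sample")) sample$total
            else sample
  if (length(totals) == 0) stop_input("exposure sample is empty")
  mean(relative_risk(totals, crf, rr0 = rr0, disease = disease))
}

#' Population attributable fraction
#'
#' `PAF = (rr_bar - 1) / rr_bar`: the proportion of the disease burden in
#' the population attributable to the exposure.
#'
#' @param rr_bar population-average relative risk(s), >= 1.
#' @return Fraction(s) in [0, 1).
#' @export
paf <- function(rr_bar) {
  if (any(rr_bar < 1))
    stop_input("paf() requires rr_bar >= 1 (protective exposures are out of scope)")
  (rr_bar - 1) / rr_bar
}

#' Apportion a PAF across exposure sources
#'
#' Splits the total PAF proportionally to each source's mean exposure
#' concentration (the approach used to divide PM2.5 burden between household
#' and ambient air pollution). If the total mean exposure is zero the
#' attributable burden is zero and all source PAFs are 0 by convention.
#'
#' @param paf_total total PAF (scalar fraction).
#' @param c_bar_by_source non-negative mean concentrations per source.
#' @return Named source-specific PAFs summing to `paf_total`.
#' @export
apportion_paf <- function(paf_total, c_bar_by_source) {
  if (any(c_bar_by_source < 0))
    stop_input("mean concentrations must be non-negative")
  tot <- sum(c_bar_by_source)
  if (tot == 0) return(c_bar_by_source * 0)
  c_bar_by_source / tot * paf_total
}

#' Attributable DALYs for one cell
#'
#' `DALYs = fraction x (daly_rate / 100000) x population`.
#'
#' @param paf_s attributable fraction (source-specific PAF).
#' @param daly_rate baseline DALY rate per 100,000 person-years.
#' @param population persons.
#' @return DALYs (person-years).
#' @export
dalys <- function(paf_s, daly_rate, population) {
  if (any(paf_s < 0) || any(daly_rate < 0) || any(population < 0))
    stop_input("dalys() inputs must be non-negative")
  paf_s * (daly_rate / 1e5) * population
}

#' Potential impact fraction of a control scenario
#'
#' `PIF = (rr_bar_s0 - rr_bar_si) / rr_bar_s0`: the proportion of the burden
#' avoided by shifting the exposure distribution from the baseline (S0) to a
#' counterfactual (Si). Control scenarios never raise exposure, so
#' `rr_bar_si > rr_bar_s0` is rejected as a malformed scenario rather than
#' clipped.
#'
#' @param rr_bar_s0 baseline population-average RR (>= 1).
#' @param rr_bar_si counterfactual population-average RR (>= 1).
#' @return Fraction(s) in [0, 1).
#' @export
pif <- function(rr_bar_s0, rr_bar_si) {
  if (any(rr_bar_si < 1) || any(rr_bar_s0 < 1))
    stop_input("pif() requires average relative risks >= 1")
  if (any(rr_bar_si > rr_bar_s0))
    stop_input("pif() requires rr_bar_si <= rr_bar_s0; a control scenario may not raise exposure")
  (rr_bar_s0 - rr_bar_si) / rr_bar_s0
}

#' DALYs avoided by a control scenario
#'
#' As [dalys()] with the potential impact fraction in place of the PAF.
#'
#' @param pif_si potential impact fraction.
#' @inheritParams dalys
#' @return DALYs avoided (person-years).
#' @export
rdalys <- function(pif_si, daly_rate, population) {
  dalys(pif_si, daly_rate, population)
}

#' Monetize DALYs by the human capital approach
#'
#' One DALY is valued at one GDP per capita of lost production.
#'
#' @param dalys DALYs (person-years), >= 0.
#' @param gdp_per_capita CNY per person, >= 0.
#' @return Economic loss, CNY.
#' @export
monetize <- function(dalys, gdp_per_capita) {
  if (any(dalys < 0) || any(gdp_per_capita < 0))
    stop_input("monetize() inputs must be non-negative")
  dalys * gdp_per_capita
}

# ---------------------------------------------------------------------------

# One row per stratum with environment columns joined; shared by the
# deterministic pipeline and the Monte Carlo engine.
build_strata <- function(cohort) {
  base <- cohort$baseline
  key <- unique(base[c("city_id", "province_id", "tier", "age_group", "sex")])
  skey <- paste(base$city_id, base$age_group, base$sex)
  pop <- base$population[match(paste(key$city_id, key$age_group, key$sex),
                               skey)]
  idx <- match(key$city_id, cohort$environment$city_id)
  key$population <- pop
  key$outdoor_no2 <- cohort$environment$outdoor_no2[idx]
  key$f_exp <- cohort$environment$f_exp[idx]
  key$gdp_per_capita <- cohort$environment$gdp_per_capita[idx]
  rownames(key) <- NULL
  key
}

# Wide per-stratum source means/sds aligned with build_strata() row order.
exposure_wide <- function(cohort, strata) {
  ex <- cohort$exposure
  sk <- paste(strata$city_id, strata$age_group, strata$sex)
  out <- list()
  for (src in exposure_sources()) {
    rows <- ex[ex$source == src, ]
    idx <- match(sk, paste(rows$city_id, rows$age_group, rows$sex))
    out[[src]] <- list(mean = rows$mean[idx], sd = rows$sd[idx])
  }
  out
}

# Per-source multiplicative factors implementing each scenario as a
# transform of the common baseline sample (common random numbers):
# remove_source -> 0; ambient_cap -> target/outdoor for capped cities.
scenario_factors <- function(strata, scenarios) {
  S <- length(scenarios)
  f <- array(1, dim = c(nrow(strata), 3L, S),
             dimnames = list(NULL, exposure_sources(),
                             vapply(scenarios, `[[`, "", "name")))
  for (j in seq_len(S)) {
    sc <- scenarios[[j]]
    if (sc$kind == "remove_source") {
      f[, sc$removed_source, j] <- 0
    } else if (sc$kind == "ambient_cap") {
      capped <- strata$outdoor_no2 > sc$target
      f[capped, "ambient", j] <- sc$target / strata$outdoor_no2[capped]
    }
  }
  f
}

baseline_index <- function(scenarios) {
  ib <- which(vapply(scenarios, `[[`, "", "kind") == "baseline")
  if (length(ib) != 1L)
    stop_input("scenario list must contain exactly one baseline scenario")
  ib
}

#' Deterministic burden pipeline (point estimates)
#'
#' Runs the full estimation with every individual placed at the stratum mean
#' exposure and all uncertain quantities at their central values: RR from
#' the total mean concentration, PAF apportioned across sources, DALYs from
#' central baseline rates, PIF-based reductions for control scenarios, and
#' monetization at the city GDP per capita. This is the exact limit of the
#' two-stage Monte Carlo when all variability and uncertainty collapse.
#'
#' @param cohort a validated `no2_cohort`.
#' @param scenarios list of `no2_scenario` (must include one baseline).
#' @param crfs CRF table, see [default_crfs()].
#' @return List of class `no2_burden_det` with data frames `attributable`
#'   (stratum x disease x source: paf, dalys, economic_loss) and
#'   `reductions` (stratum x disease x control scenario: pif, rdalys,
#'   economic_reduction).
#' @export
estimate_burden <- function(cohort, scenarios = scenario_suite(),
                            crfs = default_crfs()) {
  validate_cohort(cohort)
  crfs <- validate_crfs(crfs)
  strata <- build_strata(cohort)
  ew <- exposure_wide(cohort, strata)
  fac <- scenario_factors(strata, scenarios)
  ib <- baseline_index(scenarios)
  means0 <- cbind(ambient = ew$ambient$mean, cooking = ew$cooking$mean,
                  shs = ew$shs$mean)
  scen_names <- unname(dimnames(fac)[[3]])
  G <- nrow(strata)
  base <- cohort$baseline
  rate_of <- function(d) {
    rows <- base[base$disease == d, ]
    idx <- match(paste(strata$city_id, strata$age_group, strata$sex),
                 paste(rows$city_id, rows$age_group, rows$sex))
    rows$daly_rate_central[idx]
  }

  attributable <- NULL
  reductions <- NULL
  for (d in crfs$disease) {
    cr <- crf_row(crfs, d)
    rate <- rate_of(d)
    rr_by_scen <- vapply(seq_along(scen_names), function(j) {
      fj <- matrix(fac[, , j], nrow = G)
      # summed in fixed source order so the Monte Carlo engine's degenerate
      # limit (all individuals at the mean) reproduces this bitwise
      tot <- means0[, 1] * fj[, 1] + means0[, 2] * fj[, 2] +
        means0[, 3] * fj[, 3]
      relative_risk(tot, cr)
    }, numeric(G))
    if (G == 1L) rr_by_scen <- matrix(rr_by_scen, nrow = 1L)
    rr0bar <- rr_by_scen[, ib]
    paf_tot <- paf(rr0bar)
    shares <- means0 / ifelse(rowSums(means0) == 0, 1, rowSums(means0))
    shares[rowSums(means0) == 0, ] <- 0
    for (src in exposure_sources()) {
      p_s <- shares[, src] * paf_tot
      dl <- dalys(p_s, rate, strata$population)
      attributable <- rbind(attributable, data.frame(
        strata[c("city_id", "province_id", "tier", "age_group", "sex")],
        disease = d, source = src, paf = p_s, dalys = dl,
        economic_loss = monetize(dl, strata$gdp_per_capita)))
    }
    for (j in setdiff(seq_along(scen_names), ib)) {
      pif_j <- pif(rr0bar, rr_by_scen[, j])
      rd <- rdalys(pif_j, rate, strata$population)
      reductions <- rbind(reductions, data.frame(
        strata[c("city_id", "province_id", "tier", "age_group", "sex")],
        disease = d, scenario = scen_names[j], pif = pif_j, rdalys = rd,
        economic_reduction = monetize(rd, strata$gdp_per_capita)))
    }
  }
  rownames(attributable) <- rownames(reductions) <- NULL
  structure(list(attributable = attributable, reductions = reductions),
            class = "no2_burden_det")
}
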