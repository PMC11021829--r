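# Shared fixtures: small exposure sets, hand-built single-stratum cohorts,
# and a deterministic quadrature oracle for the population-average RR.

crf_of <- function(disease, crfs = default_crfs()) {
  crfs[crfs$disease == disease, ]
}

# One stratum's exposure rows.
stratum_exposure <- function(ambient = c(18, 0), cooking = c(12, 0),
                             shs = c(0.3, 0), city_id = "C001") {
  data.frame(city_id = city_id, age_group = "45-59", sex = "male",
             source = c("ambient", "cooking", "shs"),
             mean = c(ambient[1], cooking[1], shs[1]),
             sd = c(ambient[2], cooking[2], shs[2]),
             stringsAsFactors = FALSE)
}

# Minimal hand-built cohort: one city, configurable strata and exposures.
tiny_cohort <- function(ambient_mean = 21, cooking_mean = 8, shs_mean = 0.3,
                        sds = c(0, 0, 0), outdoor = 30, f_exp = 0.7,
                        gdp = 70000, rate = 500, population = 1e6,
                        rate_ui = c(1, 1)) {
  key <- data.frame(city_id = "C001", province_id = "P01", tier = "other",
                    age_group = "45-59", sex = "male",
                    stringsAsFactors = FALSE)
  exposure <- rbind(
    cbind(key, source = "ambient", mean = ambient_mean, sd = sds[1]),
    cbind(key, source = "cooking", mean = cooking_mean, sd = sds[2]),
    cbind(key, source = "shs", mean = shs_mean, sd = sds[3]))
  baseline <- do.call(rbind, lapply(c("LC", "COPD", "DM"), function(d)
    cbind(key, disease = d, daly_rate_central = rate,
          daly_rate_lower = rate * rate_ui[1],
          daly_rate_upper = rate * rate_ui[2], population = population)))
  env <- data.frame(city_id = "C001", province_id = "P01", tier = "other",
                    outdoor_no2 = outdoor, f_exp = f_exp,
                    gdp_per_capita = gdp, stringsAsFactors = FALSE)
  structure(list(environment = env, exposure = exposure,
                 baseline = baseline), class = "no2_cohort")
}

# Collapse a synthetic cohort to degenerate distributions (sd = 0 exposures,
# point baseline-rate intervals).
collapse_cohort <- function(cohort) {
  cohort$exposure$sd <- 0
  cohort$baseline$daly_rate_lower <- cohort$baseline$daly_rate_central
  cohort$baseline$daly_rate_upper <- cohort$baseline$daly_rate_central
  cohort
}

collapsed_crfs <- function() {
  cr <- default_crfs()
  cr$rr0_lower95 <- cr$rr0_central
  cr$rr0_upper95 <- cr$rr0_central
  cr
}

# Deterministic quadrature oracle: E[RR(C)] for a moment-matched lognormal
# exposure, integrating the capped power law below max_c and adding the
# capped tail mass in closed form.
mean_rr_quad <- function(m, s, crf, rr0 = crf$rr0_central) {
  s2 <- log1p((s / m)^2)
  mu <- log(m) - s2 / 2
  sig <- sqrt(s2)
  body <- stats::integrate(function(c)
    exp(log(rr0) * c / crf$delta_c0) * stats::dlnorm(c, mu, sig),
    lower = 0, upper = crf$max_c, rel.tol = 1e-10)$value
  tail <- exp(log(rr0) * crf$max_c / crf$delta_c0) *
    stats::plnorm(crf$max_c, mu, sig, lower.tail = FALSE)
  body + tail
}
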