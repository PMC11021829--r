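# Synthetic cohort generator: city environments, per-stratum source-specific
# NO2 exposure distributions and baseline disease burden, calibrated to
# national summary figures so the full pipeline is runnable and testable
# without external data.

#' Age bands used throughout the package
#'
#' Ten disjoint bands covering all ages (years).
#' @return Character vector of band labels, ordered by age.
#' @export
age_bands <- function() {
  c("0-0.5", "0.5-1", "1-2", "3-6", "7-11", "12-17",
    "18-44", "45-59", "60-80", "80+")
}

#' NO2 exposure sources
#' @return Character vector: ambient, cooking, shs.
#' @export
exposure_sources <- function() c("ambient", "cooking", "shs")

adult_bands <- function() c("18-44", "45-59", "60-80", "80+")

# Default age structure (share of urban population per band) and sex split.
default_age_shares <- function() {
  stats::setNames(c(0.005, 0.005, 0.02, 0.045, 0.055, 0.065,
                    0.40, 0.22, 0.16, 0.025), age_bands())
}

# Baseline DALY rates per 100,000 person-years by age band (rows) and
# disease (columns). Under-18 bands are near zero: LC/COPD/DM are diseases
# of adulthood.
default_rate_table <- function() {
  m <- rbind(
    "0-0.5"  = c(0.3, 0.8, 0.5),
    "0.5-1"  = c(0.3, 0.8, 0.5),
    "1-2"    = c(0.3, 0.8, 0.5),
    "3-6"    = c(0.3, 0.8, 0.5),
    "7-11"   = c(0.3, 0.8, 0.5),
    "12-17"  = c(0.3, 0.8, 0.5),
    "18-44"  = c(90, 60, 160),
    "45-59"  = c(1100, 700, 900),
    "60-80"  = c(3200, 3800, 1900),
    "80+"    = c(4200, 9000, 2600))
  colnames(m) <- c("LC", "COPD", "DM")
  m
}

#' Configuration for the synthetic cohort generator
#'
#' Returns a validated configuration list. All hyperparameters have
#' defaults emulating urban China in 2019: 330 cities across 31 provinces,
#' higher ambient NO2 and larger populations in first-tier and new
#' first-tier cities, cooking exposure elevated 1.5x for adult women, and
#' calibration targets pinning the national population-weighted total
#' exposure (26.7 ug/m3), the indoor-source share (34.5%) and the
#' secondhand-smoke share (1%) of that total.
#'
#' @param n_cities number of cities to generate.
#' @param seed RNG seed; generation is a pure function of (config, seed).
#' @param pw_exposure_total calibration target: national population-weighted
#'   mean of total NO2 exposure (ug/m3).
#' @param indoor_share calibration target: indoor (cooking + SHS) fraction of
#'   the population-weighted total exposure.
#' @param shs_share calibration target: SHS fraction of the total exposure.
#' @param tier1_frac,new_tier1_frac fractions of cities in each tier.
#' @param n_provinces number of provinces cities are assigned to.
#' @param outdoor_mean named vector of tier-specific mean outdoor NO2
#'   (ug/m3) before calibration; `outdoor_cv` its coefficient of variation
#'   across cities.
#' @param outdoor_cv,city_pop_cv,gdp_cv,cooking_city_cv,shs_city_cv
#'   city-level coefficients of variation.
#' @param f_exp_min,f_exp_max range of the province-level exposure factor
#'   (ratio of inhaled outdoor-originated concentration to the outdoor
#'   concentration; below 1 because of indoor surface removal).
#' @param city_pop_mean mean urban population per city; `pop_mult` named
#'   tier multipliers.
#' @param gdp_mean mean GDP per capita (CNY); `gdp_mult` tier multipliers.
#' @param cooking_mean city-level mean cooking NO2 exposure (ug/m3) before
#'   calibration.
#' @param female_cooking_mult multiplier on cooking exposure for women in
#'   adult age bands.
#' @param shs_mean city-level mean SHS NO2 exposure before calibration.
#' @param exposure_cv named per-source within-stratum coefficients of
#'   variation (sd = cv * mean).
#' @param rate_noise_cv lognormal stratum-level noise on baseline DALY rates.
#' @param rate_ui_lower,rate_ui_upper multipliers giving the lower/upper 95%
#'   bounds of baseline DALY rates relative to the central value.
#' @param age_shares named population shares per age band (summing to 1).
#' @param male_share share of males in each city population.
#' @param pop_mult,gdp_mult named tier multipliers (other, new_tier1, tier1).
#' @return A list of class `no2_config`.
#' @export
synthetic_config <- function(n_cities = 330L,
                             seed = 1L,
                             pw_exposure_total = 26.7,
                             indoor_share = 0.345,
                             shs_share = 0.01,
                             tier1_frac = 0.012,
                             new_tier1_frac = 0.045,
                             n_provinces = 31L,
                             outdoor_mean = c(other = 24, new_tier1 = 32,
                                              tier1 = 38),
                             outdoor_cv = 0.35,
                             f_exp_min = 0.55,
                             f_exp_max = 0.85,
                             city_pop_mean = 1.8e6,
                             city_pop_cv = 1.0,
                             pop_mult = c(other = 1, new_tier1 = 3, tier1 = 6),
                             gdp_mean = 70000,
                             gdp_cv = 0.4,
                             gdp_mult = c(other = 1, new_tier1 = 1.4,
                                          tier1 = 1.8),
                             cooking_mean = 8,
                             cooking_city_cv = 0.3,
                             female_cooking_mult = 1.5,
                             shs_mean = 0.5,
                             shs_city_cv = 0.3,
                             exposure_cv = c(ambient = 0.55, cooking = 0.9,
                                             shs = 0.9),
                             rate_noise_cv = 0.15,
                             rate_ui_lower = 0.8,
                             rate_ui_upper = 1.25,
                             age_shares = default_age_shares(),
                             male_share = 0.512) {
  cfg <- as.list(environment())
  class(cfg) <- "no2_config"
  validate_synthetic_config(cfg)
}

validate_synthetic_config <- function(cfg) {
  if (!inherits(cfg, "no2_config")) stop_config("not a synthetic configuration")
  chk_pos <- function(field) {
    v <- cfg[[field]]
    if (!is.numeric(v) || any(!is.finite(v)) || any(v <= 0))
      stop_config("configuration field '%s' must be positive and finite",
                  field)
  }
  if (!is.numeric(cfg$n_cities) || cfg$n_cities < 1)
    stop_config("configuration field 'n_cities' must be >= 1")
  for (f in c("pw_exposure_total", "outdoor_mean", "outdoor_cv",
              "city_pop_mean", "city_pop_cv", "pop_mult", "gdp_mean",
              "gdp_cv", "gdp_mult", "cooking_mean", "cooking_city_cv",
              "female_cooking_mult", "shs_mean", "shs_city_cv",
              "rate_noise_cv", "rate_ui_upper", "rate_ui_lower",
              "male_share", "n_provinces"))
    chk_pos(f)
  if (any(cfg$exposure_cv < 0))
    stop_config("configuration field 'exposure_cv' must be non-negative")
  if (cfg$indoor_share <= 0 || cfg$indoor_share >= 1)
    stop_config("configuration field 'indoor_share' must be in (0, 1)")
  if (cfg$shs_share <= 0 || cfg$shs_share >= cfg$indoor_share)
    stop_config("configuration field 'shs_share' must be in (0, indoor_share)")
  if (cfg$f_exp_min <= 0 || cfg$f_exp_max > 1 ||
        cfg$f_exp_min > cfg$f_exp_max)
    stop_config("configuration fields 'f_exp_min'/'f_exp_max' must satisfy 0 < min <= max <= 1")
  if (cfg$rate_ui_lower > 1 || cfg$rate_ui_upper < 1)
    stop_config("configuration fields 'rate_ui_lower'/'rate_ui_upper' must bracket 1")
  if (abs(sum(cfg$age_shares) - 1) > 1e-8)
    stop_config("configuration field 'age_shares' must sum to 1")
  if (!all(names(cfg$age_shares) == age_bands()))
    stop_config("configuration field 'age_shares' must be named by the ten age bands")
  cfg
}

#' Generate a synthetic urban cohort
#'
#' Draws city environments (outdoor NO2, exposure factor, GDP per capita),
#' per-stratum source-specific exposure distributions (mean/sd, lognormal at
#' the individual level) and baseline DALY rates with populations, for
#' `n_cities` x 10 age bands x 2 sexes strata. After drawing the raw
#' structure, ambient, cooking and SHS levels are rescaled globally so that
#' the national population-weighted total exposure and the indoor/SHS shares
#' equal the configured calibration targets exactly.
#'
#' @param config a `no2_config`, see [synthetic_config()].
#' @return A list of class `no2_cohort` with data frames `environment`
#'   (city_id, province_id, tier, outdoor_no2, f_exp, gdp_per_capita),
#'   `exposure` (stratum key + source + mean + sd) and `baseline`
#'   (stratum key + disease + daly_rate_central/lower/upper + population).
#' @examples
#' cohort <- generate_cohort(synthetic_config(n_cities = 3, seed = 7))
#' nrow(cohort$exposure)  # 3 cities x 20 strata x 3 sources
#' @export
generate_cohort <- function(config = synthetic_config()) {
  cfg <- validate_synthetic_config(config)
  with_seed(cfg$seed, {
    n <- as.integer(cfg$n_cities)
    n_t1 <- round(cfg$tier1_frac * n)
    n_nt1 <- round(cfg$new_tier1_frac * n)
    tier <- rep("other", n)
    if (n_t1 > 0) tier[seq_len(min(n, n_t1))] <- "tier1"
    if (n_nt1 > 0 && n_t1 < n)
      tier[n_t1 + seq_len(min(n - n_t1, n_nt1))] <- "new_tier1"
    city_id <- sprintf("C%03d", seq_len(n))
    province_id <- sprintf("P%02d", 1 + (seq_len(n) - 1) %% cfg$n_provinces)

    f_exp_prov <- stats::runif(cfg$n_provinces, cfg$f_exp_min, cfg$f_exp_max)
    f_exp <- f_exp_prov[1 + (seq_len(n) - 1) %% cfg$n_provinces]

    outdoor <- rlnorm_cv(cfg$outdoor_mean[tier], cfg$outdoor_cv)
    city_pop <- rlnorm_cv(cfg$city_pop_mean * cfg$pop_mult[tier],
                          cfg$city_pop_cv)
    gdp <- rlnorm_cv(cfg$gdp_mean * cfg$gdp_mult[tier], cfg$gdp_cv)
    cook_city <- rlnorm_cv(rep(cfg$cooking_mean, n), cfg$cooking_city_cv)
    shs_city <- rlnorm_cv(rep(cfg$shs_mean, n), cfg$shs_city_cv)

    strata <- expand.grid(city = seq_len(n),
                          age_group = age_bands(),
                          sex = c("male", "female"),
                          KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
    sex_share <- ifelse(strata$sex == "male", cfg$male_share,
                        1 - cfg$male_share)
    population <- round(city_pop[strata$city] *
                          cfg$age_shares[strata$age_group] * sex_share)

    amb_mean <- outdoor[strata$city] * f_exp[strata$city]
    cook_mult <- ifelse(strata$sex == "female" &
                          strata$age_group %in% adult_bands(),
                        cfg$female_cooking_mult, 1)
    cook_mean <- cook_city[strata$city] * cook_mult
    shs_mean <- shs_city[strata$city]

    # Exact calibration: rescale each source so the population-weighted
    # totals hit the configured national targets.
    w <- population / sum(population)
    tgt_amb <- cfg$pw_exposure_total * (1 - cfg$indoor_share)
    tgt_shs <- cfg$pw_exposure_total * cfg$shs_share
    tgt_cook <- cfg$pw_exposure_total * (cfg$indoor_share - cfg$shs_share)
    s_amb <- tgt_amb / sum(w * amb_mean)
    s_cook <- tgt_cook / sum(w * cook_mean)
    s_shs <- tgt_shs / sum(w * shs_mean)
    outdoor <- outdoor * s_amb
    amb_mean <- outdoor[strata$city] * f_exp[strata$city]
    cook_mean <- cook_mean * s_cook
    shs_mean <- shs_mean * s_shs

    key <- data.frame(city_id = city_id[strata$city],
                      province_id = province_id[strata$city],
                      tier = tier[strata$city],
                      age_group = strata$age_group,
                      sex = strata$sex,
                      stringsAsFactors = FALSE)
    cv <- cfg$exposure_cv
    exposure <- rbind(
      cbind(key, source = "ambient", mean = amb_mean,
            sd = cv[["ambient"]] * amb_mean),
      cbind(key, source = "cooking", mean = cook_mean,
            sd = cv[["cooking"]] * cook_mean),
      cbind(key, source = "shs", mean = shs_mean,
            sd = cv[["shs"]] * shs_mean))
    rownames(exposure) <- NULL

    rates <- default_rate_table()
    sex_mult <- rbind(male = c(LC = 1.35, COPD = 1.30, DM = 1.05),
                      female = c(LC = 0.65, COPD = 0.70, DM = 0.95))
    base_parts <- lapply(colnames(rates), function(d) {
      central <- rates[strata$age_group, d] * sex_mult[strata$sex, d]
      central <- rlnorm_cv(central, cfg$rate_noise_cv)
      cbind(key, disease = d,
            daly_rate_central = central,
            daly_rate_lower = central * cfg$rate_ui_lower,
            daly_rate_upper = central * cfg$rate_ui_upper,
            population = population)
    })
    baseline <- do.call(rbind, base_parts)
    rownames(baseline) <- NULL

    environment <- data.frame(city_id = city_id, province_id = province_id,
                              tier = tier, outdoor_no2 = outdoor,
                              f_exp = f_exp, gdp_per_capita = gdp,
                              stringsAsFactors = FALSE)
    out <- list(environment = environment, exposure = exposure,
                baseline = baseline)
    class(out) <- "no2_cohort"
    out
  })
}

#' Validate that cohort tables are mutually consistent
#'
#' Every stratum must have one exposure row per source, one baseline row per
#' disease, and a city environment row; populations must agree across
#' diseases within a stratum.
#'
#' @param cohort a `no2_cohort` list (environment, exposure, baseline).
#' @return The cohort, invisibly, or an input error listing missing keys.
#' @export
validate_cohort <- function(cohort) {
  for (tab in c("environment", "exposure", "baseline"))
    if (is.null(cohort[[tab]])) stop_input("cohort is missing the %s table", tab)
  env <- cohort$environment
  exp_tab <- cohort$exposure
  base <- cohort$baseline
  skey <- function(df) paste(df$city_id, df$age_group, df$sex, sep = "|")
  strata_keys <- sort(unique(c(skey(exp_tab), skey(base))))
  for (src in exposure_sources()) {
    have <- skey(exp_tab[exp_tab$source == src, , drop = FALSE])
    miss <- setdiff(strata_keys, have)
    if (length(miss))
      stop_input("exposure table is missing source '%s' for strata: %s", src,
                 paste(utils::head(miss, 5), collapse = ", "))
  }
  for (d in unique(base$disease)) {
    have <- skey(base[base$disease == d, , drop = FALSE])
    miss <- setdiff(strata_keys, have)
    if (length(miss))
      stop_input("baseline table is missing disease '%s' for strata: %s", d,
                 paste(utils::head(miss, 5), collapse = ", "))
  }
  miss_env <- setdiff(unique(c(exp_tab$city_id, base$city_id)), env$city_id)
  if (length(miss_env))
    stop_input("environment table is missing cities: %s",
               paste(utils::head(miss_env, 5), collapse = ", "))
  if (any(exp_tab$mean < 0) || any(exp_tab$sd < 0))
    stop_input("exposure means and sds must be non-negative")
  if (any(base$population < 0))
    stop_input("populations must be non-negative")
  invisible(cohort)
}

#' Write cohort tables as CSV
#'
#' Writes `environment.csv`, `exposure.csv` and `baseline.csv` (UTF-8,
#' comma-separated, header row, '.' decimal) into `dir`.
#'
#' @param cohort a `no2_cohort`.
#' @param dir output directory (created if absent).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  for (tab in c("environment", "exposure", "baseline"))
    utils::write.csv(cohort[[tab]], file.path(dir, paste0(tab, ".csv")),
                     row.names = FALSE)
  invisible(dir)
}

#' Read cohort tables from CSV
#'
#' @param dir directory holding `environment.csv`, `exposure.csv`,
#'   `baseline.csv` as written by [write_cohort()].
#' @return A validated `no2_cohort`.
#' @export
read_cohort <- function(dir) {
  paths <- file.path(dir, c("environment.csv", "exposure.csv", "baseline.csv"))
  missing <- paths[!file.exists(paths)]
  if (length(missing))
    stop_input("missing input files: %s", paste(missing, collapse = ", "))
  out <- list(environment = utils::read.csv(paths[1]),
              exposure = utils::read.csv(paths[2]),
              baseline = utils::read.csv(paths[3]))
  class(out) <- "no2_cohort"
  validate_cohort(out)
  out
}
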