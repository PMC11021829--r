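# Counterfactual exposure scenarios: the 2019 baseline (S0), indoor source
# removals (S1 smoking ban, S2 electric cooking) and ambient caps at the WHO
# interim targets and air quality guideline (S3-S6).

#' Define a counterfactual exposure scenario
#'
#' @param name scenario label (e.g. "S0", "S2").
#' @param kind one of `baseline`, `remove_source`, `ambient_cap`.
#' @param removed_source for `remove_source`: the source zeroed out.
#' @param target for `ambient_cap`: target annual outdoor NO2 (ug/m3).
#' @return A list of class `no2_scenario`.
#' @export
scenario_spec <- function(name,
                          kind = c("baseline", "remove_source", "ambient_cap"),
                          removed_source = NULL, target = NULL) {
  kind <- match.arg(kind)
  if (kind == "remove_source") {
    if (is.null(removed_source) ||
          !removed_source %in% exposure_sources())
      stop_config("scenario '%s': removed_source must be one of %s", name,
                  paste(exposure_sources(), collapse = ", "))
    if (!is.null(target))
      stop_config("scenario '%s': target must not be set for remove_source",
                  name)
  } else if (kind == "ambient_cap") {
    if (is.null(target) || !is.numeric(target) || target <= 0)
      stop_config("scenario '%s': ambient_cap requires a positive target",
                  name)
    if (!is.null(removed_source))
      stop_config("scenario '%s': removed_source must not be set for ambient_cap",
                  name)
  } else if (!is.null(removed_source) || !is.null(target)) {
    stop_config("scenario '%s': baseline takes no removed_source or target",
                name)
  }
  structure(list(name = name, kind = kind,
                 removed_source = removed_source, target = target),
            class = "no2_scenario")
}

#' The shipped scenario suite S0-S6
#'
#' S0: 2019 baseline. S1: indoor smoking ban (SHS exposure set to 0).
#' S2: electric instead of gas cooking (cooking exposure set to 0).
#' S3-S6: outdoor NO2 capped at the WHO interim targets 1-3 and the air
#' quality guideline (40, 30, 20, 10 ug/m3).
#'
#' @return List of seven `no2_scenario` objects named S0-S6.
#' @export
scenario_suite <- function() {
  specs <- list(
    scenario_spec("S0", "baseline"),
    scenario_spec("S1", "remove_source", removed_source = "shs"),
    scenario_spec("S2", "remove_source", removed_source = "cooking"),
    scenario_spec("S3", "ambient_cap", target = 40),
    scenario_spec("S4", "ambient_cap", target = 30),
    scenario_spec("S5", "ambient_cap", target = 20),
    scenario_spec("S6", "ambient_cap", target = 10))
  stats::setNames(specs, vapply(specs, `[[`, "", "name"))
}

#' Apply a scenario to source-specific exposure distributions
#'
#' Transforms per-stratum exposure distributions (mean, sd per source) under
#' a counterfactual. `remove_source` zeroes the named source. `ambient_cap`
#' leaves cities whose monitored outdoor concentration is at or below the
#' target unchanged; otherwise it rescales the ambient distribution by
#' `target / outdoor_no2`, so the new ambient mean equals
#' `target * f_exp` while within-population variability is preserved
#' (`cap_mode = "rescale"`, default). `cap_mode = "literal"` instead sets the
#' ambient mean to `target * f_exp` with sd 0 for capped cities.
#'
#' @param exposure data frame of exposure rows (stratum key columns plus
#'   `source`, `mean`, `sd`); may span one or many strata.
#' @param env city environment: for a single stratum, a one-row data frame
#'   or list with `outdoor_no2` and `f_exp`; for multi-city tables, the
#'   environment table keyed by `city_id`.
#' @param scenario a `no2_scenario`.
#' @param cap_mode "rescale" or "literal" (see Details).
#' @return The transformed exposure data frame, same shape as the input.
#' @export
apply_scenario <- function(exposure, env, scenario,
                           cap_mode = c("rescale", "literal")) {
  cap_mode <- match.arg(cap_mode)
  if (!inherits(scenario, "no2_scenario"))
    stop_input("scenario must be created with scenario_spec()")
  miss <- setdiff(exposure_sources(), unique(exposure$source))
  if (length(miss))
    stop_input("exposure set is missing source rows: %s",
               paste(miss, collapse = ", "))
  if (scenario$kind == "baseline") return(exposure)
  out <- exposure
  if (scenario$kind == "remove_source") {
    hit <- out$source == scenario$removed_source
    out$mean[hit] <- 0
    out$sd[hit] <- 0
    return(out)
  }
  # ambient_cap
  if (scenario$target <= 0) stop_config("ambient cap target must be positive")
  if (!is.null(exposure$city_id) && !is.null(env$city_id)) {
    idx <- match(out$city_id, env$city_id)
    if (anyNA(idx))
      stop_input("environment table is missing cities: %s",
                 paste(unique(out$city_id[is.na(idx)]), collapse = ", "))
    outdoor <- env$outdoor_no2[idx]
    f_exp <- env$f_exp[idx]
  } else {
    outdoor <- rep(env$outdoor_no2[[1]], nrow(out))
    f_exp <- rep(env$f_exp[[1]], nrow(out))
  }
  amb <- out$source == "ambient"
  capped <- amb & outdoor > scenario$target
  if (cap_mode == "rescale") {
    ratio <- scenario$target / outdoor
    out$mean[capped] <- out$mean[capped] * ratio[capped]
    out$sd[capped] <- out$sd[capped] * ratio[capped]
  } else {
    out$mean[capped] <- scenario$target * f_exp[capped]
    out$sd[capped] <- 0
  }
  out
}

#' Draw individual-level exposures for one stratum
#'
#' Samples `n` individuals from the moment-matched lognormal distribution of
#' each source (sd 0 collapses to the mean; mean 0 gives zeros) and forms
#' per-individual totals as the sum over sources. Draws come from the
#' current RNG state; seed with `set.seed()` for reproducibility.
#'
#' @param exposure exposure rows for a single stratum (three sources).
#' @param n number of individuals (>= 1).
#' @return A list of class `no2_exposure_sample` with `values` (n x 3
#'   matrix, columns ambient/cooking/shs) and `total` (row sums).
#' @export
sample_individuals <- function(exposure, n) {
  if (!is.numeric(n) || n < 1) stop_input("n must be a positive count")
  n <- as.integer(n)
  miss <- setdiff(exposure_sources(), exposure$source)
  if (length(miss))
    stop_input("exposure set is missing source rows: %s",
               paste(miss, collapse = ", "))
  if (any(exposure$mean < 0) || any(exposure$sd < 0))
    stop_input("exposure means and sds must be non-negative")
  values <- vapply(exposure_sources(), function(src) {
    row <- exposure[exposure$source == src, ][1, ]
    rlnorm_mm(n, row$mean, row$sd)
  }, numeric(n))
  if (n == 1L) values <- matrix(values, nrow = 1,
                                dimnames = list(NULL, exposure_sources()))
  structure(list(values = values, total = rowSums(values)),
            class = "no2_exposure_sample")
}
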