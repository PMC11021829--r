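#' Concentration-response functions for NO2
#'
#' A concentration-response function (CRF) links annual NO2 exposure
#' concentration to the relative risk of a disease through a capped power
#' law: \eqn{RR = RR_0^{\min(C, MaxC)/\Delta C_0}}. `RR0` is the relative
#' risk per `delta_c0` (10 ug/m3) increase; `max_c` is the highest exposure
#' level supported by the underlying epidemiology, beyond which the RR is
#' held constant as a conservative choice.
#'
#' @param disease character vector of disease codes.
#' @param rr0_central,rr0_lower95,rr0_upper95 relative risk per `delta_c0`
#'   increase (central estimate and 95% CI bounds).
#' @param delta_c0 concentration increment (ug/m3) the RR0 refers to.
#' @param max_c cap concentration (ug/m3).
#' @return A data frame of class `no2_crf` with one row per disease.
#' @export
crf_table <- function(disease, rr0_central, rr0_lower95, rr0_upper95,
                      delta_c0 = 10, max_c) {
  out <- data.frame(disease = as.character(disease),
                    rr0_central = rr0_central,
                    rr0_lower95 = rr0_lower95,
                    rr0_upper95 = rr0_upper95,
                    delta_c0 = delta_c0,
                    max_c = max_c,
                    stringsAsFactors = FALSE)
  validate_crfs(out)
}

validate_crfs <- function(crfs) {
  need <- c("disease", "rr0_central", "rr0_lower95", "rr0_upper95",
            "delta_c0", "max_c")
  miss <- setdiff(need, names(crfs))
  if (length(miss))
    stop_input("CRF table is missing columns: %s", paste(miss, collapse = ", "))
  if (anyDuplicated(crfs$disease))
    stop_input("CRF table has duplicated disease entries")
  bad <- !(crfs$rr0_lower95 <= crfs$rr0_central &
             crfs$rr0_central <= crfs$rr0_upper95)
  if (any(bad))
    stop_input("CRF for %s violates lower95 <= central <= upper95",
               paste(crfs$disease[bad], collapse = ", "))
  if (any(crfs$rr0_lower95 < 1))
    stop_input("CRF relative risks must be >= 1 (protective exposures are out of scope)")
  if (any(crfs$delta_c0 <= 0)) stop_input("CRF delta_c0 must be positive")
  if (any(crfs$max_c <= 0)) stop_input("CRF max_c must be positive")
  class(crfs) <- c("no2_crf", "data.frame")
  crfs
}

#' Default NO2 concentration-response functions
#'
#' Meta-analytic relative risks per 10 ug/m3 NO2 for lung cancer (LC),
#' chronic obstructive pulmonary disease (COPD) and diabetes mellitus (DM),
#' with the maximal concentrations observed in the source epidemiology used
#' as RR caps.
#'
#' @return A `no2_crf` data frame with rows LC, COPD, DM.
#' @examples
#' default_crfs()
#' @export
default_crfs <- function() {
  crf_table(disease = c("LC", "COPD", "DM"),
            rr0_central = c(1.055, 1.016, 1.019),
            rr0_lower95 = c(1.010, 1.012, 1.009),
            rr0_upper95 = c(1.101, 1.020, 1.029),
            delta_c0 = 10,
            max_c = c(54.0, 60.7, 44.0))
}
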