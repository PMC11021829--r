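# Two-stage Monte Carlo: stage 1 draws individual exposures to capture
# intra-population variability; stage 2 draws concentration-response and
# baseline-rate parameters to capture uncertainty. Outputs per-cell
# iteration vectors of DALYs and reductions.

#' Configuration for the two-stage Monte Carlo
#'
#' Defaults mirror the full analysis: 2,000 variability iterations x 1,000
#' uncertainty iterations (2,000,000 in total). Exposure samples are drawn
#' once per stratum and reused across scenarios and uncertainty iterations
#' (common random numbers), which keeps scenario contrasts low-variance;
#' `redraw_per_iteration = TRUE` redraws them in every uncertainty
#' iteration instead. RR0 draws are shared across strata within an
#' iteration (systematic CRF uncertainty); baseline-rate draws are
#' independent across strata by default.
#'
#' @param n_variability individuals drawn per stratum (stage 1).
#' @param n_uncertainty parameter-uncertainty iterations (stage 2).
#' @param seed RNG seed; the run is a pure function of (inputs, config).
#' @param rr0_distribution family for RR0 draws: lognormal fitted to the
#'   95% CI on the log scale.
#' @param rate_distribution family for baseline-rate draws: lognormal
#'   fitted to the 95% UI, or a normal truncated at zero.
#' @param rr0_shared share one RR0 draw per disease across all strata
#'   within an iteration.
#' @param rate_shared share the rate-draw quantile across strata within an
#'   iteration (fully correlated baseline-rate uncertainty).
#' @param redraw_per_iteration redraw stage-1 exposures in each stage-2
#'   iteration instead of reusing a common sample.
#' @param cap_mode passed to the scenario transform, see [apply_scenario()].
#' @return A list of class `no2_mc_config`.
#' @export
uncertainty_config <- function(n_variability = 2000L,
                               n_uncertainty = 1000L,
                               seed = 1L,
                               rr0_distribution = "lognormal_from_ci",
                               rate_distribution = c("lognormal_from_ui",
                                                     "normal_truncated"),
                               rr0_shared = TRUE,
                               rate_shared = FALSE,
                               redraw_per_iteration = FALSE,
                               cap_mode = c("rescale", "literal")) {
  rate_distribution <- match.arg(rate_distribution)
  cap_mode <- match.arg(cap_mode)
  if (!identical(rr0_distribution, "lognormal_from_ci"))
    stop_config("unknown rr0_distribution '%s'", rr0_distribution)
  if (n_variability < 1 || n_uncertainty < 1)
    stop_config("iteration counts must be >= 1")
  structure(list(n_variability = as.integer(n_variability),
                 n_uncertainty = as.integer(n_uncertainty),
                 seed = as.integer(seed),
                 rr0_distribution = rr0_distribution,
                 rate_distribution = rate_distribution,
                 rr0_shared = isTRUE(rr0_shared),
                 rate_shared = isTRUE(rate_shared),
                 redraw_per_iteration = isTRUE(redraw_per_iteration),
                 cap_mode = cap_mode),
            class = "no2_mc_config")
}

#' Draw RR0 values from a CRF's uncertainty distribution
#'
#' Lognormal with median at the central RR0 and log-scale sd implied by the
#' 95% CI: `sdlog = (ln upper - ln lower) / (2 * 1.959964)`. A degenerate
#' CI (upper = lower) returns the central value exactly. Draws are floored
#' at 1: the fitted lognormal places a small tail mass below 1 even when
#' the CI lies entirely above it, and protective effects are out of scope,
#' so such draws are treated as no effect. This keeps attributable
#' fractions in [0, 1) and burdens non-negative in every iteration.
#'
#' @param crf a single CRF row or table plus `disease`.
#' @param n number of draws.
#' @param disease disease code when `crf` is a multi-row table.
#' @return Numeric vector of positive RR0 draws.
#' @export
sample_rr0 <- function(crf, n = 1L, disease = NULL) {
  cr <- crf_row(crf, disease)
  if (cr$rr0_upper95 == cr$rr0_lower95) return(rep(cr$rr0_central, n))
  pmax(qlnorm_ui(stats::runif(n), cr$rr0_central, cr$rr0_lower95,
                 cr$rr0_upper95), 1)
}

# Baseline-rate draws through a common-quantile mapping so that "shared"
# correlation across strata is a matter of reusing the same uniform.
rate_quantile <- function(p, central, lower, upper, distribution) {
  switch(distribution,
         lognormal_from_ui = qlnorm_ui(p, central, lower, upper),
         normal_truncated = qtnorm_ui(p, central, lower, upper),
         stop_config("unknown rate_distribution '%s'", distribution))
}

#' Run the two-stage Monte Carlo burden estimation
#'
#' For each stratum, draws `n_variability` individual exposures per source
#' under the baseline scenario; counterfactuals transform that common
#' sample (source removal zeroes a column, ambient caps rescale it), so per
#' iteration the counterfactual exposure of every individual is at most
#' their baseline exposure. For each of `n_uncertainty` iterations, RR0 per
#' disease and baseline DALY rates are drawn, population-average RRs
#' computed (cap applied per individual before averaging), and PAF/PIF,
#' DALYs/reductions evaluated per cell.
#'
#' @param cohort a validated `no2_cohort`.
#' @param scenarios list of `no2_scenario` including one baseline.
#' @param crfs CRF table.
#' @param config an `no2_mc_config`, see [uncertainty_config()].
#' @return List of class `no2_mc` with: `strata` (with population and GDP),
#'   `diseases`, `sources`, `scenario_names`, `control_names`, `dalys`
#'   (array strata x disease x source x iteration), `rdalys` (strata x
#'   disease x control scenario x iteration), `c_bar` (strata x source x
#'   scenario mean concentrations of the common sample) and `config`.
#' @export
run_two_stage <- function(cohort, scenarios = scenario_suite(),
                          crfs = default_crfs(),
                          config = uncertainty_config()) {
  validate_cohort(cohort)
  crfs <- validate_crfs(crfs)
  if (!inherits(config, "no2_mc_config"))
    stop_input("config must be created with uncertainty_config()")
  if (config$n_variability < 50 || config$n_uncertainty < 50)
    warning("small iteration counts (< 50) may give unstable summaries",
            call. = FALSE)
  strata <- build_strata(cohort)
  ew <- exposure_wide(cohort, strata)
  fac <- scenario_factors(strata, scenarios)
  ib <- baseline_index(scenarios)
  scen_names <- dimnames(fac)[[3]]
  ctrl_idx <- setdiff(seq_along(scen_names), ib)
  G <- nrow(strata)
  D <- nrow(crfs)
  S <- length(scen_names)
  nv <- config$n_variability
  nu <- config$n_uncertainty
  srcs <- exposure_sources()
  diseases <- crfs$disease

  base <- cohort$baseline
  sk <- paste(strata$city_id, strata$age_group, strata$sex)
  rate_cols <- lapply(diseases, function(d) {
    rows <- base[base$disease == d, ]
    idx <- match(sk, paste(rows$city_id, rows$age_group, rows$sex))
    list(central = rows$daly_rate_central[idx],
         lower = rows$daly_rate_lower[idx],
         upper = rows$daly_rate_upper[idx])
  })
  names(rate_cols) <- diseases

  with_seed(config$seed, {
    # Stage-2 parameter draws first, in a fixed order.
    if (config$rr0_shared) {
      log_rr0 <- matrix(0, D, nu, dimnames = list(diseases, NULL))
      for (d in seq_len(D)) log_rr0[d, ] <- log(sample_rr0(crfs[d, ], nu))
    } else {
      log_rr0 <- array(0, c(G, D, nu))
      for (d in seq_len(D))
        log_rr0[, d, ] <- log(sample_rr0(crfs[d, ], G * nu))
    }
    rate_draws <- array(0, c(G, D, nu))
    for (d in seq_len(D)) {
      rc <- rate_cols[[d]]
      u <- if (config$rate_shared) {
        matrix(stats::runif(nu), G, nu, byrow = TRUE)
      } else {
        matrix(stats::runif(G * nu), G, nu)
      }
      for (g in seq_len(G))
        rate_draws[g, d, ] <- rate_quantile(u[g, ], rc$central[g],
                                            rc$lower[g], rc$upper[g],
                                            config$rate_distribution)
    }

    dal <- array(0, c(G, D, 3L, nu),
                 dimnames = list(NULL, diseases, srcs, NULL))
    rdal <- array(0, c(G, D, length(ctrl_idx), nu),
                  dimnames = list(NULL, diseases, scen_names[ctrl_idx], NULL))
    c_bar <- array(0, c(G, 3L, S),
                   dimnames = list(NULL, srcs, scen_names))
    scen_grp <- rep(seq_len(S), each = nv)

    for (g in seq_len(G)) {
      n_draw <- if (config$redraw_per_iteration) nv * nu else nv
      X <- cbind(rlnorm_mm(n_draw, ew$ambient$mean[g], ew$ambient$sd[g]),
                 rlnorm_mm(n_draw, ew$cooking$mean[g], ew$cooking$sd[g]),
                 rlnorm_mm(n_draw, ew$shs$mean[g], ew$shs$sd[g]))
      cb0 <- colMeans(X)
      fg <- matrix(fac[g, , ], nrow = 3L)            # 3 x S
      c_bar[g, , ] <- cb0 * fg
      Tm <- outer(X[, 1], fg[1, ]) + outer(X[, 2], fg[2, ]) +
        outer(X[, 3], fg[3, ])                       # draws x S totals
      shares <- if (sum(cb0) > 0) cb0 / sum(cb0) else c(0, 0, 0)
      for (d in seq_len(D)) {
        e <- pmin(Tm, crfs$max_c[d]) / crfs$delta_c0[d]
        B <- if (config$rr0_shared) log_rr0[d, ] else log_rr0[g, d, ]
        if (!config$redraw_per_iteration) {
          M <- exp(outer(as.vector(e), B))           # (nv*S) x nu
          rrb <- rowsum(M, scen_grp, reorder = FALSE) / nv   # S x nu
        } else {
          # e has nv*nu rows; iteration i uses rows (i-1)*nv + 1:nv with B[i]
          e3 <- array(e, c(nv, nu, S))
          M <- exp(e3 * rep(B, each = nv))           # broadcast over draws
          rrb <- t(apply(M, c(2, 3), mean))          # S x nu
        }
        rr0b <- rrb[ib, ]
        pafv <- (rr0b - 1) / rr0b
        rate5 <- rate_draws[g, d, ] / 1e5
        N <- strata$population[g]
        for (s in 1:3) dal[g, d, s, ] <- shares[s] * pafv * rate5 * N
        for (k in seq_along(ctrl_idx))
          rdal[g, d, k, ] <- (rr0b - rrb[ctrl_idx[k], ]) / rr0b * rate5 * N
      }
    }
    structure(list(strata = strata, diseases = diseases, sources = srcs,
                   scenario_names = scen_names,
                   control_names = scen_names[ctrl_idx],
                   dalys = dal, rdalys = rdal, c_bar = c_bar,
                   config = config),
              class = "no2_mc")
  })
}

#' Summarize iteration vectors as mean and 95% uncertainty interval
#'
#' Arithmetic mean and empirical 2.5th/97.5th percentiles (linear
#' interpolation on order statistics). A vector of length 1 returns the
#' mean with an `undefined_interval` attribute instead of percentiles.
#'
#' @param x numeric vector of Monte Carlo iterates.
#' @return Named vector `c(mean, p2.5, p97.5)`.
#' @export
summarize_draws <- function(x) {
  if (length(x) < 2) {
    out <- c(mean = mean(x), p2.5 = NA_real_, p97.5 = NA_real_)
    attr(out, "undefined_interval") <- TRUE
    return(out)
  }
  q <- ui_quantiles(x)
  c(mean = mean(x), p2.5 = q[1], p97.5 = q[2])
}
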