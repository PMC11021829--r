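# Internal helpers: classed conditions, seeded evaluation, moment-matched
# lognormal draws shared by the generator, the scenario sampler and the
# Monte Carlo engine.

stop_config <- function(fmt, ...) {
  stop(errorCondition(sprintf(fmt, ...),
                      class = c("no2_config_error", "no2_error")))
}

stop_input <- function(fmt, ...) {
  stop(errorCondition(sprintf(fmt, ...),
                      class = c("no2_input_error", "no2_error")))
}

stop_query <- function(fmt, ...) {
  stop(errorCondition(sprintf(fmt, ...),
                      class = c("no2_query_error", "no2_error")))
}

# Evaluate `code` under a fixed RNG seed, restoring the caller's RNG state
# afterwards, so generation is a pure function of (config, seed).
with_seed <- function(seed, code) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  code
}

# Lognormal draws parameterized by arithmetic mean and sd (moment matching).
# Degenerate cases: mean 0 -> all zeros; sd 0 -> all draws equal the mean
# (returned exactly, not through exp(log(.))).
rlnorm_mm <- function(n, mean, sd) {
  if (length(mean) == 1L && length(sd) == 1L) {
    if (mean == 0) return(rep(0, n))
    if (sd == 0) return(rep(mean, n))
    s2 <- log1p((sd / mean)^2)
    return(stats::rlnorm(n, meanlog = log(mean) - s2 / 2, sdlog = sqrt(s2)))
  }
  mean <- rep_len(mean, n)
  sd <- rep_len(sd, n)
  out <- numeric(n)
  pos <- mean > 0 & sd > 0
  out[mean > 0 & sd == 0] <- mean[mean > 0 & sd == 0]
  if (any(pos)) {
    s2 <- log1p((sd[pos] / mean[pos])^2)
    out[pos] <- stats::rlnorm(sum(pos), log(mean[pos]) - s2 / 2, sqrt(s2))
  }
  out
}

# Vectorized lognormal with mean vector and a common coefficient of variation.
rlnorm_cv <- function(mean, cv) {
  if (cv == 0) return(mean)
  s2 <- log1p(cv^2)
  mean * stats::rlnorm(length(mean), -s2 / 2, sqrt(s2))
}

# Lognormal quantile parameterized by a median and a 95% interval
# (lower, upper) on the original scale: sdlog from the interval width on the
# log scale. Degenerate interval -> the central value exactly.
qlnorm_ui <- function(p, central, lower, upper) {
  sdlog <- (log(upper) - log(lower)) / (2 * stats::qnorm(0.975))
  if (length(central) == 1L && (upper == lower || central == 0))
    return(rep(central, length(p)))
  out <- exp(log(central) + sdlog * stats::qnorm(p))
  deg <- rep_len(upper == lower | central == 0, length(out))
  out[deg] <- rep_len(central, length(out))[deg]
  out
}

# Truncated-normal (at zero) quantile with mean `central` and sd implied by a
# symmetric 95% interval.
qtnorm_ui <- function(p, central, lower, upper) {
  s <- (upper - lower) / (2 * stats::qnorm(0.975))
  if (all(s == 0)) return(rep_len(central, length(p)))
  p0 <- stats::pnorm(0, mean = central, sd = s)
  out <- stats::qnorm(p0 + p * (1 - p0), mean = central, sd = s)
  deg <- rep_len(s == 0, length(out))
  out[deg] <- rep_len(central, length(out))[deg]
  pmax(out, 0)
}

# Empirical 2.5th/97.5th percentiles with linear interpolation on order
# statistics (quantile type 7).
ui_quantiles <- function(x) {
  stats::quantile(x, probs = c(0.025, 0.975), type = 7, names = FALSE)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
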