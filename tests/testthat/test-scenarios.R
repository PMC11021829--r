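test_that("the shipped suite has seven scenarios with the WHO targets", {
  suite <- scenario_suite()
  expect_named(suite, paste0("S", 0:6))
  expect_equal(suite$S0$kind, "baseline")
  expect_equal(suite$S1$removed_source, "shs")
  expect_equal(suite$S2$removed_source, "cooking")
  expect_equal(vapply(suite[4:7], `[[`, 0, "target"),
               c(S3 = 40, S4 = 30, S5 = 20, S6 = 10))
})

test_that("malformed scenario specs are rejected", {
  expect_error(scenario_spec("X", "ambient_cap", target = -5),
               class = "no2_config_error")
  expect_error(scenario_spec("X", "remove_source", removed_source = "radon"),
               class = "no2_config_error")
  expect_error(scenario_spec("X", "baseline", target = 10),
               class = "no2_config_error")
})

test_that("source removal zeroes one source and leaves the others", {
  ex <- stratum_exposure(ambient = c(18, 2), cooking = c(12, 3),
                         shs = c(0.3, 0.1))
  env <- list(outdoor_no2 = 25, f_exp = 0.72)
  out <- apply_scenario(ex, env, scenario_spec("S2", "remove_source",
                                               removed_source = "cooking"))
  expect_equal(out$mean, c(18, 0, 0.3))
  expect_equal(out$sd, c(2, 0, 0.1))
})

test_that("ambient caps rescale only cities above the target", {
  s3 <- scenario_spec("S3", "ambient_cap", target = 40)
  s4 <- scenario_spec("S4", "ambient_cap", target = 30)
  ex <- stratum_exposure(ambient = c(35, 10), cooking = c(8, 2),
                         shs = c(0.3, 0.1))
  # outdoor at or below the target: unchanged (ties take the unchanged branch)
  expect_equal(apply_scenario(ex, list(outdoor_no2 = 35, f_exp = 0.7), s3),
               ex)
  expect_equal(apply_scenario(ex, list(outdoor_no2 = 40, f_exp = 0.7), s3),
               ex)
  # outdoor 50, f_exp 0.7, ambient mean 35 -> capped to 30 * 0.7 = 21
  ex2 <- stratum_exposure(ambient = c(35, 10), cooking = c(8, 2),
                          shs = c(0.3, 0.1))
  out <- apply_scenario(ex2, list(outdoor_no2 = 50, f_exp = 0.7), s4)
  expect_equal(out$mean[out$source == "ambient"], 21)
  expect_equal(out$sd[out$source == "ambient"], 10 * 30 / 50)
  expect_equal(out$mean[out$source != "ambient"], c(8, 0.3))
  # literal mode collapses the capped ambient distribution to a point
  lit <- apply_scenario(ex2, list(outdoor_no2 = 50, f_exp = 0.7), s4,
                        cap_mode = "literal")
  expect_equal(lit$mean[lit$source == "ambient"], 21)
  expect_equal(lit$sd[lit$source == "ambient"], 0)
})

test_that("scenario application is identity for S0, monotone in the target, and commutes with restriction", {
  co <- generate_cohort(synthetic_config(n_cities = 6, seed = 13))
  suite <- scenario_suite()
  expect_identical(apply_scenario(co$exposure, co$environment, suite$S0),
                   co$exposure)
  capped <- lapply(suite[4:7], function(s)
    apply_scenario(co$exposure, co$environment, s))
  amb <- co$exposure$source == "ambient"
  # smaller target => no larger post-cap ambient mean, stratum-wise
  expect_true(all(capped$S6$mean[amb] <= capped$S5$mean[amb]))
  expect_true(all(capped$S5$mean[amb] <= capped$S4$mean[amb]))
  expect_true(all(capped$S4$mean[amb] <= capped$S3$mean[amb]))
  expect_true(all(capped$S3$mean[amb] <= co$exposure$mean[amb]))
  # capped cities land exactly on target * f_exp
  env <- co$environment
  idx <- match(co$exposure$city_id, env$city_id)
  hit <- amb & env$outdoor_no2[idx] > 20
  expect_equal(capped$S5$mean[hit],
               20 * env$f_exp[idx][hit])
  # restriction to a subset commutes with application
  sub <- co$exposure$city_id == env$city_id[1]
  expect_equal(apply_scenario(co$exposure[sub, ], env, suite$S5),
               capped$S5[sub, ])
})

test_that("missing sources and bad targets are input errors", {
  ex <- stratum_exposure()[-2, ]
  expect_error(apply_scenario(ex, list(outdoor_no2 = 25, f_exp = 0.7),
                              scenario_spec("S0", "baseline")),
               "missing source", class = "no2_input_error")
  expect_error(sample_individuals(stratum_exposure(), 0),
               class = "no2_input_error")
})

test_that("individual sampling matches the moment-matched lognormal", {
  # degenerate distributions collapse to the mean
  ex <- stratum_exposure(ambient = c(20, 0), cooking = c(10, 0),
                         shs = c(0, 0))
  s <- sample_individuals(ex, 5)
  expect_equal(s$total, rep(30, 5))
  expect_equal(s$values[, "shs"], rep(0, 5))
  ex0 <- stratum_exposure(ambient = c(0, 0), cooking = c(0, 0), shs = c(0, 0))
  expect_equal(sample_individuals(ex0, 4)$total, rep(0, 4))
  # totals are row sums exactly
  set.seed(42)
  ex2 <- stratum_exposure(ambient = c(20, 8), cooking = c(9, 5),
                          shs = c(0.3, 0.2))
  s2 <- sample_individuals(ex2, 1000)
  expect_identical(s2$total, rowSums(s2$values))
  expect_true(all(s2$values >= 0))
  # moment recovery at large n
  set.seed(7)
  big <- sample_individuals(stratum_exposure(ambient = c(20, 8),
                                             cooking = c(0, 0),
                                             shs = c(0, 0)), 2e5)
  expect_equal(mean(big$values[, "ambient"]), 20, tolerance = 0.005)
  expect_equal(sd(big$values[, "ambient"]), 8, tolerance = 0.02)
})
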