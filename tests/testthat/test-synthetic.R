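test_that("cohort dimensions follow n_cities x 10 age bands x 2 sexes", {
  co <- generate_cohort(synthetic_config(n_cities = 3, seed = 11))
  expect_equal(nrow(co$environment), 3)
  expect_equal(nrow(unique(co$baseline[c("city_id", "age_group", "sex")])), 60)
  expect_equal(nrow(co$exposure), 180)
  expect_equal(nrow(co$baseline), 180)
  expect_silent(validate_cohort(co))
})

test_that("generation is a pure function of (config, seed)", {
  cfg <- synthetic_config(n_cities = 4, seed = 99)
  expect_identical(generate_cohort(cfg), generate_cohort(cfg))
  # and does not disturb the caller's RNG stream
  set.seed(1); a <- runif(1)
  set.seed(1); invisible(generate_cohort(cfg)); b <- runif(1)
  expect_identical(a, b)
})

test_that("invalid hyperparameters raise configuration errors naming the field", {
  expect_error(synthetic_config(cooking_mean = -1),
               "cooking_mean", class = "no2_config_error")
  expect_error(synthetic_config(f_exp_max = 1.2), "f_exp",
               class = "no2_config_error")
  expect_error(synthetic_config(n_cities = 0), "n_cities",
               class = "no2_config_error")
  expect_error(synthetic_config(shs_share = 0.5), "shs_share",
               class = "no2_config_error")
})

test_that("generated tables satisfy the domain invariants", {
  co <- generate_cohort(synthetic_config(n_cities = 8, seed = 2))
  env <- co$environment
  expect_true(all(env$f_exp > 0 & env$f_exp <= 1))
  expect_true(all(env$outdoor_no2 >= 0 & is.finite(env$outdoor_no2)))
  expect_true(all(env$gdp_per_capita > 0))
  expect_true(all(co$exposure$mean >= 0 & co$exposure$sd >= 0))
  # ambient mean equals outdoor_no2 * f_exp for every stratum
  amb <- co$exposure[co$exposure$source == "ambient", ]
  idx <- match(amb$city_id, env$city_id)
  expect_equal(amb$mean, env$outdoor_no2[idx] * env$f_exp[idx])
  # baseline rate intervals bracket the central value; child rates near zero
  b <- co$baseline
  expect_true(all(b$daly_rate_lower <= b$daly_rate_central &
                    b$daly_rate_central <= b$daly_rate_upper))
  young <- b$age_group %in% c("0-0.5", "0.5-1", "1-2", "3-6", "7-11", "12-17")
  expect_true(all(b$daly_rate_central[young] < 5))
  expect_true(all(b$daly_rate_central[b$age_group == "60-80"] > 100))
})

test_that("adult women draw higher cooking exposure than men in the same city", {
  co <- generate_cohort(synthetic_config(n_cities = 5, seed = 21))
  ck <- co$exposure[co$exposure$source == "cooking" &
                      co$exposure$age_group == "45-59", ]
  f <- ck$mean[ck$sex == "female"][order(ck$city_id[ck$sex == "female"])]
  m <- ck$mean[ck$sex == "male"][order(ck$city_id[ck$sex == "male"])]
  expect_equal(f / m, rep(1.5, 5))
})

test_that("population-weighted exposure and source shares hit the calibration targets", {
  co <- generate_cohort(synthetic_config(n_cities = 40, seed = 31))
  pw <- population_weighted_exposure(co$exposure, co$baseline,
                                     interval = FALSE)
  expect_equal(pw$mean, 26.7, tolerance = 1e-9)
  pop <- co$baseline[!duplicated(co$baseline[c("city_id", "age_group", "sex")]),
                     c("city_id", "age_group", "sex", "population")]
  sk <- paste(pop$city_id, pop$age_group, pop$sex)
  by_source <- sapply(exposure_sources(), function(src) {
    rows <- co$exposure[co$exposure$source == src, ]
    m <- rows$mean[match(sk, paste(rows$city_id, rows$age_group, rows$sex))]
    sum(m * pop$population) / sum(pop$population)
  })
  indoor <- (by_source[["cooking"]] + by_source[["shs"]]) / sum(by_source)
  expect_gt(indoor, 0.30)
  expect_lt(indoor, 0.40)
  expect_lt(by_source[["shs"]] / sum(by_source), 0.011)
})

test_that("default CRFs carry the meta-analytic values", {
  cr <- default_crfs()
  expect_equal(cr$disease, c("LC", "COPD", "DM"))
  expect_equal(cr$rr0_central, c(1.055, 1.016, 1.019))
  expect_equal(cr$rr0_lower95, c(1.010, 1.012, 1.009))
  expect_equal(cr$rr0_upper95, c(1.101, 1.020, 1.029))
  expect_equal(cr$max_c, c(54.0, 60.7, 44.0))
  expect_equal(cr$delta_c0, rep(10, 3))
})

test_that("doubling every population doubles every downstream DALY total", {
  co <- generate_cohort(synthetic_config(n_cities = 3, seed = 8))
  co2 <- co
  co2$baseline$population <- co$baseline$population * 2
  d1 <- estimate_burden(co)
  d2 <- estimate_burden(co2)
  expect_equal(d2$attributable$dalys, 2 * d1$attributable$dalys)
  expect_equal(d2$reductions$rdalys, 2 * d1$reductions$rdalys)
})

test_that("cohort CSV round trip preserves the tables", {
  co <- generate_cohort(synthetic_config(n_cities = 2, seed = 4))
  dir <- withr::local_tempdir()
  write_cohort(co, dir)
  expect_true(all(file.exists(file.path(dir, c("environment.csv",
                                               "exposure.csv",
                                               "baseline.csv")))))
  back <- read_cohort(dir)
  expect_equal(back$exposure$mean, co$exposure$mean)
  expect_equal(back$baseline$population, co$baseline$population)
  expect_error(read_cohort(file.path(dir, "nope")),
               class = "no2_input_error")
})

test_that("mutually inconsistent tables are rejected with the missing keys", {
  co <- generate_cohort(synthetic_config(n_cities = 2, seed = 4))
  co$exposure <- co$exposure[-1, ]
  expect_error(validate_cohort(co), "missing source",
               class = "no2_input_error")
})
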