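mc_fixture <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      co <- generate_cohort(synthetic_config(n_cities = 4, seed = 19))
      cache <<- run_two_stage(co, config = uncertainty_config(
        n_variability = 100, n_uncertainty = 80, seed = 7))
    }
    cache
  }
})

test_that("aggregation is additive over any partition", {
  mc <- mc_fixture()
  nat <- aggregate_burden(mc)
  by_sex <- aggregate_burden(mc, by = "sex")
  expect_equal(sum(by_sex$mean), nat$mean)
  by_dis <- aggregate_burden(mc, by = "disease")
  expect_equal(nrow(by_dis), 3)
  expect_equal(sum(by_dis$mean), nat$mean)
  by_city_el <- aggregate_burden(mc, by = "city", metric = "economic_loss")
  nat_el <- aggregate_burden(mc, metric = "economic_loss")
  expect_equal(sum(by_city_el$mean), nat_el$mean)
  # scaling is presentational
  expect_equal(aggregate_burden(mc, scale = "thousand")$mean * 1e3, nat$mean)
  expect_error(aggregate_burden(mc, by = "planet"),
               class = "no2_query_error")
})

test_that("the burden table's margins are per-iteration sums", {
  mc <- mc_fixture()
  bt <- burden_table(mc)
  get <- function(src, dis, col = "dalys")
    bt[[col]][bt$scenario == "S0" & !is.na(bt$source) & bt$source == src &
                bt$disease == dis]
  for (d in c("LC", "COPD", "DM", "total"))
    expect_equal(get("total", d),
                 get("ambient", d) + get("cooking", d) + get("shs", d))
  for (s in c("ambient", "cooking", "shs", "total"))
    expect_equal(get(s, "total"),
                 get(s, "LC") + get(s, "COPD") + get(s, "DM"))
  expect_true(all(bt$dalys_p2.5 <= bt$dalys + 1e-12))
  expect_true(all(bt$dalys <= bt$dalys_p97.5 + 1e-12))
  # control rows: one per scenario x disease plus a total column
  expect_equal(sum(is.na(bt$source) & bt$disease == "total"), 6)
})

test_that("shares round half-even and reductions floor to whole percent", {
  expect_equal(reduction_percent(49, 138), 35)
  expect_equal(reduction_percent(35.9, 100), 35)
  expect_true(is.na(reduction_percent(10, 0)))
  mc <- mc_fixture()
  sr <- shares_and_reductions(burden_table(mc))
  expect_equal(sum(sr$disease_share_pct), 100, tolerance = 0.02)
  expect_true(all(sr$reduction_pct_el >= 0))
  expect_named(sr$reduction_pct_el, paste0("S", 1:6))
})

test_that("a burden table can be built from mean cell values", {
  cells <- expand.grid(scenario = "S0",
                       source = c("ambient", "cooking", "shs"),
                       disease = c("LC", "COPD", "DM"),
                       stringsAsFactors = FALSE)
  cells$dalys <- c(600, 400, 10, 200, 130, 3, 150, 100, 2)
  cells$el <- cells$dalys / 12
  ctrl <- data.frame(scenario = "S2", source = NA_character_,
                     disease = c("LC", "COPD", "DM"),
                     dalys = c(390, 125, 95), el = c(390, 125, 95) / 12)
  bt <- burden_table(rbind(cells, ctrl))
  tot <- bt$dalys[bt$scenario == "S0" & !is.na(bt$source) &
                    bt$source == "total" & bt$disease == "total"]
  expect_equal(tot, sum(cells$dalys))
  sr <- shares_and_reductions(bt)
  expect_equal(unname(sr$disease_share_pct["LC"]),
               round(1010 / 1595 * 100))
  expect_equal(unname(sr$reduction_pct_dalys["S2"]),
               floor(610 / 1595 * 100))
})

test_that("formatting is presentation-only and flags rounding conventions", {
  mc <- mc_fixture()
  bt <- burden_table(mc)
  before <- bt$dalys
  f <- format_burden_table(bt)
  expect_identical(bt$dalys, before)
  expect_true(all(grepl("\\(", f$dalys[!is.na(bt$dalys_p2.5)])))
  # idempotence: formatting the same table twice gives the same strings
  expect_identical(f, format_burden_table(bt))
})

test_that("population-weighted exposure averages with population weights", {
  key <- data.frame(city_id = c("C001", "C002"), age_group = "18-44",
                    sex = "male", stringsAsFactors = FALSE)
  exposure <- data.frame(city_id = rep(key$city_id, each = 3),
                         age_group = "18-44", sex = "male",
                         source = rep(c("ambient", "cooking", "shs"), 2),
                         mean = c(8, 1.5, 0.5, 25, 4.5, 0.5), sd = 0,
                         stringsAsFactors = FALSE)
  pops <- cbind(key, population = c(1, 3))
  pw <- population_weighted_exposure(exposure, pops, interval = FALSE)
  expect_equal(pw$mean, (10 * 1 + 30 * 3) / 4)
  # uniform exposure: the weighted mean is that exposure
  exposure$mean <- rep(c(15, 4, 1), 2)
  expect_equal(population_weighted_exposure(exposure, pops,
                                            interval = FALSE)$mean, 20)
  pops$population <- c(0, 0)
  expect_error(population_weighted_exposure(exposure, pops),
               class = "no2_input_error")
})
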