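test_that("the spec validates its hyper-parameters", {
  expect_s3_class(synthetic_spec(), "synthetic_spec")
  expect_error(synthetic_spec(pm25_range = c(194, 33)))
  expect_error(synthetic_spec(gap_fraction = 1.2))
  expect_error(synthetic_spec(reduction_fraction = -0.1))
  expect_error(
    synthetic_spec(cause_share_ranges = list(
      NCD_LRI = c(0.10, 0.12), IHD = c(0.2, 0.3), Stroke = c(0.06, 0.1),
      COPD = c(0.06, 0.12), LC = c(0.01, 0.02), LRI = c(0.03, 0.06)
    )),
    "tighten"
  )
})

test_that("generators are byte-identical under a fixed seed", {
  spec <- synthetic_spec(n_cities = 6, seed = 99)
  expect_identical(generate_daily_pm(spec), generate_daily_pm(spec))
  b1 <- generate_city_table(spec)
  b2 <- generate_city_table(spec)
  expect_identical(b1, b2)
  expect_identical(serialize(b1, NULL), serialize(b2, NULL))
  # a different seed changes the draw
  b3 <- generate_city_table(synthetic_spec(n_cities = 6, seed = 100))
  expect_false(identical(b1$exposure$pm25_annual, b3$exposure$pm25_annual))
})

test_that("noiseless daily pairs recover the generating line exactly", {
  spec <- synthetic_spec(noise_sd = 0, gap_fraction = 0, outlier_fraction = 0,
                         seed = 4)
  pair <- generate_daily_pm(spec)
  rel <- fit_pm_relation(pair$pm10, pair$pm25)
  expect_equal(rel$slope, pair$truth$slope, tolerance = 1e-10)
  expect_equal(rel$intercept, 0, tolerance = 1e-8)
  expect_equal(rel$pearson_r, 1, tolerance = 1e-10)
  expect_equal(rel$n_pairs, spec$n_days)
})

test_that("degraded daily series exercise screening and still recover", {
  spec <- synthetic_spec(seed = 12, gap_fraction = 0.1, outlier_fraction = 0.05)
  pair <- generate_daily_pm(spec)
  expect_lte(nrow(pair$pm25), spec$n_days)
  raw_out <- sum(pair$pm25$value < 2 | pair$pm25$value > 1000)
  expect_gt(raw_out, 0)
  scr <- screen_daily(pair$pm25, quiet = TRUE)
  expect_equal(attr(scr, "n_removed"), raw_out)
  rel <- fit_pm_relation(screen_daily(pair$pm10, quiet = TRUE), scr)
  expect_equal(rel$slope, spec$pm10_slope, tolerance = 0.1)
})

test_that("generated bundles honour the consuming modules' invariants", {
  for (s in 1:100) {
    spec <- synthetic_spec(n_cities = 2 + (s %% 5), seed = s,
                           pm25_range = c(5 + (s %% 3) * 10, 200))
    b <- generate_city_table(spec)
    expect_true(all(b$exposure$pm25_annual >= spec$pm25_range[1] &
                      b$exposure$pm25_annual <= spec$pm25_range[2]))
    expect_true(all(b$demography$population > 0))
    expect_true(all(b$demography$population <=
                      b$demography$district_urban_population))
    expect_true(all(b$demography$adult_share > 0 &
                      b$demography$adult_share < 1))
    wide <- tidyr::pivot_wider(b$cause_shares, names_from = cause,
                               values_from = share)
    expect_true(all(rowSums(wide[cod5_causes()]) <= wide$NCD_LRI))
    # the ledger respects AF < 1: attributable deaths below each baseline
    ba <- allcause_baseline(b$demography)
    expect_true(all(b$truth$by_city$delta_ncd_lri <= ba$deaths))
    expect_true(all(b$truth$by_city_cause$delta_e >= 0))
  }
})

test_that("a city at the counterfactual has zero ledger burden", {
  spec <- synthetic_spec(n_cities = 1, seed = 8, pm25_range = c(2.4, 2.4))
  b <- generate_city_table(spec)
  expect_equal(b$truth$totals$deaths[["central"]], 0)
  expect_equal(b$truth$totals$loss_musd[["central"]], 0)
})

test_that("the study-shaped fixture pins printed concentrations and strata", {
  b <- paper_like_fixture()
  expect_equal(nrow(b$cities), 31)
  pm <- setNames(b$exposure$pm25_annual, b$exposure$city_id)
  expect_equal(pm[["Delhi"]], 121)
  expect_equal(pm[["Ghaziabad"]], 194)
  expect_equal(pm[["Kanpur"]], 138)
  expect_equal(pm[["Dehradun"]], 147)
  expect_equal(pm[["Lucknow"]], 109)
  expect_equal(pm[["Patna"]], 131)
  expect_equal(sum(b$cities$class == "X"), 7)
  expect_equal(sum(b$cities$class == "Y"), 24)
  expect_equal(as.vector(table(b$cities$zone)[c("North", "Central", "East",
                                                "West", "South")]),
               c(7, 8, 6, 6, 4))
  # regeneration under the pinned seed is byte-identical
  expect_identical(serialize(b, NULL), serialize(paper_like_fixture(), NULL))
})
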