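series_of <- function(values, start = "2017-01-01", pollutant = "PM2.5",
                      city = "C", station = "S") {
  daily_pm_series(station, city, pollutant,
                  as.Date(start) + seq_along(values) - 1, values)
}

test_that("screening applies the closed plausibility window", {
  s <- series_of(c(1.5, 50, 1200))
  out <- suppressMessages(screen_daily(s))
  expect_equal(out$value, 50)
  expect_equal(attr(out, "n_removed"), 2)

  # closed interval: both endpoints retained
  ends <- screen_daily(series_of(c(2, 1000)), quiet = TRUE)
  expect_equal(ends$value, c(2, 1000))

  # empty input is an explicit empty result, not an error
  empty <- screen_daily(series_of(numeric(0)), quiet = TRUE)
  expect_equal(nrow(empty), 0)

  expect_error(screen_daily(s, lo = 10, hi = 10), "strictly less")
})

test_that("screening keeps in-window data untouched and is idempotent", {
  set.seed(11)
  s <- series_of(runif(365, 10, 100))
  once <- screen_daily(s, quiet = TRUE)
  expect_equal(nrow(once), 365) # all draws inside the window by construction
  twice <- screen_daily(once, quiet = TRUE)
  expect_identical(once$value, twice$value)
  expect_lte(nrow(once), nrow(s))
})

test_that("annual mean enforces the completeness rule", {
  m <- annual_mean(series_of(rep(80, 200)))
  expect_equal(m$pm25_annual, 80)
  expect_equal(m$provenance, "measured")
  expect_equal(m$n_valid_days, 200)

  short <- annual_mean(series_of(rep(80, 103)))
  expect_equal(short$provenance, "insufficient")
  expect_true(is.na(short$pm25_annual))
  expect_equal(short$n_valid_days, 103)

  # 104 valid days is enough (inclusive reading of the threshold)
  expect_equal(annual_mean(series_of(rep(80, 104)))$provenance, "measured")

  alt <- annual_mean(series_of(rep(c(40, 60), 75)))
  expect_equal(alt$pm25_annual, 50)

  mixed <- rbind(series_of(rep(50, 60)),
                 series_of(rep(90, 60), start = "2017-03-15",
                           pollutant = "PM10"))
  expect_error(annual_mean(mixed), "mixes pollutants")
})

test_that("annual mean of screened data stays inside the window", {
  set.seed(21)
  s <- series_of(c(runif(150, 5, 900), 1500, 1))
  scr <- screen_daily(s, quiet = TRUE)
  m <- annual_mean(scr)
  expect_gte(m$pm25_annual, 2)
  expect_lte(m$pm25_annual, 1000)
})

test_that("PM10-PM2.5 relation recovers exact and noisy coefficients", {
  x <- seq(20, 200, length.out = 50)
  pm10 <- series_of(x, pollutant = "PM10")
  pm25 <- series_of(0.5 * x)
  rel <- fit_pm_relation(pm10, pm25)
  expect_equal(rel$slope, 0.5, tolerance = 1e-10)
  expect_equal(rel$intercept, 0, tolerance = 1e-8)
  expect_equal(rel$pearson_r, 1, tolerance = 1e-10)
  expect_equal(rel$n_pairs, 50)

  # noisy fixture: compare against closed-form OLS and check the 95% CI
  set.seed(7)
  x <- runif(200, 30, 300)
  y <- 0.45 * x + rnorm(200, 0, 5)
  rel <- fit_pm_relation(series_of(x, pollutant = "PM10"), series_of(y))
  beta_hat <- sum((x - mean(x)) * (y - mean(y))) / sum((x - mean(x))^2)
  expect_equal(rel$slope, beta_hat, tolerance = 1e-12)
  half <- qt(0.975, rel$df) * rel$se_slope
  expect_lt(abs(rel$slope - 0.45), half)
})

test_that("degenerate relation inputs error", {
  const <- series_of(rep(100, 30), pollutant = "PM10")
  resp <- series_of(rnorm(30, 50, 5))
  expect_error(fit_pm_relation(const, resp), "zero variance")
  expect_error(
    fit_pm_relation(series_of(c(10, 20), pollutant = "PM10"),
                    series_of(c(5, 9))),
    "at least 3"
  )
})

test_that("a weak correlation warns but still returns the fit", {
  set.seed(9)
  x <- runif(100, 30, 300)
  y <- 0.45 * x + rnorm(100, 0, 200) # drown the signal
  expect_warning(
    rel <- fit_pm_relation(series_of(x, pollutant = "PM10"), series_of(y)),
    "acceptance floor"
  )
  expect_true(rel$below_floor)
})

test_that("regression imputation and ratio conversion follow their formulas", {
  rel <- structure(list(slope = 0.5, intercept = 0), class = "pm_relation")
  expect_equal(impute_pm25(100, rel)$pm25_annual, 50)
  rel2 <- structure(list(slope = 0.4, intercept = 10), class = "pm_relation")
  out <- impute_pm25(100, rel2, city_id = "K", year = 2017)
  expect_equal(out$pm25_annual, 50)
  expect_equal(out$provenance, "regression_imputed")

  rel3 <- structure(list(slope = 0.5, intercept = -100), class = "pm_relation")
  expect_warning(neg <- impute_pm25(10, rel3), "clipped")
  expect_equal(neg$pm25_annual, 0)

  expect_equal(ratio_convert(200, 0.5)$pm25_annual, 100)
  expect_equal(ratio_convert(77, 1)$pm25_annual, 77)
  expect_equal(ratio_convert(138 / 0.45, 0.45)$pm25_annual, 138)
  expect_equal(ratio_convert(100, 0.45)$provenance, "ratio_converted")
  expect_error(ratio_convert(100, 0), "\\(0, 1\\]")
  expect_error(ratio_convert(100, 1.2), "\\(0, 1\\]")
})

test_that("city aggregation averages stations and degrades provenance", {
  one <- ratio_convert(121 / 0.45, 0.45, city_id = "A", year = 2017)
  expect_equal(city_annual(one)$pm25_annual, 121)

  two <- rbind(
    impute_pm25(200, structure(list(slope = 0.5, intercept = 0),
                               class = "pm_relation"), "A", 2017),
    impute_pm25(280, structure(list(slope = 0.5, intercept = 0),
                               class = "pm_relation"), "A", 2017)
  )
  agg <- city_annual(two)
  expect_equal(agg$pm25_annual, 120)
  expect_equal(agg$provenance, "regression_imputed")

  mixed <- rbind(
    annual_mean(series_of(rep(100, 200), city = "A")),
    two[1, ],
    ratio_convert(240, 0.5, "A", 2017)
  )
  expect_equal(city_annual(mixed)$provenance, "ratio_converted")

  expect_error(city_annual(mixed[0, ]), "at least one")
  insuf <- annual_mean(series_of(rep(100, 10), city = "A"))
  expect_error(city_annual(insuf), "insufficient")
})

test_that("slope CI coverage is nominal over replicates", {
  set.seed(123)
  n_rep <- 500
  covered <- logical(n_rep)
  for (i in seq_len(n_rep)) {
    x <- runif(150, 30, 300)
    y <- 0.45 * x + rnorm(150, 0, 5)
    rel <- fit_pm_relation(series_of(x, pollutant = "PM10"), series_of(y))
    half <- qt(0.975, rel$df) * rel$se_slope
    covered[i] <- abs(rel$slope - 0.45) < half
  }
  expect_gte(mean(covered), 0.92)
  expect_lte(mean(covered), 0.98)
})
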