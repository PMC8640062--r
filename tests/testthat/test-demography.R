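demog_row <- function(city_id = "A", population = 1e6, adult_share = 0.5,
                      district_deaths = 10000, district_pop = 2e6,
                      age_share = 0.8, state_id = "S1") {
  tibble::tibble(
    city_id = city_id, state_id = state_id, population = population,
    adult_share = adult_share, district_urban_deaths = district_deaths,
    district_urban_population = district_pop,
    state_age_share_25plus = age_share
  )
}

test_that("all-cause baseline is the registry product formula", {
  # identity: city = district and full age share
  d <- demog_row(population = 2e6, age_share = 1)
  expect_equal(allcause_baseline(d)$deaths, 10000)

  # direct product
  d <- demog_row() # ratio 0.5, age share 0.8
  expect_equal(allcause_baseline(d)$deaths, 4000)

  # construct-then-recover: invert a known B_all exactly
  b_target <- 12345.6
  d <- demog_row(district_deaths = b_target / (0.8 * 0.25),
                 population = 5e5, district_pop = 2e6, age_share = 0.8)
  expect_equal(allcause_baseline(d)$deaths, b_target, tolerance = 1e-12)

  expect_error(allcause_baseline(demog_row(population = 3e6)),
               "exceeds district")
})

test_that("all-cause baseline is linear in deaths and population ratio", {
  d1 <- demog_row()
  d2 <- demog_row(district_deaths = 2 * d1$district_urban_deaths)
  d3 <- demog_row(population = 2 * d1$population)
  b1 <- allcause_baseline(d1)$deaths
  expect_equal(allcause_baseline(d2)$deaths, 2 * b1)
  expect_equal(allcause_baseline(d3)$deaths, 2 * b1)
})

shares_for <- function(state = "S1", ncd = 0.40, ihd = 0.10, stroke = 0.04,
                       copd = 0.05, lc = 0.005, lri = 0.02) {
  tibble::tibble(
    state_id = state,
    cause = c("NCD_LRI", "IHD", "Stroke", "COPD", "LC", "LRI"),
    share = c(ncd, ihd, stroke, copd, lc, lri)
  )
}

test_that("cause split applies state shares to the city baseline", {
  b <- allcause_baseline(demog_row()) # 4000 deaths
  out <- cause_baseline(b, shares_for(ihd = 0.25))
  expect_equal(out$deaths[out$cause == "IHD"], 1000)
  expect_equal(nrow(out), 6)

  zero <- cause_baseline(b, shares_for(ncd = 0, ihd = 0, stroke = 0,
                                       copd = 0, lc = 0, lri = 0))
  expect_equal(zero$deaths, rep(0, 6))

  # B_all = 1000, IHD share 0.25 -> 250
  b1 <- b
  b1$deaths <- 1000
  expect_equal(
    cause_baseline(b1, shares_for(ihd = 0.25))$deaths[out$cause == "IHD"],
    250
  )

  expect_error(cause_baseline(b, shares_for()[-2, ]), "missing cause")
  # five specific causes may not outweigh the aggregate
  expect_error(cause_baseline(b, shares_for(ncd = 0.10)), "exceed")
  expect_error(cause_baseline(b, shares_for(state = "S9")), "no cause shares")
})

test_that("cause split conserves mass against the aggregate", {
  b <- allcause_baseline(demog_row())
  sh <- shares_for()
  out <- cause_baseline(b, sh)
  cod5 <- sum(out$deaths[out$cause %in% cod5_causes()])
  ncd <- out$deaths[out$cause == "NCD_LRI"]
  expect_lte(cod5, ncd)
  expect_lte(sum(out$deaths) - ncd + (ncd - cod5), b$deaths)
  # shares reconstruct exactly
  expect_equal(out$deaths / b$deaths,
               sh$share[match(out$cause, sh$cause)], tolerance = 1e-12)
})

test_that("NCD-other segregation subtracts and clamps", {
  expect_equal(ncd_other(100, 80), 20)
  expect_warning(zero <- ncd_other(100, 110), "clamped")
  expect_equal(zero, 0)
  # published aggregate: 80,447 - 72,903 = 7,544
  expect_equal(ncd_other(80447, 72903), 7544)
  # additivity when unclamped
  expect_equal(ncd_other(500, 120) + 120, 500)
})

test_that("crude-rate screen flags without failing", {
  b <- allcause_baseline(demog_row()) # 4000
  expect_true(srs_plausibility(b, 5e5, low = 0.008, high = 0.012)$in_band)
  # closed interval at the bound
  expect_true(srs_plausibility(b, 4000 / 0.008, 0.008, 0.012)$in_band)
  b0 <- b
  b0$deaths <- 0
  expect_false(srs_plausibility(b0, 5e5, 0.008, 0.012)$in_band)
  rep <- srs_plausibility(b, 5e5, 0.001, 0.002)
  expect_s3_class(rep, "tbl_df") # out-of-band is a flag, not an error
  expect_false(rep$in_band)
})
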