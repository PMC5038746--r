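test_that("declination follows the Cooper formula and stays bounded", {
  expect_equal(solar_declination(81), 0, tolerance = 1e-6)
  expect_equal(solar_declination(172), 23.44978, tolerance = 1e-4)
  expect_equal(solar_declination(355), -23.44978, tolerance = 1e-4)
  all_days <- solar_declination(1:365)
  expect_true(all(abs(all_days) <= 23.45 + 1e-12))
  # 365-periodicity: day n and n+365 map to the same angle argument
  expect_equal(23.45 * sin((360 * (284 + 1 + 365) / 365) * pi / 180),
               solar_declination(1), tolerance = 1e-12)
  expect_error(solar_declination(0), "1..365")
  expect_error(solar_declination(366), "1..365")
})

test_that("sunrise hour angle handles equator, equinox and rejects polar cases", {
  expect_equal(sunrise_hour_angle(0, 23.45), 90)
  expect_equal(sunrise_hour_angle(55, 0), 90)
  expect_equal(sunrise_hour_angle(39.9, 23.45), 111.2656, tolerance = 1e-3)
  expect_error(sunrise_hour_angle(80, 23.45), "polar")
  for (phi in c(-60, -30, 0, 30, 60)) {
    wr <- sunrise_hour_angle(phi, solar_declination(172))
    expect_true(wr >= 0 && wr <= 180)
  }
})

test_that("climate constants match their closed forms and allow overrides", {
  cc <- climate_constants(60)
  expect_equal(cc$a, 0.409)
  expect_equal(cc$b, 0.6609)
  cc <- climate_constants(150)
  expect_equal(cc$a, 0.9106)
  expect_equal(cc$b, 0.1842)
  cc <- climate_constants(111.2656)
  expect_equal(cc$a, 0.8003, tolerance = 1e-3)
  expect_equal(cc$b, 0.2890, tolerance = 1e-3)
  site <- solar_site(39.9, 172, climate_a = 0.5, climate_b = 0.3)
  expect_equal(solarskin:::site_climate_constants(site), list(a = 0.5, b = 0.3))
})

test_that("hourly ratio is zero at sunrise, symmetric, and ~0.119 at noon", {
  wr <- 111.2656
  a <- 0.8003; b <- 0.2890
  expect_equal(hourly_ratio(wr, wr, a, b), 0)
  expect_equal(hourly_ratio(0, wr, a, b), 0.1188, tolerance = 1e-3)
  for (w in c(15, 45, 75, 105)) {
    expect_equal(hourly_ratio(w, wr, a, b), hourly_ratio(-w, wr, a, b))
  }
  expect_equal(hourly_ratio(c(120, 170, -130), wr, a, b), c(0, 0, 0))
  expect_warning(hourly_ratio(100, 110, a = 0.05, b = 0.9), "clamped")
})

test_that("hourly ratios over the daylight hours sum to ~1 at mid-latitudes", {
  for (phi in c(20, 39.9, 55)) {
    delta <- solar_declination(172)
    wr <- sunrise_hour_angle(phi, delta)
    cc <- climate_constants(wr)
    hours <- seq(-180, 180, by = 15)
    total <- sum(hourly_ratio(hours, wr, cc$a, cc$b))
    expect_equal(total, 1, tolerance = 0.05)
  }
})

test_that("daily and hourly irradiation follow the Angstrom-type model", {
  site <- solar_site(39.9, 172, H0 = 8000, mean_sunshine_hours = 10,
                     max_sunshine_hours = 10, climate_a = 0.8, climate_b = 0.289)
  expect_equal(daily_irradiation(site), 8000 * (0.8 + 0.289))
  site$mean_sunshine_hours <- 0
  expect_equal(daily_irradiation(site), 0.8 * 8000)
  site$mean_sunshine_hours <- 5
  expect_equal(daily_irradiation(site), 7556)
  expect_equal(hourly_irradiation(7556, 0), 0)
  expect_equal(hourly_irradiation(1, 0.119), 0.119)
  expect_equal(hourly_irradiation(7556, 0.119), 899.164)
})

test_that("site construction enforces its invariants", {
  expect_error(solar_site(90, 100), "latitude")
  expect_error(solar_site(40, 100, mean_sunshine_hours = 12,
                          max_sunshine_hours = 10), "exceed")
  expect_error(solar_site(40, 400), "day_of_year")
})

test_that("the day table reports geometry per hour and zero ratio at night", {
  tab <- solar_day_table(example_site())
  expect_equal(nrow(tab), 24)
  expect_true(all(tab$r0 >= 0))
  expect_true(all(tab$r0[tab$hour %in% c(0, 1, 2, 22, 23)] == 0))
  expect_true(all(tab$I[tab$r0 > 0] > 0))
  noon <- solar_instant(example_site(), 12)
  expect_equal(tab$r0[tab$hour == 12], noon$hourly_ratio)
})
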