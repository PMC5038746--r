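test_that("spot diameter follows the thin-lens cone geometry", {
  expect_equal(spot_diameter(lens_spec(3.00, 1.60, 1.60)), 0)
  expect_equal(spot_diameter(lens_spec(3.00, 1.60, 0)), 3.00)
  expect_equal(spot_diameter(lens_spec(3.00, 1.60, 0.53)), 2.006, tolerance = 1e-3)
  # continuity across the focal plane and zero only there
  Ls <- seq(0, 3, by = 0.05)
  ds <- vapply(Ls, function(L) spot_diameter(lens_spec(3, 1.6, L)), numeric(1))
  expect_true(all(ds[Ls != 1.6] > 0))
})

test_that("standoff inversion returns the pre-focal solution and round-trips", {
  expect_equal(standoff_for_spot(2.00, 3.00, 1.60), 0.5333, tolerance = 1e-3)
  expect_equal(standoff_for_spot(3.00, 3.00, 1.60), 0)
  expect_equal(standoff_for_spot(0, 3.00, 1.60), 1.60)
  expect_error(standoff_for_spot(3.5, 3.00, 1.60), "exceed")
  for (d in c(0.5, 1, 2, 2.9)) {
    L <- standoff_for_spot(d, 3, 1.6)
    expect_equal(spot_diameter(lens_spec(3, 1.6, L)), d)
  }
})

test_that("aperture power is irradiance times aperture area", {
  lens <- lens_spec(3.00, 1.60, 0.53)
  expect_equal(incident_power(0, lens), 0)
  expect_equal(incident_power(0.0679, lens), 0.480, tolerance = 1e-3)
  expect_equal(incident_power(1, lens_spec(2 / sqrt(pi), 1.6, 0.53)), 1)
  # linearity
  expect_equal(incident_power(0.2, lens), 2 * incident_power(0.1, lens))
})

test_that("oblique spot offset matches a thin-lens two-ray trace", {
  lens <- lens_spec(3.00, 1.60, 0.53, axis_shift_cm = 0)
  expect_equal(spot_offset(90, 0, lens), c(x = 0, y = 0))
  # exact compensation: shift equal in magnitude to the raw offset
  raw <- spot_offset(73.5, 0, lens)
  comp <- spot_offset(73.5, 0, lens, axis_shift_cm = -raw[["y"]])
  expect_equal(unname(comp), c(0, 0), tolerance = 1e-12)
  # two-ray oracle: rays at +/-h through an ideal thin lens with slope
  # s = tan(zenith) leave with slope s - h/f and land at h(1 - L/f) + L s;
  # the spot centre is their midpoint
  zen <- (90 - 73.5) * pi / 180
  s <- tan(zen); h <- 1.5; f <- 1.6; L <- 0.53
  y_plus <- h * (1 - L / f) + L * s
  y_minus <- -h * (1 - L / f) + L * s
  centre <- (y_plus + y_minus) / 2
  expect_equal(abs(raw[["y"]]), centre, tolerance = 1e-12)
  expect_equal(centre, 0.157, tolerance = 1e-3)
  # azimuth rotates the offset in-plane without changing its magnitude
  r2 <- spot_offset(73.5, 45, lens)
  expect_equal(sqrt(sum(r2^2)), sqrt(sum(raw^2)))
  expect_error(spot_offset(0, 0, lens), "altitude")
})

test_that("skin irradiance converts spot power to W/m^2", {
  expect_equal(skin_irradiance(0, 1), 0)
  expect_equal(skin_irradiance(0.1848, 1.00), 588.24, tolerance = 1e-4)
  expect_equal(skin_irradiance(pi / 100, 1.00), 100)
  expect_equal(skin_irradiance(0.2, 1), 2 * skin_irradiance(0.1, 1))
})

test_that("the ICNIRP verdict is strict, scaled by CA, and monotone", {
  expect_true(safety_check(588.53, safety_limit(1))$pass)
  expect_false(safety_check(2000, safety_limit(1))$pass)
  expect_true(safety_check(2500, safety_limit(1.5))$pass)
  expect_error(safety_limit(0.5), "CA")
  irr <- seq(0, 4000, by = 250)
  verdicts <- vapply(irr, function(x) safety_check(x)$pass, logical(1))
  expect_true(all(diff(verdicts) <= 0)) # never flips fail -> pass
  v <- safety_check(588.53)
  expect_equal(v$margin_W_m2, 2000 - 588.53)
})

test_that("beam profile carries the lens spot and focus geometry", {
  lens <- lens_spec(3.00, 1.60, 0.53)
  b <- beam_profile(lens, 0.1848)
  expect_equal(b$spot_radius_cm, spot_diameter(lens) / 2)
  expect_equal(b$spot_area_cm2, pi * b$spot_radius_cm^2)
  expect_false(b$converging)
  expect_equal(b$focus_depth_cm, 1.07)
  expect_error(lens_spec(-1, 1, 1))
  expect_error(beam_profile(lens, -2))
})
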