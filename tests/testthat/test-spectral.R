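test_that("band filtering keeps in-band samples and preserves band power", {
  sp <- default_solar_spectrum()
  full <- band_filter(sp, min(sp$wavelength_um), max(sp$wavelength_um))
  expect_equal(full$wavelength_um, sp$wavelength_um)
  expect_equal(full$power_density, sp$power_density)
  expect_error(band_filter(sp, 2.0, 3.0), "intersect")

  flat <- solar_spectrum(c(0.3, 1.8), c(1, 1))
  band <- band_filter(flat, 0.5, 1.0)
  expect_equal(range(band$wavelength_um), c(0.5, 1.0))
  band_pow <- solarskin:::spectrum_band_power(flat, 0.5, 1.0)
  total_pow <- solarskin:::spectrum_band_power(flat, 0.3, 1.8)
  expect_equal(band_pow / total_pow, 0.5 / 1.5)
})

test_that("spectral weights integrate the spectrum over node sub-bands", {
  sp <- default_solar_spectrum()
  w1 <- spectral_weights(sp, 0.75)
  expect_equal(w1$weight, 1)
  flat <- solar_spectrum(c(0.5, 1.0), c(1, 1))
  weq <- spectral_weights(flat, c(0.55, 0.65, 0.75, 0.85, 0.95))
  expect_equal(weq$weight, rep(0.2, 5), tolerance = 1e-12)
  # densities 2:1 over equal sub-bands -> weights 2/3, 1/3
  eps <- 1e-9
  steppy <- solar_spectrum(c(0, 0.5 - eps, 0.5 + eps, 1), c(2, 2, 1, 1))
  w2 <- spectral_weights(steppy, c(0.25, 0.75))
  expect_equal(w2$weight, c(2 / 3, 1 / 3), tolerance = 1e-6)
  # default band/node setup: weights sum to 1 to machine precision
  band <- band_filter(sp, 0.5, 1.0)
  w <- spectral_weights(band, seq(0.5, 1.0, by = 0.05))
  expect_equal(sum(w$weight), 1, tolerance = 1e-12)
  expect_true(all(w$weight >= 0))
  expect_error(spectral_weights(band, c(0.4, 0.6)), "within")
})

test_that("superposition is a cellwise weighted sum preserving totals", {
  g1 <- fake_grid(0.2)
  expect_equal(superpose(list(g1), 1)$flux_W, g1$flux_W)
  g2 <- fake_grid(0.2)
  s <- superpose(list(g1, g2), c(0.3, 0.7))
  expect_equal(s$flux_W, g1$flux_W)
  g3 <- fake_grid(0.6)
  s2 <- superpose(list(g1, g3), c(0.25, 0.75))
  expect_equal(unique(as.vector(s2$flux_W_cm2)), 0.5)
  # total power of the combination is the weighted mean of totals
  expect_equal(s2$power_W, 0.25 * g1$power_W + 0.75 * g3$power_W)
  bad <- fake_grid(0.2, nr = 10)
  expect_error(superpose(list(g1, bad), c(0.5, 0.5)), "geometry")
})

test_that("annulus integration recovers uniform-disc power and plane totals", {
  empty <- fake_grid(0)
  expect_equal(integrate_energy(empty, 0.5, 0.2), 0)
  g <- fake_grid(0.077) # uniform areal density (W/cm^2)
  for (R in c(0.25, 0.5, 1.0)) {
    expect_equal(integrate_energy(g, R, 0.2), 0.077 * pi * R^2,
                 tolerance = 1e-9)
  }
  # integrating to the grid extent equals the plane's total downward power
  beam <- beam_profile(lens_spec(), 0.1848)
  mc <- run_mc(0.8, beam, human_skin_stack(), small_grid(),
               n_photons = 2000, seed = 2)
  R_full <- mc$nr * mc$Rs_cm
  j <- floor(0.5 / mc$Ds_cm + 1e-9) + 1
  expect_equal(integrate_energy(mc, R_full, 0.5), sum(mc$flux_W[, j]),
               tolerance = 1e-9)
  # cumulative mode accumulates every plane above the target depth
  byplane <- vapply((1:j) - 0.5, function(zj) {
    integrate_energy(mc, 0.5, zj * mc$Ds_cm)
  }, numeric(1))
  expect_equal(integrate_energy(mc, 0.5, 0.5, mode = "cumulative"),
               sum(byplane), tolerance = 1e-9)
  expect_error(integrate_energy(mc, 0.5, 0.5, Rs_cm = 0.01), "match")
})

test_that("electric power range scales the delivered power by efficiency", {
  expect_equal(electric_power_range(0, 0.1, 0.2), c(lo = 0, hi = 0))
  expect_equal(electric_power_range(0.028, 0.10, 0.20),
               c(lo = 0.0028, hi = 0.0056))
  expect_equal(electric_power_range(0.5, 1, 1), c(lo = 0.5, hi = 0.5))
  expect_error(electric_power_range(1, 0.3, 0.2))
})
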