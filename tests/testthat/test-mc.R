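# Transport kernel and engine tests. Statistical checks use R's own RNG
# (seeded) as the independent deviate source and 3-standard-error bands.

test_that("free-path sampling is exponential with mean 1/mu_t", {
  expect_equal(sample_step(1, 5), 0)
  expect_equal(sample_step(exp(-1), 2), 0.5)
  set.seed(11)
  s <- sample_step(runif(1e5), 5)
  se <- sd(s) / sqrt(length(s))
  expect_lt(abs(mean(s) - 0.2), 3 * se)
  expect_error(sample_step(0, 5))
})

test_that("Henyey-Greenstein sampling has first moment g", {
  u <- c(0.1, 0.4, 0.9)
  expect_equal(scatter_hg(0, u), 2 * u - 1)
  expect_equal(scatter_hg(0, 0.25) + scatter_hg(0, 0.75), 0)
  set.seed(12)
  for (g in c(0.5, 0.9)) {
    ct <- scatter_hg(g, runif(1e5))
    expect_true(all(ct >= -1 & ct <= 1))
    se <- sd(ct) / sqrt(length(ct))
    expect_lt(abs(mean(ct) - g), 3 * se)
  }
  expect_error(scatter_hg(1, 0.5))
})

test_that("Fresnel reflectance matches closed forms and caps at TIR", {
  expect_equal(fresnel_reflectance(1.4, 1.4, 0.7), 0)
  expect_equal(fresnel_reflectance(1.0, 1.4, 1), (0.4 / 2.4)^2)
  # beyond the critical angle sin(theta_c) = 1/1.4
  expect_equal(fresnel_reflectance(1.4, 1.0, 0.2), 1)
  r <- fresnel_reflectance(1.0, 1.4, seq(0.05, 1, by = 0.05))
  expect_true(all(r >= 0 & r <= 1))
})

test_that("Russian roulette is unbiased and leaves live weights alone", {
  expect_equal(roulette(0.5, 1e-4, 10, 0.99), 0.5)
  expect_equal(roulette(1e-5, 1e-4, 10, 0.05), 1e-4)
  set.seed(13)
  out <- roulette(rep(1e-5, 1e5), 1e-4, 10, runif(1e5))
  se <- sd(out) / sqrt(length(out))
  expect_lt(abs(mean(out) - 1e-5), 3 * se)
})

test_that("a pure absorber reproduces Beer-Lambert transmittance", {
  tab <- flat_table(mu_a = 2, mu_s = 0, g = 0, n = 1)
  slab <- tissue_stack("slab", 0.5, table = tab)
  n <- 2e4
  g <- run_mc(0.75, test_beam(), slab, small_grid(), n_photons = n, seed = 3)
  p <- exp(-2 * 0.5)
  se <- sqrt(p * (1 - p) / n)
  expect_lt(abs(g$transmitted_W / g$power_W - p), 3 * se)
  expect_equal(g$specular_W, 0) # matched indices: no entry reflection
})

test_that("a conservative scatterer loses no weight", {
  tab <- flat_table(mu_a = 0, mu_s = 10, g = 0, n = 1)
  slab <- tissue_stack("slab", 0.3, table = tab)
  g <- run_mc(0.75, test_beam(), slab, small_grid(), n_photons = 3000, seed = 4)
  expect_equal(g$diffuse_reflectance_W + g$transmitted_W, g$power_W,
               tolerance = 1e-12)
  expect_equal(g$absorbed_W_total, 0)
})

test_that("energy is conserved through the full human stack", {
  beam <- beam_profile(lens_spec(), 0.1848)
  g <- run_mc(0.80, beam, human_skin_stack(), small_grid(r_extent = 1.5,
              z_extent = 2), n_photons = 5000, seed = 5)
  balance <- g$specular_W + g$diffuse_reflectance_W + g$absorbed_W_total +
    g$transmitted_W + g$lost_W
  expect_lt(abs(balance - g$power_W) / g$power_W, 1e-3)
})

test_that("identical seeds reproduce the grid exactly; seeds and streams differ", {
  beam <- beam_profile(lens_spec(), 0.1848)
  st <- human_skin_stack()
  a <- run_mc(0.70, beam, st, small_grid(), n_photons = 500, seed = 9)
  b <- run_mc(0.70, beam, st, small_grid(), n_photons = 500, seed = 9)
  expect_identical(a$flux_W, b$flux_W)
  expect_identical(a$absorbed_W, b$absorbed_W)
  c1 <- run_mc(0.70, beam, st, small_grid(), n_photons = 500, seed = 10)
  expect_false(identical(a$flux_W, c1$flux_W))
  c2 <- run_mc(0.70, beam, st, small_grid(), n_photons = 500, seed = 9,
               stream = 1)
  expect_false(identical(a$flux_W, c2$flux_W))
})

test_that("the compiled engine reproduces the scalar reference step-for-step", {
  beam <- beam_profile(lens_spec(), 0.1848)
  st <- human_skin_stack()
  for (wl in c(0.55, 0.85)) {
    fast <- run_mc(wl, beam, st, small_grid(), n_photons = 150, seed = 21)
    ref <- solarskin:::run_mc_reference(wl, beam, st, small_grid(),
                                        n_photons = 150, seed = 21)
    expect_identical(fast$flux_W, ref$flux_W)
    expect_identical(fast$absorbed_W, ref$absorbed_W)
    expect_identical(fast$transmit_r_W, ref$transmit_r_W)
    expect_identical(fast$specular_W, ref$specular_W)
    expect_identical(fast$diffuse_reflectance_W, ref$diffuse_reflectance_W)
  }
  # and for a converging beam on a finite slab
  slab <- make_fat_slab(0.3)
  cb <- beam_profile(lens_spec(), 0.1, converging = TRUE)
  fast <- run_mc(0.70, cb, slab, small_grid(), n_photons = 150, seed = 22)
  ref <- solarskin:::run_mc_reference(0.70, cb, slab, small_grid(),
                                      n_photons = 150, seed = 22)
  expect_identical(fast$flux_W, ref$flux_W)
  expect_identical(fast$transmitted_W, ref$transmitted_W)
})

test_that("downward power through deepening planes does not grow", {
  # absorbing-dominated slab so multiple re-crossings carry little weight
  tab <- flat_table(mu_a = 1, mu_s = 5, g = 0.8, n = 1.4)
  slab <- tissue_stack("slab", 1, table = tab)
  g <- run_mc(0.75, test_beam(power_W = 1), slab, small_grid(),
              n_photons = 5000, seed = 6)
  tot <- g$plane_total_W
  expect_true(all(diff(tot) <= 1e-3 * g$power_W))
})

test_that("deviate substreams are deterministic functions of seed and stream", {
  expect_identical(solarskin:::mix_seed(7, 0), solarskin:::mix_seed(7, 0))
  expect_false(solarskin:::mix_seed(7, 0) == solarskin:::mix_seed(7, 1))
  expect_false(solarskin:::mix_seed(7, 0) == solarskin:::mix_seed(8, 0))
  s <- solarskin:::mix_seed(1, 0)
  for (i in 1:1000) {
    s <- solarskin:::minstd_next(s)
    expect_true(s >= 1 && s <= 2147483646)
  }
})
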