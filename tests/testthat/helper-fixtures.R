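# Shared fixtures, all built in code at test time.

# homogeneous two-node property table for a named single-layer medium
flat_table <- function(layer = "slab", mu_a = 1, mu_s = 10, g = 0, n = 1) {
  data.frame(wavelength_um = c(0.50, 1.00), layer = layer,
             mu_a_per_cm = mu_a, mu_s_per_cm = mu_s, g = g, n = n)
}

# small collimated beam for slab tests
test_beam <- function(power_W = 1, radius_cm = 0.05, converging = FALSE) {
  lens <- lens_spec(D_cm = 2 * radius_cm, f_cm = 1, L_cm = 0)
  beam_profile(lens, power_W, converging = converging)
}

# coarse scoring grid keeping slab runs fast
small_grid <- function(r_extent = 1.0, z_extent = 1.0, step = 0.05) {
  grid_spec(Rs_cm = step, Ds_cm = step,
            r_extent_cm = r_extent, z_extent_cm = z_extent)
}

# minimal synthetic scoring grid with a prescribed areal flux density,
# geometry-consistent in all derived fields
fake_grid <- function(density_W_cm2, nr = 20, nz = 10, step = 0.05) {
  g <- grid_spec(step, step, nr * step, nz * step)
  areas <- pi * (((seq_len(nr) - 1) * step + step)^2 -
                   ((seq_len(nr) - 1) * step)^2)
  dens <- matrix(density_W_cm2, nr, nz)
  flux <- sweep(dens, 1, areas, "*")
  structure(list(
    Rs_cm = step, Ds_cm = step, nr = nr, nz = nz,
    r_lo_cm = (seq_len(nr) - 1) * step,
    plane_z_cm = (seq_len(nz) - 0.5) * step,
    annulus_area_cm2 = areas,
    absorbed_W = matrix(0, nr, nz),
    flux_W = flux, flux_W_cm2 = dens,
    flux_overflow_W = numeric(nz),
    plane_total_W = colSums(flux),
    transmit_r_W = numeric(nr), transmitted_W = 0,
    absorbed_W_total = 0, specular_W = 0, diffuse_reflectance_W = 0,
    lost_W = 0, power_W = sum(flux[, 1]),
    wavelength_um = 0.8, n_photons = 1, seed = 1, stream = 0
  ), class = "scoring_grid")
}

# fast low-photon pipeline configuration for smoke/determinism tests
tiny_config <- function(n_photons = 2000, nodes = c(0.60, 0.80, 1.00)) {
  cfg <- default_config()
  cfg$mc$n_photons <- n_photons
  cfg$spectral$nodes <- nodes
  cfg$integration$Rs_cm <- 0.05
  cfg$integration$Ds_cm <- 0.05
  cfg$grid$r_extent_cm <- 1.5
  cfg$grid$z_extent_cm <- 2.0
  cfg
}
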