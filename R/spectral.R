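# Spectral superposition: band selection, solar-spectrum weighting, weighted
# combination of per-wavelength scoring grids, and depth-resolved energy
# integration over annuli.

#' Solar spectrum container
#'
#' @param wavelength_um Strictly increasing wavelength samples (um).
#' @param power_density Spectral power density at each sample (W/m^2/um),
#'   non-negative.
#' @return Object of class `solar_spectrum`.
#' @export
solar_spectrum <- function(wavelength_um, power_density) {
  stopifnot(length(wavelength_um) == length(power_density),
            length(wavelength_um) >= 2)
  if (any(diff(wavelength_um) <= 0)) stop("wavelengths must be strictly increasing")
  if (any(power_density < 0)) stop("power density must be non-negative")
  structure(list(wavelength_um = wavelength_um,
                 power_density = power_density),
            class = "solar_spectrum")
}

#' Bundled terrestrial reference spectrum
#'
#' A coarse synthetic approximation of the terrestrial (AM1.5-global-like)
#' solar spectral power density over 0.30-1.80 um, used only for relative
#' spectral weighting of the transport band.
#'
#' @return A [solar_spectrum()].
#' @export
default_solar_spectrum <- function() {
  path <- system.file("extdata", "solar_spectrum.csv",
                      package = "solarskin", mustWork = TRUE)
  d <- utils::read.csv(path, comment.char = "#")
  solar_spectrum(d$wavelength_um, d$power_density_W_m2_um)
}

spectrum_interp <- function(spectrum, x) {
  stats::approx(spectrum$wavelength_um, spectrum$power_density, xout = x)$y
}

# trapezoid integral of the (linearly interpolated) density over [lo, hi]
spectrum_band_power <- function(spectrum, lo, hi) {
  xs <- sort(unique(c(lo, hi,
    spectrum$wavelength_um[spectrum$wavelength_um > lo &
                           spectrum$wavelength_um < hi])))
  ys <- spectrum_interp(spectrum, xs)
  sum(diff(xs) * (utils::head(ys, -1) + utils::tail(ys, -1)) / 2)
}

#' Restrict a spectrum to a wavelength band
#'
#' Keeps samples inside `[lo, hi]`, adding interpolated samples at the band
#' edges so the band-integrated power is preserved.
#'
#' @param spectrum A [solar_spectrum()].
#' @param lo_um,hi_um Band limits in um, `lo < hi`, intersecting the
#'   spectrum's range.
#' @return A [solar_spectrum()] covering exactly `[lo, hi]`.
#' @export
band_filter <- function(spectrum, lo_um, hi_um) {
  stopifnot(inherits(spectrum, "solar_spectrum"), lo_um < hi_um)
  rng <- range(spectrum$wavelength_um)
  if (hi_um <= rng[1] || lo_um >= rng[2]) {
    stop("band does not intersect the spectrum's wavelength range")
  }
  lo <- max(lo_um, rng[1]); hi <- min(hi_um, rng[2])
  inside <- spectrum$wavelength_um > lo & spectrum$wavelength_um < hi
  xs <- c(lo, spectrum$wavelength_um[inside], hi)
  solar_spectrum(xs, spectrum_interp(spectrum, xs))
}

#' Solar-spectrum weights for a set of wavelength nodes
#'
#' Each node receives the spectrum's power integrated over its sub-band
#' (bounded by the midpoints between adjacent nodes), normalized to sum to
#' one.
#'
#' @param spectrum A [solar_spectrum()] (already band-filtered or not).
#' @param node_wavelengths_um Strictly increasing node wavelengths inside
#'   the spectrum's range.
#' @return Object of class `spectral_weights`: `wavelength_um`, `weight`
#'   (summing to 1).
#' @export
spectral_weights <- function(spectrum, node_wavelengths_um) {
  stopifnot(inherits(spectrum, "solar_spectrum"))
  nodes <- node_wavelengths_um
  if (length(nodes) >= 2 && any(diff(nodes) <= 0)) {
    stop("node wavelengths must be strictly increasing")
  }
  rng <- range(spectrum$wavelength_um)
  if (any(nodes < rng[1] | nodes > rng[2])) {
    stop("nodes must lie within the spectrum's wavelength range")
  }
  if (length(nodes) == 1) {
    w <- 1
  } else {
    mids <- (utils::head(nodes, -1) + utils::tail(nodes, -1)) / 2
    edges <- c(rng[1], mids, rng[2])
    w <- vapply(seq_along(nodes), function(i) {
      spectrum_band_power(spectrum, edges[i], edges[i + 1])
    }, numeric(1))
    if (sum(w) <= 0) stop("spectrum carries no power over the node sub-bands")
    w <- w / sum(w)
  }
  structure(list(wavelength_um = nodes, weight = w),
            class = "spectral_weights")
}

#' Weighted superposition of per-wavelength scoring grids
#'
#' Cellwise weighted sum of power-normalized grids: every tally of the
#' combined grid is `sum_i weight_i * grid_i`, so with weights summing to 1
#' the combined grid describes the full-spectrum beam at the common power.
#'
#' @param grids List of `scoring_grid` objects with identical geometry.
#' @param weights A [spectral_weights()] or a bare numeric vector matching
#'   `grids`.
#' @return A combined `scoring_grid` (`wavelength_um` set to `NA`).
#' @export
superpose <- function(grids, weights) {
  w <- if (inherits(weights, "spectral_weights")) weights$weight else weights
  stopifnot(length(grids) == length(w), length(grids) >= 1)
  g0 <- grids[[1]]
  for (g in grids) {
    stopifnot(inherits(g, "scoring_grid"))
    if (g$nr != g0$nr || g$nz != g0$nz ||
        g$Rs_cm != g0$Rs_cm || g$Ds_cm != g0$Ds_cm) {
      stop("scoring grids must share the same geometry")
    }
  }
  comb <- g0
  fields <- c("absorbed_W", "flux_W", "flux_W_cm2", "flux_overflow_W",
              "plane_total_W", "transmit_r_W", "transmitted_W",
              "absorbed_W_total", "specular_W", "diffuse_reflectance_W",
              "lost_W", "power_W")
  for (f in fields) {
    comb[[f]] <- Reduce(`+`, Map(function(g, wi) g[[f]] * wi, grids, w))
  }
  comb$wavelength_um <- NA_real_
  comb$n_photons <- sum(vapply(grids, `[[`, numeric(1), "n_photons"))
  comb
}

#' Depth-resolved energy integration
#'
#' Computes the optical power `E` delivered at a target depth within a
#' radius `R`, by summing the downward areal power density `f(r, z)` times
#' the annulus area `S_r = pi ((r + Rs)^2 - r^2)` over the radial bins of
#' the scored plane at the target depth (the first scored plane at or below
#' it). `mode = "cumulative"` instead accumulates every scored plane from
#' the surface down to the target depth — the literal reading of a double
#' sum over depth and radius.
#'
#' @param grid A `scoring_grid`.
#' @param R_cm Integration radius in cm (within the grid's radial extent).
#' @param depth_cm Target depth in cm (within the grid's depth extent).
#' @param Rs_cm,Ds_cm Step lengths; must match the grid's own steps (a
#'   mismatch is an error, not a resample).
#' @param mode `"plane"` (default) or `"cumulative"`.
#' @return Power in W.
#' @export
integrate_energy <- function(grid, R_cm, depth_cm,
                             Rs_cm = grid$Rs_cm, Ds_cm = grid$Ds_cm,
                             mode = c("plane", "cumulative")) {
  stopifnot(inherits(grid, "scoring_grid"))
  mode <- match.arg(mode)
  if (abs(Rs_cm - grid$Rs_cm) > 1e-12 || abs(Ds_cm - grid$Ds_cm) > 1e-12) {
    stop("step lengths must match the scoring grid's steps")
  }
  if (R_cm <= 0 || R_cm > grid$nr * grid$Rs_cm + 1e-12) {
    stop("integration radius outside the grid's radial extent")
  }
  if (depth_cm < 0 || depth_cm > grid$nz * grid$Ds_cm + 1e-12) {
    stop("target depth outside the grid's depth extent")
  }
  n_r <- as.integer(round(R_cm / Rs_cm))
  j <- min(grid$nz, floor(depth_cm / Ds_cm + 1e-9) + 1L)
  planes <- if (mode == "plane") j else seq_len(j)
  sum(grid$flux_W_cm2[seq_len(n_r), planes, drop = FALSE] *
        grid$annulus_area_cm2[seq_len(n_r)])
}

#' Depth profile of delivered power
#'
#' `E(z)` evaluated at every scored plane for a fixed integration radius.
#'
#' @param grid A `scoring_grid`.
#' @param R_cm Integration radius in cm.
#' @return Data frame with `z_cm` (plane depths) and `E_W`.
#' @export
energy_depth_profile <- function(grid, R_cm) {
  n_r <- as.integer(round(R_cm / grid$Rs_cm))
  n_r <- min(n_r, grid$nr)
  E <- colSums(grid$flux_W[seq_len(n_r), , drop = FALSE])
  data.frame(z_cm = grid$plane_z_cm, E_W = E)
}

#' Electric power range from photovoltaic efficiency bounds
#'
#' @param E_W Optical power reaching the cell, W.
#' @param eff_lo,eff_hi Conversion-efficiency bounds, `0 <= lo <= hi <= 1`.
#' @return Named numeric vector `c(lo = E * eff_lo, hi = E * eff_hi)`.
#' @export
electric_power_range <- function(E_W, eff_lo = 0.10, eff_hi = 0.20) {
  stopifnot(E_W >= 0, eff_lo >= 0, eff_lo <= eff_hi, eff_hi <= 1)
  c(lo = E_W * eff_lo, hi = E_W * eff_hi)
}
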