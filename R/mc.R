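# Single-wavelength Monte Carlo transport: scalar kernels (exposed for
# testing and reuse), the seedable deviate stream, and the engine wrapper
# that produces a power-normalized cylindrical scoring grid.

#' @useDynLib solarskin, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

#' Sample a free path length
#'
#' `s = -log(u) / mu_t`: exponential free path between interactions.
#'
#' @param u Uniform deviate in (0, 1].
#' @param mu_t Total interaction coefficient (1/cm), > 0.
#' @return Path length in cm.
#' @export
sample_step <- function(u, mu_t) {
  stopifnot(all(u > 0), all(u <= 1), all(mu_t > 0))
  -log(u) / mu_t
}

#' Sample a Henyey-Greenstein deflection cosine
#'
#' Analytic inversion of the Henyey-Greenstein phase function; `g = 0`
#' reduces to isotropic scattering `cos(theta) = 2u - 1`. The mean of the
#' sampled cosine equals `g`.
#'
#' @param g Scattering anisotropy, `|g| < 1`.
#' @param u Uniform deviate in (0, 1).
#' @return `cos(theta)` in `[-1, 1]`.
#' @export
scatter_hg <- function(g, u) {
  stopifnot(abs(g) < 1)
  if (g == 0) return(2 * u - 1)
  tmp <- (1 - g^2) / (1 - g + 2 * g * u)
  pmin(1, pmax(-1, (1 + g^2 - tmp^2) / (2 * g)))
}

#' Unpolarized Fresnel reflectance at a planar interface
#'
#' Average of the s- and p-polarized Fresnel coefficients; returns 1 beyond
#' the critical angle.
#'
#' @param n1,n2 Refractive indices of the incident and transmitting media.
#' @param cos_i Cosine of the incidence angle, in (0, 1].
#' @return Reflection probability in `[0, 1]`.
#' @export
fresnel_reflectance <- function(n1, n2, cos_i) {
  stopifnot(n1 >= 1, n2 >= 1, all(cos_i > 0), all(cos_i <= 1))
  if (n1 == n2) return(rep(0, length(cos_i)))
  sin_i <- sqrt(1 - cos_i^2)
  sin_t <- n1 / n2 * sin_i
  out <- numeric(length(cos_i))
  tir <- sin_t >= 1
  out[tir] <- 1
  ok <- !tir
  cos_t <- sqrt(1 - sin_t[ok]^2)
  rs <- (n1 * cos_i[ok] - n2 * cos_t) / (n1 * cos_i[ok] + n2 * cos_t)
  rp <- (n1 * cos_t - n2 * cos_i[ok]) / (n1 * cos_t + n2 * cos_i[ok])
  out[ok] <- 0.5 * (rs^2 + rp^2)
  out
}

#' Russian roulette
#'
#' Unbiased termination of a low-weight packet: below the threshold the
#' packet survives with probability `1/m` at weight `m w`, otherwise its
#' weight drops to zero. The expectation of the returned weight equals the
#' input weight.
#'
#' @param w Packet weight (>= 0).
#' @param threshold Roulette trigger weight.
#' @param m Survival boost factor (> 1).
#' @param u Uniform deviate in (0, 1).
#' @return Updated weight.
#' @export
roulette <- function(w, threshold, m, u) {
  stopifnot(all(w >= 0), m > 1)
  ifelse(w >= threshold, w, ifelse(u < 1 / m, w * m, 0))
}

# -- deviate stream -----------------------------------------------------------

# MINSTD Lehmer stream; floor-based remainder so the state arithmetic is
# exact in doubles and expression-identical between this file and the C++
# engine, which consume the same deviate streams.
minstd_next <- function(state) {
  a <- 48271 * state
  r <- a - floor(a / 2147483647) * 2147483647
  if (r < 0) r + 2147483647 else if (r >= 2147483647) r - 2147483647 else r
}

minstd_u <- function(state) state / 2147483647

#' Mix a user seed and a stream index into an RNG state
#'
#' Gives each wavelength (or other sub-run) an independent, order-free
#' substream of the package's Lehmer generator.
#'
#' @param seed Integer-valued user seed.
#' @param stream Non-negative integer substream index.
#' @return RNG state (a double holding an integer in `[1, 2^31 - 2]`).
#' @keywords internal
mix_seed <- function(seed, stream = 0) {
  s <- (abs(seed) %% 2147483647)
  s <- (s * 69621 + (stream + 1) * 268435399) %% 2147483647
  if (s == 0) s <- 12345
  for (i in 1:10) s <- minstd_next(s)
  s
}

# -- scoring grid -------------------------------------------------------------

#' Cylindrical scoring-grid geometry
#'
#' @param Rs_cm Radial step (bin width) in cm.
#' @param Ds_cm Depth step in cm; downward flux is scored at planes
#'   `z = (j + 1/2) Ds`.
#' @param r_extent_cm Radial extent of the grid (cm).
#' @param z_extent_cm Depth extent of the grid (cm).
#' @return Object of class `grid_spec` with `nr`, `nz` and the steps.
#' @export
grid_spec <- function(Rs_cm = 0.01, Ds_cm = 0.01,
                      r_extent_cm = 1.5, z_extent_cm = 2.0) {
  stopifnot(Rs_cm > 0, Ds_cm > 0, r_extent_cm > 0, z_extent_cm > 0)
  structure(list(Rs_cm = Rs_cm, Ds_cm = Ds_cm,
                 r_extent_cm = r_extent_cm, z_extent_cm = z_extent_cm,
                 nr = as.integer(round(r_extent_cm / Rs_cm)),
                 nz = as.integer(round(z_extent_cm / Ds_cm))),
            class = "grid_spec")
}

layer_matrix <- function(stack, wavelength_um) {
  nl <- length(stack$names)
  m <- matrix(0, nl, 6)
  colnames(m) <- c("mu_a", "mu_s", "g", "n", "z_top", "z_bot")
  for (i in seq_len(nl)) {
    p <- props_at(stack, i, wavelength_um)
    m[i, ] <- c(p$mu_a, p$mu_s, p$g, p$n, stack$z_top[i], stack$z_bot[i])
  }
  m
}

#' Run a single-wavelength Monte Carlo transport simulation
#'
#' Launches photon packets uniformly over the on-skin spot disc (collimated
#' or converging towards the lens focus), propagates them through the stack
#' with the hop-drop-spin scheme (implicit capture, Henyey-Greenstein
#' scattering, unpolarized Fresnel boundary events, Russian roulette at
#' threshold 1e-4 with survival factor 10), and tallies absorption per
#' (r, z) cell and the downward partial current at planes `z = (j+1/2) Ds`.
#' Tallies are normalized so the total launched weight equals the beam power
#' in W.
#'
#' @param wavelength_um Wavelength in um (must be inside the property
#'   table's range).
#' @param beam A [beam_profile()] with positive power.
#' @param stack A [tissue_stack()].
#' @param grid A [grid_spec()].
#' @param n_photons Number of photon packets (>= 1).
#' @param seed Integer seed for the deviate stream.
#' @param stream Substream index (defaults to 0; the spectral pipeline uses
#'   the wavelength index so runs are order-independent).
#' @return Object of class `scoring_grid`: matrices `absorbed_W` and
#'   `flux_W` (`nr` x `nz`; flux is W crossing each annulus at each plane),
#'   `flux_W_cm2` (flux divided by annulus area), vectors `plane_z_cm`,
#'   `r_lo_cm`, `transmit_r_W`, and scalars `specular_W`,
#'   `diffuse_reflectance_W`, `transmitted_W`, `absorbed_W_total`,
#'   `power_W`, plus per-plane totals `plane_total_W` (including radial
#'   overflow).
#' @export
run_mc <- function(wavelength_um, beam, stack, grid = grid_spec(),
                   n_photons = 1e5, seed = 1, stream = 0) {
  stopifnot(inherits(beam, "beam_profile"), inherits(stack, "tissue_stack"),
            inherits(grid, "grid_spec"), n_photons >= 1)
  if (beam$power_W <= 0) stop("beam power must be positive")
  lm <- layer_matrix(stack, wavelength_um)
  state <- mix_seed(seed, stream)
  raw <- mc_engine(as.integer(n_photons), state, lm,
                   stack$ambient_n, stack$ambient_n_below,
                   beam$spot_radius_cm,
                   beam$center_offset[1], beam$center_offset[2],
                   if (isTRUE(beam$converging)) beam$focus_depth_cm else 0,
                   grid$nr, grid$nz, grid$Rs_cm, grid$Ds_cm,
                   1e-4, 10)
  finish_grid(raw, beam, grid, wavelength_um, n_photons, seed, stream)
}

# shared normalization/packaging for the C++ engine and the R reference
finish_grid <- function(raw, beam, grid, wavelength_um, n_photons, seed,
                        stream) {
  k <- beam$power_W / raw$launched
  r_lo <- (seq_len(grid$nr) - 1) * grid$Rs_cm
  areas <- annulus_areas(grid)
  flux_W <- raw$flux * k
  structure(list(
    Rs_cm = grid$Rs_cm, Ds_cm = grid$Ds_cm, nr = grid$nr, nz = grid$nz,
    r_lo_cm = r_lo,
    plane_z_cm = (seq_len(grid$nz) - 0.5) * grid$Ds_cm,
    annulus_area_cm2 = areas,
    absorbed_W = raw$absorbed * k,
    flux_W = flux_W,
    flux_W_cm2 = sweep(flux_W, 1, areas, "/"),
    flux_overflow_W = raw$flux_overflow * k,
    plane_total_W = colSums(flux_W) + raw$flux_overflow * k,
    transmit_r_W = raw$transmit_r * k,
    transmitted_W = (sum(raw$transmit_r) + raw$transmit_overflow) * k,
    absorbed_W_total = (sum(raw$absorbed) + raw$absorbed_overflow) * k,
    specular_W = raw$specular * k,
    diffuse_reflectance_W = raw$diffuse_reflectance * k,
    lost_W = raw$lost * k,
    power_W = beam$power_W,
    wavelength_um = wavelength_um,
    n_photons = n_photons, seed = seed, stream = stream
  ), class = "scoring_grid")
}

annulus_areas <- function(grid) {
  r_lo <- (seq_len(grid$nr) - 1) * grid$Rs_cm
  pi * ((r_lo + grid$Rs_cm)^2 - r_lo^2)
}

#' @export
print.scoring_grid <- function(x, ...) {
  cat(sprintf("Monte Carlo scoring grid (%.2f um, %g photons)\n",
              x$wavelength_um, x$n_photons))
  cat(sprintf("  beam %.4f W | specular %.4f | diffuse refl %.4f | absorbed %.4f | transmitted %.4f\n",
              x$power_W, x$specular_W, x$diffuse_reflectance_W,
              x$absorbed_W_total, x$transmitted_W))
  invisible(x)
}

#' Export a scoring grid as a long-format data frame
#'
#' One row per (r, z) cell with the absorbed power, the downward power
#' crossing the plane through the cell, and the same as an areal density.
#'
#' @param grid A `scoring_grid` from [run_mc()] or [superpose()].
#' @return Data frame with columns `ir`, `iz`, `r_lo_cm`, `z_lo_cm`,
#'   `absorbed_W`, `downward_W`, `downward_W_per_cm2`.
#' @export
grid_as_table <- function(grid) {
  stopifnot(inherits(grid, "scoring_grid"))
  idx <- expand.grid(ir = seq_len(grid$nr) - 1L, iz = seq_len(grid$nz) - 1L)
  data.frame(idx,
             r_lo_cm = idx$ir * grid$Rs_cm,
             z_lo_cm = idx$iz * grid$Ds_cm,
             absorbed_W = as.vector(grid$absorbed_W),
             downward_W = as.vector(grid$flux_W),
             downward_W_per_cm2 = as.vector(grid$flux_W_cm2))
}
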