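# Ideal thin-lens Fresnel focusing geometry and the ICNIRP skin-exposure
# check. The lens is modelled as an ideal thin lens; real Fresnel groove
# losses can be folded into `transmission`.

#' Fresnel lens specification
#'
#' @param D_cm Aperture diameter in cm (> 0).
#' @param f_cm Focal length in cm (> 0).
#' @param L_cm Lens-to-skin standoff distance in cm (>= 0).
#' @param axis_shift_cm In-plane shift of the lens axis relative to the
#'   implanted cell centre, in cm; used to recentre the spot under oblique
#'   incidence. Default 0.50 cm.
#' @param transmission Scalar power transmission of the filter+lens train
#'   (0..1]. Default 1 (ideal).
#' @return An object of class `lens_spec`.
#' @export
lens_spec <- function(D_cm = 3.00, f_cm = 1.60, L_cm = 0.53,
                      axis_shift_cm = 0.50, transmission = 1.0) {
  stopifnot(D_cm > 0, f_cm > 0, L_cm >= 0,
            transmission > 0, transmission <= 1)
  structure(list(D_cm = D_cm, f_cm = f_cm, L_cm = L_cm,
                 axis_shift_cm = axis_shift_cm,
                 transmission = transmission),
            class = "lens_spec")
}

#' Spot diameter on the skin plane
#'
#' For a collimated beam filling the aperture, the cone below the lens gives
#' a spot of diameter `d = |f - L| D / f` on a plane at standoff `L`; zero
#' exactly at the focal plane.
#'
#' @param lens A [lens_spec()].
#' @return Spot diameter in cm.
#' @export
spot_diameter <- function(lens) {
  stopifnot(inherits(lens, "lens_spec"))
  abs(lens$f_cm - lens$L_cm) * lens$D_cm / lens$f_cm
}

#' Standoff distance for a target spot diameter
#'
#' Inverts the spot-diameter relation, returning the pre-focal solution
#' `L = f (1 - d/D)` (the post-focal solution `f (1 + d/D)` trades away
#' luminous flux for the same spot size).
#'
#' @param d_cm Target spot diameter in cm, `0 <= d <= D`.
#' @param D_cm Aperture diameter in cm.
#' @param f_cm Focal length in cm.
#' @return Standoff `L` in cm.
#' @export
standoff_for_spot <- function(d_cm, D_cm, f_cm) {
  stopifnot(d_cm >= 0, D_cm > 0, f_cm > 0)
  if (d_cm > D_cm) stop("spot diameter cannot exceed the aperture diameter")
  f_cm * (1 - d_cm / D_cm)
}

#' Power entering the lens aperture
#'
#' @param surface_irradiance_W_cm2 Solar irradiance at the surface in W/cm^2.
#' @param lens A [lens_spec()].
#' @return Power in W: `irradiance * pi (D/2)^2`.
#' @export
incident_power <- function(surface_irradiance_W_cm2, lens) {
  stopifnot(surface_irradiance_W_cm2 >= 0, inherits(lens, "lens_spec"))
  surface_irradiance_W_cm2 * pi * (lens$D_cm / 2)^2
}

#' Spot-centre offset under oblique incidence
#'
#' The chief ray through the thin-lens centre is undeviated, so sunlight
#' arriving at zenith angle `90 - altitude` displaces the spot centre on the
#' skin plane by `L tan(90 - altitude)` along the propagation azimuth
#' (i.e. below the lens axis for a sun in front of the wearer). The
#' configured axis shift is applied against that displacement so the spot
#' centre approaches the implanted cell centre.
#'
#' @param altitude_deg Solar altitude angle in degrees, `(0, 90]`.
#' @param azimuth_deg Solar azimuth angle in degrees (0 = straight ahead;
#'   positive east of it, matching the convention of the hour-by-hour table).
#' @param lens A [lens_spec()].
#' @param axis_shift_cm Axis shift in cm; defaults to the lens's own.
#' @return Length-2 numeric vector `(x, y)` in cm: residual spot-centre
#'   offset from the cell centre after the shift.
#' @export
spot_offset <- function(altitude_deg, azimuth_deg, lens,
                        axis_shift_cm = lens$axis_shift_cm) {
  stopifnot(inherits(lens, "lens_spec"))
  if (altitude_deg <= 0 || altitude_deg > 90) {
    stop("altitude_deg must be in (0, 90]")
  }
  zen <- (90 - altitude_deg) * pi / 180
  az <- azimuth_deg * pi / 180
  mag <- lens$L_cm * tan(zen)
  raw <- c(x = mag * sin(az), y = -mag * cos(az))
  # shifting the lens axis down by axis_shift moves the cell-relative spot up
  raw + c(x = 0, y = axis_shift_cm)
}

#' Mean irradiance of the on-skin spot
#'
#' @param on_skin_power_W Power in the spot, W.
#' @param spot_radius_cm Spot radius, cm (> 0).
#' @return Irradiance in W/m^2 (power over the disc area, converted).
#' @export
skin_irradiance <- function(on_skin_power_W, spot_radius_cm) {
  stopifnot(on_skin_power_W >= 0, spot_radius_cm > 0)
  on_skin_power_W / (pi * spot_radius_cm^2) * 1e4
}

#' ICNIRP skin-exposure limit
#'
#' For visible and near-infrared radiation (400-1400 nm) on skin the ICNIRP
#' limit is `2.0e3 * C_A` W/m^2 with the spectral correction `C_A >= 1`.
#'
#' @param CA Spectral correction factor, `>= 1`.
#' @return Object of class `safety_limit` with `limit_base_W_m2` and `CA`.
#' @export
safety_limit <- function(CA = 1.0) {
  stopifnot(CA >= 1)
  structure(list(limit_base_W_m2 = 2.0e3, CA = CA), class = "safety_limit")
}

#' Check an irradiance against the ICNIRP limit
#'
#' @param irradiance_W_m2 Skin irradiance in W/m^2.
#' @param limit A [safety_limit()].
#' @return List of class `safety_verdict`: `pass` (TRUE iff irradiance is
#'   strictly below the effective limit), `irradiance_W_m2`,
#'   `limit_W_m2`, and `margin_W_m2` (limit minus irradiance).
#' @export
safety_check <- function(irradiance_W_m2, limit = safety_limit()) {
  stopifnot(irradiance_W_m2 >= 0, inherits(limit, "safety_limit"))
  eff <- limit$limit_base_W_m2 * limit$CA
  structure(list(pass = irradiance_W_m2 < eff,
                 irradiance_W_m2 = irradiance_W_m2,
                 limit_W_m2 = eff,
                 margin_W_m2 = eff - irradiance_W_m2),
            class = "safety_verdict")
}

#' @export
print.safety_verdict <- function(x, ...) {
  cat(sprintf("ICNIRP skin exposure check: %s\n",
              if (x$pass) "PASS" else "FAIL"))
  cat(sprintf("  irradiance %.2f W/m^2 vs limit %.2f W/m^2 (margin %.2f)\n",
              x$irradiance_W_m2, x$limit_W_m2, x$margin_W_m2))
  invisible(x)
}

#' On-skin beam profile for the transport simulation
#'
#' Describes the launch distribution used by [run_mc()]: a uniform disc of
#' the lens's spot diameter carrying `power_W`, either collimated or
#' converging towards the lens focus at depth `f - L` below the skin.
#'
#' @param lens A [lens_spec()].
#' @param power_W On-skin power in W.
#' @param converging Logical; when FALSE (default) photons travel straight
#'   down (collimated launch); when TRUE their directions point at the
#'   nominal focus at depth `f - L`. In strongly scattering tissue the two
#'   are nearly indistinguishable beyond the first transport mean free path.
#' @param center_offset In-plane `(x, y)` spot-centre offset in cm.
#' @return Object of class `beam_profile` with `spot_radius_cm`, `power_W`,
#'   `converging`, `focus_depth_cm`, `center_offset`.
#' @export
beam_profile <- function(lens, power_W, converging = FALSE,
                         center_offset = c(0, 0)) {
  stopifnot(inherits(lens, "lens_spec"), power_W >= 0)
  d <- spot_diameter(lens)
  structure(list(spot_radius_cm = d / 2,
                 spot_area_cm2 = pi * (d / 2)^2,
                 power_W = power_W,
                 converging = converging,
                 focus_depth_cm = lens$f_cm - lens$L_cm,
                 center_offset = center_offset),
            class = "beam_profile")
}
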