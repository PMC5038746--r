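# Hourly solar irradiation model: declination, sunrise hour angle, climate
# constants, and the hourly-to-daily irradiation ratio r0. All angles are in
# degrees at the interface; conversion to radians is internal.

deg2rad <- function(x) x * pi / 180
sind <- function(x) sin(deg2rad(x))
cosd <- function(x) cos(deg2rad(x))
tand <- function(x) tan(deg2rad(x))

#' Describe a solar site
#'
#' Bundles the geographic and climatic inputs of the hourly irradiation model:
#' latitude, day of year, the mean daily exoatmospheric irradiation `H0`, and
#' the sunshine-duration ratio used by the Angstrom-type daily model
#' `Ha = H0 (a + b nbar/N)`.
#'
#' @param latitude_deg Geographic latitude in degrees, strictly between -90
#'   and 90 (the sunrise hour angle is undefined at the poles).
#' @param day_of_year Day number counted from January 1 (1..365).
#' @param H0 Mean daily exoatmospheric irradiation for the site
#'   (W h / m^2 / day). No default: this is site data the user must supply.
#' @param mean_sunshine_hours,max_sunshine_hours Mean observed (`nbar`) and
#'   maximum possible (`N`) daily sunshine duration in hours;
#'   `nbar <= N` is required.
#' @param climate_a,climate_b Optional explicit climate constants. When `NULL`
#'   (default) they are computed from the sunrise hour angle via
#'   [climate_constants()]; sites with known regression values may override.
#' @param surface_irradiance_override Optional measured surface irradiance in
#'   W/cm^2. When supplied, downstream code uses it directly and bypasses the
#'   daily/hourly model entirely.
#' @return An object of class `solar_site`.
#' @examples
#' solar_site(39.9, 172, H0 = 8000, mean_sunshine_hours = 7, max_sunshine_hours = 14)
#' @export
solar_site <- function(latitude_deg, day_of_year, H0 = NA_real_,
                       mean_sunshine_hours = NA_real_,
                       max_sunshine_hours = NA_real_,
                       climate_a = NULL, climate_b = NULL,
                       surface_irradiance_override = NULL) {
  stopifnot(is.numeric(latitude_deg), length(latitude_deg) == 1)
  if (abs(latitude_deg) >= 90) {
    stop("latitude_deg must satisfy |latitude| < 90 degrees")
  }
  if (day_of_year < 1 || day_of_year > 365) {
    stop("day_of_year must be in 1..365")
  }
  if (!is.na(mean_sunshine_hours) && !is.na(max_sunshine_hours) &&
      mean_sunshine_hours > max_sunshine_hours) {
    stop("mean_sunshine_hours must not exceed max_sunshine_hours")
  }
  structure(list(
    latitude_deg = latitude_deg,
    day_of_year = as.integer(day_of_year),
    H0 = H0,
    mean_sunshine_hours = mean_sunshine_hours,
    max_sunshine_hours = max_sunshine_hours,
    climate_a = climate_a,
    climate_b = climate_b,
    surface_irradiance_override = surface_irradiance_override
  ), class = "solar_site")
}

#' Illustrative mid-latitude example site
#'
#' A Beijing-like site (latitude 39.9 deg N) at the summer solstice with
#' illustrative values of `H0`, `nbar` and `N`. The irradiation values it
#' yields demonstrate the model; they are not a climatological record.
#'
#' @return A [solar_site()] object.
#' @export
example_site <- function() {
  solar_site(latitude_deg = 39.9, day_of_year = 172,
             H0 = 8000, mean_sunshine_hours = 7.45,
             max_sunshine_hours = 14.9)
}

#' Solar declination
#'
#' `delta = 23.45 * sin(360 * (284 + n) / 365)` degrees, the standard
#' Cooper approximation.
#'
#' @param day_of_year Day number from January 1 (1..365).
#' @return Declination in degrees, bounded by +/- 23.45.
#' @examples
#' solar_declination(172) # close to +23.45 (summer solstice)
#' @export
solar_declination <- function(day_of_year) {
  if (any(day_of_year < 1 | day_of_year > 365)) {
    stop("day_of_year must be in 1..365")
  }
  23.45 * sind(360 * (284 + day_of_year) / 365)
}

#' Sunrise hour angle
#'
#' `omega_r = arccos(-tan(phi) tan(delta))` in degrees. Errors (rather than
#' returning NaN) under polar day/night, where `|tan(phi) tan(delta)| > 1`.
#'
#' @param latitude_deg Latitude phi in degrees.
#' @param declination_deg Declination delta in degrees.
#' @return Sunrise hour angle in degrees, in `[0, 180]`.
#' @export
sunrise_hour_angle <- function(latitude_deg, declination_deg) {
  x <- -tand(latitude_deg) * tand(declination_deg)
  if (any(abs(x) > 1)) {
    stop("polar day/night: |tan(latitude) * tan(declination)| > 1")
  }
  acos(x) * 180 / pi
}

#' Climate constants from the sunrise hour angle
#'
#' `a = 0.409 + 0.5016 sin(omega_r - 60)`,
#' `b = 0.6609 - 0.4767 sin(omega_r - 60)` (angles in degrees). These feed
#' both the daily model and the hourly ratio; sites with locally fitted
#' Angstrom coefficients can override them in [solar_site()].
#'
#' @param sunrise_hour_angle_deg Sunrise hour angle in degrees, `[0, 180]`.
#' @return Named list with components `a` and `b`.
#' @export
climate_constants <- function(sunrise_hour_angle_deg) {
  if (any(sunrise_hour_angle_deg < 0 | sunrise_hour_angle_deg > 180)) {
    stop("sunrise_hour_angle_deg must be in [0, 180]")
  }
  s <- sind(sunrise_hour_angle_deg - 60)
  list(a = 0.409 + 0.5016 * s, b = 0.6609 - 0.4767 * s)
}

#' Hourly-to-daily irradiation ratio
#'
#' Collares-Pereira/Rabl-type ratio of hourly to daily global irradiation:
#' `r0 = (pi/24) (a + b cos(omega)) (cos(omega) - cos(omega_r)) /
#'  (sin(omega_r) - (pi omega_r / 180) cos(omega_r))`.
#' The ratio is clamped to zero outside daylight (`|omega| >= omega_r`) and
#' whenever the formula goes negative at extreme hour angles (with a warning).
#'
#' @param hour_angle_deg Hour angle omega in degrees (15 deg per hour, 0 at
#'   solar noon, negative in the morning).
#' @param sunrise_hour_angle_deg Sunrise hour angle omega_r in degrees,
#'   strictly inside `(0, 180)`.
#' @param a,b Climate constants (see [climate_constants()]).
#' @return Dimensionless ratio `r0 >= 0`. Summed over the daylight hours it
#'   is close to 1.
#' @export
hourly_ratio <- function(hour_angle_deg, sunrise_hour_angle_deg, a, b) {
  wr <- sunrise_hour_angle_deg
  if (wr <= 0 || wr >= 180) stop("sunrise_hour_angle_deg must be in (0, 180)")
  denom <- sind(wr) - (pi * wr / 180) * cosd(wr)
  r0 <- (pi / 24) * (a + b * cosd(hour_angle_deg)) *
    (cosd(hour_angle_deg) - cosd(wr)) / denom
  night <- abs(hour_angle_deg) >= wr
  r0[night] <- 0
  neg <- r0 < 0
  if (any(neg)) {
    warning("negative hourly ratio clamped to 0 at extreme hour angle")
    r0[neg] <- 0
  }
  r0
}

#' Daily global irradiation at the surface
#'
#' Angstrom-type daily model `Ha = H0 (a + b nbar / N)`. Climate constants
#' come from the site when overridden there, otherwise from
#' [climate_constants()] at the site's sunrise hour angle.
#'
#' @param site A [solar_site()] with `H0`, `mean_sunshine_hours` and
#'   `max_sunshine_hours` set.
#' @return Daily irradiation `Ha` in the units of `H0` (per day).
#' @export
daily_irradiation <- function(site) {
  stopifnot(inherits(site, "solar_site"))
  if (is.na(site$H0) || site$H0 <= 0) stop("site H0 must be positive")
  if (is.na(site$max_sunshine_hours) || site$max_sunshine_hours <= 0) {
    stop("site max_sunshine_hours must be positive")
  }
  ab <- site_climate_constants(site)
  site$H0 * (ab$a + ab$b * site$mean_sunshine_hours / site$max_sunshine_hours)
}

#' Hourly irradiation from the daily total
#'
#' `I = Ha * r0`.
#'
#' @param Ha Daily irradiation (energy per day).
#' @param r0 Hourly ratio from [hourly_ratio()].
#' @return Hourly irradiation in the units of `Ha` (per hour).
#' @export
hourly_irradiation <- function(Ha, r0) {
  stopifnot(all(Ha >= 0), all(r0 >= 0))
  Ha * r0
}

site_climate_constants <- function(site) {
  if (!is.null(site$climate_a) && !is.null(site$climate_b)) {
    return(list(a = site$climate_a, b = site$climate_b))
  }
  delta <- solar_declination(site$day_of_year)
  wr <- sunrise_hour_angle(site$latitude_deg, delta)
  climate_constants(wr)
}

#' Solar geometry and irradiation at one instant
#'
#' Evaluates declination, sunrise hour angle, hourly ratio and (when the site
#' carries `H0`/sunshine data) hourly irradiation for a clock hour.
#'
#' @param site A [solar_site()].
#' @param hour Local solar hour (0..24, 12 = solar noon).
#' @return A list of class `solar_instant` with components
#'   `hour_angle_deg`, `declination_deg`, `sunrise_hour_angle_deg`,
#'   `climate_a`, `climate_b`, `hourly_ratio`, `hourly_irradiation`.
#' @export
solar_instant <- function(site, hour) {
  stopifnot(inherits(site, "solar_site"))
  omega <- 15 * (hour - 12)
  delta <- solar_declination(site$day_of_year)
  wr <- sunrise_hour_angle(site$latitude_deg, delta)
  ab <- site_climate_constants(site)
  r0 <- hourly_ratio(omega, wr, ab$a, ab$b)
  I <- if (is.na(site$H0)) NA_real_ else hourly_irradiation(daily_irradiation(site), r0)
  structure(list(
    hour_angle_deg = omega,
    declination_deg = delta,
    sunrise_hour_angle_deg = wr,
    climate_a = ab$a, climate_b = ab$b,
    hourly_ratio = r0,
    hourly_irradiation = I
  ), class = "solar_instant")
}

#' Hour-by-hour solar table for a site
#'
#' @param site A [solar_site()].
#' @param hours Vector of local solar hours (default every hour of the day).
#' @return A data frame with one row per hour: `hour`, `hour_angle_deg`,
#'   `declination_deg`, `sunrise_hour_angle_deg`, `r0`, `I` (hourly
#'   irradiation; `NA` when the site lacks `H0`). Suitable for `write.csv`.
#' @export
solar_day_table <- function(site, hours = 0:23) {
  rows <- lapply(hours, function(h) {
    inst <- solar_instant(site, h)
    data.frame(hour = h,
               hour_angle_deg = inst$hour_angle_deg,
               declination_deg = inst$declination_deg,
               sunrise_hour_angle_deg = inst$sunrise_hour_angle_deg,
               r0 = inst$hourly_ratio,
               I = inst$hourly_irradiation)
  })
  do.call(rbind, rows)
}
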