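# Run configuration: defaults, YAML loading with unknown-key rejection, and
# validation. Every physical quantity carries its unit in the key name.

#' Default run configuration
#'
#' The full default configuration of the simulation pipeline: the four-layer
#' human skin preset, the reference-scenario lens geometry (D = 3.00 cm,
#' f = 1.60 cm, L = 0.53 cm, 0.50 cm axis shift), a 0.1848 W on-skin beam
#' (the noon on-skin power of the reference scenario, used directly as
#' input), the 0.50-1.00 um transport band sampled at 0.05 um steps, and
#' Eq.-style integration at depth 1.00 cm within radius 1.00 cm with 0.01 cm
#' steps.
#'
#' @return Nested list of class `run_config`.
#' @export
default_config <- function() {
  structure(list(
    site = list(
      latitude_deg = 39.9,
      day_of_year = 172L,
      hour = 12,
      H0 = NULL,
      sunshine_ratio = NULL,
      surface_irradiance_override = 0.0679  # W/cm^2, measured noon value
    ),
    lens = list(
      D_cm = 3.00, f_cm = 1.60, L_cm = 0.53,
      axis_shift_cm = 0.50, transmission = 1.0
    ),
    beam = list(
      power_W = 0.1848,   # NULL -> irradiance x aperture x transmission
      converging = FALSE
    ),
    tissue = list(
      preset = "human4",        # human4 | fat_slab
      fat_thickness_cm = 1.0,
      table_path = NULL
    ),
    spectral = list(
      band = c(0.50, 1.00),
      nodes = seq(0.50, 1.00, by = 0.05)
    ),
    mc = list(n_photons = 1e5, seed = 1L),
    grid = list(r_extent_cm = 1.5, z_extent_cm = 2.0),
    integration = list(
      R_cm = 1.0, depth_cm = 1.0,
      Rs_cm = 0.01, Ds_cm = 0.01,
      mode = "plane"
    ),
    safety = list(CA = 1.0),
    pv = list(eff_lo = 0.10, eff_hi = 0.20)
  ), class = "run_config")
}

merge_config <- function(defaults, user, path = character()) {
  if (is.null(user)) return(defaults)
  if (!is.list(user)) stop("config section '", paste(path, collapse = "."),
                           "' must be a mapping")
  unknown <- setdiff(names(user), names(defaults))
  if (length(unknown)) {
    stop("unknown config key: ",
         paste(paste(c(path, unknown[1]), collapse = "."), collapse = ", "))
  }
  for (k in names(user)) {
    if (is.null(user[[k]])) next # explicit null keeps the default
    if (is.list(defaults[[k]]) && !is.null(names(defaults[[k]]))) {
      defaults[[k]] <- merge_config(defaults[[k]], user[[k]], c(path, k))
    } else {
      defaults[[k]] <- user[[k]]
    }
  }
  defaults
}

validate_config <- function(cfg) {
  with(cfg, {
    stopifnot(lens$D_cm > 0, lens$f_cm > 0, lens$L_cm >= 0,
              lens$transmission > 0, lens$transmission <= 1,
              mc$n_photons >= 1,
              grid$r_extent_cm > 0, grid$z_extent_cm > 0,
              integration$R_cm > 0, integration$depth_cm > 0,
              integration$Rs_cm > 0, integration$Ds_cm > 0,
              safety$CA >= 1,
              pv$eff_lo >= 0, pv$eff_lo <= pv$eff_hi, pv$eff_hi <= 1)
    if (!tissue$preset %in% c("human4", "fat_slab")) {
      stop("tissue.preset must be 'human4' or 'fat_slab'")
    }
    if (!integration$mode %in% c("plane", "cumulative")) {
      stop("integration.mode must be 'plane' or 'cumulative'")
    }
    if (length(spectral$band) != 2 || spectral$band[1] >= spectral$band[2]) {
      stop("spectral.band must be c(lo, hi) with lo < hi")
    }
  })
  cfg
}

#' Load a run configuration from a YAML file
#'
#' Unknown keys are rejected with the offending key path; missing keys take
#' their defaults, so an empty file yields [default_config()].
#'
#' @param path Path to a YAML file.
#' @return A validated `run_config`.
#' @export
load_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  user <- yaml::read_yaml(path)
  cfg <- merge_config(default_config(), user)
  class(cfg) <- "run_config"
  validate_config(cfg)
}

#' Write a configuration to YAML
#'
#' @param cfg A `run_config`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
save_config <- function(cfg, path) {
  yaml::write_yaml(unclass(cfg), path)
  invisible(path)
}
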