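# Layered-medium description: the four-layer human skin stack, single-layer
# fat-slab variants, and wavelength-resolved optical-property lookup.
# Convention: z increases downward from the skin surface (z = 0), with
# cylindrical symmetry about the beam axis; a point exactly on a layer
# boundary belongs to the deeper layer.

#' Bundled wavelength-resolved optical-property table
#'
#' Reads the packaged table of absorption coefficient, scattering
#' coefficient, scattering anisotropy and refractive index for epidermis,
#' dermis, subcutaneous fat and muscle at 0.05 um steps over 0.50-1.00 um,
#' compiled from standard tissue-optics literature values. Users may supply
#' their own table of the same shape anywhere one is accepted.
#'
#' @return Data frame with columns `wavelength_um`, `layer`, `mu_a_per_cm`,
#'   `mu_s_per_cm`, `g`, `n`.
#' @export
default_optical_table <- function() {
  path <- system.file("extdata", "skin_optical_properties.csv",
                      package = "solarskin", mustWork = TRUE)
  utils::read.csv(path, comment.char = "#")
}

#' Tissue stack
#'
#' An ordered set of horizontal layers. Thicknesses are in cm; only the last
#' layer may be semi-infinite (`Inf`). Each layer carries a per-wavelength
#' property table slice.
#'
#' @param names Character vector of layer names.
#' @param thicknesses_cm Numeric vector of layer thicknesses (cm), strictly
#'   positive; `Inf` allowed for the last layer only.
#' @param table Property table as in [default_optical_table()]; must contain
#'   every layer name.
#' @param ambient_n Refractive index of the medium above the stack
#'   (default 1.0, air).
#' @param ambient_n_below Refractive index below a finite stack (ignored for
#'   a semi-infinite bottom layer).
#' @return Object of class `tissue_stack` with fields `names`,
#'   `thicknesses_cm`, `z_top`, `z_bot`, `table`, `ambient_n`,
#'   `ambient_n_below`, `finite_bottom`.
#' @export
tissue_stack <- function(names, thicknesses_cm, table = default_optical_table(),
                         ambient_n = 1.0, ambient_n_below = 1.0) {
  stopifnot(length(names) == length(thicknesses_cm), length(names) >= 1)
  if (any(thicknesses_cm <= 0)) stop("layer thicknesses must be positive")
  inf <- is.infinite(thicknesses_cm)
  if (any(inf[-length(inf)])) {
    stop("only the last layer may be semi-infinite")
  }
  missing <- setdiff(names, unique(table$layer))
  if (length(missing)) {
    stop("property table lacks layer(s): ", paste(missing, collapse = ", "))
  }
  z_bot <- cumsum(thicknesses_cm)
  z_top <- c(0, z_bot[-length(z_bot)])
  structure(list(names = names,
                 thicknesses_cm = thicknesses_cm,
                 z_top = z_top, z_bot = z_bot,
                 table = table,
                 ambient_n = ambient_n,
                 ambient_n_below = ambient_n_below,
                 finite_bottom = !inf[length(inf)]),
            class = "tissue_stack")
}

#' Default four-layer human skin stack
#'
#' Epidermis 0.0065 cm, dermis 0.125 cm, subcutaneous fat 1.2 cm, and a
#' semi-infinite muscle layer, with the bundled optical-property table.
#'
#' @param table Optional replacement property table.
#' @return A [tissue_stack()].
#' @export
human_skin_stack <- function(table = default_optical_table()) {
  tissue_stack(c("epidermis", "dermis", "fat", "muscle"),
               c(0.0065, 0.125, 1.2, Inf), table = table)
}

#' Single-layer fat slab
#'
#' A finite slab of subcutaneous fat bounded below by a transmission-scoring
#' plane, emulating a bench phantom of excised fat tissue placed on a
#' detector.
#'
#' @param thickness_cm Slab thickness in cm (> 0).
#' @param table Property table containing a `fat` layer.
#' @return A [tissue_stack()] with one finite layer.
#' @export
make_fat_slab <- function(thickness_cm, table = default_optical_table()) {
  stopifnot(thickness_cm > 0)
  tissue_stack("fat", thickness_cm, table = table)
}

#' Optical properties of a layer at a wavelength
#'
#' Linear interpolation between the bracketing table wavelengths; exact at
#' table nodes. Wavelengths outside the table's range are an error (no
#' extrapolation).
#'
#' @param stack A [tissue_stack()].
#' @param layer_index 1-based layer index.
#' @param wavelength_um Query wavelength in um.
#' @return List with `mu_a`, `mu_s` (1/cm), `g`, `n`.
#' @export
props_at <- function(stack, layer_index, wavelength_um) {
  stopifnot(inherits(stack, "tissue_stack"),
            layer_index >= 1, layer_index <= length(stack$names))
  sl <- stack$table[stack$table$layer == stack$names[layer_index], ]
  sl <- sl[order(sl$wavelength_um), ]
  rng <- range(sl$wavelength_um)
  if (wavelength_um < rng[1] || wavelength_um > rng[2]) {
    stop(sprintf("wavelength %.3f um outside table range [%.2f, %.2f]",
                 wavelength_um, rng[1], rng[2]))
  }
  interp <- function(col) {
    stats::approx(sl$wavelength_um, sl[[col]], xout = wavelength_um)$y
  }
  list(mu_a = interp("mu_a_per_cm"), mu_s = interp("mu_s_per_cm"),
       g = interp("g"), n = interp("n"))
}

#' Layer containing a depth
#'
#' Half-open convention: depth z belongs to layer i when
#' `z_top[i] <= z < z_bot[i]`; a boundary point belongs to the deeper layer.
#'
#' @param stack A [tissue_stack()].
#' @param z_cm Depth below the surface, cm (>= 0).
#' @return 1-based layer index.
#' @export
layer_at_depth <- function(stack, z_cm) {
  stopifnot(inherits(stack, "tissue_stack"), z_cm >= 0)
  idx <- findInterval(z_cm, stack$z_top)
  if (stack$finite_bottom && z_cm >= stack$z_bot[length(stack$z_bot)]) {
    stop("depth below the bottom of a finite stack")
  }
  idx
}
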