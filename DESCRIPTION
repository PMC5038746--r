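Package: solarskin
Title: Transcutaneous Solar Power Delivery Simulation
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates delivery of focused sunlight to a photovoltaic cell
    implanted under human skin. Combines an hourly solar-irradiation model
    (declination, sunrise hour angle, climate constants), ideal thin-lens
    Fresnel focusing geometry, multi-wavelength Monte Carlo photon transport
    through a four-layer skin stack (epidermis, dermis, fat, muscle) with
    Henyey-Greenstein scattering and Fresnel boundary physics, solar-spectrum
    weighted superposition of per-wavelength energy distributions, and
    depth-resolved integration of the delivered optical power, together with
    an ICNIRP skin-exposure safety check.
License: MIT
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
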