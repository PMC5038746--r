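---
title: "Modelling transcutaneous solar power delivery"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling transcutaneous solar power delivery}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(solarskin)
```

## The problem

Optical recharging of an implanted photovoltaic cell asks a quantitative
question: of the sunlight a small wearable lens concentrates onto the skin,
how much power survives transport through the tissue layers to the depth of
the implant, and is the skin exposure safe? `solarskin` answers it with a
chain of models — solar irradiation, thin-lens focusing, multi-wavelength
Monte Carlo photon transport, and spectrum-weighted superposition — each of
which is described here together with its assumptions and the choices that
were genuinely open.

## Solar input

Daily global irradiation at a site follows the Angstrom-type regression
$H_a = H_0\,(a + b\,\bar n/N)$, where $H_0$ is the mean daily
exoatmospheric irradiation, $\bar n/N$ the sunshine-duration ratio, and
$a, b$ climate constants. The hourly share is a Collares-Pereira/Rabl-type
ratio $r_0(\omega)$ of hourly to daily irradiation, driven by the hour
angle $\omega$ (15°/h, zero at solar noon), the sunrise hour angle
$\omega_r = \arccos(-\tan\varphi\tan\delta)$ and the Cooper declination
$\delta = 23.45^\circ \sin\!\big(360\,(284+n)/365\big)$. By construction
$r_0 \ge 0$, it vanishes outside daylight, and its sum over the daylight
hours is close to one (the test suite checks 5% at mid-latitudes). At
extreme hour angles just inside sunrise the regression can dip below zero;
we clamp to zero with a warning rather than return an unphysical negative.

Two deliberate interface choices:

* **Angles in degrees** throughout the user interface, matching the
  convention of the source formulas; radians are internal.
* $H_0$, $\bar n$, $N$ are **user inputs**. They are site climatology, not
  physics, and no defensible universal default exists; the packaged
  `example_site()` (a mid-latitude, Beijing-like site at the summer
  solstice) is labelled illustrative. Users with measured surface
  irradiance can bypass the model entirely via
  `site.surface_irradiance_override` (the default configuration does
  exactly this with a measured noon value of 0.0679 W/cm²), because the
  regression constants are rarely known to better than tens of percent.

## Lens geometry and safety

The Fresnel lens is an ideal thin lens with unit transmission (a scalar
`lens.transmission` derates it if desired). A collimated beam filling the
aperture $D$ converges to a cone, so the spot diameter at standoff $L$ is
$d = |f-L|\,D/f$. Inverting for a target spot size has two solutions; we
return the pre-focal one, $L = f(1-d/D)$, which keeps the lens close to the
skin and the full beam power inside the spot. With the default
$D = 3.00$ cm, $f = 1.60$ cm and a 2.00 cm spot this gives
$L = 0.53$ cm.

Under oblique sun (altitude $< 90^\circ$) the chief ray through the lens
centre is undeviated, so the spot centre lands $L\tan(\text{zenith})$ from
the lens axis, on the far side from the sun. A fixed axis shift (default
0.50 cm) recentres the spot on the implanted cell; the residual offset is
reported. The shift magnitude is a configuration parameter, not a computed
optimum, because the optimal value depends on the daily arc one wants to
average over.

Safety uses the ICNIRP skin limit for 400–1400 nm, $2.0\times10^3\,C_A$
W/m² with $C_A \ge 1$: the mean spot irradiance (power over disc area) must
be strictly below it. The reference 0.1848 W spot of 1.00 cm radius sits at
588 W/m², a factor ~3.4 below the limit.

Band selection (0.50–1.00 μm) is attributed to an ideal filter ahead of the
lens: shorter wavelengths (UV) are blocked for safety and barely penetrate
anyway; beyond 1 μm water absorption dominates and silicon response falls
off. Out-of-band power is discarded, not tracked.

## Tissue model and optical properties

The skin is four infinite horizontal layers — epidermis 0.0065 cm, dermis
0.125 cm, subcutaneous fat 1.2 cm, muscle semi-infinite — in cylindrical
coordinates with $z$ increasing downward from the surface. Optical
properties ($\mu_a$, $\mu_s$, $g$, $n$) are constant within a layer and
linearly interpolated in wavelength between the bundled table's 0.05 μm
nodes.

The bundled table is the package's most consequential data choice. It was
compiled once from standard tissue-optics literature relations: a melanin
power law (≈5% melanosome volume fraction) plus baseline for epidermis,
blood and water features for dermis, weak absorption with a ~0.93 μm lipid
band for fat, myoglobin/water for muscle, and reduced-scattering power laws
converted to $\mu_s$ with $g = 0.85$–$0.9$ and $n = 1.37$–$1.44$. Published
values for human tissue span factors of 2–3 between sources and
individuals (pigmentation, hydration, blood content), so any single table
is a representative stand-in, not a ground truth; every downstream energy
figure inherits that spread. The table ships as plain CSV
(`inst/extdata/skin_optical_properties.csv`) and any same-shaped
replacement can be supplied via `tissue.table_path`.

A single-layer fat slab preset (`make_fat_slab`) emulates a bench phantom:
excised fat of a chosen thickness over a transmission-scoring plane, as one
would place over a detector to measure delivered power versus thickness.

## Monte Carlo transport

The engine is the de facto standard formalism for layered tissue:
photon packets launched with unit weight, exponential free paths
$s = -\ln u/\mu_t$, implicit capture depositing $w\,\mu_a/\mu_t$ per
interaction, Henyey–Greenstein deflection sampling, unpolarized Fresnel
splitting at layer boundaries (total internal reflection included), and
Russian roulette below weight $10^{-4}$ with survival factor $m = 10$.
Specular entry reflection at the air–epidermis interface is applied
per photon as a weight split. A photon exactly on a boundary belongs to
the deeper layer, matching `layer_at_depth`.

Scoring is cylindrical: absorption per $(r, z)$ cell, and the downward
partial current tallied whenever a packet crosses one of the planes
$z = (j+\tfrac12)\,D_s$ moving downward. Placing planes at cell centres
makes the reported depths (0.0050, 0.0550, … cm) unambiguous. The current
is reported both as W per annulus and as W/cm² (divided by the annulus
area) — the two readings of a flux-times-area sum only agree if the
density convention is stated, so both are exported.

Launch distribution: uniform over the spot disc, collimated by default.
A converging option (directions aimed at the nominal focus at depth
$f - L$) exists, but in strongly scattering tissue the transport mean free
path in dermis is ~0.1 mm, so directional memory is erased almost
immediately: delivered power at 1 cm agrees between the two launches to
within Monte Carlo noise (about a percent at the default photon count).
The collimated default is therefore kept for simplicity.

### Randomness and reproducibility

The deviate stream is a MINSTD Lehmer generator (multiplier 48271, modulus
$2^{31}-1$) implemented with floor-based remainders that are exact in
double arithmetic. The same stream is consumed by the compiled engine and
by a pure-R scalar reference implementation, and the test suite requires
their tallies to be *identical* (the build disables floating-point
contraction to keep operation-for-operation equivalence). Each wavelength
node runs on an independent substream mixed from (seed, node index), so
spectral runs are reproducible and order-independent. Two runs with the
same seed produce byte-identical output files.

Default problem size: $10^5$ photon packets per wavelength node (11 nodes),
which puts the Monte Carlo standard error of the headline integral well
below 1% and completes in about two minutes on one CPU; tests use
$10^2$–$2\times10^4$ packets per scenario. A per-photon event cap
($10^6$) guards against pathological zero-absorption orbits; weight lost
that way is tracked and is zero in all shipped scenarios.

## Spectral superposition and delivered power

Each wavelength node's grid is normalized to the full beam power, and the
combined distribution is the weighted sum with weights proportional to the
solar spectral power density integrated over each node's sub-band
(midpoint-bounded), normalized to one. The bundled spectrum is a coarse
synthetic AM1.5-global-like curve (plain CSV, labelled synthetic); only its
relative shape over 0.50–1.00 μm matters, and users may substitute measured
data.

Delivered power at depth $z$ within radius $R$ is
$E = \sum_r f(r, z)\,S_r$ with $S_r = \pi((r+R_s)^2 - r^2)$, summing the
downward areal density over annuli at the scored plane at the target depth
(the first plane at or beyond it, e.g. $z = 1.0050$ cm for a 1.00 cm
target). A `cumulative` mode that also sums over all shallower planes is
provided because a double sum over depth and radius admits both readings;
the plane reading is the default since only it has the units of power
delivered *at* a depth. With a uniform density the annulus areas telescope
to $\pi R^2$ exactly, which the tests use as a closed-form oracle, and
integrating to the grid's radial extent reproduces the plane's total
downward power to $10^{-9}$.

Electric power is the delivered optical power times a photovoltaic
efficiency range (default 10–20%); for a delivered 0.028 W that arithmetic
gives 0.0028–0.0056 W. (Statements elsewhere that treat the optical power
itself as the electric range conflate the two; the package implements the
explicit multiplication.)

## Known limitations

* **Property-table sensitivity.** With the bundled literature table the
  reference scenario delivers ≈0.009 W at 1 cm depth from a 0.1848 W spot
  (≈5% transmission; ~40% diffuse reflectance at the red/NIR nodes). Both
  fractions are in the standard range for human skin, but reported
  simulations of the same scenario built on undisclosed property sets can
  differ by factors of 2–3 in either direction — more transparent
  assumptions yield up to ~15% transmission. The package reports what its
  stated inputs imply and exposes the table for substitution rather than
  fitting it to any external headline number.
* **No sub-surface build-up of in-spot power.** With a uniform-disc launch
  carrying all power inside the scoring radius, the downward current
  through the shallowest plane already includes the full beam (plus
  backscatter re-crossings) and decays with depth. A rise of in-window
  power over the first half millimetre requires a structured (e.g.
  ring-shaped) beam profile with substantial power outside the window at
  the surface, as groove-level lens ray tracing produces; that fidelity is
  outside this package's ideal-lens scope.
* The solar model has no atmosphere: no cloud, aerosol or diffuse/direct
  split beyond what the climate constants absorb.
* Tissue is homogeneous per layer: no melanin/haemoglobin spatial
  structure, no property drift with depth, no temperature dependence.
* Transport is steady-state, unpolarized, and index-matched within each
  layer; no fluorescence or thermal feedback.
* The fat-slab phantom scenario assumes properties constant through the
  slab; real excised tissue drifts within hours.

## What the tests do and do not show

The suite verifies the closed-form layers exactly (lens geometry, Fresnel
coefficients, annulus integration, the solar formulas), verifies the
transport engine against a Beer–Lambert limit, a conservative-scatterer
energy balance, Henyey–Greenstein and roulette moment checks, and the
scalar reference implementation (bitwise), and verifies pipeline-level
invariants (determinism, monotone decay with depth and slab thickness,
absorption sensitivity). Passing them shows the machinery is faithful to
its stated model; it does not validate the bundled optical properties
against any particular person's skin, which is the dominant uncertainty in
every absolute power figure.
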