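---
title: "A seasonally forced channel model of eddy iron supply and Southern Ocean productivity"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A seasonally forced channel model of eddy iron supply}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The scientific problem

Away from dust, shelf and glacial sources, phytoplankton in the open
Southern Ocean depend on iron that arrives from below.  The candidate
supply routes are vertical (KPP-type) boundary-layer mixing, seasonal
entrainment as the mixing layer deepens, and eddy transport — mesoscale
isopycnal stirring and submesoscale mixed-layer instability (MLI).
Because isopycnals in the Antarctic Circumpolar Current (ACC) region slope
steeply, along-isopycnal stirring has a vertical projection: it can carry
iron from the deep ferrocline up across the base of the mixing layer, where
boundary-layer mixing takes over and delivers it to the euphotic zone.
Coarse-resolution ocean climate models cannot resolve these eddies and must
parametrize them; whether the standard parametrizations reproduce the
iron supply — and hence primary production — is the question this package
is built around.

`channelfe` implements a desk-scale latitude-depth (y-z) reduction of a
seasonally forced ACC-like channel: a tracer-transport and biogeochemistry
model driven by the standard eddy-parametrization battery, an iron-limited
ecosystem, and the diagnostic pipeline (mixing-layer depth, integrated
biomass, bloom phenology, per-process vertical iron fluxes, budget
closure) needed to quantify how isopycnal stirring controls production.
The central numerical experiment is a paired sensitivity run: the coarse
scenario with Redi isopycnal diffusion at 1000 m^2 s^-1 against an
otherwise identical twin with Redi switched off.

## Domain and reduction

The model domain is a channel of width `Ly = 2000` km and depth
`H = 3000` m, collapsed in the zonal direction: all fields live in the
(y, z) plane, and "zonal" statistics of the original three-dimensional
problem degenerate to meridional-band statistics (the band y = 600-1400 km
is the analysis region).  The reduction is motivated by the approximate
zonal symmetry of the ACC; the price is that no eddies can be resolved, so
*all* eddy transport is parametrized — which is precisely the regime the
package is designed to study.  The default grid is 20 x 40 cells with
uniform 100 km meridional spacing (the "coarse, CMIP-class" resolution)
and geometrically stretched vertical spacing from 5 m at the surface to
about 300 m at depth, so the seasonal boundary layer is well resolved.

Latitude-depth staggering follows the standard finite-volume C-grid:
scalars at cell centers, fluxes on faces, streamfunctions on corners, so
discrete non-divergence and conservation are exact identities.

## Forcing: the synthetic study conditions

All inputs are generated by `make_seasonal_forcing()`; no external data
are read.  The defaults *are* the study conditions and are not tuning
knobs:

* **Seasonal cycles.** Surface photosynthetically available radiation
  cycles between 20 and 200 W m^-2, peaking in mid-January (austral
  summer).  The mixing-layer depth target cycles between 50 m (late
  February) and 250 m (late August), anti-phased with light, as a smooth
  cosine.  Both cycles are exactly 365-day periodic.
* **Stratification.** Buoyancy carries a surface-intensified exponential
  profile (`N^2 = 2.2e-5 * exp(z/300 m) + 8e-7` s^-2) chosen so the
  mid-channel first-baroclinic deformation radius, diagnosed by the WKB
  integral `R = (pi |f|)^{-1} \int N dz`, is about 14 km — an order of
  magnitude below the 100 km grid spacing, making the "eddies must be
  parametrized" premise explicit.  The meridional buoyancy gradient is
  uniform (`M^2 = 4e-9` s^-2, dense water to the south), the natural
  zonal-mean idealization of the broad ACC frontal zone; an optional
  Gaussian front (`M2_front_s2`) can be added for experiments with
  meridionally localized jets.
* **Ferrocline.** The northern-boundary iron profile is a saturating
  exponential with 0.05 umol Fe m^-3 at the surface and an asymptote
  tuned so the concentration at 1000 m is 0.4 umol Fe m^-3, the canonical
  open-Southern-Ocean values.  The e-folding scale (150 m) concentrates
  the iron gradient in the 100-400 m range that winter entrainment and
  eddy stirring actually sample, which is also what pins the maximum of
  the eddy iron-flux profile near the mixing-layer base.  There is no aeolian dust flux at the
  surface and no benthic source: iron enters only through the northern
  relaxation zone, so internal transport is the only supply route.
* **Boundary relaxation.** A 200 km sponge at the northern wall relaxes
  iron to the ferrocline profile and buoyancy to its initial state with a
  20-day timescale at the boundary (quadratic ramp).  Detritus reaching
  the sea floor leaves the domain (burial), closing the iron loop:
  boundary supply balances export at equilibrium.
* **Mean circulation.** The Eulerian-mean overturning is a prescribed
  Deacon-cell streamfunction of amplitude 1.25 m^2 s^-1 (about 1.3 Sv per
  1000 km of zonal extent), confined to the upper 1200 m, with its center
  at y = 2/3 Ly so the analysis band sits in the upwelling limb — the
  slow wind-driven upwelling of iron-rich deep water characteristic of
  the region.  Together with the background diapycnal diffusivity it
  forms the Redi-independent share of the iron supply against which the
  Redi on/off sensitivity is measured.

## Transport operators

All operators are pure functions of (state, parameters, grid) returning
both tendencies and face fluxes; every tendency equals minus the discrete
divergence of its flux field, so per-process budgets close to round-off.

**Isopycnal slope.** `S = -b_y / b_z`, clipped at `|S| <= 0.01`; where
`b_z` falls below `1e-8` s^-2 the slope is set to the clipped limit with
the sign of `-b_y`.  Clipping (rather than an exponential taper) is the
simplest bounded scheme; the bound is configuration-exposed.

**Visbeck-scaled GM.** The GM coefficient per column is
`kappa = alpha |f| Ri^{-1/2} L^2`, with the vertical-mean Richardson
number `Ri = <N^2> f^2 / <b_y^2>` from thickness-weighted column means,
clipped to [200, 2500] m^2 s^-1.  With `alpha = 0.015` and `L = 200` km
the default stratification lands mid-range (about 900-1400 m^2 s^-1);
columns with no shear fall to the lower clip (quiescent limit).  The
streamfunction is `psi = kappa S` on cell corners in the adiabatic
interior; inside the boundary layer it transitions *linearly in z* from
its value at the boundary-layer base to zero at the surface — the
simplest realization of diabatic-layer matching — and it vanishes on all
solid walls.  Bolus velocities `v = -psi_z`, `w = psi_y` are discretely
non-divergent cell by cell.

**Redi isopycnal diffusion.** Small-slope tensor fluxes
`F_y = -kappa_R (C_y + S C_z)`, `F_z = -kappa_R (S C_y + S^2 C_z)`.
The coefficient is 1000 m^2 s^-1 in the coarse scenario, 200 m^2 s^-1 in
the MLI scenario, 0 in the "off" twins.  Inside the boundary layer the
slope entering the tensor is tapered linearly to zero at the surface
(diabatic-layer treatment), so near-surface Redi diffusion rotates toward
horizontal.

**MLI streamfunction.** Fox-Kemper-type restratification confined to the
mixing layer, `psi = -ce (dy/lf) h^2 (db_ml/dy) / |f| mu(z/h)` with the
canonical vertical structure `mu(s) = (1-(2s+1)^2)(1+(5/21)(2s+1)^2)`
clipped at zero.  `mu` vanishes at the surface and at `z = -h`, so the
MLI vertical flux at the mixing-layer base is *exactly* zero: MLI
restratifies within the layer but cannot supply iron across its base.
The sign convention restratifies the front under the same velocity
convention as GM.

**KPP-like vertical mixing.** The boundary-layer diffusivity is
`kappa_v = kappa_bg + kappa_bl G(sigma)`, `sigma = -z/h`, with the cubic
shape `G = (27/4) sigma (1-sigma)^2` that vanishes at the base; below the
layer only the background `kappa_bg = 1e-5` m^2 s^-1 remains.  The
boundary-layer depth is prescribed by the forcing (no surface-flux
solver), and `kappa_bl = 0.1` m^2 s^-1 homogenizes the layer in a few
days.  In the flux ledger the boundary-layer ("kpp") and background
("bg") contributions are split, so the contract "KPP flux is identically
zero at and below the mixing-layer base" holds exactly.

**Advection.** Flux-form finite volume with a van Leer (MUSCL) limited
reconstruction: second order on smooth fields, conservative to round-off,
monotonicity-preserving in each direction.  A donor-cell outflow limiter
(no cell may lose more than 95% of its content per step) guards
positivity against the small multidimensional overdraw of the unsplit
update; the limited fluxes are what enter the ledger, so closure is
unaffected.  A CFL check errors with the offending location.

## Numerical treatment and operator splitting

Time stepping is forward Euler with operator splitting, in the order
mean advection -> GM -> MLI -> Redi -> vertical mixing -> sinking ->
biology -> boundary relaxation.  Splitting is a deliberate choice:
per-process budget attribution is exact under splitting, and the
diagnostics are the point of the package.  The default step is 6 h,
comfortably inside the advective CFL limit (the largest parametrized
velocities give CFL of order 0.05) and the explicit stability limits of
the lateral and cross Redi terms.

Two terms are treated implicitly (backward Euler, tridiagonal per
column): vertical mixing, and the `S^2 C_z` vertical component of the
Redi tensor, whose explicit stability limit in thin surface cells would
otherwise force a prohibitively small step.  Backward-Euler diffusion is
unconditionally stable, positivity-preserving, and its flux (evaluated at
the new state) closes the budget exactly.

Buoyancy is carried as a prognostic tracer mixed vertically and restored
(30-day timescale) toward a seasonal target — the initial stratification
homogenized over the current mixing-layer depth — plus the northern
sponge; it is not advected.  Coupling is one-way: the mean overturning
and the eddy streamfunctions stir the ecosystem tracers, while the slope
and stratification fields those parametrizations need come from the
maintained buoyancy state.  The alternative — letting the parametrized
bolus flow and the mean cell rework the buoyancy field on a coarse grid
with clipped slopes — was found to erode the deep stratification and
feed back into grid-scale noise in the eddy fluxes, with equilibria that
depend on grid size and integration length; the semi-prescribed buoyancy
is both more robust and closer to the "prescribed physics, free
biogeochemistry" spirit of the reduction.  Two numerical safeguards are
kept in the stepping regardless: a light 1-2-1 smoothing of the slope
field entering the prognostic GM streamfunction, and a convective
adjustment that homogenizes statically unstable column segments.  The
GM streamfunction also ramps linearly to zero over the bottom 300 m
(the mirror of its surface taper).  The operators themselves are
agnostic: the unit suite exercises them on arbitrary buoyancy fields.

In this zonal-mean frame with a meridionally uniform gradient the GM
bolus velocity is structurally weak inside the analysis band (the
streamfunction is nearly uniform in y), so the cross-base eddy transport
is carried almost entirely by Redi stirring — consistent with the
attribution of the cross-base supply to isopycnal stirring that the
package is built to examine.  The Redi-independent supply (boundary-layer
mixing interpolated at the base, background diapycnal mixing at
`kappa_bg = 5e-5` m^2 s^-1, and mean upwelling) sets the denominator of
the on/off sensitivity.

The ecosystem update limits each pool's sinks so that no tracer can be
driven negative within a step (the iron-uptake limiter scales primary
production and the quota-locked iron drawdown together, preserving the
Fe:C link).  After every split sub-step all tracers are non-negative.

## The reduced ecosystem

Four tracers: phytoplankton carbon P, zooplankton carbon Z, detritus D
(mg C m^-3) and dissolved iron Fe (umol Fe m^-3).  Growth is
`mu = mu_max * gamma_I * gamma_N` (multiplicative limitation; a Liebig
`min()` alternative is a configuration switch).  The light factor is
`gamma_I = 1 - exp(-I/I_k)` with exponentially attenuated irradiance and
self-shading by the overlying biomass column; the iron factor is the
Monod curve `gamma_N = Fe/(Fe + K_Fe)`.  Grazing is Holling-II;
mortality and unassimilated grazing are partially remineralized on the
spot (fraction `remin_frac`), the rest entering detritus, which sinks at
`w_sink` and remineralizes at `r_remin`.  Iron moves in fixed proportion
to carbon through the quota `R_FeC`; with full recycling, no sinking and
no scavenging, `Fe + R_FeC (P + Z + D)` is exactly conserved.
Scavenging is linear above a ligand threshold — the simplest monotone
stand-in for particle chemistry, configuration-exposed because the
functional form of scavenging is a known inter-model uncertainty.

Key defaults and the reasoning behind them:

| parameter | default | units | why |
|---|---|---|---|
| `mu_max` | 0.9 | d^-1 | cold-water maximum growth |
| `K_Fe` | 0.065 | umol Fe m^-3 | places the seasonal surface-iron swing (~0.13 winter to ~0.03 post-bloom) on the steep part of the Monod curve, so `gamma_N` traverses roughly 0.67 to 0.3 and below |
| `I_k` | 25 | W m^-2 | winter irradiance (20 W m^-2) is strongly limiting, summer (200) is not: the winter biomass minimum is light-driven |
| `k_w`, `k_chl` | 0.04, 1e-3 | m^-1, m^-1/(mg C m^-2) | clear-water euphotic depth ~100 m; self-shading caps bloom amplitude |
| `g_max`, `K_P` | 1.0, 25 | d^-1, mg C m^-3 | moderate top-down control; strong enough to terminate blooms with iron, weak enough not to decouple biomass from supply |
| `remin_frac`, `r_remin`, `w_sink` | 0.65, 0.04, 12 | -, d^-1, m d^-1 | a deliberately "leaky" iron loop: a substantial share of uptake is exported below the euphotic zone, so standing biomass tracks *new* (transported) iron rather than recycled iron |
| `R_FeC` | 3e-3 | umol Fe (mg C)^-1 | iron-stressed Fe:C of ~36 umol mol^-1; makes bloom drawdown of iron comparable to the winter surface inventory |
| `lambda_scav`, `fe_ligand` | 5e-3, 0.6 | d^-1, umol Fe m^-3 | scavenging only above ligand saturation; inactive at the concentrations the run visits, but exposed |

Under these conditions the simulated climatology reproduces the expected
phenology chain, which the test suite asserts rather than this document
claiming numbers: the biomass minimum (bloom onset) falls in late winter
while the mixing layer is still deepening; the maximum (apex) falls in
late October / November after shoaling has begun, while the light factor
is still improving; and the iron factor — not the light factor —
collapses across the apex.  Iron is the limiting nutrient year-round
(annual-median `gamma_N` below annual-median `gamma_I` in the top 100 m).

## Diagnostics

* **Mixing-layer depth**: the 99th percentile (linear-interpolation
  order-statistic convention, configurable) of the boundary-layer-depth
  sample across the band — the kinematically active layer, the relevant
  depth for transport.
* **Integrated biomass** `<C_p>`: at each depth, the spatial *median* of P
  over the band (the simulated biomass distribution is approximately
  log-normal), then the full-depth vertical integral, in g C m^-2.
* **Bloom onset/apex**: circular argmin/argmax of the 365-day `<C_p>`
  climatology, ties broken by the earliest day; a constant series is
  flagged degenerate with a warning.
* **Cross-mixing-layer-base iron flux** `F^z_Fe`: each day, every
  process's band-mean vertical flux profile is linearly interpolated to
  the evaluation depth `max(MLD, 100 m)` — the "whichever is deeper" rule
  that excludes KPP mixing by construction — then summed over processes;
  the annual mean (mean daily flux x 365) is reported in
  umol Fe m^-2 yr^-1.  Per-day evaluation followed by averaging is used
  (the alternative, a fixed annual-mean depth, is a one-line change).
* **Snapshot-anomaly flux** `w'Fe'`: primes are deviations of 15-daily
  snapshots from the per-day-of-year climatology (and zonal mean for 3-D
  input); the operator applies unchanged to external gridded output.  At
  least two years of snapshots are required.
* **Scenario table**: annual median of daily `<C_p>` (final output year)
  against annual-mean `F^z_Fe` per scenario — the biomass-versus-supply
  plane in which the resolution and parametrization dependence of the
  original problem is usually drawn.

"Top 100 m" masks cells whose centers are shallower than 100 m.  The
annual biomass aggregate is the *median* of daily `<C_p>`, matching the
scenario-table convention.

## Spin-up, equilibrium and problem sizes

`spin_up_to_cycle()` integrates whole years until the year-over-year
change of the annual-mean domain-integrated iron and phytoplankton
inventories falls below 1% (default cap 10 years at the default grid;
non-convergence is a recorded warning, not an error).  The package's
standard experiment is 10 spin-up plus 2 output years on the 20 x 40
grid, which a single CPU completes in about three minutes; the test
suite uses 7 + 2 years on a 16 x 40 grid for its run-level properties,
sizes chosen so the whole suite stays lightweight while remaining inside
the equilibrated regime (the equilibrium-seasonality check — consecutive
output years repeating within 2% — is asserted at that size).

## What the generator emulates, and what it does not

The synthetic forcing reproduces the *structure* of the original
problem: seasonal light and mixing-layer cycles, an ACC-like front, a
realistic ferrocline with the observed surface and 1000 m anchor values,
iron-only limitation, and the separation of supply routes (mixing confined
to the layer, eddy stirring across its base, MLI contained inside it).
It does not emulate resolved eddies or their statistics: there is no
internal variability, no submesoscale w', no storms, no multi-species
community, no silicate co-limitation, no dust.  Passing tests therefore
demonstrate that the parametrized transport battery and diagnostics behave
as specified under clean, controlled conditions — not that the model
reproduces any particular observed or eddy-resolving magnitude.  The
headline sensitivity (the Redi on/off pair recomputed by
`scripts/acceptance.R`) is a scaled-down analog of the corresponding
coarse-model experiment, and only ratios and percent changes are
meaningful at desk scale.

## Degenerate inputs and tie-breaks

Weakly stratified or unstable columns: slopes go to the clipped limit
(transport stays bounded); the Rossby-radius diagnostic, which has no
meaningful answer there, errors naming the offending column.  Zero shear:
the Visbeck coefficient falls to its lower clip.  `f = 0` is rejected by
the MLI operator (the channel is off-equator by construction).  `h -> 0`
collapses KPP to the background diffusivity.  Equal-extremum biomass
series: earliest day wins.  Constant biomass series: degenerate, both
phenology days set to 0 with a warning.  Empty percentile samples and
out-of-domain bands error.

## Known limitations

* The zonal collapse means "eddy" always means "parametrized eddy";
  resolved-eddy statistics (and the magnitudes that come with partial
  resolution) are out of reach by design.
* One-way buoyancy coupling: the parametrized eddy flow does not
  restratify the model's own buoyancy field; the seasonal cycle of
  stratification is imposed, not emergent.
* The ecosystem is a single-phytoplankton, single-zooplankton reduction
  with a fixed Fe:C quota; community shifts and variable stoichiometry
  are out of scope.
* Scavenging is linear-above-threshold; ligand dynamics are not modeled.
* Run storage is plain-text CSV/JSON; no NetCDF bindings are used.
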