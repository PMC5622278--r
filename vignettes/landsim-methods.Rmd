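---
title: "The landsim model: processes, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The landsim model: processes, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(landsim)
```

landsim simulates arable and grassland agro-ecosystems on a daily time step
over a grid of cells, coupling a capacity soil water model, RothC-style
organic matter turnover with parallel nitrogen and phosphorus stocks,
mineral N and P dynamics with gaseous and leaching losses, a
light-use-efficiency crop model, and lateral routing of runoff and
dissolved nutrients between cells.  This vignette explains each process,
its assumptions, the parameters that matter, and the choices made where the
design was genuinely open.  All constants live in `landsim_params()` and
`crop_params()` and can be overridden there or through a YAML configuration
(`read_config()`), so nothing numerical is buried in the code.

## Soil water

The profile is three layers (230 mm each by default).  Retention anchors —
volumetric water content at saturation, −5 kPa, −10 kPa (field capacity),
−40 kPa and −1500 kPa (wilting) — come from the continuous HYPRES
pedotransfer regressions for the van Genuchten parameters, with topsoil and
subsoil variants, evaluated from texture, organic matter (taken as TOC ×
1.724, the Van Bemmelen factor) and bulk density.  Inputs outside the
pedotransfer calibration range are clamped with a warning.

Infiltrating water fills each layer to field capacity from the top down;
the excess cascades to the layer below, and outflow from layer 3 is
drainage.  Runoff is generated by capacity excess: water beyond the
slope-reduced surface storage `S = (1 − g/g_max) S_max` plus the remaining
capacity of layer 1 to saturation runs off.  The gradient ceiling `g_max`
defaults to 0.2 (a 20 % slope, a practical ceiling for UK farmland) and
`S_max` to 10 mm.  The source describing the slope-storage rule states the
catchment-scale idea qualitatively; the capacity-excess reading used here
is a deliberate, configurable interpretation — on free-draining loams it
makes surface runoff rare (most storms infiltrate and leave as drainage),
which is the observed behaviour of such soils.

Potential evaporation and transpiration use the Penman formulation of the
LINTUL crop-model lineage, split between soil and canopy by
`exp(−0.5 LAI)`.  Soil evaporation is limited by the water stored above
air-dry in layer 1; air-dry is defined as 0.33 × wilting-point content,
a value also used for the 20 mm surface mixing store of the runoff
chemistry.  Daily potential transpiration is reduced per layer by a
four-branch stress function of water content (unstressed between −5 and
−40 kPa; reduced towards saturation for arable crops; reduced towards
wilting for all, with grass bottoming out at 0.4 and feeling no saturation
stress), weighted by the root fraction per layer, with the squared stress
in the numerator of the layer allocation so that stressed layers
contribute disproportionately little.

Topsoil bulk density is re-derived daily from sand, clay and organic
carbon through a nomogram-style mixing rule: a texture-dependent mineral
packing density combined harmonically with organic matter at 0.224 g cm⁻³.
Thickness is rescaled to conserve soil mass (`δ·BD` invariant), and the
retention anchors are re-evaluated, so adding farmyard manure loosens and
deepens the topsoil.

## Organic carbon, nitrogen and phosphorus

Organic matter sits in four active pools — decomposable plant material
(DPM), resistant plant material (RPM), microbial biomass (BIO) and humus
(HUM) — plus inert organic matter (IOM).  Each pool decomposes first-order
with annual constants 10, 0.3, 0.66 and 0.02 yr⁻¹, modified by a
temperature factor `47.91/(1 + exp(106.06/(T + 18.27)))`, a topsoil
moisture-deficit factor falling from 1 to 0.2 beyond 44.4 % of the maximum
deficit, and a plant-retainment factor (0.6 vegetated, 1.0 bare).
Decomposed carbon splits between CO₂ and (BIO + HUM) by the clay response
`x = 1.67(1.85 + 1.60 e^{−0.0786 clay})` with `x` the CO₂:(BIO+HUM) ratio,
and BIO:HUM fixed at 46:54.  The pools live in the topsoil only and use
layer-1 moisture; this keeps the turnover model within the depth over which
its rate constants were calibrated.

Every pool carries N and P stocks.  BIO and HUM stoichiometry is pinned
(C:N 8.5 for both; C:P 50 and 100), DPM and RPM float with their inputs.
The N mineralised by a day's decomposition is
`Σ_i (Δ_i/ρ_i − B_i/ρ_BIO − U_i/ρ_HUM)`; a positive sum enters the soil as
ammonium, a negative sum immobilises, drawing ammonium before nitrate, and
if the requirement exceeds the mineral N present the whole day's
decomposition is cancelled.  P mineralisation is computed identically with
the C:P ratios; immobilised P draws the available pool first, then the
non-available pool, and does not halt decomposition unless both mineral P
pools are exhausted (a guard that preserves mass balance in that extreme).

Fresh residue splits DPM:RPM 59:41.  Farmyard manure splits 49:49:2 into
DPM:RPM:HUM; since HUM stoichiometry is fixed, the HUM share takes N and P
at the HUM ratios and the remainder goes to DPM and RPM pro-rata carbon.
FYM composition is 25 % dry matter, 40 % C of DM, 250 kg N and 45 kg P per
35 t fresh.

Equilibrium initialisation scales the magnitude of the annual plant input
by bisection until the steady state of the active pools plus IOM matches a
target TOC to 0.001 %.  The steady state for a candidate input is the fixed
point of the affine one-year pool map assembled by running the daily
kernel over a representative year of rate modifiers — equivalent to, but
much faster than, a millennial forward run, and robust under the
stoichiometric coupling because only carbon enters the fixed-point solve;
N and P pools are then set from the equilibrium carbon and the input
ratios.

## Mineral nitrogen

Atmospheric deposition declines linearly from 35 kg N yr⁻¹ in 1966 to
20 kg N yr⁻¹ in 2012 (clamped outside) and arrives evenly through the year
as nitrate; the annual rate is divided by the actual calendar length of
the year, so a leap year receives the same annual total.  Fertiliser
enters ammonium, nitrate or both according to its form.

Runoff chemistry mixes the top 20 mm: surface N is `(20/δ₁)(NH₄ + NO₃)`
and the runoff water carries the fraction `W_run/(W_run + W_surf)` of it,
where the surface water store is the saturation-minus-air-dry capacity of
the top 20 mm.  Nitrate leaches convectively: the flux from a layer is its
concentration times the drainage flux, capped at the pool, cascading
top-down within the day.

Nitrification emits N₂O as `10⁻⁴ · NH₄ · S_pH · (1 − WFPS)` and produces
nitrate as `(NH₄ − N₂O − 0.05) (1 − e^{−0.15 f_T g_M})`.  The temperature
and moisture responses of nitrification are defined in sources outside the
model description, so they are implemented here as configurable saturating
responses normalised to [0, 1]: a Q10-style curve equal to 0.5 at 10 °C
and capped at 1, and a linear function of plant-available water fraction.
The pH response `S_pH` reuses the tent function shared with the P model
(0→1 over pH 0→7, back to 0 at pH 14), the only pH response defined
anywhere in the model family.

Denitrification applies to the top two layers only.  N₂O is
`0.000735 · NO₃ · f(WFPS) · exp(−0.00045 (T − 23.65)²)` with
`f(WFPS) = exp(−0.6151 [ln(WFPS/(1 − WFPS))]² − 1.192)` — natural log and a
squared log-ratio, the symmetric reading that is maximal near mid-range
water-filled pore space; at WFPS = 0.5 all readings coincide.  N₂ is
`0.0052 · NO₃` times the product of two logistic factors,
`σ(0.14975 T − 4)` and `σ(12 (WFPS − 0.62))`; the product-of-logistics
grouping was chosen where the printed expression is ambiguous.  The
temperature width 0.00045 is used as printed even though the narrative
standard deviation quoted alongside it implies a different width; the
printed coefficient is taken as authoritative.  Both gas fluxes are capped
so the nitrate pool cannot go negative.

Crop N uptake is met from nitrate in the rooted layers, pro-rata root
fraction, limited by demand, the pool, and 6 kg N ha⁻¹ d⁻¹.

## Mineral phosphorus

Mineral P is two pools, available and non-available.  Fertiliser splits
80:20 between them.  The equilibrium fraction of total P that is available,
`V`, follows two regressions of Olsen-P on total P (slope 0.113, intercept
−49.3 above the branch junction at ≈476 mg kg⁻¹; 0.0201 and −5.1 below),
read as the ratio form `V = (α P_tot + β)/P_tot` — the only reading that
yields a fraction — and clamped to [0.001, 0.95] because the lower branch
goes negative below ≈254 mg kg⁻¹.  Daily re-equilibration transfers
`λ P_av f_pH` to the non-available pool and `λ P_nonav RRF f_pH` back,
with `RRF = V/(1 − V)` and λ = 0.01 d⁻¹.  The analytic relaxation rate of
an available-P excess is `λ(1 + RRF)`, giving a half-life of ≈65 days at
Broadbalk-like total P (~1050 mg kg⁻¹) — the printed half-life is matched
by the two-pool rate, not by `ln 2/λ` alone, which is how the coexistence
of λ = 0.01 and "≈65 days" is reconciled.  Unit conversion between
kg P ha⁻¹ and mg kg⁻¹ uses the layer soil mass `δ · BD · 10` t ha⁻¹.

Runoff carries the top-20 mm share of mobile P (10 % of available P);
leaching moves solution P (1 % of available P) with the drainage cascade.
Crop uptake is capped at 2 kg P ha⁻¹ d⁻¹.

## Crop and grassland growth

Daily biomass is `dB = Q ε W_rf N_NI P_NI`: intercepted PAR (half the
global radiation through a Beer's-law canopy with extinction coefficient
0.6) times light-use efficiency (3.0 g DM MJ⁻¹ PAR) times the water and
nutrient stress indices.  For grass, ε is additionally scaled by a
radiation ramp (1.0 → 0.33 over 10 → 40 MJ m⁻² d⁻¹) and a temperature ramp
(0 → 1 over 6 → 9 °C).  New biomass is partitioned root/shoot and the shoot
into leaf, stem and storage by DVS-indexed tables of the LINTUL wheat
lineage (kept in `crop_params()`, not in code); grass partitions constantly
and has no storage organ.

Development stage accumulates thermal time above a 0 °C base over stage
durations of 1550 °C d to anthesis and 900 °C d to maturity for wheat,
scaled pre-anthesis by a vernalisation factor (days within −4 to 17 °C
against a 50-day requirement; the photoperiod response is left as a neutral
hook).  These stage durations place anthesis in mid-June and maturity in
early August for autumn sowing under the synthetic SE-England weather.
Grass is capped just below DVS 1 and never flowers.

Before the canopy closes (LAI < 0.75 and DVS < 0.3) leaf area expands
exponentially with thermal time at 0.009 (°C d)⁻¹, representing
sink-limited juvenile growth from seed reserves; without this standard
device a Beer's-law canopy starting from seed mass can never bootstrap
itself through a UK winter.

Roots deepen 12 mm d⁻¹ to a crop maximum, distributed exponentially so
that 98 % of root length lies above the rooting depth.  Nutrient demand is
the gap between maximum and actual organ contents for roots, stems and
leaves (maximum leaf N for wheat `0.046 e^{−1.7 DVS} + 0.014`, grass
0.0425; stem maxima half the leaf; leaf P maxima interpolate
0.0066 → 0.0036 → 0.0009 over DVS 0 → 0.7 → 1).  All uptake happens before
anthesis; storage N and P are filled afterwards by translocation from the
vegetative organs at 3 % of the translocatable stock per day, capped at
grain ceilings of 2.5 % N and 0.35 % P.  The translocation rate is the main
lever between grain nutrient content and late-season canopy collapse
(translocation drains the leaves, lowers the nutrition indices and thereby
accelerates senescence); 0.03 d⁻¹ keeps both within agronomic ranges.

Leaf death combines a background rate with heat (above 30 °C), N-stress and
self-shading (LAI > 4) terms — rate multipliers standing in for functional
forms that live in sources outside the model description, and configurable
for that reason.  Half of the standing dead leaves become litter each day.
Roots die at 2 % d⁻¹ once wheat passes DVS 1.5, and at 1 % d⁻¹ for
established grass.  All dead C, N and P returns to DPM/RPM.  Cutting and
grazing remove aboveground biomass down to a 50 g m⁻² floor; grazing
deposits manure C and N at per-head rates (beef 4.03 kg C and 0.22 kg N
head⁻¹ d⁻¹; dairy 6.45 and 0.35; sheep 0.45 and 0.02) times the stocking
rate, incorporated like FYM.  Harvest converts the storage organ to yield
at 85 % dry matter (t ha⁻¹).

## The landscape grid

Cells carry elevation, area, edge designations (field, ditch, hedgerow,
margin) and 4-neighbour (edge-sharing) links; gradients come from
neighbour elevation differences over the cell spacing.  Each day cells are
processed in descending elevation order (ties broken by id) so runoff and
its solutes cascade through the grid within the day; the alternative —
lagging transfers one cell per day — was rejected because it makes
catchment response depend on grid resolution.  Runoff splits among
strictly-downslope edges proportional to slope; ditch edges compete at the
cell's own gradient (floored at 0.001 so a ditch always captures) and
export water and solutes to the catchment output.  A closed depression
re-infiltrates its runoff.  Dissolved N arriving at a cell joins the
layer-1 nitrate pool (nitrate being the dominant mobile species), P the
available pool.

Within a cell the daily order is: management events; bulk-density and
retention update; deposition; rain partition and runoff (lateral inflow
counting as rain); routing; drainage cascade; soil evaporation; crop
development, growth, uptake and senescence; decomposition and
mineralisation; nitrification; denitrification; leaching.  Surface
processes precede profile transport; transformations precede the leaching
that moves their products.  Catchment aggregation converts ditch capture
(and, where the field-drain flag is set, layer-3 drainage with its
nitrate and solution P) to m³ d⁻¹ and kg d⁻¹ using cell areas.

## Synthetic weather and fixture farms

`synth_weather()` emulates a temperate maritime station record:
sinusoidal annual temperature (mean 9.8 °C, amplitude 6.3 °C, peak near
20 July) with AR(1) daily anomalies; radiation as a cloud-modulated
clearness fraction of the extraterrestrial flux at the given latitude;
rainfall from a two-state Markov occurrence chain (dry→wet 0.3, wet→wet
0.6) with exponential wet-day amounts calibrated to 700 mm yr⁻¹, typical
of SE England; vapour pressure near saturation at the daily minimum; and
log-normal windspeed.  It reproduces seasonal cycles, wet/dry spell
clustering and rain–radiation correlation; it does not reproduce
interannual oscillations, heatwave persistence beyond AR(1) memory, or
frontal storm depth distributions — so passing tests demonstrate correct
process coupling under realistic forcing, not skill against any particular
observed year.

`build_fixture_farm()` supplies ready-to-run configurations: a continuous
winter-wheat plot on a silty clay loam with the classical N ladder
(0–288 kg N ha⁻¹ in steps of 48, P in autumn, or FYM at 35 t ha⁻¹), a
permanent-grassland plot cut in June and November with 96 kg N ha⁻¹ each
spring, a two-cell slope draining to a ditch, and a 21-ha 3 × 3 inclined
plane.  Fixture organic pools start with plant-material stoichiometry near
the long-run residue input (C:N ≈ 30, C:P ≈ 300): pools initialised far
from the input ratio would spend the first simulated decade flushing or
locking up mineral N and obscure the management signal the fixtures exist
to show.

## Numerical choices and degenerate inputs

Mass balances are enforced by construction: every flux is drawn from and
added to explicit pools in the same arithmetic, so daily closure of water,
C, N and P is at floating-point noise (the test suite asserts < 10⁻⁶ mm
and < 10⁻⁹ kg or t per day over ten simulated years).  Gas and leaching
fluxes are capped at their source pools; transpiration at the water above
wilting; evaporation at the water above air-dry.  Zero carrier water means
zero solute flux.  Division-by-zero states (empty canopy, empty pools,
zero potential transpiration) resolve to the neutral element (indices of
1, fluxes of 0).  WFPS is clamped to [0.01, 0.99] inside the log-ratio.
The juvenile leaf expansion is capped so LAI cannot overshoot its
threshold in one step.  Daily first-order decay uses
`1 − exp(−k f/365)`, so a year of unit modifiers compounds exactly to
`exp(−k)`.

## Trade-off optimisation

`optimise_pareto()` couples non-dominated sorting with differential
evolution (rand/1/bin, F = 0.7, CR = 0.9, population 40, 60 generations by
default — the source names the two algorithms but no settings, so standard
values are used).  Offspring join parents and the next generation is
selected front-by-front with crowding-distance tie-breaks, the standard
coupling when the replacement rule is unspecified.  Out-of-bounds
offspring reflect back into range.  Convergence — a qualitative "similar
front each iteration" in the source — is operationalised as relative front
hypervolume stability below 10⁻³ over five consecutive generations, with
exact hypervolume computed for two or three objectives.
`optimise_fertiliser()` exposes the timing and amount of a single N
dressing as decisions against mean annual yield (maximised), nitrate
leached and N₂O (minimised), evaluated over a fixed multi-year weather
sample so the optimisation surface is deterministic.

## Problem sizes used by the test suite

The suite exercises the model at sizes chosen to make every property
observable while keeping a full run of the package's checks comfortably
interactive: kernel oracles on single layers and single days; conservation
audits over one- and ten-year single-cell runs and a multi-month two-cell
run; the fertiliser ladder over four years per rate; the optimiser's toy
problem at population 40 for at most 60 generations and the
simulator-coupled search at reduced budget.  These sizes are the package's
own validation choices; the model itself has no intrinsic limits besides
memory for the daily flux table.

## Known limitations

Ammonia volatilisation and biological N fixation are not modelled (the
grass fixtures therefore understate N inputs under clover-rich swards);
nor are weeds, pests, diseases, snow, preferential flow, channel routing
within ditches, groundwater, or sorption-isotherm P chemistry.  Soil
temperature is approximated by air temperature, which damps and advances
the real subsoil cycle.  Nitrification's temperature and moisture
responses, the leaf-death functional forms and the grazing intake rates
are pragmatic stand-ins for relationships defined outside the model
description, and are configurable.  The wheat parameterisation targets a
generic modern winter wheat; no cultivar tuning is attempted.
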