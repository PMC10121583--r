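---
title: "Carbonate budgets, coral restoration, and keeping pace with sea-level rise"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Carbonate budgets, coral restoration, and keeping pace with sea-level rise}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(reefshield)
```

## The problem

Shallow reef crests dissipate most of the wave energy reaching reef-lined
coasts, and in the western Atlantic those crests were built by the
branching coral *Acropora palmata*. Disease and thermal stress have
reduced its cover to a few percent, so many reefs now erode rather than
accrete, and the gap between the reef surface and rising sea level is
widening — which lets larger waves reach the shore during storms.
`reefshield` implements a desk-scale pipeline for asking whether, and at
what scale, outplanting *A. palmata* could reverse this: census-based
carbonate budgets, coral growth-assay rates, a decadal outplanting cohort
model, a keep-pace comparison against sea-level-rise scenarios, and
post-processing of externally computed shoreline total-water-level (TWL)
tables.

## The carbonate-budget model

A site's budget balances gross carbonate production against four
bioerosion terms:

* **Gross production** `G = Σ_t cover_t × c_t × r_t` over calcifying taxa,
  where `c_t` is the calcification rate at 100% planar cover
  (kg CaCO₃ m⁻² y⁻¹) and `r_t` a rugosity correction (≥ 1, corals only)
  accounting for three-dimensional surface hidden from planar photo
  quadrats. The *A. palmata* pair (10.88 × 3.3309 ≈ 36.24 kg m⁻² y⁻¹
  effective) anchors the table.
* **Parrotfish bioerosion**: per-individual rates by species, 15-mm
  fork-length bin and life phase (g ind⁻¹ y⁻¹) times belt-transect counts,
  converted over the 120 m² belt and averaged across the two belts.
* **Urchin bioerosion**: a test-size allometry `rate = a·size^b`
  (g ind⁻¹ y⁻¹) evaluated at 20-mm bin midpoints, times density, scaled by
  the 0.57 sediment-reingestion factor.
* **Endolithic macro- and microbioerosion**: fixed rates
  (0.4 and 0.27 kg m⁻² y⁻¹) times the dead-coral substratum fraction.

Net production converts to vertical terms through framework density: for
net-positive sites the cover-weighted mean of taxon skeletal densities,
`D_i = Σ (x_n / X_i) d_n`; for net-erosional sites the regional average
1670 kg m⁻³. Framework accretion is `F_i = 1000·net/D_i` (mm y⁻¹), and
reef-accretion potential credits the sediment and void fill seen in
Holocene cores **only when the budget is positive**:

`A_i = F_i (1 + sed/frame + void/frame)`, with sed/void/frame = 33/18/49
(% of linear core depth), i.e. `A_i = F_i × 100/49`. Erosional sites get
no fill credit (`A_i = F_i`): an eroding framework does not accumulate
loose sediment. Elevation change by year *y* is `A_i (y − 2016)/1000` m,
with 2016 the survey datum (84 years to 2100). Budgets are aggregated as
mean ± SE (sample SD/√n) by sector × habitat zone.

Two wordings for the endolithic substrate ("dead coral substratum" for
macroborers, "available substrate" for microborers) are reconciled by
defaulting both to the same dead-coral fraction, with an argument to pass
distinct fractions where the two are scored separately.

### Rate tables are configuration

Only the *A. palmata* calcification/rugosity anchor is an empirical
constant here; the other taxon rates and the parrotfish/urchin allometries
are **documented placeholders** with the right structure, units and
magnitudes, meant to be replaced from a user's own calibration through
`read_rate_table()` (YAML; any omitted block falls back to the defaults:
density 1670 kg m⁻³, reingestion 0.57, macro/micro 0.4/0.27, core
33/18/49). The placeholder parrotfish allometry scales per-individual
erosion with the cube of fork length from a species base rate at 300 mm
(2.5 × 10⁴–2 × 10⁵ g y⁻¹, excavators ≫ scrapers), chosen so that a
typical belt survey yields total bioerosion of 3–4 kg m⁻² y⁻¹ — the
erosion-dominated regime this kind of protected Caribbean reef exhibits.

## Growth assays

Buoyant weights convert to dry skeletal mass by Archimedes' principle,
`m_dry = m_b/(1 − ρ_sw/ρ_sk)` with ρ_sw = 1.023, ρ_sk = 2.93 g cm⁻³
(standard aragonite/seawater values, overridable). Colony footprints are
ellipses from caliper diameters (π/4·d_max·d_min). Calcification is the
first-to-last dry-mass change normalized by planar area and time
(kg m⁻² y⁻¹); the normalizing area defaults to the interval **mean** of
start and end footprints — exact for a constant mass-flux density over a
linearly growing footprint — with `start`/`end` switches. Height and
planar-area extension are plain finite differences (negative allowed:
partial mortality shrinks colonies). Colonies with complete mortality are
excluded from summaries, which are exposed at both colony and station
level since either averaging convention is defensible.

## The outplanting cohort model

A single cohort of N outplants (presets 10⁵, 2.5 × 10⁵, 5 × 10⁵ — about
0.6, 1.5 and 3 colonies m⁻² over the 166,407 m² reef-crest habitat) is
established at 2030 after a 2020–2030 outplanting window. Each decade k
the cohort survives with probability `s_k = s₀·m^(k−1)` (clamped ≤ 1),
with `s₀ = 0.60` — 3% decadal colony survival plus a 55% net decadal
fragmentation gain, 58%, rounded — and m = 1, 0.95 or 1.05 for fixed,
increasing-impact and decreasing-impact mortality. The seventh-decade
endpoints are 44% and 80% survival, so decadal mortality spans 20–56%
across regimes. Colonies grow isometrically in planar area at
196.21 cm² y⁻¹; the ~28 cm² initial branch-tip footprint is deliberately
**excluded** (area = g × elapsed years), which is what makes the model's
decade-end covers close exactly on 8.5/21.2/42.4% at 2050 for the three
cohort sizes. Added cover is `N × Πs_k × area / reef_area`, linear in N,
assuming containment in the habitat and no colony overlap — so it is an
upper envelope at high cover. No sexual reproduction is modelled. A
Monte-Carlo per-colony validator (`mc_population_oracle()`, binomial
decade thinning) checks the deterministic cohort arithmetic.

Restored budgets add ΔC ∈ (0, 0.30] of *A. palmata* cover at the
**measured, uncorrected** calcification rate 29.07 kg m⁻² y⁻¹ — not the
rugosity-corrected census rate 36.24 — as the more conservative choice;
density and the accretion chain are then recomputed. Substrate bioerosion
is unchanged by default (an option deducts the overgrown dead substrate).

The keep-pace verdict compares cumulative accretion with cumulative rise
at 2050 and 2100, margin `A·Δt/1000 − rise`, boundary inclusive. The
bundled scenario set anchors Low ≈ 0.36 m and High ≈ 2.0 m of rise by
2100 (≈ 0.5 m Intermediate-Low, ≈ 1 m Intermediate); the 2050 entries and
Intermediate-High are round interpolations consistent with those anchors,
and the whole table is replaceable configuration. Because budgets omit
storm damage and dissolution, a historic-baseline lower bound is exposed:
the restored-budget chain evaluated at the historic 62% cover, minus the
13.4 mm y⁻¹ maximum accretion observed in Holocene cores; the operative
default offset is 3.08 mm y⁻¹, subtracted from the accretion rate before
projecting the lower-bound elevation.

## TWL post-processing

Shoreline maximum-TWL tables are produced offline by a hydrodynamic wave
model at sea-level offsets {0, 0.2, 0.5, 1.2, 2.0} m and two storm return
periods (10- and 50-year); this package never runs wave physics.
Restoration-adjusted TWLs interpolate the table linearly at
`max(slr − elevation_gain, 0)` with sector-specific gains; the clamp at
the +0.0 scenario exists because the tables contain no
shallower-than-present states, and no extrapolation is allowed outside
the tabulated range (errors, not guesses). Alongshore summaries are mean
± SE over shoreline points; restoration-case uncertainty is the
root-sum-square of the TWL SE and the reef-elevation SE.

## Synthetic data: what it does and does not emulate

`gen_census()`, `gen_growth()` and `gen_twl()` generate the three input
streams with recorded ground truth: multinomial point counts per image
over a category simplex, Poisson fish/urchin counts per transect, linear
colony growth with Gaussian observation noise and survival thinning, and
TWL tables linear in sea level with a fixed alongshore point effect
(monotone by construction). All randomness flows through one explicit
seed per generator call; fixed seed ⇒ identical output. An `exact` mode
replaces draws with deterministic expectations (largest-remainder point
allocation, rounded Poisson means) so budgets can be checked against
closed-form oracles at 1e-9.

Defaults reflect the emulated campaign: 54 sites in a 2 sector × 3
habitat × 9 site layout, 10–13 images × 75 points, two 120 m² belts,
true growth rates 29.07 kg m⁻² y⁻¹ / 6.99 cm y⁻¹ / 196.21 cm² y⁻¹, and
145/71 northern/southern shoreline points. The default zone simplex is
sparse in coral (8%) with an enriched (~15% coral) southern reef crest in
the analysis scripts, so the synthetic reef is erosion-dominated with a
marginally positive southern crest. What the generator does **not**
emulate: spatial autocorrelation of real benthic mosaics, observer error
in point classification, size-structured fish/urchin populations, storm
pulses in growth records, and any hydrodynamic realism beyond
monotonicity — so green tests demonstrate the pipeline's arithmetic and
contracts, not field realism.

## Numerical choices and degenerate inputs

* Cover is a fraction everywhere internally; percent appears only at I/O
  edges (prevents double-scaling).
* Size bins are labelled by lower edge, closed-open [lower, lower+width);
  rates are evaluated at bin midpoints.
* A zero-fish site contributes 0; a single-transect site errors unless
  `lenient = TRUE` (then warns and uses the one belt).
* Zero coral cover with positive net production is an error (density
  undefined); zero total points is an error.
* `net = 0` takes the erosional branch (no fill credit), making A = F = 0.
* TWL interpolation is exact at nodes; ±1e-12 tolerance at range edges.
* The zonal bathymetry tool works on plain matrices and ESRI ASCII grids
  (elevation positive up, NODATA respected); cells labelled `none`/`NA`
  pass through unchanged.

## Problem sizes

The bundled analysis runs 54 synthetic sites, 30 assay colonies over 5
visits, 216 shoreline points × 2 storms × 5 offsets, 200 Monte-Carlo
cohort replicates, and six restoration increments over the 18 reef-crest
sites — a few seconds end to end; the same code scales linearly in sites
and points.

## Known limitations

The cohort model has no recruitment, no density dependence and no overlap
correction, so high-cover projections are optimistic by construction.
Placeholder bioerosion rate values must be replaced for site-specific
work. The keep-pace comparison treats accretion as constant over the
projection window. TWL adjustment inherits every bias of the upstream
wave model and cannot see alongshore redistribution of energy caused by
the elevation changes themselves.
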