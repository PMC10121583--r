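# reefshield

Carbonate budgets, coral-restoration projections, and storm-driven
flooding assessment for reef-lined coasts.

Degraded western Atlantic reef crests — once built to sea level by the
branching coral *Acropora palmata* — are now eroding, and the growing gap
between reef surface and rising sea level lets larger storm waves reach
the shore. `reefshield` is for reef ecologists and coastal-hazard
analysts who want to quantify that feedback and ask what scale of
*A. palmata* outplanting could reverse it. It implements:

* **census-based carbonate budgets**: gross production
  `G = Σ cover_t·c_t·r_t` (calcification rates with rugosity correction),
  minus parrotfish, urchin, and endolithic macro/micro bioerosion; net
  production converts to reef-accretion potential via framework density
  `D_i = Σ (x_n/X_i)d_n` and, for net-positive sites only, the
  sediment/void core credit `A_i = F_i(1 + sed/frame + void/frame)`
  with sed/void/frame = 33/18/49;
* **growth assays**: buoyant weight → dry mass
  (`m_b/(1 − ρ_sw/ρ_sk)`), elliptical footprints, calcification and
  extension rates per colony;
* **a decadal outplanting cohort model**: planar growth 196.21 cm² y⁻¹
  from 2030, decadal survival `s_k = 0.60·m^(k−1)` (m = 1/0.95/1.05),
  added cover `N·Πs_k·area/166 407 m²`;
* **keep-pace assessment** of accretion against five sea-level-rise
  scenarios, with a historic-baseline lower-uncertainty offset
  (3.08 mm y⁻¹);
* **total-water-level post-processing**: linear interpolation of
  externally computed shoreline TWL tables at restoration-adjusted sea
  levels `max(slr − gain, 0)`, clamped at the +0.0 scenario, with
  root-sum-square uncertainties;
* **synthetic survey generators** with recorded ground truth for all
  three input streams.

## Worked example

```r
library(reefshield)

# project a 500,000-colony outplanting cohort under fixed mortality
traj <- project_cover(population_scenario(500000))
round(100 * traj$added_cover, 1)
#> [1] 35.4 42.4 38.2 30.6 22.9 16.5 11.6
traj$year[which.max(traj$added_cover)]
#> [1] 2050
```

Added cover peaks at **42.4%** in 2050 (21.2% and 8.5% for 250k and 100k
cohorts) and declines afterwards as mortality outruns colony growth;
under the decreasing-impact regime the 500k cohort still holds 32.2% in
2100. A budget under that restoration:

```r
rates <- default_rate_table()
# one all-abiotic demonstration site: 75 points, all dead coral
demo <- site_census(
  "demo", "southern", "reef_crest",
  data.frame(image = 1, category = "dead_coral", count = 75),
  data.frame(transect = 1:2, species = "sparisoma_viride",
             size_bin = 150, phase = "initial", count = c(0, 0)),
  data.frame(species = character(), size_bin = numeric(),
             count = numeric())
)
site <- site_budget(demo, rates)
round(site$accretion, 2)            # eroding at -0.40 mm/y
#> [1] -0.4
r <- restored_budget(site, 0.30, rates)
round(r$accretion, 2)               # +30% A. palmata at 29.07 kg/m2/y
#> [1] 11.33
keep_pace(r$accretion, slr_scenarios(), target_years = 2100)$keeps_pace
#> [1]  TRUE  TRUE FALSE FALSE FALSE
```

The restored site keeps pace with the Low and Intermediate-Low rise
scenarios by 2100 and falls behind the higher ones.

## The analysis workflow

Numbered scripts under `analysis/` run the full study on synthetic data
and write tables to `results/`:

| script | what it does |
| --- | --- |
| `01_simulate_survey.R` | 54-site census (2 sectors × 3 habitats × 9), 30-colony growth assay, 216-point TWL table |
| `02_carbonate_budgets.R` | per-site budgets, zone summaries, projected 2100 bathymetry grid |
| `03_coral_growth.R` | calcification/extension rates and species summaries |
| `04_restoration_projection.R` | cohort trajectories, +5…+30% restored budgets, keep-pace table, historic lower bound |
| `05_flooding.R` | restoration-adjusted TWLs and alongshore summaries |

```sh
for s in analysis/0*.R; do Rscript "$s"; done
```

On the bundled synthetic reef this prints, among other things, a mean
reef-accretion potential of −1.06 mm y⁻¹ (±0.14 SE) over 54 sites with
48 of 54 net-erosional, a positive mean only on the southern reef crest,
and a ~0.8 m mean reduction in 50-year-storm total water levels under
the +30% restoration scenario at high sea-level rise.

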