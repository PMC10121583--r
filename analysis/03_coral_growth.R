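#!/usr/bin/env Rscript

# Step 3: growth-assay records -> calcification and extension rates.
#
# Buoyant weights are converted to dry skeletal mass (Archimedes, with
# aragonite and seawater densities), planar footprints to elliptical
# areas, and per-colony first-to-last differences to calcification
# (kg m-2 y-1, normalized by interval-mean footprint), height extension
# (cm y-1) and planar-area extension (cm2 y-1). Colonies that died are
# excluded from species summaries.

library(reefshield)

records <- read_growth_records("results/growth_records.csv")
rates <- growth_rates(records)
utils::write.csv(rates, "results/colony_growth_rates.csv",
                 row.names = FALSE)

by_colony <- summarise_growth(rates, level = "colony")
by_station <- summarise_growth(rates, level = "station")
utils::write.csv(by_colony, "results/growth_summary_colony.csv",
                 row.names = FALSE)
utils::write.csv(by_station, "results/growth_summary_station.csv",
                 row.names = FALSE)

cat(sprintf("colonies with usable rate intervals: %d of %d\n",
            nrow(rates), length(unique(records$colony_id))))
cat(sprintf("A. palmata calcification: %.2f (+/- %.2f SE) kg m-2 y-1\n",
            by_colony$calcification_mean, by_colony$calcification_se))
cat(sprintf("height extension: %.2f (+/- %.2f SE) cm y-1\n",
            by_colony$height_rate_mean, by_colony$height_rate_se))
cat(sprintf("planar-area extension: %.2f (+/- %.2f SE) cm2 y-1\n",
            by_colony$area_rate_mean, by_colony$area_rate_se))
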