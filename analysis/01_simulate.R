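#!/usr/bin/env Rscript
# Stage 1: generate the study inputs.
# A table of 13 paired ammonium/nitrate labelling sites (with plot-level
# isotope measurements behind it) and a coarse gridded world: nine predictor
# layers, forest cover, four deposition maps, and soil C/N layers.

library(ndepsink)
dir.create("results", showWarnings = FALSE)

seed <- 20260921L

sites <- make_site_table(site_generator_config(seed = seed))
write_site_csv(sites, "results/sites.csv")
cat(sprintf("site table: %d sites x 2 forms -> results/sites.csv\n",
            length(unique(sites$site_id))))
cat("cross-site mean recoveries (%):\n")
means <- aggregate(cbind(rec_plant, rec_org, rec_min, loss) ~ form,
                   sites, mean)
means[, -1] <- round(means[, -1], 1)
print(means)

meas <- make_plot_measurements(sites, n_plots = 3, seed = seed + 1L)
write.csv(meas, "results/plot_measurements.csv", row.names = FALSE)
cat(sprintf("plot-level measurements: %d rows -> results/plot_measurements.csv\n",
            nrow(meas)))

world <- make_world(world_generator_config(seed = seed + 2L))
write_grid_stack(world$grid, "results/world",
                 provenance = list(seed = seed + 2L,
                                   package = "ndepsink"))
# downstream stages regenerate deposition maps and C/N layers from this seed
cat(sprintf("world: %d x %d cells, %d deposition maps, %d wood C/N sets -> results/world/\n",
            length(world$grid$lat), length(world$grid$lon),
            length(world$deposition), length(world$wood_cn_sets)))
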