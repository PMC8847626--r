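#!/usr/bin/env Rscript
# Stage 4: upscale retention fractions over the gridded world.
# Applies the selected relations at every cell under the chained allocation
# (loss and organic layer first, the remainder split between plant and
# mineral soil, woody share within plant) and writes per-form fraction maps.
# The per-pool regression mode is run alongside for comparison.

library(ndepsink)

seed <- 20260921L
sites <- read_site_csv("results/sites.csv")
world <- make_world(world_generator_config(seed = seed + 2L))
mask <- forest_mask(world$grid, 0.2)
cat(sprintf("forest cells (cover > 0.2): %d of %d\n", sum(mask),
            length(mask)))

for (mode in c("chained", "regression")) {
  maps <- upscale_retention(sites, world$grid, mode = mode,
                            selection = "subset")
  for (form in c("NHx", "NOy")) {
    m <- maps[[form]]
    dir <- sprintf("results/retention_%s_%s", mode, form)
    write_grid_stack(retention_maps_as_stack(m, world$grid), dir,
                     provenance = list(mode = mode, form = form,
                                       seed = seed))
    tot <- m$frac_plant + m$frac_org + m$frac_min + m$frac_loss
    cat(sprintf(
      "%s %s: plant %5.1f%%, org %5.1f%%, min %5.1f%%, loss %5.1f%% (forest means); max |sum-100| = %.1e; %d cells extrapolate\n",
      mode, form, mean(m$frac_plant[mask]), mean(m$frac_org[mask]),
      mean(m$frac_min[mask]), mean(m$frac_loss[mask]),
      max(abs(tot - 100)), sum(attr(m, "extrapolation"))))
  }
}
cat("maps -> results/retention_<mode>_<form>/\n")
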