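#!/usr/bin/env Rscript
# Step 1: generate the synthetic study inputs.
#
# Emulates the three data streams the pipeline consumes: (a) single-particle
# SEM/EDX tables for the coarse-mode impactor stages above and below the
# canopy, (b) ESEM hydration frame pairs and STXM transmission-map pairs at
# the measured growth factors, (c) daily and hourly spore / sea-salt
# concentration series for the wet and dry seasons plus a small grid.
# Data-scale intermediates (particle tables, series, images) go to
# scratch/ and are regenerated on demand; later steps write their small
# summary tables to results/.

library(sporesalt)

dir.create("results", showWarnings = FALSE)
dir.create("scratch", showWarnings = FALSE)

message("-- particle tables (n = 2000 each) --")
tabs <- list(
  coarse_above = generator_config(2000, default_mixture("coarse"),
                                  canopy = "above", period = "night",
                                  seed = 101),
  below_canopy = generator_config(2000, default_mixture("below_canopy"),
                                  canopy = "below", period = "night",
                                  seed = 102)
)
for (nm in names(tabs)) {
  pt <- gen_particle_table(tabs[[nm]])
  write.csv(pt, file.path("scratch", paste0("particles_", nm, ".csv")),
            row.names = FALSE)
  message(sprintf("  %s: %d particles, %d on grid edge", nm, nrow(pt),
                  sum(pt$on_grid_edge)))
}

message("-- hydration and transmission image pairs --")
for (gf in c(2.4, 1.1)) {
  pr <- gen_hydration_pair(gf, noise_sd = 0.01, seed = 103)
  write_hydration_pair(pr,
    sprintf("scratch/esem_gf%.1f_dry.tif", gf),
    sprintf("scratch/esem_gf%.1f_wet.tif", gf))
}
message("  ESEM pairs written for diameter GFs 2.4 and 1.1 (94% RH)")
for (mr in c(3.6, 1.5)) {
  sx <- gen_stxm_pair(mr, seed = 104)
  saveRDS(sx, sprintf("scratch/stxm_mr%.1f.rds", mr))
}
message("  STXM pairs written for mass ratios 3.6 and 1.5 (96% RH)")

message("-- concentration series --")
wet <- gen_concentration_series(series_config(181, "wet", hourly = TRUE,
                                              seed = 105))
dry <- gen_concentration_series(series_config(184, "dry", hourly = TRUE,
                                              seed = 106))
write_series(wet, "scratch/series_wet.csv")
write_series(dry, "scratch/series_dry.csv")
message(sprintf("  wet season: %d days, sea-salt median %.3f ug/m3", 181,
                median(wet$seasalt_ugm3)))
message(sprintf("  dry season: %d days, sea-salt median %.3f ug/m3", 184,
                median(dry$seasalt_ugm3)))

grid <- gen_grid_series(9, series_config(181, "wet", seed = 107),
                        gradient = c(0.5, 0.5, 1, 1, 1, 2, 2, 4, 4))
write_series(grid, "scratch/series_grid.csv")
message("  9-cell grid with a 0.5-4x sea-salt gradient written")
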