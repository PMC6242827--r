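#!/usr/bin/env Rscript
# Step 3: sodium mass carried by individual fungal spores.
#
# Derives the population Na dry-mass fraction from the mean spore carbon
# content and the 4:1 C:Na mass ratio (0.51 / 4 = 0.1275, i.e. ~13%),
# computes per-particle Na masses for the spore-flagged particles of the
# below-canopy table (measured per-particle Na weight where available,
# population default otherwise), and tests the size dependence of the Na
# weight fraction.

library(sporesalt)

params <- spore_na_params()
w_na <- spore_na_weight_fraction(params$carbon_wt_mean, params$c_to_na_ratio)
message(sprintf("population Na dry-mass fraction: %.4f (~%d%%)",
                w_na, round(100 * w_na)))
message(sprintf("carbon-range bracket: %.3f - %.3f",
                spore_na_weight_fraction(params$carbon_wt_range[1], 4),
                spore_na_weight_fraction(params$carbon_wt_range[2], 4)))
message(sprintf("mass of a 4 um spore at unit density: %.2f pg",
                spore_mass(4, params$density_g_cm3)))

pt <- read.csv("scratch/particles_below_canopy.csv", stringsAsFactors = FALSE)
pt <- exclude_edge_particles(pt, quiet = TRUE)
res <- read.csv("scratch/classified_below_canopy.csv",
                stringsAsFactors = FALSE)
spores <- pt[res$is_fungal_spore, ]

# measured per-particle Na weight fraction from the composition columns
af <- spores[, grep("^af_", names(spores))]
na_wt <- apply(af, 1L, function(a) {
  a <- unlist(a); a <- a[a > 0]
  names(a) <- sub("^af_", "", names(a))
  unname(atomic_to_weight(a / sum(a))["Na"])
})
na_pg <- particle_na_mass(spores$diameter_um, na_wt, default_na_wt = w_na)
out <- data.frame(particle_id = spores$particle_id,
                  diameter_um = spores$diameter_um,
                  na_wt = na_wt, na_mass_pg = na_pg)
write.csv(out, "scratch/spore_na_mass.csv", row.names = FALSE)
message(sprintf("%d spores: median Na mass %.3f pg, total %.1f pg",
                nrow(out), median(na_pg), sum(na_pg)))

tr <- na_fraction_size_trend(spores$diameter_um, na_wt)
message(sprintf("size trend of Na weight fraction: %s (rho = %.3f, p = %.3g)",
                tr$trend, tr$spearman_rho, tr$p_value))
write.csv(tr$binned, "results/spore_na_size_trend.csv", row.names = FALSE)
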