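# sporesalt

Coarse aerosol particles rich in mixed sodium salts are ubiquitous over the
central Amazon basin and are usually ascribed to marine aerosol carried in
from the Atlantic. `sporesalt` implements the desk-scale computational
chain behind the competing attribution — that locally emitted **fungal
spores** are a major source of that sodium — for atmospheric chemists and
bioaerosol researchers who want the single-particle statistics, the
hygroscopicity analysis and the sodium budget in one tested, reproducible
package.

Four analysis stages, each backed by a synthetic-data generator so the
whole pipeline runs without external data:

1. **Single-particle classification** — rule-based typing of SEM/EDX
   records (atomic fractions + morphology) into Na-rich, dust, mixed
   biological-dust, sulfate, carbonaceous and other, plus a fungal-spore
   flag (spherical/rod-like/spheroidal, 1–6 µm, carbonaceous with a
   phosphorus marker) and a sodium-containing flag (Na ≥ 3 wt%). Group
   number fractions carry binomial standard errors √(p(1−p)/n).
2. **Spore sodium content** — w_Na = w_C / r with mean carbon content
   w_C = 0.51 and C:Na mass ratio r = 4, giving 0.1275 (~13% of dry mass);
   per-spore sodium mass m_Na = (π/6) d³ ρ · w_Na.
3. **Hygroscopic growth** — area growth factor as the wet/dry ratio of
   area-equivalent diameters d = 2√(A/π) from segmented ESEM frame pairs;
   mass growth factor as the wet/dry ratio of integrated optical density
   OD = −ln(I/I₀) from STXM transmission maps at the oxygen edge.
4. **Sodium budget** — per-step spore contribution
   f = p·w_s·C_spore / (p·w_s·C_spore + w_m·C_seasalt) with w_s = 0.13,
   w_m = 0.30, p = 0.70 (sensitivity variants 0.30/0.50), factor-of-10/2
   perturbation bounds, day/night splits (night = 18:00–06:00), and the
   percentage of days with f ≥ 50%.

## Worked example

```r
library(sporesalt)

# a 2000-particle synthetic coarse-mode (1.0-3.2 um) table, classified
cfg <- generator_config(n_particles = 2000, seed = 11)
pt  <- exclude_edge_particles(gen_particle_table(cfg), quiet = TRUE)
res <- classify_particles(pt)
mean(res$composition_class == "na_rich")
#> [1] 0.4731707

# growth factors recovered from synthetic hydration imagery
area_growth_factor(gen_hydration_pair(2.4, noise_sd = 0, seed = 2))$gf_area
#> [1] 2.4002
sx <- gen_stxm_pair(3.6)
mass_growth_factor(sx$dry, sx$wet)$gf_mass
#> [1] 3.6

# sodium budget on a synthetic hourly wet-season series
s <- gen_concentration_series(series_config(n_days = 181, hourly = TRUE,
                                            seed = 3))
sodium_budget(s)
#> Sodium budget (wet season):
#>   mean spore contribution: 71.3% (bounds 20.2-97.1%)
#>   days with contribution >= 50%: 82.9%
#>   diagnostic fraction-of-mean-masses: 0.684
```

The classified Na-rich fraction (47.3%) recovers the configured 48%
coarse-mode mixture within binomial error; the growth factors recover the
configured 2.4 (area, 94% RH) and 3.6 (mass, 96% RH) to pixelation and
integration accuracy; the budget line reads as "on this series, sodium-rich
spores carry ~71% of particulate sodium on average, 20–97% under the
factor-of-10/2 concentration perturbations, and exceed half the sodium on
83% of days". Budget values computed on synthetic series characterize the
generator's calibration, not measured atmospheric fractions.

## The analysis workflow

Numbered drivers under `analysis/` run the full study on synthetic inputs
and write tables to `results/`:

```sh
Rscript analysis/01_simulate.R        # particle tables, image pairs, series
Rscript analysis/02_classify.R        # classes, fractions, size distributions
Rscript analysis/03_sodium_content.R  # 13% derivation, per-spore Na mass
Rscript analysis/04_hygroscopicity.R  # area + mass growth factors
Rscript analysis/05_budget.R          # seasonal budgets, bounds, diel, grid
```

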