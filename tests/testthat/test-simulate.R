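test_that("generator output is byte-identical under a fixed seed", {
  cfg <- generator_config(n_particles = 50, seed = 13)
  expect_identical(gen_particle_table(cfg), gen_particle_table(cfg))
  p1 <- gen_hydration_pair(1.8, noise_sd = 0.02, seed = 13)
  p2 <- gen_hydration_pair(1.8, noise_sd = 0.02, seed = 13)
  expect_identical(p1, p2)
  s1 <- gen_stxm_pair(2.5, seed = 13, noise_sd = 0.01)
  s2 <- gen_stxm_pair(2.5, seed = 13, noise_sd = 0.01)
  expect_identical(s1, s2)
  cfs <- series_config(n_days = 30, seed = 13)
  expect_identical(gen_concentration_series(cfs),
                   gen_concentration_series(cfs))
  expect_identical(gen_grid_series(3, cfs), gen_grid_series(3, cfs))
})

test_that("degenerate single-class mixture yields spore-like particles", {
  cfg <- generator_config(n_particles = 10,
                          mixture = c(fungal_spore = 1.0), seed = 1)
  pt <- gen_particle_table(cfg)
  expect_equal(nrow(pt), 10)
  expect_true(all(pt$morphology %in% c("spherical", "rod-like", "spheroidal")))
  expect_true(all(pt$diameter_um >= 1 & pt$diameter_um <= 6))
  expect_equal(pt$diameter_um, 2 * sqrt(pt$area_um2 / pi))
  # atomic fractions sum to 1 per particle
  af <- as.matrix(pt[, grep("^af_", names(pt))])
  expect_equal(unname(rowSums(af)), rep(1, 10), tolerance = 1e-9)
})

test_that("invalid generator configurations are rejected", {
  expect_error(generator_config(mixture = c(na_rich = 0.6, dust = 0.39)),
               "sum to 1")
  cfg <- generator_config(mixture = c(unobtainium = 1.0))
  expect_error(gen_particle_table(cfg), "unknown class")
  expect_error(gen_hydration_pair(0.9), ">= 1")
  expect_error(series_config(spore_lognormal = c(-1, 2)), "positive")
})

test_that("classifier recovers configured mixture fractions within 3 SE", {
  cfg <- generator_config(n_particles = 2000, seed = 17)
  pt <- exclude_edge_particles(gen_particle_table(cfg), quiet = TRUE)
  res <- classify_particles(pt)
  n <- nrow(res)
  for (cls in c("na_rich", "dust", "sulfate", "carbonaceous")) {
    p_cfg <- unname(cfg$mixture[cls])
    p_obs <- mean(res$composition_class == cls)
    se <- sqrt(p_cfg * (1 - p_cfg) / n)
    expect_lt(abs(p_obs - p_cfg), 3 * se)
  }
  # spore flag recovers the configured fungal fraction
  p_spore <- unname(cfg$mixture["fungal_spore"])
  se_spore <- sqrt(p_spore * (1 - p_spore) / n)
  expect_lt(abs(mean(res$is_fungal_spore) - p_spore), 3 * se_spore)
})

test_that("concentration series honor their configured structure", {
  # geometric SD 1 and no scavenging: constant series
  cfg0 <- series_config(n_days = 20, spore_lognormal = c(1.0, 1),
                        seasalt_lognormal = c(0.30, 1),
                        scavenging_prob = 0, seed = 3)
  s0 <- gen_concentration_series(cfg0)
  expect_equal(s0$spore_ugm3, rep(1.0, 20))
  expect_equal(s0$seasalt_ugm3, rep(0.30, 20))
  # degenerate series: every daily budget fraction identical
  f <- sodium_fraction(s0$spore_ugm3, s0$seasalt_ugm3)
  expect_equal(length(unique(round(f, 12))), 1L)
  # positivity and geometric-mean recovery within 3 SE on the log scale
  cfg <- series_config(n_days = 400, spore_lognormal = c(1.0, 1.8),
                       scavenging_prob = 0, seed = 23)
  s <- gen_concentration_series(cfg)
  expect_true(all(s$spore_ugm3 > 0 & s$seasalt_ugm3 > 0))
  se_log <- log(1.8) / sqrt(400)
  expect_lt(abs(mean(log(s$spore_ugm3)) - log(1.0)), 3 * se_log)
  # wet-season sea salt sits below dry-season sea salt (same base seed)
  wet <- gen_concentration_series(series_config(365, "wet", seed = 4))
  dry <- gen_concentration_series(series_config(365, "dry", seed = 4))
  expect_lt(median(wet$seasalt_ugm3), median(dry$seasalt_ugm3))
})

test_that("hourly series carry the configured nighttime spore enhancement", {
  cfg <- series_config(n_days = 10, hourly = TRUE, diurnal_amplitude = 2,
                       spore_lognormal = c(1, 1), scavenging_prob = 0,
                       seed = 5)
  s <- gen_concentration_series(cfg)
  expect_equal(nrow(s), 240)
  night <- s$hour >= 18 | s$hour < 6
  expect_equal(mean(s$spore_ugm3[night]) / mean(s$spore_ugm3[!night]), 2)
  # daily mean preserved by the diurnal reweighting
  expect_equal(as.numeric(tapply(s$spore_ugm3, s$date, mean)), rep(1, 10))
})

test_that("grid series apply the sea-salt gradient per cell", {
  cfg <- series_config(n_days = 120, spore_lognormal = c(1, 1.6), seed = 6)
  g <- gen_grid_series(4, cfg, gradient = c(1, 1, 2, 2))
  expect_setequal(unique(g$cell_id), 1:4)
  # single cell reduces to the plain generator
  g1 <- gen_grid_series(1, cfg)
  s1 <- gen_concentration_series(cfg, cell_id = 1L)
  expect_identical(g1, s1)
  # cells with doubled sea salt show a lower >= 50%-days statistic
  gm <- grid_map(g, budget_params(), threshold = 0.5)
  expect_lt(mean(gm$pct_days[gm$cell_id %in% 3:4]),
            mean(gm$pct_days[gm$cell_id %in% 1:2]))
})

test_that("spore number-to-mass conversion uses the emission-size sphere", {
  expect_equal(mass_per_spore_pg(4, 1), 33.51, tolerance = 1e-4)
  expect_equal(mass_per_spore_pg(4, 1), pi / 6 * 4^3)
})
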