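# hand-built weight-fraction vectors for precedence checks
w_narich <- c(Na = 0.20, Cl = 0.15, C = 0.40, O = 0.25)
w_dust <- c(Al = 0.06, Si = 0.08, Fe = 0.02, O = 0.84)
w_sulf <- c(S = 0.12, O = 0.87, Na = 0.01)
w_spore <- c(C = 0.55, N = 0.05, O = 0.28, P = 0.01, K = 0.11)

test_that("composition classes follow the precedence rules on hand cases", {
  expect_identical(assign_composition_class(w_narich), "na_rich")
  expect_identical(assign_composition_class(w_dust), "dust")
  expect_identical(assign_composition_class(w_sulf), "sulfate")
  expect_identical(assign_composition_class(c(C = 0.7, O = 0.25, N = 0.05)),
                   "carbonaceous")
  # biological matrix with crustal traces outranks dust
  w_mix <- c(C = 0.40, N = 0.05, O = 0.30, P = 0.01, Al = 0.05, Si = 0.12,
             Fe = 0.02, K = 0.05)
  expect_identical(assign_composition_class(w_mix), "mixed_bio_dust")
  # bare Si without Al/Fe corroboration is substrate background, not dust
  w_si <- c(Si = 0.30, C = 0.40, O = 0.30)
  expect_identical(assign_composition_class(w_si), "other")
  # Cu is stripped before the rules run
  w_cu <- c(Na = 0.10, Cl = 0.05, C = 0.20, O = 0.15, Cu = 0.50)
  expect_identical(assign_composition_class(w_cu), "na_rich")
})

test_that("sodium-containing flag sits exactly at the 3 wt% detection limit", {
  expect_true(flag_sodium_containing(c(Na = 0.031, C = 0.969)))
  expect_false(flag_sodium_containing(c(Na = 0.029, C = 0.971)))
  expect_false(flag_sodium_containing(c(C = 1.0)))
  # monotone in Na weight fraction
  na_grid <- seq(0, 0.2, by = 0.01)
  flags <- vapply(na_grid, function(na) {
    flag_sodium_containing(c(Na = na, C = 1 - na))
  }, logical(1))
  expect_true(all(diff(flags) >= 0))
})

test_that("fungal-spore flag gates on morphology, size and composition", {
  expect_true(flag_fungal_spore("spherical", 3, w_spore))
  expect_false(flag_fungal_spore("spherical", 0.8, w_spore))   # size gate
  expect_false(flag_fungal_spore("spherical", 6.5, w_spore))
  expect_false(flag_fungal_spore("irregular", 3, w_spore))     # morphology
  expect_false(flag_fungal_spore("spherical", 3, w_dust))      # composition
  no_p <- c(C = 0.55, N = 0.05, O = 0.28, K = 0.12)
  expect_false(flag_fungal_spore("spherical", 3, no_p))        # P marker
})

test_that("increasing Na moves a particle toward na_rich, never away", {
  set.seed(7)
  for (i in 1:30) {
    els <- c("C", "N", "O", "Al", "Si", "S", "Cl", "K", "Fe", "P")
    base <- runif(length(els))
    names(base) <- els
    was_na_rich <- FALSE
    for (na in seq(0, 0.9, by = 0.1)) {
      w <- c(base / sum(base) * (1 - na), Na = na)
      cls <- assign_composition_class(w)
      if (was_na_rich) expect_identical(cls, "na_rich")
      was_na_rich <- cls == "na_rich"
    }
  }
})

test_that("classification is total, deterministic and permutation-equivariant", {
  pt <- gen_particle_table(generator_config(n_particles = 300, seed = 5))
  res <- classify_particles(pt)
  expect_equal(nrow(res), 300)
  expect_true(all(res$composition_class %in%
    c("na_rich", "mixed_bio_dust", "dust", "sulfate", "carbonaceous", "other")))
  expect_identical(res, classify_particles(pt))
  perm <- sample(nrow(pt))
  res_perm <- classify_particles(pt[perm, ])
  expect_identical(res_perm$composition_class, res$composition_class[perm])
  expect_identical(res$sodium_salt_particle, res$is_sodium_containing)
})

test_that("edge-particle exclusion removes exactly the flagged rows", {
  pt <- data.frame(particle_id = sprintf("p%03d", 1:100),
                   on_grid_edge = rep(c(TRUE, FALSE), c(7, 93)))
  expect_equal(nrow(exclude_edge_particles(pt, quiet = TRUE)), 93)
  pt$on_grid_edge <- FALSE
  expect_identical(exclude_edge_particles(pt, quiet = TRUE), pt)
  pt$on_grid_edge <- TRUE
  expect_equal(nrow(exclude_edge_particles(pt, quiet = TRUE)), 0)
})

test_that("group fractions carry binomial standard errors", {
  res <- data.frame(
    grp = "below",
    cls = rep(c("bio", "rest"), c(360, 240)))  # p = 0.6, n = 600
  out <- group_number_fractions(res, "grp", class_col = "cls")
  bio <- out[out$class == "bio", ]
  expect_equal(bio$fraction, 0.6)
  expect_equal(bio$standard_error, sqrt(0.6 * 0.4 / 600))
  expect_equal(bio$standard_error, 0.02, tolerance = 1e-9)
  # single-class group: fraction 1, SE 0
  one <- group_number_fractions(data.frame(g = "a", cls = rep("x", 10)),
                                "g", class_col = "cls")
  expect_equal(one$fraction, 1)
  expect_equal(one$standard_error, 0)
})

test_that("size distributions conserve counts and recover the generator mode", {
  cfg <- generator_config(n_particles = 800,
                          mixture = c(fungal_spore = 1), seed = 9)
  pt <- gen_particle_table(cfg)
  res <- classify_particles(pt)
  edges <- c(0.5, 1, 1.8, 2.5, 3.5, 5, 7, 10)
  for (cls in unique(res$composition_class)) {
    h <- size_distribution(pt, res, cls, edges)
    in_range <- sum(pt$diameter_um >= edges[1] & pt$diameter_um <= edges[8] &
                      res$composition_class == cls)
    expect_equal(sum(h$count), in_range)
  }
  # spores generated at median 3 um: histogram mode in the bin holding 3 um
  h_all <- size_distribution(pt, res, res$composition_class[1], edges)
  pooled <- hist(pt$diameter_um, breaks = edges, plot = FALSE)$counts
  expect_equal(which.max(pooled), findInterval(3.0, edges))
  # empty class yields a zero histogram
  h0 <- size_distribution(pt, res, "no_such_class", edges)
  expect_true(all(h0$count == 0))
})
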