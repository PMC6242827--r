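# hand-computed single-step oracle: C_spore = 1.0, C_seasalt = 0.30,
# defaults p_rich = 0.7, w_spore = 0.13, w_seasalt = 0.30:
#   numerator 0.7*0.13*1.0 = 0.091, denominator 0.091 + 0.09 = 0.181
one_step <- data.frame(date = as.Date("2015-01-01"), hour = NA_integer_,
                       cell_id = 1L, spore_ugm3 = 1.0, seasalt_ugm3 = 0.30,
                       season = "wet")

test_that("sodium fraction matches the hand-computed single-step oracle", {
  expect_equal(sodium_fraction(1.0, 0.30), 0.091 / 0.181, tolerance = 1e-9)
  expect_equal(sodium_fraction(1.0, 0.30), 0.5028, tolerance = 1e-4)
  expect_equal(sodium_fraction(1.0, 0), 1.0)
  expect_equal(sodium_fraction(0, 0.5), 0.0)
  expect_warning(f00 <- sodium_fraction(0, 0), "zero total sodium")
  expect_true(is.na(f00))
  expect_error(sodium_fraction(-1, 1), "nonnegative")
})

test_that("factor-of-10/2 bounds match hand arithmetic and bracket the mean", {
  b <- budget_bounds(one_step)
  expect_equal(unname(b["bound_low"]), 0.0091 / 0.1891, tolerance = 1e-9)
  expect_lt(abs(unname(b["bound_low"]) - 0.0481), 1e-4)
  expect_equal(unname(b["bound_high"]), 0.91 / 0.955, tolerance = 1e-9)
  expect_equal(unname(b["bound_high"]), 0.9529, tolerance = 1e-4)
  # exact bracket on every random series (per-step dominance, not sampling)
  for (seed in 1:10) {
    s <- gen_concentration_series(series_config(n_days = 60, seed = seed))
    res <- sodium_budget(s)
    expect_lte(res$bound_low, res$mean_fraction)
    expect_lte(res$mean_fraction, res$bound_high)
  }
})

test_that("mean contribution is strictly monotone in the Na-rich fraction", {
  sens <- sensitivity_p_rich(one_step)
  expect_equal(sens$mean_fraction[sens$p_rich == 0.3], 0.039 / 0.129,
               tolerance = 1e-9)
  expect_equal(sens$mean_fraction[sens$p_rich == 0.3], 0.3023,
               tolerance = 1e-4)
  expect_equal(sens$mean_fraction[sens$p_rich == 0.7], 0.5028,
               tolerance = 1e-4)
  s <- gen_concentration_series(series_config(n_days = 90, seed = 8))
  sens2 <- sensitivity_p_rich(s)
  expect_true(all(diff(sens2$mean_fraction) > 0))
})

test_that("fraction is monotone in spores, p_rich; antitone in sea salt", {
  set.seed(19)
  for (i in 1:50) {
    cs <- runif(1, 0.01, 5); cl <- runif(1, 0.01, 5)
    eps <- runif(1, 0.01, 1)
    f0 <- sodium_fraction(cs, cl)
    expect_true(f0 >= 0 && f0 <= 1)
    expect_gt(sodium_fraction(cs + eps, cl), f0)
    expect_lt(sodium_fraction(cs, cl + eps), f0)
    p <- runif(2, 0.05, 1)
    pr <- budget_params(p_rich = min(p))
    ph <- budget_params(p_rich = max(p))
    if (min(p) < max(p)) {
      expect_lt(sodium_fraction(cs, cl, pr), sodium_fraction(cs, cl, ph))
    }
  }
})

test_that("mean-of-fractions differs from fraction-of-means when it should", {
  # heterogeneous two-step fixture chosen so Jensen's gap is visible
  s <- data.frame(date = as.Date("2015-01-01") + 0:1, hour = NA_integer_,
                  cell_id = 1L, spore_ugm3 = c(1.0, 0.05),
                  seasalt_ugm3 = c(0.05, 1.0), season = "wet")
  res <- sodium_budget(s)
  expect_gt(abs(res$mean_fraction - res$fraction_of_means), 0.05)
  # homogeneous series: the two coincide
  s2 <- s
  s2$spore_ugm3 <- 1; s2$seasalt_ugm3 <- 0.3
  res2 <- sodium_budget(s2)
  expect_equal(res2$mean_fraction, res2$fraction_of_means)
})

test_that("percentage of exceedance days counts daily means correctly", {
  mk <- function(f_target, n) {
    # spore level chosen so the default-parameter fraction equals f_target
    cs <- 0.30 * 0.30 * f_target / (0.7 * 0.13 * (1 - f_target))
    data.frame(date = as.Date("2015-01-01") + seq_len(n) - 1,
               hour = NA_integer_, cell_id = 1L, spore_ugm3 = cs,
               seasalt_ugm3 = 0.30, season = "wet")
  }
  alternating <- rbind(mk(0.6, 5), mk(0.4, 5))
  alternating$date <- as.Date("2015-01-01") + 0:9
  expect_equal(pct_days_above(alternating, threshold = 0.5), 50)
  expect_equal(pct_days_above(mk(1 - 1e-9, 7), threshold = 0.5), 100)
  expect_equal(pct_days_above(mk(0.3, 7), threshold = 0), 100)
  # monotone nonincreasing in the threshold
  s <- gen_concentration_series(series_config(n_days = 120, seed = 9))
  pcts <- vapply(seq(0, 1, by = 0.1), function(th) {
    pct_days_above(s, threshold = th)
  }, numeric(1))
  expect_true(all(diff(pcts) <= 0))
})

test_that("diel split shows the nighttime enhancement and window convention", {
  cfg <- series_config(n_days = 60, hourly = TRUE, diurnal_amplitude = 2,
                       seed = 10)
  s <- gen_concentration_series(cfg)
  ds <- diel_split(s)
  expect_gt(ds["night", "median"], ds["day", "median"])
  expect_equal(ds["night", "n"] + ds["day", "n"], nrow(s))
  # 18:00 belongs to the night window, 06:00 to the day window
  s18 <- s[s$hour == 18, ][1, ]
  amp <- s18$spore_ugm3 / mean(s$spore_ugm3[s$date == s18$date])
  expect_gt(amp, 1)  # the 18:00 step carries the night enhancement
  s06 <- s[s$hour == 6, ][1, ]
  amp06 <- s06$spore_ugm3 / mean(s$spore_ugm3[s$date == s06$date])
  expect_lt(amp06, 1)
  # no diurnal cycle: medians agree within sampling error
  cfg1 <- series_config(n_days = 60, hourly = TRUE, diurnal_amplitude = 1,
                        spore_lognormal = c(1, 1), seasalt_lognormal = c(0.3, 1),
                        scavenging_prob = 0, seed = 10)
  ds1 <- diel_split(gen_concentration_series(cfg1))
  expect_equal(ds1["night", "median"], ds1["day", "median"])
  # daily series are rejected with guidance
  daily <- gen_concentration_series(series_config(n_days = 10, seed = 2))
  expect_error(diel_split(daily), "sub-daily")
})
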