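#' Parameters of the sodium mass-budget apportionment
#'
#' Sodium dry-mass contents of the two source classes (13% for sodium-rich
#' fungal spores - the rounded form of 0.51/4 - and 30% for sea salt), the
#' assumed fraction of spores that are sodium-rich (70% upper-bound
#' assumption, with 30% and 50% sensitivity variants), the bound
#' multipliers (spore concentrations varied by a factor of 10, sea salt by
#' a factor of 2), and the night window (18:00-06:00, half-open).
#'
#' @param w_na_spore Na dry-mass fraction of sodium-rich spores.
#' @param w_na_seasalt Na dry-mass fraction of sea salt.
#' @param p_rich Fraction of spores assumed sodium-rich, in (0, 1].
#' @param spore_factor Bound multiplier for spore concentrations, > 1.
#' @param seasalt_factor Bound multiplier for sea-salt concentrations, > 1.
#' @param night_window Length-2 start/end hours of the night window,
#'   interpreted half-open: hour h is night when h >= start or h < end.
#' @return Object of class `"budget_params"`.
#' @export
budget_params <- function(w_na_spore = 0.13, w_na_seasalt = 0.30,
                          p_rich = 0.70, spore_factor = 10,
                          seasalt_factor = 2, night_window = c(18, 6)) {
  fr <- c(w_na_spore, w_na_seasalt, p_rich)
  if (any(fr <= 0) || any(fr > 1)) {
    stop("mass fractions and p_rich must lie in (0, 1]", call. = FALSE)
  }
  if (spore_factor <= 1 || seasalt_factor <= 1) {
    stop("bound factors must exceed 1", call. = FALSE)
  }
  structure(list(w_na_spore = w_na_spore, w_na_seasalt = w_na_seasalt,
                 p_rich = p_rich, spore_factor = spore_factor,
                 seasalt_factor = seasalt_factor,
                 night_window = night_window),
            class = "budget_params")
}

#' Fraction of particulate sodium contributed by fungal spores
#'
#' f = (p_rich w_spore C_spore) / (p_rich w_spore C_spore +
#' w_seasalt C_seasalt): sodium mass carried by the sodium-rich spore
#' subpopulation over total sodium mass from spores plus sea salt.
#' Vectorized over the concentrations. Steps with both concentrations zero
#' have no defined fraction and return `NA` with a warning.
#'
#' @param c_spore Spore mass concentrations (ug m^-3), >= 0.
#' @param c_seasalt Sea-salt mass concentrations (ug m^-3), >= 0.
#' @param params A [budget_params()].
#' @return Numeric vector of fractions in [0, 1].
#' @export
sodium_fraction <- function(c_spore, c_seasalt, params = budget_params()) {
  if (any(c_spore < 0) || any(c_seasalt < 0)) {
    stop("concentrations must be nonnegative", call. = FALSE)
  }
  num <- params$p_rich * params$w_na_spore * c_spore
  den <- num + params$w_na_seasalt * c_seasalt
  f <- num / den
  if (any(den == 0)) {
    warning("steps with zero total sodium flagged NA", call. = FALSE)
    f[den == 0] <- NA_real_
  }
  f
}

#' Approximate lower and upper bounds on the mean spore contribution
#'
#' Per-step fractions are recomputed under the pessimistic perturbation
#' (spores divided by `spore_factor`, sea salt multiplied by
#' `seasalt_factor`) and the optimistic one (the reverse), then averaged.
#' Because the perturbation moves every step's fraction in the same
#' direction, bound_low <= mean <= bound_high holds exactly per series,
#' not just statistically.
#'
#' @param series Series data frame with `spore_ugm3` and `seasalt_ugm3`.
#' @param params A [budget_params()].
#' @return Named numeric: `bound_low`, `bound_high` (means of perturbed
#'   per-step fractions).
#' @export
budget_bounds <- function(series, params = budget_params()) {
  if (nrow(series) == 0L) stop("empty series", call. = FALSE)
  low <- sodium_fraction(series$spore_ugm3 / params$spore_factor,
                         series$seasalt_ugm3 * params$seasalt_factor, params)
  high <- sodium_fraction(series$spore_ugm3 * params$spore_factor,
                          series$seasalt_ugm3 / params$seasalt_factor, params)
  c(bound_low = mean(low, na.rm = TRUE), bound_high = mean(high, na.rm = TRUE))
}

#' Sensitivity of the mean contribution to the sodium-rich spore fraction
#'
#' Recomputes the mean per-step sodium fraction for each assumed
#' sodium-rich spore fraction. The mean is strictly increasing in p_rich
#' whenever both sources are present somewhere in the series.
#'
#' @param series Series data frame.
#' @param params A [budget_params()] (its `p_rich` is overridden per value).
#' @param p_values Sodium-rich fractions to evaluate, each in (0, 1].
#' @return Data frame with columns `p_rich`, `mean_fraction`.
#' @export
sensitivity_p_rich <- function(series, params = budget_params(),
                               p_values = c(0.3, 0.5, 0.7)) {
  stopifnot(all(p_values > 0), all(p_values <= 1))
  means <- vapply(p_values, function(p) {
    pp <- params
    pp$p_rich <- p
    mean(sodium_fraction(series$spore_ugm3, series$seasalt_ugm3, pp),
         na.rm = TRUE)
  }, numeric(1))
  data.frame(p_rich = p_values, mean_fraction = means)
}

# daily means of per-step fractions (mean-of-fractions convention)
.daily_fractions <- function(series, params) {
  f <- sodium_fraction(series$spore_ugm3, series$seasalt_ugm3, params)
  as.numeric(tapply(f, series$date, mean, na.rm = TRUE))
}

#' Percentage of days exceeding a contribution threshold
#'
#' Sub-daily series are first aggregated to daily means of the per-step
#' fractions; the statistic is 100 x (#days with daily fraction >=
#' threshold) / (#days).
#'
#' @param series Series data frame with a `date` column.
#' @param params A [budget_params()].
#' @param threshold Contribution threshold in [0, 1]. Default 0.5.
#' @return Percentage of days (0-100).
#' @export
pct_days_above <- function(series, params = budget_params(),
                           threshold = 0.5) {
  if (nrow(series) == 0L) stop("empty series", call. = FALSE)
  fd <- .daily_fractions(series, params)
  100 * mean(fd >= threshold, na.rm = TRUE)
}

#' Day/night split of the sodium-fraction distribution
#'
#' Splits sub-daily per-step fractions into the night (18:00-06:00,
#' half-open: the 18:00 step is night, the 06:00 step is day) and day
#' windows and summarizes each distribution with median, quartiles and
#' range - the statistics a violin plot of daily fractions would display.
#'
#' @param series Hourly series data frame (`hour` must be populated).
#' @param params A [budget_params()].
#' @return Data frame with rows `night` and `day` and columns `n`,
#'   `median`, `q25`, `q75`, `min`, `max`.
#' @export
diel_split <- function(series, params = budget_params()) {
  if (all(is.na(series$hour))) {
    stop("series lacks sub-daily resolution; use daily statistics ",
         "(pct_days_above, budget bounds) instead", call. = FALSE)
  }
  f <- sodium_fraction(series$spore_ugm3, series$seasalt_ugm3, params)
  h <- series$hour
  nw <- params$night_window
  night <- h >= nw[1] | h < nw[2]
  summarize <- function(x) {
    x <- x[!is.na(x)]
    q <- quantile(x, c(0.25, 0.5, 0.75), names = FALSE)
    data.frame(n = length(x), median = q[2], q25 = q[1], q75 = q[3],
               min = min(x), max = max(x))
  }
  out <- rbind(night = summarize(f[night]), day = summarize(f[!night]))
  out
}

#' Threshold-exceedance map over a grid of cells
#'
#' [pct_days_above()] per grid cell, rows ordered by `cell_id` for
#' reproducible output.
#'
#' @param grid_series Output of [gen_grid_series()] (or any series with a
#'   `cell_id` column).
#' @param params A [budget_params()].
#' @param threshold Contribution threshold. Default 0.5.
#' @return Data frame with columns `cell_id`, `pct_days`.
#' @export
grid_map <- function(grid_series, params = budget_params(),
                     threshold = 0.5) {
  cells <- sort(unique(grid_series$cell_id))
  pct <- vapply(cells, function(cl) {
    pct_days_above(grid_series[grid_series$cell_id == cl, , drop = FALSE],
                   params, threshold)
  }, numeric(1))
  data.frame(cell_id = cells, pct_days = pct)
}

#' Full budget summary of a concentration series
#'
#' Per-step sodium fractions, their seasonal mean, the factor-of-10/2
#' bounds, the threshold-exceedance statistic, and - as a diagnostic - the
#' fraction computed from mean concentrations. On heterogeneous series the
#' mean of per-step fractions and the fraction of mean masses differ
#' (Jensen's inequality); the former is the reported quantity.
#'
#' @param series Series data frame.
#' @param params A [budget_params()].
#' @param threshold Threshold for [pct_days_above()].
#' @return Object of class `"budget_result"`: list with `fractions`
#'   (per-step), `mean_fraction`, `bound_low`, `bound_high`,
#'   `pct_days_ge_threshold`, `fraction_of_means`, `season`, `params`.
#' @export
sodium_budget <- function(series, params = budget_params(), threshold = 0.5) {
  if (nrow(series) == 0L) stop("empty series", call. = FALSE)
  f <- sodium_fraction(series$spore_ugm3, series$seasalt_ugm3, params)
  b <- budget_bounds(series, params)
  structure(list(
    fractions = f,
    mean_fraction = mean(f, na.rm = TRUE),
    bound_low = unname(b["bound_low"]),
    bound_high = unname(b["bound_high"]),
    pct_days_ge_threshold = pct_days_above(series, params, threshold),
    fraction_of_means = sodium_fraction(mean(series$spore_ugm3),
                                        mean(series$seasalt_ugm3), params),
    season = unique(series$season),
    params = params
  ), class = "budget_result")
}

#' @export
print.budget_result <- function(x, ...) {
  cat(sprintf("Sodium budget (%s season):\n", paste(x$season, collapse = "/")))
  cat(sprintf("  mean spore contribution: %.1f%% (bounds %.1f-%.1f%%)\n",
              100 * x$mean_fraction, 100 * x$bound_low, 100 * x$bound_high))
  cat(sprintf("  days with contribution >= 50%%: %.1f%%\n",
              x$pct_days_ge_threshold))
  cat(sprintf("  diagnostic fraction-of-mean-masses: %.3f\n",
              x$fraction_of_means))
  invisible(x)
}
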