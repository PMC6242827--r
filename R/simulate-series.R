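#' Mass of a single spore at its emission size
#'
#' Helper for number-to-mass conversion of spore concentrations:
#' m = (pi/6) d^3 rho, giving 33.51 pg for the 4 um emission diameter at
#' unit density.
#'
#' @param diameter_um Emission diameter (um). Default 4.
#' @param density_g_cm3 Density (g cm^-3). Default 1.
#' @return Mass per spore in pg.
#' @export
mass_per_spore_pg <- function(diameter_um = 4, density_g_cm3 = 1) {
  spore_mass(diameter_um, density_g_cm3)
}

#' Configuration for synthetic concentration series
#'
#' Daily (optionally hourly) spore and sea-salt mass concentrations with
#' the gross structure the budget analysis assumes: lognormal day-to-day
#' variability, a nighttime spore enhancement, and episodic wet scavenging
#' of sea salt. Wet-season defaults give lower sea-salt medians and more
#' frequent scavenging than dry-season defaults, reflecting stronger wet
#' removal of long-range marine aerosol in the wet season.
#'
#' @param n_days Number of days.
#' @param season `"wet"` (starts 1 Jan) or `"dry"` (starts 1 Jul).
#' @param spore_lognormal Length-2: median (ug m^-3) and geometric SD of
#'   daily spore mass concentration.
#' @param seasalt_lognormal Same for sea salt; default median 0.15 (wet) or
#'   0.60 (dry) ug m^-3.
#' @param diurnal_amplitude Night/day spore concentration ratio applied to
#'   hourly series (default 2: nighttime enhancement).
#' @param scavenging_prob Daily probability that precipitation multiplies
#'   sea salt by `scavenging_factor`; default 0.35 (wet) or 0.08 (dry).
#' @param scavenging_factor Depletion multiplier for scavenged days.
#' @param hourly Emit 24 rows per day with the spore diurnal cycle applied.
#' @param year Calendar year for the date column.
#' @param seed Integer seed.
#' @return Object of class `"series_config"`.
#' @export
series_config <- function(n_days = 180, season = c("wet", "dry"),
                          spore_lognormal = c(1.0, 1.8),
                          seasalt_lognormal = NULL,
                          diurnal_amplitude = 2,
                          scavenging_prob = NULL,
                          scavenging_factor = 0.2,
                          hourly = FALSE, year = 2015, seed = 1L) {
  season <- match.arg(season)
  if (is.null(seasalt_lognormal)) {
    seasalt_lognormal <- if (season == "wet") c(0.15, 2.2) else c(0.60, 2.0)
  }
  if (is.null(scavenging_prob)) {
    scavenging_prob <- if (season == "wet") 0.35 else 0.08
  }
  if (spore_lognormal[1] <= 0 || seasalt_lognormal[1] <= 0) {
    stop("concentration medians must be positive", call. = FALSE)
  }
  stopifnot(n_days >= 1, spore_lognormal[2] >= 1, seasalt_lognormal[2] >= 1,
            diurnal_amplitude > 0, scavenging_prob >= 0, scavenging_prob <= 1,
            scavenging_factor > 0, scavenging_factor <= 1)
  structure(list(n_days = as.integer(n_days), season = season,
                 spore_lognormal = spore_lognormal,
                 seasalt_lognormal = seasalt_lognormal,
                 diurnal_amplitude = diurnal_amplitude,
                 scavenging_prob = scavenging_prob,
                 scavenging_factor = scavenging_factor,
                 hourly = hourly, year = year, seed = as.integer(seed)),
            class = "series_config")
}

#' Generate a synthetic concentration series
#'
#' Daily spore and sea-salt mass concentrations are independent lognormal
#' draws; on scavenged days sea salt is multiplied by the depletion factor.
#' Hourly series spread each day's spore concentration over a two-level
#' diurnal cycle (night hours, 18:00-06:00, elevated by
#' `diurnal_amplitude` relative to day hours) normalized so the daily mean
#' equals the daily draw; sea salt has no diurnal cycle.
#'
#' @param config A [series_config()].
#' @param cell_id Cell identifier attached to the rows.
#' @return Data frame with columns `date`, `hour` (`NA` for daily series),
#'   `cell_id`, `spore_ugm3`, `seasalt_ugm3`, `season`.
#' @export
gen_concentration_series <- function(config, cell_id = 1L) {
  stopifnot(inherits(config, "series_config"))
  withr::with_seed(config$seed, {
    n <- config$n_days
    spore_day <- rlnorm(n, log(config$spore_lognormal[1]),
                        log(config$spore_lognormal[2]))
    salt_day <- rlnorm(n, log(config$seasalt_lognormal[1]),
                       log(config$seasalt_lognormal[2]))
    scav <- runif(n) < config$scavenging_prob
    salt_day[scav] <- salt_day[scav] * config$scavenging_factor
    start <- as.Date(sprintf("%d-%02d-01", config$year,
                             if (config$season == "wet") 1L else 7L))
    dates <- start + seq_len(n) - 1L
    if (!config$hourly) {
      return(data.frame(date = dates, hour = NA_integer_, cell_id = cell_id,
                        spore_ugm3 = spore_day, seasalt_ugm3 = salt_day,
                        season = config$season, stringsAsFactors = FALSE))
    }
    hours <- 0:23
    night <- hours >= 18 | hours < 6
    w <- ifelse(night, config$diurnal_amplitude, 1)
    w <- w / mean(w)
    data.frame(
      date = rep(dates, each = 24L), hour = rep(hours, n),
      cell_id = cell_id,
      spore_ugm3 = rep(spore_day, each = 24L) * rep(w, n),
      seasalt_ugm3 = rep(salt_day, each = 24L),
      season = config$season, stringsAsFactors = FALSE
    )
  })
}

#' Generate a grid of concentration series
#'
#' One series per model cell. `gradient` is a per-cell multiplier applied
#' to the sea-salt median (emulating, e.g., proximity to the marine
#' source); cells are otherwise independent, with per-cell seeds derived
#' from the base seed.
#'
#' @param n_cells Number of grid cells, >= 1.
#' @param config A [series_config()] used as the base for every cell.
#' @param gradient Numeric vector of length `n_cells` (or scalar) of
#'   sea-salt median multipliers.
#' @return Data frame in the [gen_concentration_series()] schema, rows for
#'   all cells, `cell_id` in 1..n_cells.
#' @export
gen_grid_series <- function(n_cells, config, gradient = 1) {
  stopifnot(n_cells >= 1)
  gradient <- rep_len(gradient, n_cells)
  stopifnot(all(gradient > 0))
  out <- lapply(seq_len(n_cells), function(cell) {
    cfg <- config
    cfg$seasalt_lognormal[1] <- config$seasalt_lognormal[1] * gradient[cell]
    cfg$seed <- config$seed + (cell - 1L)
    gen_concentration_series(cfg, cell_id = cell)
  })
  do.call(rbind, out)
}

#' Write or read a concentration series CSV
#'
#' @param series Series data frame.
#' @param path File path.
#' @return `write_series`: invisibly, the path. `read_series`: the series.
#' @export
write_series <- function(series, path) {
  utils::write.csv(series, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_series
#' @export
read_series <- function(path) {
  s <- utils::read.csv(path, stringsAsFactors = FALSE)
  s$date <- as.Date(s$date)
  s
}
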