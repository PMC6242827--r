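#' Sodium-quantification parameters for fungal spores
#'
#' Population constants from X-ray microanalysis of spores: carbon dry-mass
#' content 42-66% with mean 0.51, carbon-to-sodium mass ratio 4:1, and unit
#' density (1 g cm^-3). Dividing the mean carbon content by the C:Na ratio
#' gives an Na dry-mass fraction of 0.1275, i.e. ~13% - the constant the
#' budget module applies to sodium-rich spores.
#'
#' @param carbon_wt_mean Mean carbon weight fraction of spore dry mass.
#' @param carbon_wt_range Length-2 plausible range for `carbon_wt_mean`.
#' @param c_to_na_ratio Carbon-to-sodium dry-mass ratio.
#' @param density_g_cm3 Spore bulk density (g cm^-3).
#' @return Object of class `"spore_na_params"`.
#' @export
spore_na_params <- function(carbon_wt_mean = 0.51,
                            carbon_wt_range = c(0.42, 0.66),
                            c_to_na_ratio = 4.0,
                            density_g_cm3 = 1.0) {
  stopifnot(carbon_wt_mean > 0, c_to_na_ratio > 0, density_g_cm3 > 0,
            carbon_wt_mean >= carbon_wt_range[1],
            carbon_wt_mean <= carbon_wt_range[2])
  structure(list(carbon_wt_mean = carbon_wt_mean,
                 carbon_wt_range = carbon_wt_range,
                 c_to_na_ratio = c_to_na_ratio,
                 density_g_cm3 = density_g_cm3),
            class = "spore_na_params")
}

#' Sodium weight fraction of spore dry mass
#'
#' w_Na = w_C / r where w_C is the carbon weight fraction and r the
#' carbon-to-sodium mass ratio. With the defaults (0.51, 4) this is 0.1275,
#' which rounds to the 13% used for sodium-rich spores in the budget.
#'
#' @param carbon_wt Carbon weight fraction, in (0, 1].
#' @param c_to_na_ratio Carbon-to-sodium mass ratio, > 0.
#' @return Sodium weight fraction.
#' @export
spore_na_weight_fraction <- function(carbon_wt = 0.51, c_to_na_ratio = 4.0) {
  if (any(carbon_wt <= 0) || any(carbon_wt > 1)) {
    stop("carbon_wt must lie in (0, 1]", call. = FALSE)
  }
  if (any(c_to_na_ratio <= 0)) {
    stop("c_to_na_ratio must be positive", call. = FALSE)
  }
  carbon_wt / c_to_na_ratio
}

#' Spore mass from area-equivalent diameter
#'
#' m = (pi/6) d^3 rho, treating the spore as a sphere of its area-equivalent
#' diameter. With d in um and rho in g cm^-3, 1 um^3 at unit density is 1 pg,
#' so the result is in picograms (a 4 um spore at unit density is 33.51 pg).
#'
#' @param diameter_um Area-equivalent diameter (um), > 0. Vectorized.
#' @param density_g_cm3 Density (g cm^-3).
#' @return Mass in pg.
#' @export
spore_mass <- function(diameter_um, density_g_cm3 = 1.0) {
  if (any(diameter_um <= 0)) {
    stop("diameter must be positive", call. = FALSE)
  }
  if (any(density_g_cm3 <= 0)) {
    stop("density must be positive", call. = FALSE)
  }
  pi / 6 * diameter_um^3 * density_g_cm3
}

#' Per-particle sodium mass
#'
#' Sodium mass (pg) of each particle: spore mass from its diameter times its
#' Na weight fraction. A measured per-particle Na weight fraction (from the
#' particle's own composition) is preferred; where absent, the population
#' default from [spore_na_weight_fraction()] is used as fallback.
#'
#' @param diameter_um Diameters (um). Vectorized.
#' @param na_wt Per-particle Na weight fractions; `NA` entries fall back to
#'   `default_na_wt`.
#' @param default_na_wt Population fallback; `NULL` means no fallback, and
#'   any `NA` in `na_wt` is an error.
#' @param density_g_cm3 Density (g cm^-3).
#' @return Numeric vector of Na masses (pg).
#' @export
particle_na_mass <- function(diameter_um, na_wt,
                             default_na_wt = spore_na_weight_fraction(),
                             density_g_cm3 = 1.0) {
  stopifnot(length(diameter_um) == length(na_wt))
  if (anyNA(na_wt)) {
    if (is.null(default_na_wt)) {
      stop("Na weight fraction missing and no default supplied", call. = FALSE)
    }
    na_wt[is.na(na_wt)] <- default_na_wt
  }
  spore_mass(diameter_um, density_g_cm3) * na_wt
}

#' Size dependence of the sodium weight fraction
#'
#' Bins particles by diameter, reports the mean Na weight fraction per bin,
#' and tests the monotone association between diameter and Na content with
#' Spearman rank correlation. A negative sign means smaller particles carry
#' a higher sodium fraction.
#'
#' @param diameter_um Diameters (um).
#' @param na_wt Na weight fractions, same length.
#' @param bin_edges Diameter bin edges (um), strictly increasing.
#' @return List with `binned` (data frame: bin_lo, bin_hi, n, mean_na_wt),
#'   `spearman_rho`, `p_value`, and `trend` (one of "decreasing",
#'   "increasing", "flat" by sign of rho at p < 0.05).
#' @export
na_fraction_size_trend <- function(diameter_um, na_wt,
                                   bin_edges = c(0.32, 0.56, 1, 1.8, 3.2, 5.6, 10)) {
  stopifnot(length(diameter_um) == length(na_wt), all(diff(bin_edges) > 0))
  keep <- diameter_um >= bin_edges[1] & diameter_um <= bin_edges[length(bin_edges)]
  d <- diameter_um[keep]
  w <- na_wt[keep]
  bin <- cut(d, breaks = bin_edges, include.lowest = TRUE)
  occupied <- length(unique(bin[!is.na(bin)]))
  if (occupied < 2L) {
    stop("need particles in at least 2 size bins for a trend", call. = FALSE)
  }
  binned <- data.frame(
    bin_lo = bin_edges[-length(bin_edges)],
    bin_hi = bin_edges[-1],
    n = as.integer(table(bin)),
    mean_na_wt = as.numeric(tapply(w, bin, mean))
  )
  ct <- suppressWarnings(cor.test(d, w, method = "spearman", exact = FALSE))
  rho <- unname(ct$estimate)
  trend <- if (ct$p.value >= 0.05 || rho == 0) "flat"
           else if (rho < 0) "decreasing" else "increasing"
  list(binned = binned, spearman_rho = rho, p_value = ct$p.value,
       trend = trend)
}
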