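#' Standard atomic masses of elements quantified by SEM/EDX
#'
#' Masses (g/mol) for the elements reported in single-particle X-ray
#' microanalysis of ambient coarse-mode aerosol. Cu is listed because it
#' appears as substrate background on TEM grids; it is stripped from
#' composition vectors before classification, never used in normalization.
#'
#' @format Named numeric vector.
#' @export
atomic_masses <- c(
  C = 12.011, N = 14.007, O = 15.999, Na = 22.990, Mg = 24.305,
  Al = 26.982, Si = 28.085, P = 30.974, S = 32.06, Cl = 35.45,
  K = 39.098, Ca = 40.078, Fe = 55.845, Cu = 63.546
)

.check_elements <- function(x) {
  unknown <- setdiff(names(x), names(atomic_masses))
  if (length(unknown) > 0L) {
    stop("unknown element symbol(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  if (is.null(names(x)) || any(!nzchar(names(x)))) {
    stop("composition vector must be fully named by element symbol",
         call. = FALSE)
  }
  invisible(x)
}

#' Convert atomic fractions to weight fractions
#'
#' EDX microanalysis reports per-particle composition as atomic fractions
#' a_i; classification thresholds are stated in weight percent, so
#' w_i = a_i M_i / sum_j a_j M_j with M the standard atomic masses.
#'
#' @param atomic_fractions Named numeric vector of atomic fractions
#'   (nonnegative, summing to 1).
#' @return Named numeric vector of weight fractions summing to 1.
#' @seealso [weight_to_atomic()] for the inverse.
#' @examples
#' atomic_to_weight(c(C = 0.5, O = 0.5))
#' @export
atomic_to_weight <- function(atomic_fractions) {
  .check_elements(atomic_fractions)
  stopifnot(all(atomic_fractions >= 0))
  if (abs(sum(atomic_fractions) - 1) > 1e-6) {
    stop("atomic fractions must sum to 1", call. = FALSE)
  }
  m <- atomic_fractions * atomic_masses[names(atomic_fractions)]
  m / sum(m)
}

#' Convert weight fractions to atomic fractions
#'
#' Inverse of [atomic_to_weight()]: a_i = (w_i / M_i) / sum_j (w_j / M_j).
#' Used by the synthetic-data generator, which parameterizes class profiles
#' in weight fractions but emits particle tables in atomic fractions, as a
#' microanalysis instrument would.
#'
#' @param weight_fractions Named numeric vector of weight fractions
#'   (nonnegative, summing to 1).
#' @return Named numeric vector of atomic fractions summing to 1.
#' @export
weight_to_atomic <- function(weight_fractions) {
  .check_elements(weight_fractions)
  stopifnot(all(weight_fractions >= 0))
  if (abs(sum(weight_fractions) - 1) > 1e-6) {
    stop("weight fractions must sum to 1", call. = FALSE)
  }
  m <- weight_fractions / atomic_masses[names(weight_fractions)]
  m / sum(m)
}
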