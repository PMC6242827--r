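#' Segment the largest particle in a grayscale frame
#'
#' Otsu's criterion splits the frame into background and foreground
#' (foreground = the brighter side for ESEM frames, or the high-OD side for
#' optical-density maps); connected-component labelling then keeps the
#' largest foreground blob as the particle. Area is pixel count times the
#' squared pixel size.
#'
#' @param frame Numeric matrix (grayscale intensities or OD values).
#' @param pixel_size_um Pixel edge length (um). Default 1 (areas in px^2).
#' @return List with `mask` (logical matrix), `area_px`, `area_um2`.
#' @export
detect_particle <- function(frame, pixel_size_um = 1) {
  stopifnot(is.matrix(frame), length(frame) > 0)
  rng <- range(frame, finite = TRUE)
  if (!all(is.finite(rng)) || rng[1] == rng[2]) {
    stop("no foreground detected: frame has no contrast", call. = FALSE)
  }
  scaled <- (frame - rng[1]) / (rng[2] - rng[1])
  thr <- EBImage::otsu(EBImage::Image(scaled), range = c(0, 1))
  fg <- scaled > thr
  if (!any(fg)) stop("no foreground detected above threshold", call. = FALSE)
  lab <- EBImage::bwlabel(EBImage::Image(fg * 1))
  lab <- EBImage::imageData(lab)
  sizes <- tabulate(lab[lab > 0])
  mask <- lab == which.max(sizes)
  list(mask = mask, area_px = sum(mask),
       area_um2 = sum(mask) * pixel_size_um^2)
}

#' Area-equivalent diameter of a projected area
#'
#' d = 2 sqrt(A / pi): the diameter of the circle with the same projected
#' area as the particle.
#'
#' @param area_um2 Projected area (um^2), > 0. Vectorized.
#' @return Diameter in um.
#' @export
area_equivalent_diameter <- function(area_um2) {
  if (any(area_um2 <= 0)) stop("area must be positive", call. = FALSE)
  2 * sqrt(area_um2 / pi)
}

#' Hydration image pair container
#'
#' @param frame_dry,frame_wet Numeric matrices of equal dimension.
#' @param rh_dry,rh_wet Relative humidities (%), `rh_wet > rh_dry`.
#' @param pixel_size_um Pixel edge length (um).
#' @return Object of class `"hydration_pair"`.
#' @export
hydration_pair <- function(frame_dry, frame_wet, rh_dry, rh_wet,
                           pixel_size_um = 0.05) {
  stopifnot(is.matrix(frame_dry), is.matrix(frame_wet),
            all(dim(frame_dry) == dim(frame_wet)))
  if (rh_wet <= rh_dry) stop("rh_wet must exceed rh_dry", call. = FALSE)
  structure(list(frame_dry = frame_dry, frame_wet = frame_wet,
                 rh_dry = rh_dry, rh_wet = rh_wet,
                 pixel_size_um = pixel_size_um),
            class = "hydration_pair")
}

#' Area growth factor from a hydration pair
#'
#' Segments the dry and wet frames independently, converts projected areas
#' to area-equivalent diameters, and reports the growth factor as the
#' wet-to-dry diameter ratio (the parenthetical definition used with ESEM
#' hydration experiments). The raw wet/dry projected-area ratio - exactly
#' the squared diameter ratio - is reported alongside.
#'
#' @param pair A [hydration_pair()].
#' @return List of class `"growth_result"`: `gf_area` (diameter ratio),
#'   `area_ratio`, `d_dry_um`, `d_wet_um`, `rh_pair`.
#' @export
area_growth_factor <- function(pair) {
  stopifnot(inherits(pair, "hydration_pair"))
  dry <- detect_particle(pair$frame_dry, pair$pixel_size_um)
  wet <- detect_particle(pair$frame_wet, pair$pixel_size_um)
  d_dry <- area_equivalent_diameter(dry$area_um2)
  d_wet <- area_equivalent_diameter(wet$area_um2)
  structure(list(gf_area = d_wet / d_dry,
                 area_ratio = wet$area_um2 / dry$area_um2,
                 d_dry_um = d_dry, d_wet_um = d_wet,
                 rh_pair = c(pair$rh_dry, pair$rh_wet)),
            class = "growth_result")
}

#' Per-pixel optical density via Beer-Lambert's law
#'
#' OD = -ln(I / I0) for transmitted intensity I and reference intensity I0.
#' Pixels with nonpositive intensity are marked `NA` (no transmission
#' measurement). At an element's absorption edge the integrated OD over the
#' particle is proportional to that element's mass.
#'
#' @param intensity Numeric matrix of transmitted intensities.
#' @param i0 Reference intensity, scalar or matrix of matching dimension;
#'   `NULL` estimates I0 as the median intensity of the frame border
#'   (one-pixel margin), assumed particle-free.
#' @return Numeric matrix of OD values.
#' @export
optical_density <- function(intensity, i0 = NULL) {
  stopifnot(is.matrix(intensity))
  if (is.null(i0)) {
    nr <- nrow(intensity); nc <- ncol(intensity)
    border <- c(intensity[1, ], intensity[nr, ],
                intensity[, 1], intensity[, nc])
    i0 <- median(border)
  }
  if (any(i0 <= 0)) stop("i0 must be positive", call. = FALSE)
  od <- matrix(NA_real_, nrow(intensity), ncol(intensity))
  ok <- intensity > 0
  i0m <- if (length(i0) == 1L) i0 else i0[ok]
  od[ok] <- -log(intensity[ok] / i0m)
  od
}

#' Optical-density map container
#'
#' @param intensity Transmitted-intensity matrix.
#' @param i0 Reference intensity (scalar or matrix); `NULL` to estimate from
#'   the frame border.
#' @param mask Optional logical particle mask; `NULL` segments the OD map
#'   with [detect_particle()].
#' @return Object of class `"od_map"` with fields `intensity`, `i0`, `od`,
#'   `mask`.
#' @export
od_map <- function(intensity, i0 = NULL, mask = NULL) {
  od <- optical_density(intensity, i0)
  if (is.null(i0)) {
    nr <- nrow(intensity); nc <- ncol(intensity)
    i0 <- median(c(intensity[1, ], intensity[nr, ],
                   intensity[, 1], intensity[, nc]))
  }
  if (is.null(mask)) {
    finite_od <- od
    finite_od[!is.finite(finite_od)] <- 0
    mask <- detect_particle(finite_od)$mask
  }
  stopifnot(all(dim(mask) == dim(od)))
  structure(list(intensity = intensity, i0 = i0, od = od, mask = mask),
            class = "od_map")
}

#' Mass growth factor from dry/wet optical-density maps
#'
#' gf_mass = integrated OD over the wet state / integrated OD over the dry
#' state, both taken over the union of the dry and wet particle masks so
#' water condensed beyond the dry boundary is counted. With maps recorded
#' at the oxygen absorption edge this is the wet-to-dry oxygen-mass ratio.
#' Pixels outside the union mask (including negative-OD noise) never enter
#' the integrals.
#'
#' @param dry,wet [od_map()] objects of equal dimension.
#' @return List of class `"growth_result"`: `gf_mass`, `od_integral_dry`,
#'   `od_integral_wet`.
#' @export
mass_growth_factor <- function(dry, wet) {
  stopifnot(inherits(dry, "od_map"), inherits(wet, "od_map"),
            all(dim(dry$od) == dim(wet$od)))
  m <- dry$mask | wet$mask
  if (!any(m)) stop("empty particle masks", call. = FALSE)
  int_dry <- sum(dry$od[m], na.rm = TRUE)
  int_wet <- sum(wet$od[m], na.rm = TRUE)
  if (int_dry <= 0) stop("zero dry OD integral", call. = FALSE)
  structure(list(gf_mass = int_wet / int_dry,
                 od_integral_dry = int_dry, od_integral_wet = int_wet),
            class = "growth_result")
}

#' @export
print.growth_result <- function(x, ...) {
  if (!is.null(x$gf_area)) {
    cat(sprintf("Area growth factor (wet/dry diameter): %.3f (area ratio %.3f)\n",
                x$gf_area, x$area_ratio))
    cat(sprintf("  d_dry = %.3f um, d_wet = %.3f um, RH %g%% -> %g%%\n",
                x$d_dry_um, x$d_wet_um, x$rh_pair[1], x$rh_pair[2]))
  }
  if (!is.null(x$gf_mass)) {
    cat(sprintf("Mass growth factor (wet/dry integrated OD): %.3f\n",
                x$gf_mass))
  }
  invisible(x)
}

#' Read a hydration pair from two single-channel TIFF files
#'
#' @param path_dry,path_wet Paths to grayscale TIFFs.
#' @inheritParams hydration_pair
#' @return A [hydration_pair()].
#' @export
read_hydration_pair <- function(path_dry, path_wet, rh_dry, rh_wet,
                                pixel_size_um = 0.05) {
  rd <- function(p) {
    m <- tiff::readTIFF(p)
    if (length(dim(m)) == 3L) m <- m[, , 1]
    m
  }
  hydration_pair(rd(path_dry), rd(path_wet), rh_dry, rh_wet, pixel_size_um)
}

#' Write a hydration pair as two single-channel TIFF files
#'
#' Frames are rescaled to [0, 1] jointly so relative contrast is preserved.
#'
#' @param pair A [hydration_pair()].
#' @param path_dry,path_wet Output paths.
#' @return Invisibly, the two paths.
#' @export
write_hydration_pair <- function(pair, path_dry, path_wet) {
  lo <- min(pair$frame_dry, pair$frame_wet)
  hi <- max(pair$frame_dry, pair$frame_wet)
  sc <- function(m) if (hi > lo) (m - lo) / (hi - lo) else m * 0
  tiff::writeTIFF(sc(pair$frame_dry), path_dry)
  tiff::writeTIFF(sc(pair$frame_wet), path_wet)
  invisible(c(path_dry, path_wet))
}
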