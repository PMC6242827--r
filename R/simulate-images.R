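# Shape rasterizers for synthetic microscopy frames. Shapes are simple
# filled regions on a uniform background - enough structure to exercise
# threshold-and-measure operators, nothing more. Each mask is built so its
# linear dimensions scale with `scale`, hence projected area with scale^2.

.shape_mask <- function(shape, dim_px, scale_px, cx, cy) {
  xs <- matrix(seq_len(dim_px[2]), nrow = dim_px[1], ncol = dim_px[2],
               byrow = TRUE)
  ys <- matrix(seq_len(dim_px[1]), nrow = dim_px[1], ncol = dim_px[2])
  r <- scale_px
  switch(shape,
    spherical = (xs - cx)^2 + (ys - cy)^2 <= r^2,
    spheroidal = {  # ellipse with 1.4:1 aspect, same area as the r-disk
      a <- r * sqrt(1.4); b <- r / sqrt(1.4)
      ((xs - cx) / a)^2 + ((ys - cy) / b)^2 <= 1
    },
    `rod-like` = {  # capsule: segment of half-length L with radius rho
      rho <- r / sqrt(1 + 8 / pi)  # area pi*rho^2 + 4*L*rho = pi*r^2, L = 2*rho
      L <- 2 * rho
      px <- pmin(pmax(xs, cx - L), cx + L)
      (xs - px)^2 + (ys - cy)^2 <= rho^2
    },
    stop("unsupported shape: ", shape, call. = FALSE)
  )
}

#' Generate a synthetic ESEM hydration frame pair
#'
#' Renders a dry particle (disk, ellipse, or capsule) and a wet particle of
#' the same shape whose projected area is the dry area times
#' `gf_diameter^2`, i.e. whose area-equivalent diameter grew by exactly
#' `gf_diameter`. Foreground/background contrast is high relative to the
#' stated Gaussian noise so the pair is segmentable by thresholding.
#'
#' @param gf_diameter Diameter growth factor, >= 1.
#' @param shape One of `"spherical"`, `"rod-like"`, `"spheroidal"`.
#' @param noise_sd Gaussian intensity noise SD (intensity units; frames use
#'   background 0.2, foreground 0.8).
#' @param seed Integer seed (used for the noise field).
#' @param dim_px Frame size in pixels (square).
#' @param dry_radius_px Dry-particle scale (px): the radius of the
#'   equal-area disk.
#' @param rh_dry,rh_wet RH labels (%) attached to the pair.
#' @param pixel_size_um Pixel size (um).
#' @return A [hydration_pair()].
#' @export
gen_hydration_pair <- function(gf_diameter, shape = "spherical",
                               noise_sd = 0, seed = 1L, dim_px = 256L,
                               dry_radius_px = 30,
                               rh_dry = 60, rh_wet = 94,
                               pixel_size_um = 0.05) {
  if (gf_diameter < 1) stop("gf_diameter must be >= 1", call. = FALSE)
  shape <- match.arg(shape, c("spherical", "rod-like", "spheroidal"))
  bg <- 0.2; fg <- 0.8
  cx <- (dim_px + 1) / 2; cy <- cx
  wet_radius <- dry_radius_px * gf_diameter
  if (wet_radius * sqrt(1.4) > dim_px / 2 - 2) {
    stop("wet particle would touch the frame edge; increase dim_px",
         call. = FALSE)
  }
  withr::with_seed(as.integer(seed), {
    render <- function(scale_px) {
      m <- matrix(bg, dim_px, dim_px)
      m[.shape_mask(shape, c(dim_px, dim_px), scale_px, cx, cy)] <- fg
      if (noise_sd > 0) m <- m + matrix(rnorm(dim_px^2, sd = noise_sd),
                                        dim_px, dim_px)
      m
    }
    hydration_pair(render(dry_radius_px), render(wet_radius),
                   rh_dry, rh_wet, pixel_size_um)
  })
}

#' Generate a synthetic STXM transmission-map pair
#'
#' Builds dry and wet optical-density maps over disk masks and converts
#' them to transmitted-intensity maps via I = I0 exp(-OD). The wet disk's
#' per-pixel OD is set so that the integrated OD over the wet mask equals
#' `mass_ratio` times the integrated OD over the dry mask *exactly* for the
#' rasterized masks - at the oxygen edge, a wet/dry mass ratio of
#' `mass_ratio`.
#'
#' @param mass_ratio Wet/dry integrated-OD (mass) ratio, >= 1.
#' @param seed Integer seed (noise field).
#' @param dim_px Map size (px).
#' @param dry_radius_px Dry disk radius (px).
#' @param od_dry Per-pixel OD of the dry particle.
#' @param i0 Reference (incident) intensity.
#' @param wet_area_ratio Wet/dry projected-area ratio; the default spreads
#'   the added mass over a modestly larger footprint.
#' @param noise_sd Multiplicative intensity noise SD (fraction of I).
#' @return List with elements `dry` and `wet`, both [od_map()] objects.
#' @export
gen_stxm_pair <- function(mass_ratio, seed = 1L, dim_px = 128L,
                          dry_radius_px = 20, od_dry = 1.0, i0 = 1000,
                          wet_area_ratio = max(1, mass_ratio^(2 / 3)),
                          noise_sd = 0) {
  if (mass_ratio < 1) stop("mass_ratio must be >= 1", call. = FALSE)
  cx <- (dim_px + 1) / 2
  mask_dry <- .shape_mask("spherical", c(dim_px, dim_px), dry_radius_px,
                          cx, cx)
  wet_radius <- dry_radius_px * sqrt(wet_area_ratio)
  if (wet_radius > dim_px / 2 - 2) {
    stop("wet particle would touch the frame edge; increase dim_px",
         call. = FALSE)
  }
  mask_wet <- .shape_mask("spherical", c(dim_px, dim_px), wet_radius, cx, cx)
  od_d <- matrix(0, dim_px, dim_px)
  od_d[mask_dry] <- od_dry
  int_dry <- sum(od_d)
  od_w <- matrix(0, dim_px, dim_px)
  od_w[mask_wet] <- mass_ratio * int_dry / sum(mask_wet)
  withr::with_seed(as.integer(seed), {
    to_intensity <- function(od) {
      I <- i0 * exp(-od)
      if (noise_sd > 0) I <- I * (1 + matrix(rnorm(dim_px^2, sd = noise_sd),
                                             dim_px, dim_px))
      I
    }
    list(dry = od_map(to_intensity(od_d), i0 = i0, mask = mask_dry),
         wet = od_map(to_intensity(od_w), i0 = i0, mask = mask_wet))
  })
}
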