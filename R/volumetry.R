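#' Spherical-cap shape factor
#'
#' The deposited droplet is modelled as a spherical cap sitting on the chip
#' with contact angle `theta`. Its volume factors into a footprint-radius
#' cube times the dimensionless shape factor
#' \deqn{g(\theta) = \cos^3\theta - 3\cos\theta + 2,}
#' which runs from 0 (vanishing film) through 2 (hemisphere, 90 degrees) to
#' 4 (full sphere, 180 degrees) and is strictly increasing in between.
#'
#' @param theta_deg Contact angle in degrees, in `(0, 180]`.
#' @return The shape factor, a number in `[0, 4]`.
#' @export
#' @examples
#' shape_factor(90)   # hemisphere: 2
shape_factor <- function(theta_deg) {
  if (!is.numeric(theta_deg) || any(theta_deg < 0) || any(theta_deg > 180)) {
    stop("`theta_deg` must lie in [0, 180]", call. = FALSE)
  }
  ct <- cos(theta_deg * pi / 180)
  ct^3 - 3 * ct + 2
}

#' Volume of a spherical cap
#'
#' Stacking infinitesimal circular slices of a sphere of radius `R` up to
#' cap height `h` gives
#' \deqn{V = \int_{R-h}^{R} \pi (R^2 - y^2)\, dy
#'         = \pi R h^2 - \tfrac{1}{3}\pi h^3,}
#' the standard spherical-cap volume \eqn{\pi h^2 (3R - h) / 3}. It runs
#' from 0 at `h = 0` through the hemisphere \eqn{2\pi R^3/3} at `h = R` to
#' the full sphere \eqn{4\pi R^3/3} at `h = 2R`, and is consistent with the
#' contact-angle form used by [volume_from_area()] under
#' `h = R (1 - cos(theta))`.
#'
#' @param R Sphere radius (mm), positive.
#' @param h Cap height (mm), in `[0, 2R]`.
#' @return Cap volume in mm^3.
#' @export
#' @examples
#' cap_volume(1, 1)          # hemisphere, 2*pi/3
#' cap_volume(1, 2)          # full sphere, 4*pi/3
cap_volume <- function(R, h) {
  if (!is.numeric(R) || any(R <= 0)) {
    stop("sphere radius R must be positive", call. = FALSE)
  }
  if (!is.numeric(h) || any(h < 0) || any(h > 2 * R)) {
    stop("cap height h must lie in [0, 2R]", call. = FALSE)
  }
  pi * R * h^2 - pi * h^3 / 3
}

#' Droplet volume from its imaged footprint area
#'
#' Converts the measured pixel area of the droplet footprint into a volume
#' in nanolitres. The footprint is reduced to its equivalent-circle radius
#' `R0 = sqrt(area / pi)` (pixels), scaled to millimetres with the
#' reference-point calibration, and plugged into the spherical-cap model:
#' \deqn{V = \frac{\pi}{3}\left(\frac{D_{ref}}{D_{pix}} R_0\right)^3
#'           (\cos^3\theta - 3\cos\theta + 2).}
#' At `theta = 90` degrees this is exactly a hemisphere of radius
#' `mm_per_px * R0`.
#'
#' @param area_px Foreground area in pixels, positive.
#' @param theta_deg Contact angle in degrees, in `(0, 180]`.
#' @param scale A [scale_calibration()].
#' @return Volume in nanolitres (1 mm^3 = 1000 nL), with the equivalent
#'   footprint radius (pixels) in attribute `r0_px`.
#' @export
#' @examples
#' sc <- scale_calibration(1.2, 260)
#' volume_from_area(15831, 86.3, sc)
volume_from_area <- function(area_px, theta_deg, scale) {
  if (!is.numeric(area_px) || length(area_px) != 1 || area_px <= 0) {
    stop("`area_px` must be a single positive number", call. = FALSE)
  }
  if (length(theta_deg) != 1 || theta_deg <= 0 || theta_deg > 180) {
    stop("`theta_deg` must lie in (0, 180]", call. = FALSE)
  }
  if (!inherits(scale, "scale_calibration")) {
    stop("`scale` must be a `scale_calibration`", call. = FALSE)
  }
  r0_px <- sqrt(area_px / pi)
  v_mm3 <- (pi / 3) * (scale$mm_per_px * r0_px)^3 * shape_factor(theta_deg)
  structure(v_mm3 * 1000, r0_px = r0_px)
}

#' Read a fluid property table
#'
#' @param path CSV with header
#'   `name,density_kg_m3,viscosity_pa_s,contact_angle_deg`.
#' @return A data frame of fluid records.
#' @seealso [fluid_properties()] for the packaged table,
#'   [contact_angle_for()].
#' @export
read_fluid_table <- function(path) {
  tab <- read.csv(path, stringsAsFactors = FALSE)
  needed <- c("name", "density_kg_m3", "viscosity_pa_s", "contact_angle_deg")
  if (!all(needed %in% names(tab))) {
    stop("fluid table must have columns ", paste(needed, collapse = ", "),
         call. = FALSE)
  }
  if (nrow(tab) == 0) stop("fluid table is empty", call. = FALSE)
  bad <- tab$density_kg_m3 <= 0 | tab$viscosity_pa_s <= 0 |
    tab$contact_angle_deg <= 0 | tab$contact_angle_deg > 180
  if (any(bad)) {
    stop("invalid fluid record(s): ", paste(tab$name[bad], collapse = ", "),
         call. = FALSE)
  }
  tab
}

#' Packaged fluid property table
#'
#' Density, viscosity and measured contact angle for the four working
#' fluids: pure water, the mass-spectrometry calibrator, and two PCR-product
#' samples.
#'
#' @return A data frame with columns `name`, `density_kg_m3`,
#'   `viscosity_pa_s`, `contact_angle_deg`.
#' @export
fluid_properties <- function() {
  read_fluid_table(pindrop_extdata("fluids.csv"))
}

#' Look up or interpolate a contact angle
#'
#' Returns the tabulated contact angle when the queried density and
#' viscosity match a fluid record exactly. Otherwise the angle is
#' interpolated piecewise-linearly in viscosity (records sharing a viscosity
#' are averaged first) and clamped to the tabulated range; with only a
#' handful of anchor fluids, any richer functional form would over-claim.
#' Over the packaged fluids the angle decreases with viscosity.
#'
#' @param fluids A fluid table, e.g. [fluid_properties()].
#' @param density_kg_m3 Fluid density (kg/m^3).
#' @param viscosity_pa_s Dynamic viscosity (Pa s).
#' @return Contact angle in degrees.
#' @export
#' @examples
#' contact_angle_for(fluid_properties(), 996.81, 0.0009)  # calibrator: 86.5
contact_angle_for <- function(fluids, density_kg_m3, viscosity_pa_s) {
  if (!is.data.frame(fluids) || nrow(fluids) == 0) {
    stop("fluid table is empty", call. = FALSE)
  }
  near <- function(a, b) abs(a - b) <= 1e-9 * pmax(abs(a), abs(b), 1e-300)
  hit <- which(near(fluids$density_kg_m3, density_kg_m3) &
                 near(fluids$viscosity_pa_s, viscosity_pa_s))
  if (length(hit)) {
    return(fluids$contact_angle_deg[hit[1]])
  }
  ang <- tapply(fluids$contact_angle_deg, fluids$viscosity_pa_s, mean)
  visc <- as.numeric(names(ang))
  if (length(visc) == 1) {
    return(as.numeric(ang[1]))
  }
  approx(visc, as.numeric(ang), xout = viscosity_pa_s, rule = 2)$y
}
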