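#' Specification of a synthetic droplet scene
#'
#' Describes a top-view droplet image with known ground truth, emulating
#' what the dispenser's camera sees: a bright chip surface, a darker
#' circular droplet footprint, a linear illumination gradient across the
#' frame, plus salt-and-pepper and Gaussian sensor noise. The footprint
#' radius is *derived* from the true volume by inverting the spherical-cap
#' model, so a rendered scene and the measurement pipeline close a full
#' volume round trip.
#'
#' @param volume_nl True dispensed volume (nL); 0 renders background only.
#' @param theta_deg Contact angle in degrees.
#' @param mm_per_px Image scale (default the reference calibration
#'   1.2 mm / 260 px).
#' @param size Frame size in pixels, `c(height, width)`.
#' @param center Droplet centre `c(row, col)`, possibly fractional;
#'   default the frame centre.
#' @param background_level Gray level of the lit chip surface.
#' @param droplet_level Gray level inside the droplet (darker).
#' @param gradient_amplitude Peak-to-peak swing (levels) of the linear
#'   illumination gradient across columns.
#' @param salt_pepper Fraction of pixels replaced by extreme levels, in
#'   `[0, 1)`.
#' @param gaussian_sigma SD (levels) of additive Gaussian noise.
#' @param seed Integer seed; all scene randomness derives from it.
#' @return An object of class `scene_spec`.
#' @seealso [render_droplet()]
#' @export
scene_spec <- function(volume_nl, theta_deg = 86.3, mm_per_px = 1.2 / 260,
                       size = c(320L, 320L), center = NULL,
                       background_level = 200L, droplet_level = 90L,
                       gradient_amplitude = 15, salt_pepper = 0.005,
                       gaussian_sigma = 2, seed = 1L) {
  size <- as.integer(size)
  if (length(size) != 2 || any(size < 8)) {
    stop("`size` must be two integers >= 8", call. = FALSE)
  }
  if (is.null(center)) center <- (size + 1) / 2
  if (volume_nl < 0) stop("`volume_nl` must be >= 0", call. = FALSE)
  if (salt_pepper < 0 || salt_pepper >= 1) {
    stop("`salt_pepper` must lie in [0, 1)", call. = FALSE)
  }
  if (gaussian_sigma < 0) stop("`gaussian_sigma` must be >= 0", call. = FALSE)
  if (droplet_level >= background_level) {
    stop("droplet must be darker than the background", call. = FALSE)
  }
  spec <- structure(list(volume_nl = volume_nl, theta_deg = theta_deg,
                         mm_per_px = mm_per_px, size = size, center = center,
                         background_level = background_level,
                         droplet_level = droplet_level,
                         gradient_amplitude = gradient_amplitude,
                         salt_pepper = salt_pepper,
                         gaussian_sigma = gaussian_sigma,
                         seed = as.integer(seed)),
                    class = "scene_spec")
  r0 <- footprint_radius_px(spec)
  margin <- r0 + 2
  if (volume_nl > 0 &&
      (center[1] - margin < 1 || center[1] + margin > size[1] ||
       center[2] - margin < 1 || center[2] + margin > size[2])) {
    stop(sprintf("droplet footprint (R0 = %.1f px) does not fit the frame",
                 r0), call. = FALSE)
  }
  spec
}

# Invert the spherical-cap relation: volume + contact angle + scale ->
# footprint radius in pixels.
footprint_radius_px <- function(spec) {
  if (spec$volume_nl == 0) return(0)
  v_mm3 <- spec$volume_nl / 1000
  r0_mm <- (3 * v_mm3 / (pi * shape_factor(spec$theta_deg)))^(1 / 3)
  r0_mm / spec$mm_per_px
}

# Anti-aliased disk coverage on the pixel grid: 1 inside, 0 outside, and
# 4x4 supersampled coverage in a 2 px band around the rim.
disk_coverage <- function(size, center, radius) {
  H <- size[1]; W <- size[2]
  cov <- matrix(0, H, W)
  if (radius <= 0) return(cov)
  r <- matrix(seq_len(H), H, W)
  c <- matrix(seq_len(W), H, W, byrow = TRUE)
  d <- sqrt((r - center[1])^2 + (c - center[2])^2)
  cov[d <= radius - 1] <- 1
  edge <- which(d > radius - 1 & d < radius + 1)
  if (length(edge)) {
    off <- (seq_len(4) - 2.5) / 4
    sub <- expand.grid(dy = off, dx = off)
    for (p in edge) {
      cov[p] <- mean(sqrt((r[p] + sub$dy - center[1])^2 +
                            (c[p] + sub$dx - center[2])^2) <= radius)
    }
  }
  cov
}

finish_scene <- function(img, spec) {
  H <- spec$size[1]; W <- spec$size[2]
  cgrid <- matrix(seq_len(W), H, W, byrow = TRUE)
  img <- img + spec$gradient_amplitude * ((cgrid - 1) / (W - 1) - 0.5)
  set.seed(spec$seed)
  if (spec$gaussian_sigma > 0) {
    img <- img + rnorm(H * W, 0, spec$gaussian_sigma)
  }
  img <- round(img)
  if (spec$salt_pepper > 0) {
    n <- round(spec$salt_pepper * H * W)
    if (n > 0) {
      pos <- sample.int(H * W, n)
      img[pos] <- ifelse(runif(n) < 0.5, 1, 256)
    }
  }
  gray_image(matrix(as.integer(clamp(img, 1, 256)), H, W), S = 256L)
}

#' Render a synthetic droplet image with ground truth
#'
#' Draws the darker droplet disk (anti-aliased by 4x4 supersampled rim
#' coverage, so the rendered pixel area tracks the continuum footprint to
#' sub-pixel accuracy), applies the illumination gradient, then the seeded
#' noise.
#'
#' @param spec A [scene_spec()].
#' @return A list with `image` (a [gray_image()]) and `truth`: the exact
#'   footprint radius `r0_px`, continuum `area_px`, `volume_nl`,
#'   `theta_deg`, `mm_per_px` and `center` used.
#' @export
#' @examples
#' sc <- render_droplet(scene_spec(volume_nl = 100, seed = 7))
#' sc$truth$r0_px
render_droplet <- function(spec) {
  stopifnot(inherits(spec, "scene_spec"))
  r0 <- footprint_radius_px(spec)
  cov <- disk_coverage(spec$size, spec$center, r0)
  img <- spec$background_level -
    cov * (spec$background_level - spec$droplet_level)
  list(image = finish_scene(img, spec),
       truth = list(r0_px = r0, area_px = pi * r0^2,
                    volume_nl = spec$volume_nl, theta_deg = spec$theta_deg,
                    mm_per_px = spec$mm_per_px, center = spec$center))
}

#' Render a reference-point (fiducial) image
#'
#' Two dark dots a known centroid distance apart on the lit background,
#' for exercising [calibrate_scale()]. Centres may be fractional, so the
#' recovered `D_pix` can be validated to sub-pixel accuracy.
#'
#' @param distance_px Centroid distance between the two dots (pixels).
#' @param d_ref_mm Physical distance the dots represent (mm).
#' @param dot_radius_px Dot radius (pixels).
#' @param size Frame size `c(height, width)`; default fits the dots with
#'   margin.
#' @param noise As in [scene_spec()]: `salt_pepper` fraction and
#'   `gaussian_sigma` levels.
#' @param seed Integer seed.
#' @return A list with `image` and `truth` (`d_pix`, `d_ref_mm`, centres).
#' @export
render_reference_points <- function(distance_px, d_ref_mm = 1.2,
                                    dot_radius_px = 8,
                                    size = NULL,
                                    noise = list(salt_pepper = 0.005,
                                                 gaussian_sigma = 2),
                                    seed = 1L) {
  if (distance_px < 0) stop("`distance_px` must be >= 0", call. = FALSE)
  if (is.null(size)) {
    w <- as.integer(ceiling(distance_px + 4 * dot_radius_px + 40))
    size <- c(max(64L, as.integer(4 * dot_radius_px + 40)), max(64L, w))
  }
  size <- as.integer(size)
  mid <- (size + 1) / 2
  centers <- rbind(c(mid[1], mid[2] - distance_px / 2),
                   c(mid[1], mid[2] + distance_px / 2))
  if (any(centers[, 2] - dot_radius_px < 1) ||
      any(centers[, 2] + dot_radius_px > size[2])) {
    stop("dots do not fit the frame", call. = FALSE)
  }
  spec <- structure(list(size = size, gradient_amplitude = 0,
                         salt_pepper = noise$salt_pepper,
                         gaussian_sigma = noise$gaussian_sigma,
                         seed = as.integer(seed)),
                    class = "scene_spec_internal")
  cov <- disk_coverage(size, centers[1, ], dot_radius_px) +
    disk_coverage(size, centers[2, ], dot_radius_px)
  cov <- pmin(cov, 1)
  img <- 200 - cov * 110
  list(image = finish_scene(img, spec),
       truth = list(d_pix = distance_px, d_ref_mm = d_ref_mm,
                    centers = centers))
}

#' Specification of the stochastic dispense process
#'
#' The "true" plant the control simulator runs against: a dispense law
#' `f_true(v, h)` (by default the packaged calibration extended to 5 mm so
#' regulation has actuation headroom), multiplicative volume noise, and a
#' monotone reservoir-level drift that lowers the *effective* dipping depth
#' by `drift_mm_per_step` each dispense — the disturbance a fixed-depth
#' open-loop strategy cannot reject.
#'
#' @param grid The true [calibration_grid()]; may deliberately differ from
#'   the controller's belief.
#' @param noise_cv Relative SD of the dispensed volume (default 0.01, the
#'   ~1% repeatability of the measured volumes).
#' @param drift_mm_per_step Reservoir level drop per dispense (mm).
#' @param seed Default seed used by the run helpers.
#' @return An object of class `process_spec`.
#' @seealso [simulate_dispense()], [closed_loop_run()], [open_loop_run()]
#' @export
process_spec <- function(grid = extend_calibration(table1_grid(), 5),
                         noise_cv = 0.01, drift_mm_per_step = 0.02,
                         seed = 1L) {
  stopifnot(inherits(grid, "calibration_grid"))
  if (noise_cv < 0) stop("`noise_cv` must be >= 0", call. = FALSE)
  if (drift_mm_per_step < 0) stop("`drift_mm_per_step` must be >= 0",
                                  call. = FALSE)
  structure(list(grid = grid, noise_cv = noise_cv,
                 drift_mm_per_step = drift_mm_per_step,
                 seed = as.integer(seed)),
            class = "process_spec")
}

#' Draw one dispensed volume from the stochastic process
#'
#' The reservoir level has dropped `step * drift` mm after `step`
#' dispenses, so the commanded depth `h` reaches only an effective depth
#' `h - step * drift`. The dispensed volume is
#' `f_true(v, h_eff) * (1 + e)` with `e ~ N(0, noise_cv)`, truncated at 0.
#' Randomness comes from the caller's RNG state (seed it with `set.seed()`
#' or use the run helpers, which seed per run).
#'
#' @param proc A [process_spec()].
#' @param velocity_mm_s,depth_mm Commanded dispense parameters.
#' @param step Dispense index (1-based) driving the cumulative drift.
#' @return Volume in nL.
#' @export
simulate_dispense <- function(proc, velocity_mm_s, depth_mm, step) {
  stopifnot(inherits(proc, "process_spec"))
  if (depth_mm <= 0 || velocity_mm_s <= 0) {
    stop("dispense parameters must be positive", call. = FALSE)
  }
  eff <- depth_mm - step * proc$drift_mm_per_step
  if (eff <= 0) {
    stop(sprintf(paste0("dry dip: effective depth %.3f mm at step %d ",
                        "(reservoir exhausted)"), eff, step), call. = FALSE)
  }
  vol <- predict_volume(proc$grid, velocity_mm_s, eff)
  if (proc$noise_cv > 0) {
    vol <- vol * (1 + rnorm(1, 0, proc$noise_cv))
  }
  max(vol, 0)
}

#' Write a rendered scene to disk as PNG plus ground-truth JSON
#'
#' @param scene A list from [render_droplet()] or
#'   [render_reference_points()].
#' @param path Output PNG path; the truth sidecar goes to `<path>.json`.
#' @return `path`, invisibly.
#' @export
write_scene <- function(scene, path) {
  write_gray_image(scene$image, path)
  jsonlite::write_json(scene$truth, paste0(path, ".json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(path)
}
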