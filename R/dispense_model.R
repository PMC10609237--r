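#' Velocity-by-depth dispense calibration grid
#'
#' The contacting dispenser's output volume is an empirical function
#' `Volume = f(v, h)` of the pin's downward velocity `v` and its dipping
#' depth `h` in the sample reservoir. The grid stores measured volumes on a
#' rectangular set of `(v, h)` nodes; [predict_volume()] interpolates
#' between them.
#'
#' @param velocities Strictly increasing velocities (mm/s).
#' @param depths Strictly increasing dipping depths (mm).
#' @param volumes Matrix of dispensed volumes (nL), rows = velocities,
#'   columns = depths; complete (no `NA`) and positive.
#' @return An object of class `calibration_grid`.
#' @seealso [load_calibration()], [table1_grid()], [predict_volume()],
#'   [invert_for_depth()]
#' @export
calibration_grid <- function(velocities, depths, volumes) {
  velocities <- as.numeric(velocities)
  depths <- as.numeric(depths)
  if (length(velocities) < 1 || any(diff(velocities) <= 0)) {
    stop("velocities must be strictly increasing", call. = FALSE)
  }
  if (length(depths) < 1 || any(diff(depths) <= 0)) {
    stop("depths must be strictly increasing", call. = FALSE)
  }
  if (any(velocities <= 0) || any(depths <= 0)) {
    stop("velocities and depths must be positive", call. = FALSE)
  }
  volumes <- as.matrix(volumes)
  if (nrow(volumes) != length(velocities) ||
      ncol(volumes) != length(depths)) {
    stop("`volumes` must be a length(velocities) x length(depths) matrix",
         call. = FALSE)
  }
  if (anyNA(volumes)) stop("calibration grid has missing cells", call. = FALSE)
  if (any(volumes <= 0)) stop("all volumes must be positive", call. = FALSE)
  dimnames(volumes) <- list(format(velocities), format(depths))
  structure(list(velocities = velocities, depths = depths, volumes = volumes),
            class = "calibration_grid")
}

#' @export
print.calibration_grid <- function(x, ...) {
  cat(sprintf("<calibration_grid> %d velocities x %d depths (nL)\n",
              length(x$velocities), length(x$depths)))
  print(x$volumes)
  invisible(x)
}

#' Read a dispense calibration grid from CSV
#'
#' Expected layout: a `velocity_mm_s` column followed by one `depth_<h>`
#' column per dipping depth, e.g. `velocity_mm_s,depth_2,depth_2.1,...`.
#' Rows are sorted by velocity; duplicated velocities, unparsable depth
#' headers or missing cells are format errors.
#'
#' @param path Path to the CSV file.
#' @return A [calibration_grid()].
#' @export
load_calibration <- function(path) {
  tab <- read.csv(path, check.names = FALSE)
  if (!"velocity_mm_s" %in% names(tab) || ncol(tab) < 2) {
    stop("calibration CSV needs a `velocity_mm_s` column and at least one ",
         "`depth_<h>` column", call. = FALSE)
  }
  depth_cols <- setdiff(names(tab), "velocity_mm_s")
  if (!all(grepl("^depth_", depth_cols))) {
    stop("unexpected column(s): ",
         paste(setdiff(depth_cols, grep("^depth_", depth_cols, value = TRUE)),
               collapse = ", "), call. = FALSE)
  }
  depths <- suppressWarnings(as.numeric(sub("^depth_", "", depth_cols)))
  if (anyNA(depths)) {
    stop("cannot parse depth from column header(s)", call. = FALSE)
  }
  v <- tab$velocity_mm_s
  if (anyDuplicated(v)) {
    stop("duplicated velocity row(s) in calibration CSV", call. = FALSE)
  }
  ord <- order(v)
  vol <- as.matrix(tab[ord, depth_cols, drop = FALSE])
  if (anyNA(vol)) stop("calibration CSV has missing cells", call. = FALSE)
  dord <- order(depths)
  calibration_grid(v[ord], depths[dord], vol[, dord, drop = FALSE])
}

#' Packaged dispense calibration grid
#'
#' The measured volume grid over velocities 100/150/400/1000 mm/s and
#' dipping depths 2-3 mm that identifies the empirical dispense law
#' `f(v, h)`, shipped as `extdata/table1.csv`.
#'
#' @return A [calibration_grid()].
#' @export
#' @examples
#' predict_volume(table1_grid(), 100, 3)
table1_grid <- function() {
  load_calibration(pindrop_extdata("table1.csv"))
}

#' Extend a calibration grid to deeper dipping depths
#'
#' Appends depth nodes beyond the calibrated envelope by continuing each
#' velocity's last depth segment linearly. The measured grid tops out below
#' some useful setpoints (its densest node is ~76 nL while the instrument's
#' working band runs to 200 nL), and volume grows monotonically with depth
#' at the envelope edge, so a linear continuation is the least-commitment
#' way to give the controller headroom. Use with the usual caution owed to
#' extrapolated calibrations.
#'
#' @param grid A [calibration_grid()].
#' @param to_depth Extend until the depth axis reaches at least this (mm).
#' @param step Spacing of appended depth nodes (mm).
#' @return A [calibration_grid()] with the extra depth columns.
#' @export
extend_calibration <- function(grid, to_depth, step = 0.5) {
  stopifnot(inherits(grid, "calibration_grid"))
  nd <- length(grid$depths)
  if (nd < 2) stop("need at least two depth nodes to extend", call. = FALSE)
  last <- grid$depths[nd]
  if (to_depth <= last) return(grid)
  new_depths <- seq(last + step, to_depth + step - 1e-9, by = step)
  slope <- (grid$volumes[, nd] - grid$volumes[, nd - 1]) /
    (grid$depths[nd] - grid$depths[nd - 1])
  extra <- outer(slope, new_depths - last) + grid$volumes[, nd]
  if (any(extra <= 0)) {
    stop("linear extension would produce non-positive volumes", call. = FALSE)
  }
  calibration_grid(grid$velocities, c(grid$depths, new_depths),
                   cbind(grid$volumes, extra))
}

#' Predict dispensed volume at a velocity and depth
#'
#' Bilinear interpolation of the calibration grid, exact at grid nodes. The
#' grid is coarse and not everywhere monotone across depth, so a
#' shape-preserving spline would over-fit; bilinear is the least-commitment
#' interpolant. Queries outside the calibrated envelope are clamped to the
#' nearest edge with a warning, since behaviour out there was never
#' measured.
#'
#' @param grid A [calibration_grid()].
#' @param velocity_mm_s Downward velocity (mm/s).
#' @param depth_mm Dipping depth (mm).
#' @return Predicted volume (nL).
#' @export
#' @examples
#' g <- table1_grid()
#' predict_volume(g, 1000, 2)    # a grid node, returned exactly
#' predict_volume(g, 125, 2)     # interpolated between 100 and 150 mm/s
predict_volume <- function(grid, velocity_mm_s, depth_mm) {
  stopifnot(inherits(grid, "calibration_grid"))
  v <- grid$velocities; h <- grid$depths
  if (velocity_mm_s < v[1] || velocity_mm_s > v[length(v)] ||
      depth_mm < h[1] || depth_mm > h[length(h)]) {
    warning(sprintf(paste0("query (v = %g mm/s, h = %g mm) outside the ",
                           "calibrated envelope; clamped to its edge"),
                    velocity_mm_s, depth_mm), call. = FALSE)
    velocity_mm_s <- clamp(velocity_mm_s, v[1], v[length(v)])
    depth_mm <- clamp(depth_mm, h[1], h[length(h)])
  }
  interp_1d <- function(x, xs, f) {
    n <- length(xs)
    if (n == 1) return(f)
    i <- min(max(findInterval(x, xs), 1L), n - 1L)
    t <- (x - xs[i]) / (xs[i + 1] - xs[i])
    (1 - t) * f[i, , drop = FALSE] + t * f[i + 1, , drop = FALSE]
  }
  row <- interp_1d(velocity_mm_s, v, grid$volumes)
  as.numeric(interp_1d(depth_mm, h, t(row)))
}

# Volumes at every depth node for a fixed velocity (linear in v); the
# depth profile f(v, .) is piecewise linear between these.
depth_profile <- function(grid, velocity_mm_s) {
  v <- grid$velocities
  if (velocity_mm_s < v[1] || velocity_mm_s > v[length(v)]) {
    stop("velocity outside the calibrated envelope", call. = FALSE)
  }
  n <- length(v)
  if (n == 1) return(as.numeric(grid$volumes[1, ]))
  i <- min(max(findInterval(velocity_mm_s, v), 1L), n - 1L)
  t <- (velocity_mm_s - v[i]) / (v[i + 1] - v[i])
  as.numeric((1 - t) * grid$volumes[i, ] + t * grid$volumes[i + 1, ])
}

#' Dipping depth that yields a target volume
#'
#' Inverts the interpolated dispense law at fixed velocity: the smallest
#' depth `h` with `predict_volume(grid, v, h) == target`. The depth profile
#' is piecewise linear, so each bracketing segment is solved exactly; the
#' smallest root is returned when the profile is non-monotone. This is the
#' actuation direction of the feedback controller, which adjusts dipping
#' depth to regulate volume.
#'
#' @param grid A [calibration_grid()].
#' @param velocity_mm_s Fixed downward velocity (mm/s).
#' @param target_nl Target volume (nL). Must be achievable at this
#'   velocity; otherwise an error carrying the achievable range in
#'   attribute `achievable_nl` is thrown.
#' @return Depth in mm with `|f(v, h) - target| <= 0.01` nL.
#' @export
#' @examples
#' invert_for_depth(table1_grid(), 100, 61.72)   # back to the 3 mm node
invert_for_depth <- function(grid, velocity_mm_s, target_nl) {
  stopifnot(inherits(grid, "calibration_grid"))
  prof <- depth_profile(grid, velocity_mm_s)
  h <- grid$depths
  lo <- min(prof); hi <- max(prof)
  if (target_nl < lo - 1e-9 || target_nl > hi + 1e-9) {
    stop(structure(class = c("pindrop_range_error", "error", "condition"),
                   list(message = sprintf(
                     paste0("target %.4g nL unreachable at %g mm/s; ",
                            "achievable range is [%.4g, %.4g] nL"),
                     target_nl, velocity_mm_s, lo, hi),
                     call = NULL, achievable_nl = c(lo, hi))))
  }
  if (length(h) == 1) return(h)
  for (i in seq_len(length(h) - 1)) {
    a <- prof[i]; b <- prof[i + 1]
    if (abs(target_nl - a) <= 1e-12 * max(1, abs(a))) return(h[i])
    if ((target_nl - a) * (target_nl - b) <= 0 && a != b) {
      return(h[i] + (target_nl - a) / (b - a) * (h[i + 1] - h[i]))
    }
  }
  h[length(h)]  # target == last node value (within tolerance)
}
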