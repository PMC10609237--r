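#' Median filter an image
#'
#' Sliding-window median smoothing, the standard pre-processing step for
#' salt-and-pepper noise that preserves edges. The default window is
#' 10 x 10. Conventions for the cases a square odd window never meets:
#'
#' * **Even windows** have no centre pixel; the output pixel sits at offset
#'   `(floor((h-1)/2), floor((w-1)/2))` from the window's top-left corner.
#' * **Borders** are handled by reflect padding, which avoids the edge
#'   darkening that zero padding would feed into the area measurement.
#' * **Even pixel counts** take the *lower* median (no interpolation), so
#'   output intensities always belong to the input's value set.
#'
#' @param img A [gray_image()].
#' @param window Window size as `c(height, width)` or a single integer for a
#'   square window. Must be at least 1 and no larger than the image.
#' @return A filtered [gray_image()] of the same dimensions.
#' @export
#' @examples
#' img <- gray_image(matrix(c(5, 5, 5, 200, 5, 5, 5, 5, 5), 3, 3), S = 256)
#' median_filter(img, c(3, 3))
median_filter <- function(img, window = c(10L, 10L)) {
  assert_gray_image(img)
  if (length(window) == 1) window <- c(window, window)
  window <- as.integer(window)
  if (length(window) != 2 || anyNA(window) || any(window < 1)) {
    stop("`window` must be one or two positive integers", call. = FALSE)
  }
  if (window[1] > nrow(img) || window[2] > ncol(img)) {
    stop(sprintf("window (%d x %d) larger than image (%d x %d)",
                 window[1], window[2], nrow(img), ncol(img)), call. = FALSE)
  }
  out <- median_filter_cpp(unclass(img), window[1], window[2])
  gray_image(out, S = num_levels(img))
}

#' Gray-level histogram of an image
#'
#' Counts `n_i` of pixels at each level `i = 1..S` and the corresponding
#' probabilities `p_i = n_i / N`, treating the histogram as a discrete
#' probability distribution over gray levels.
#'
#' @param img A [gray_image()].
#' @param S Number of levels; defaults to the image's own `S`.
#' @return An object of class `gray_histogram` with fields `counts`
#'   (length `S`), `n` (total pixels) and `p` (probabilities summing to 1).
#' @export
gray_histogram <- function(img, S = NULL) {
  assert_gray_image(img)
  if (is.null(S)) S <- num_levels(img)
  S <- as.integer(S)
  if (is.na(S) || S < 2) stop("`S` must be an integer >= 2", call. = FALSE)
  if (max(img) > S) {
    stop("image has levels above S = ", S, call. = FALSE)
  }
  counts <- tabulate(as.vector(img), nbins = S)
  n <- sum(counts)
  structure(list(counts = counts, n = n, p = counts / n),
            class = "gray_histogram")
}

#' @export
print.gray_histogram <- function(x, ...) {
  occ <- which(x$counts > 0)
  cat(sprintf("<gray_histogram> %d levels, %d pixels, occupied [%d, %d]\n",
              length(x$counts), x$n, min(occ), max(occ)))
  invisible(x)
}

#' Otsu's optimal global threshold
#'
#' Splits the gray-level histogram into a low class `C0` (levels `1..k`) and
#' a high class `C1` (levels `k+1..S`) at the threshold `k*` that maximizes
#' the between-class variance
#' \deqn{\sigma_B^2(k) = \omega_0 \omega_1 (\mu_1 - \mu_0)^2,}
#' where \eqn{\omega_0, \omega_1} are the class probabilities and
#' \eqn{\mu_0, \mu_1} the class mean levels. Only thresholds with
#' \eqn{0 < \omega(k) < 1} are admissible; ties are broken to the smallest
#' `k` so the result is deterministic.
#'
#' @param h A [gray_histogram()].
#' @return The integer threshold `k*`, with the attained between-class
#'   variance in attribute `between_class_variance`.
#' @seealso [otsu_scan()] for the full criterion curve, [binarize()].
#' @export
otsu_threshold <- function(h) {
  scan <- otsu_scan(h)
  k <- scan$k[which.max(scan$sigma_b2)]
  structure(k, between_class_variance = max(scan$sigma_b2))
}

#' Between-class variance at every admissible threshold
#'
#' Returns the full scan underlying [otsu_threshold()]: for each admissible
#' `k`, the class probabilities, class means and the between-class variance.
#' Useful for inspecting the criterion and for verifying the conservation
#' identity \eqn{\omega_0\mu_0 + \omega_1\mu_1 = \sum_i i\, p_i}.
#'
#' @inheritParams otsu_threshold
#' @return A data frame with columns `k`, `omega0`, `omega1`, `mu0`, `mu1`,
#'   `sigma_b2`.
#' @export
otsu_scan <- function(h) {
  if (!inherits(h, "gray_histogram")) {
    stop("expected a `gray_histogram`", call. = FALSE)
  }
  S <- length(h$counts)
  p <- h$p
  i <- seq_len(S)
  omega <- cumsum(p)
  mu <- cumsum(i * p)
  mu_total <- mu[S]
  adm <- which(omega > 0 & omega < 1)
  if (length(adm) == 0) {
    stop("degenerate histogram: a single occupied level admits no threshold",
         call. = FALSE)
  }
  omega0 <- omega[adm]
  omega1 <- 1 - omega0
  mu0 <- mu[adm] / omega0
  mu1 <- (mu_total - mu[adm]) / omega1
  data.frame(k = adm, omega0 = omega0, omega1 = omega1,
             mu0 = mu0, mu1 = mu1,
             sigma_b2 = omega0 * omega1 * (mu1 - mu0)^2)
}

#' Threshold an image into foreground and background
#'
#' The droplet appears darker than the lit chip surface in top-view images,
#' so the default polarity takes levels `<= k` as foreground; use
#' `"bright_foreground"` for the complementary convention. The two classes
#' always partition the image.
#'
#' @param img A [gray_image()].
#' @param k Threshold level in `[1, S - 1]`, typically from
#'   [otsu_threshold()].
#' @param polarity `"dark_foreground"` (default) or `"bright_foreground"`.
#' @return A `binary_image`: logical matrix (`TRUE` = foreground) with
#'   attributes `threshold` and `polarity`.
#' @export
binarize <- function(img, k,
                     polarity = c("dark_foreground", "bright_foreground")) {
  assert_gray_image(img)
  polarity <- match.arg(polarity)
  k <- as.integer(k)
  S <- num_levels(img)
  if (is.na(k) || k < 1L || k > S - 1L) {
    stop("threshold k must lie in [1, ", S - 1L, "]", call. = FALSE)
  }
  fg <- if (polarity == "dark_foreground") unclass(img) <= k else unclass(img) > k
  structure(fg, class = "binary_image", threshold = k, polarity = polarity)
}

#' @export
print.binary_image <- function(x, ...) {
  cat(sprintf("<binary_image> %d x %d, %d foreground px (threshold %s)\n",
              nrow(x), ncol(x), sum(x),
              format(attr(x, "threshold"))))
  invisible(x)
}

#' @rdname binarize
#' @param x Object to test.
#' @export
is_binary_image <- function(x) inherits(x, "binary_image")

assert_binary_image <- function(x) {
  if (!is_binary_image(x)) {
    if (is.matrix(x) && is.logical(x)) {
      return(invisible(structure(x, class = "binary_image")))
    }
    stop("expected a `binary_image` or logical matrix", call. = FALSE)
  }
  invisible(x)
}

# Foreground components (8-connected), the border-reachable background
# (4-connected) and the hole mask, shared by the area and contour code.
segment_mask <- function(bin) {
  mask <- unclass(bin)
  labels <- label_components_cpp(mask, conn = 8L)
  outside <- outside_background_cpp(mask)
  holes <- !mask & !outside
  list(mask = mask, labels = labels, outside = outside, holes = holes)
}

#' Trace object outlines in a binary image
#'
#' Moore-neighbour boundary tracing of every 8-connected foreground
#' component: one closed outer contour per component, plus one inner contour
#' per hole (background region not connected to the image border). Contour
#' coordinates are 0-based `(Y, X)` pairs, i.e. row first, and consecutive
#' contour points are 8-neighbours.
#'
#' @param bin A `binary_image` from [binarize()].
#' @return A list of `droplet_contour` objects, each a list with `coords`
#'   (Q x 2 matrix, columns `Y`, `X`), `kind` (`"outer"` or `"inner"`) and
#'   `component` (label of the owning foreground component). Empty
#'   foreground gives an empty list.
#' @export
trace_contours <- function(bin) {
  bin <- assert_binary_image(bin)
  seg <- segment_mask(bin)
  if (!any(seg$mask)) return(list())
  nr <- nrow(seg$mask)
  contours <- list()

  n_comp <- max(seg$labels)
  for (comp in seq_len(n_comp)) {
    idx <- which(seg$labels == comp)[1]  # first in column-major order
    r0 <- (idx - 1) %% nr + 1
    c0 <- (idx - 1) %/% nr + 1
    # column-major first pixel: the pixel above it is outside the component
    coords <- moore_trace(seg$labels == comp, c(r0, c0), c(r0 - 1, c0))
    contours[[length(contours) + 1]] <- new_contour(coords, "outer", comp)
  }

  if (any(seg$holes)) {
    hole_labels <- label_components_cpp(seg$holes, conn = 4L)
    for (hole in seq_len(max(hole_labels))) {
      idx <- which(hole_labels == hole)
      rr <- (idx - 1) %% nr + 1
      cc <- (idx - 1) %/% nr + 1
      top <- which(rr == min(rr))
      j <- top[which.min(cc[top])]
      h0 <- c(rr[j], cc[j])
      start <- c(h0[1] - 1, h0[2])   # pixel above a topmost hole pixel is fg
      comp <- seg$labels[start[1], start[2]]
      coords <- moore_trace(seg$labels == comp, start, h0)
      contours[[length(contours) + 1]] <- new_contour(coords, "inner", comp)
    }
  }
  contours
}

new_contour <- function(coords, kind, component) {
  colnames(coords) <- c("Y", "X")
  structure(list(coords = coords, kind = kind, component = component),
            class = "droplet_contour")
}

#' @export
print.droplet_contour <- function(x, ...) {
  cat(sprintf("<droplet_contour> %s, %d points (component %d)\n",
              x$kind, nrow(x$coords), x$component))
  invisible(x)
}

# Moore-neighbour tracing on a logical mask. `start` is a foreground pixel,
# `back` the background pixel we conceptually arrived from (may lie outside
# the frame). Walks clockwise and stops when the (pixel, backtrack) state
# repeats, which closes the boundary even for one- and two-pixel objects.
# Returns 0-based (Y, X) coordinates.
moore_trace <- function(mask, start, back) {
  nr <- nrow(mask); nc <- ncol(mask)
  # clockwise neighbour order in image coordinates (row grows downward)
  dr <- c(-1L, -1L, 0L, 1L, 1L, 1L, 0L, -1L)
  dc <- c(0L, 1L, 1L, 1L, 0L, -1L, -1L, -1L)
  dir_index <- function(from, to) {
    which(dr == to[1] - from[1] & dc == to[2] - from[2])
  }
  is_fg <- function(r, c) {
    r >= 1 && r <= nr && c >= 1 && c <= nc && mask[r, c]
  }
  seen <- new.env(hash = TRUE, parent = emptyenv())
  p <- start; b <- back
  path_r <- integer(0); path_c <- integer(0)
  repeat {
    key <- paste(p[1], p[2], dir_index(p, b), sep = ",")
    if (!is.null(seen[[key]])) break
    seen[[key]] <- TRUE
    path_r <- c(path_r, p[1]); path_c <- c(path_c, p[2])
    d0 <- dir_index(p, b)
    moved <- FALSE
    prev <- b
    for (s in seq_len(8)) {
      d <- (d0 - 1 + s) %% 8 + 1
      q <- c(p[1] + dr[d], p[2] + dc[d])
      if (is_fg(q[1], q[2])) {
        # never cut a corner: a diagonal move would skip the orthogonal
        # pixel just after it in scan order, which touches the background
        # we scanned past diagonally and so belongs to the boundary
        if (dr[d] != 0 && dc[d] != 0) {
          d2 <- d %% 8 + 1
          q2 <- c(p[1] + dr[d2], p[2] + dc[d2])
          if (is_fg(q2[1], q2[2])) q <- q2
        }
        b <- prev
        p <- q
        moved <- TRUE
        break
      }
      prev <- q
    }
    if (!moved) break  # isolated single pixel
  }
  # drop a trailing revisit of the start pixel, if the walk closed on it
  n <- length(path_r)
  if (n > 1 && path_r[n] == path_r[1] && path_c[n] == path_c[1]) {
    path_r <- path_r[-n]; path_c <- path_c[-n]
  }
  cbind(path_r - 1L, path_c - 1L)
}

#' Foreground pixel area of the largest component
#'
#' Area of the droplet in pixels: the largest 8-connected foreground
#' component with its interior holes filled (specular highlights punch holes
#' in real droplet images, but the deposited droplet is a solid cap).
#' Smaller components are treated as satellite specks and reported in the
#' attributes, not counted.
#'
#' @param bin A `binary_image`.
#' @return Integer pixel area of the largest filled component, with
#'   attributes `n_components` (number of foreground components) and
#'   `component_areas` (filled areas, decreasing).
#' @export
measure_area <- function(bin) {
  bin <- assert_binary_image(bin)
  seg <- segment_mask(bin)
  if (!any(seg$mask)) {
    stop("no droplet: binary image has no foreground pixels", call. = FALSE)
  }
  filled <- label_components_cpp(seg$mask | seg$holes, conn = 8L)
  areas <- sort(tabulate(filled[filled > 0]), decreasing = TRUE)
  structure(as.integer(areas[1]),
            n_components = max(seg$labels),
            component_areas = as.integer(areas))
}

component_centroids <- function(bin) {
  bin <- assert_binary_image(bin)
  seg <- segment_mask(bin)
  if (!any(seg$mask)) return(matrix(numeric(0), 0, 2))
  lab <- seg$labels
  idx <- which(lab > 0)
  nr <- nrow(lab)
  r <- (idx - 1) %% nr + 1
  c <- (idx - 1) %/% nr + 1
  l <- lab[idx]
  cbind(tapply(r, l, mean), tapply(c, l, mean))
}

#' Pixel-to-millimetre scale calibration
#'
#' A pair of fiducial reference marks a known physical distance apart fixes
#' the image scale: `mm_per_px = d_ref_mm / d_pix`.
#'
#' @param d_ref_mm Physical distance between adjacent reference points (mm).
#' @param d_pix Pixel distance between their centroids.
#' @return An object of class `scale_calibration` with fields `d_ref_mm`,
#'   `d_pix` and `mm_per_px`.
#' @seealso [calibrate_scale()] to measure `d_pix` from a reference image.
#' @export
scale_calibration <- function(d_ref_mm, d_pix) {
  if (!is.numeric(d_ref_mm) || length(d_ref_mm) != 1 || d_ref_mm <= 0) {
    stop("`d_ref_mm` must be a positive number", call. = FALSE)
  }
  if (!is.numeric(d_pix) || length(d_pix) != 1 || d_pix <= 0) {
    stop("`d_pix` must be a positive number", call. = FALSE)
  }
  structure(list(d_ref_mm = d_ref_mm, d_pix = d_pix,
                 mm_per_px = d_ref_mm / d_pix),
            class = "scale_calibration")
}

#' @export
print.scale_calibration <- function(x, ...) {
  cat(sprintf("<scale_calibration> D_ref %.4g mm / D_pix %.6g px = %.6g mm/px\n",
              x$d_ref_mm, x$d_pix, x$mm_per_px))
  invisible(x)
}

#' Calibrate the image scale from a reference-point image
#'
#' Runs the same median-filter / Otsu / component pipeline used for droplet
#' measurement on an image of dark fiducial dots, takes component centroids,
#' and sets `D_pix` to the distance between the two nearest-neighbour marks.
#'
#' @param ref_img A [gray_image()] showing at least two reference marks.
#' @param d_ref_mm Known physical distance between adjacent marks (mm).
#' @param window Median filter window, as in [median_filter()].
#' @param min_area_px Components smaller than this are ignored as specks.
#' @return A [scale_calibration()].
#' @export
calibrate_scale <- function(ref_img, d_ref_mm, window = c(10L, 10L),
                            min_area_px = 5L) {
  assert_gray_image(ref_img)
  filt <- median_filter(ref_img, window)
  k <- otsu_threshold(gray_histogram(filt))
  bin <- binarize(filt, k, "dark_foreground")
  seg <- segment_mask(bin)
  keep <- which(tabulate(seg$labels[seg$labels > 0]) >= min_area_px)
  cent <- component_centroids(bin)
  cent <- cent[rownames(cent) %in% as.character(keep), , drop = FALSE]
  if (nrow(cent) < 2) {
    stop("scale calibration failed: found ", nrow(cent),
         " reference mark(s), need at least 2", call. = FALSE)
  }
  d <- as.matrix(stats::dist(cent))
  diag(d) <- Inf
  scale_calibration(d_ref_mm, min(d))
}

#' Measure a droplet image end to end
#'
#' The full sensing pipeline: median filter, Otsu threshold, binarize,
#' largest-component area with holes filled, then the spherical-cap volume
#' via [volume_from_area()].
#'
#' @param img A [gray_image()] of a deposited droplet (top view).
#' @param theta_deg Contact angle of the fluid on the surface, degrees.
#' @param scale A [scale_calibration()].
#' @param window Median filter window.
#' @param polarity Foreground polarity, see [binarize()].
#' @return An object of class `droplet_measurement`: list with `area_px`,
#'   `r0_px` (equivalent-circle footprint radius), `theta_deg`, `scale`,
#'   `volume_nl`, `threshold`, `n_components` and `contour_lengths`.
#' @export
measure_droplet <- function(img, theta_deg, scale, window = c(10L, 10L),
                            polarity = c("dark_foreground",
                                         "bright_foreground")) {
  assert_gray_image(img)
  polarity <- match.arg(polarity)
  filt <- median_filter(img, window)
  k <- otsu_threshold(gray_histogram(filt))
  bin <- binarize(filt, k, polarity)
  area <- measure_area(bin)
  contours <- trace_contours(bin)
  vol <- volume_from_area(as.integer(area), theta_deg, scale)
  structure(list(area_px = as.integer(area),
                 r0_px = attr(vol, "r0_px"),
                 theta_deg = theta_deg,
                 scale = scale,
                 volume_nl = as.numeric(vol),
                 threshold = as.integer(k),
                 n_components = attr(area, "n_components"),
                 contour_lengths = vapply(contours,
                                          function(ct) nrow(ct$coords), 1L)),
            class = "droplet_measurement")
}

#' @export
print.droplet_measurement <- function(x, ...) {
  cat(sprintf(paste0("<droplet_measurement> %.2f nL ",
                     "(area %d px, R0 %.2f px, theta %.1f deg, k* = %d)\n"),
              x$volume_nl, x$area_px, x$r0_px, x$theta_deg, x$threshold))
  invisible(x)
}

#' @export
as.list.droplet_measurement <- function(x, ...) {
  list(threshold = x$threshold,
       area_px = x$area_px,
       n_components = x$n_components,
       contour_lengths = as.integer(x$contour_lengths),
       scale = x$scale$mm_per_px,
       volume_nl = x$volume_nl)
}
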