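#' Grayscale image with 1-based intensity levels
#'
#' `pindrop` represents an image as an integer matrix of intensity *levels*
#' in `[1, S]` (default `S = 256`). Working on levels rather than raw byte
#' values keeps the histogram/threshold arithmetic literal: level `i` has
#' count `n_i`, probabilities `p_i = n_i / N`. File I/O ([read_gray_image()],
#' [write_gray_image()]) converts between 0..255 byte storage and 1..256
#' levels at the boundary.
#'
#' @param pixels Integer (or whole-number numeric) matrix, row = image row
#'   (Y), column = image column (X).
#' @param S Number of gray levels; all pixels must lie in `[1, S]`.
#' @return An object of class `gray_image`: the integer matrix with
#'   attribute `S`.
#' @export
#' @examples
#' img <- gray_image(matrix(1:6, 2, 3), S = 8)
#' dim(img)
gray_image <- function(pixels, S = 256L) {
  if (!is.matrix(pixels)) stop("`pixels` must be a matrix", call. = FALSE)
  if (nrow(pixels) < 1 || ncol(pixels) < 1) {
    stop("image must have at least one row and one column", call. = FALSE)
  }
  S <- as.integer(S)
  if (is.na(S) || S < 2) stop("`S` must be an integer >= 2", call. = FALSE)
  if (anyNA(pixels)) stop("image contains missing values", call. = FALSE)
  if (is.double(pixels) && any(pixels != round(pixels))) {
    stop("intensities must be whole numbers", call. = FALSE)
  }
  storage.mode(pixels) <- "integer"
  if (min(pixels) < 1L || max(pixels) > S) {
    stop("intensities must lie in [1, ", S, "]", call. = FALSE)
  }
  structure(pixels, class = "gray_image", S = S)
}

#' @export
print.gray_image <- function(x, ...) {
  cat(sprintf("<gray_image> %d x %d, %d levels, range [%d, %d]\n",
              nrow(x), ncol(x), attr(x, "S"), min(x), max(x)))
  invisible(x)
}

#' @rdname gray_image
#' @param x Object to test.
#' @export
is_gray_image <- function(x) inherits(x, "gray_image")

num_levels <- function(img) attr(img, "S", exact = TRUE)

assert_gray_image <- function(img) {
  if (!is_gray_image(img)) stop("expected a `gray_image`", call. = FALSE)
  invisible(img)
}

#' Read a grayscale image from PNG or TIFF
#'
#' 8-bit storage values 0..255 map to levels 1..256. Colour images are
#' converted to grayscale by averaging the colour channels (luminance
#' average); an alpha channel, if present, is dropped.
#'
#' @param path Path to a `.png`, `.tif` or `.tiff` file.
#' @return A [gray_image()] with `S = 256`.
#' @seealso [write_gray_image()]
#' @export
read_gray_image <- function(path) {
  if (!file.exists(path)) stop("no such image file: ", path, call. = FALSE)
  ext <- tolower(tools::file_ext(path))
  arr <- switch(ext,
    png = png::readPNG(path),
    tif = ,
    tiff = tiff::readTIFF(path),
    stop("unsupported image format '.", ext, "' (use PNG or TIFF)",
         call. = FALSE)
  )
  if (length(dim(arr)) == 3) {
    nch <- dim(arr)[3]
    if (nch >= 3) {
      arr <- (arr[, , 1] + arr[, , 2] + arr[, , 3]) / 3
    } else {
      arr <- arr[, , 1]
    }
  }
  gray_image(round(arr * 255) + 1L, S = 256L)
}

#' Write a grayscale image to PNG or TIFF
#'
#' Inverse of [read_gray_image()]: level `i` is stored as byte `i - 1`.
#' Images with more than 256 levels cannot be written to 8-bit files.
#'
#' @param img A [gray_image()].
#' @param path Output path; format chosen by extension (`.png`, `.tif`).
#' @return `path`, invisibly.
#' @export
write_gray_image <- function(img, path) {
  assert_gray_image(img)
  if (num_levels(img) > 256L) {
    stop("only images with S <= 256 can be written as 8-bit files",
         call. = FALSE)
  }
  v <- (unclass(img) - 1) / 255
  ext <- tolower(tools::file_ext(path))
  switch(ext,
    png = png::writePNG(v, path),
    tif = ,
    tiff = tiff::writeTIFF(v, path),
    stop("unsupported image format '.", ext, "'", call. = FALSE)
  )
  invisible(path)
}
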