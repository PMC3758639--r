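#' Grayscale image container
#'
#' A `raw_image` is a numeric matrix of luminance values in \[0, 1\] plus its
#' dimensions.  All image-processing functions in the package accept either a
#' `raw_image` or a plain numeric matrix and return a `raw_image`.
#'
#' @param pixels numeric matrix with finite values in \[0, 1\]
#' @return an object of class `raw_image` with fields `pixels`, `height`,
#'   `width`
#' @examples
#' img <- raw_image(matrix(runif(64), 8, 8))
#' dim(as.matrix(img))
#' @export
raw_image <- function(pixels) {
  if (inherits(pixels, "raw_image")) return(pixels)
  if (!is.matrix(pixels) || !is.numeric(pixels))
    .stopf("pixels must be a numeric matrix")
  if (!all(is.finite(pixels)))
    .stopf("pixels must be finite")
  if (min(pixels) < 0 || max(pixels) > 1)
    .stopf("pixel values must lie in [0, 1] (range %.3g..%.3g)",
           min(pixels), max(pixels))
  structure(list(pixels = pixels, height = nrow(pixels), width = ncol(pixels)),
            class = "raw_image")
}

#' @export
as.matrix.raw_image <- function(x, ...) x$pixels

# Accept raw_image or bare matrix; returns the pixel matrix without the
# [0,1] check (for internal intermediates).
.px <- function(image) {
  if (inherits(image, "raw_image")) image$pixels
  else if (is.matrix(image) && is.numeric(image)) image
  else .stopf("expected a raw_image or a numeric matrix")
}

#' @export
print.raw_image <- function(x, ...) {
  cat(sprintf("<raw_image %d x %d, range [%.3f, %.3f]>\n",
              x$height, x$width, min(x$pixels), max(x$pixels)))
  invisible(x)
}

#' @export
plot.raw_image <- function(x, ...) {
  graphics::image(t(x$pixels)[, x$height:1, drop = FALSE],
                  col = grDevices::gray.colors(256, 0, 1),
                  axes = FALSE, asp = x$height / x$width, ...)
  invisible(x)
}

#' Convert an RGB array to luminance
#'
#' Extracts the luma (Y) channel under the ITU-R BT.601 convention,
#' `Y = 0.299 R + 0.587 G + 0.114 B`, the first step of luminance-only
#' processing in the YCbCr colour space.
#'
#' @param image numeric array `height x width x 3` with values in \[0, 1\]
#' @return a [raw_image()] of the luma channel
#' @examples
#' arr <- array(runif(48), c(4, 4, 3))
#' rgb_to_luminance(arr)
#' @export
rgb_to_luminance <- function(image) {
  if (!is.array(image) || length(dim(image)) != 3L || dim(image)[3] != 3L)
    .stopf("expected a height x width x 3 RGB array")
  if (min(image) < 0 || max(image) > 1)
    .stopf("channel values must lie in [0, 1]")
  y <- 0.299 * image[, , 1] + 0.587 * image[, , 2] + 0.114 * image[, , 3]
  raw_image(matrix(.clip01(y), dim(image)[1], dim(image)[2]))
}
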