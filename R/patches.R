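#' Crop image boundary
#'
#' Removes `m` pixels from each side, avoiding boundary artefacts before
#' patch extraction.  A square `M x M` image becomes `(M-2m) x (M-2m)`,
#' i.e. a `D = (M-2m)^2`-pixel field.
#'
#' @param image a [raw_image()] or numeric matrix
#' @param m pixels to cut off each border (`2m < min(height, width)`)
#' @return the cropped [raw_image()]
#' @export
crop_boundary <- function(image, m) {
  x <- .px(image)
  m <- as.integer(m)
  if (m < 0) .stopf("m must be >= 0")
  if (2L * m >= min(dim(x)))
    .stopf("2m = %d must be smaller than the smallest side (%d)",
           2L * m, min(dim(x)))
  if (m == 0L) return(raw_image(.clip01(x)))
  raw_image(.clip01(x[(m + 1):(nrow(x) - m), (m + 1):(ncol(x) - m), drop = FALSE]))
}

#' 1/f pre-whitening of an image
#'
#' Natural images have an approximately 1/f amplitude spectrum, so their
#' second-order (pairwise) pixel redundancy can be removed by a radial
#' frequency-domain filter `W(f) = f * exp(-(f/f0)^4)`, a ramp with a smooth
#' low-pass lobe that prevents high-frequency noise amplification.  `f0` is
#' `f0_fraction` times the Nyquist frequency (0.5 cycles/pixel).  The output
#' is normalized to zero mean and unit (population) variance.
#'
#' @param image a [raw_image()] or numeric matrix, smallest side >= 16
#' @param f0_fraction cutoff as a fraction of Nyquist, in (0, 1\]
#' @return a numeric matrix (zero mean, unit variance; values are no longer
#'   confined to \[0, 1\])
#' @export
prewhiten_image <- function(image, f0_fraction = 0.8) {
  x <- .px(image)
  if (min(dim(x)) < 16L) .stopf("image side must be >= 16")
  if (f0_fraction <= 0 || f0_fraction > 1) .stopf("f0_fraction must be in (0, 1]")
  if (stats::sd(as.vector(x)) < 1e-14)
    .stopf("constant image cannot be pre-whitened (zero variance)")
  f0 <- f0_fraction * 0.5
  fr <- .fftfreq(nrow(x))
  fc <- .fftfreq(ncol(x))
  f <- sqrt(outer(fr^2, fc^2, `+`))
  W <- f * exp(-(f / f0)^4)
  y <- Re(stats::fft(stats::fft(x) * W, inverse = TRUE)) / length(x)
  y <- y - mean(y)
  v <- mean(y^2)
  if (v < 1e-20) .stopf("degenerate image after pre-whitening")
  y / sqrt(v)
}

#' Extract non-overlapping patches from a set of images
#'
#' Crops each image by `m` pixels per side, tiles the cropped field with
#' non-overlapping `p x p` patches and vectorizes each tile column-major into
#' a column of the sample matrix `X` (`d x n`, `d = p^2`).  For `N` images of
#' `D` cropped pixels each this yields `n = N * D / d` patches when the sides
#' divide evenly; trailing remainder rows/columns are dropped otherwise.
#'
#' @param images a list of [raw_image()] objects or numeric matrices (a
#'   single image is also accepted)
#' @param p patch side (pixels)
#' @param m boundary crop per side
#' @param stride tile step; defaults to `p` (non-overlapping tiling)
#' @return an object of class `patch_matrix` with fields `X` (`d x n`),
#'   `d`, `n`, `p`, `origins` (data frame: 0-based `image`, `row`, `col` of
#'   each tile's top-left corner in the cropped image) and `cropped_dims`
#' @seealso [patches_to_image()]
#' @export
extract_patches <- function(images, p, m = 0L, stride = p) {
  if (!is.list(images) || inherits(images, "raw_image")) images <- list(images)
  p <- as.integer(p); m <- as.integer(m); stride <- as.integer(stride)
  if (p < 1L || stride < 1L) .stopf("p and stride must be positive")
  mats <- lapply(images, .px)
  cols <- list()
  origins <- list()
  dims <- matrix(0L, length(mats), 2L)
  for (i in seq_along(mats)) {
    xi <- mats[[i]]
    if (2L * m >= min(dim(xi))) .stopf("crop m too large for image %d", i)
    if (m > 0L) xi <- xi[(m + 1):(nrow(xi) - m), (m + 1):(ncol(xi) - m), drop = FALSE]
    if (p > min(dim(xi))) .stopf("patch side p = %d exceeds cropped image %d", p, i)
    dims[i, ] <- dim(xi)
    r0 <- seq(0L, nrow(xi) - p, by = stride)
    c0 <- seq(0L, ncol(xi) - p, by = stride)
    grid <- expand.grid(row = r0, col = c0)   # column-major tile order
    tiles <- vapply(seq_len(nrow(grid)), function(k) {
      as.vector(xi[grid$row[k] + seq_len(p), grid$col[k] + seq_len(p)])
    }, numeric(p * p))
    cols[[i]] <- tiles
    origins[[i]] <- data.frame(image = i - 1L, row = grid$row, col = grid$col)
  }
  X <- do.call(cbind, cols)
  org <- do.call(rbind, origins)
  structure(list(X = X, d = p * p, n = ncol(X), p = p, m = m, stride = stride,
                 origins = org, cropped_dims = dims),
            class = "patch_matrix")
}

#' @export
print.patch_matrix <- function(x, ...) {
  cat(sprintf("<patch_matrix d = %d (p = %d), n = %d patches from %d image(s)>\n",
              x$d, x$p, x$n, nrow(x$cropped_dims)))
  invisible(x)
}

#' Reassemble one image from its patches
#'
#' Inverse of the non-overlapping tiling of [extract_patches()]: places every
#' tile of the requested image back at its origin.  With `stride == p` and
#' evenly dividing sides this is a lossless round trip of the cropped image.
#'
#' @param pm a `patch_matrix`
#' @param image_index 1-based index of the source image
#' @return a numeric matrix of the reassembled (cropped) image
#' @export
patches_to_image <- function(pm, image_index = 1L) {
  stopifnot(inherits(pm, "patch_matrix"))
  sel <- which(pm$origins$image == image_index - 1L)
  if (!length(sel)) .stopf("no patches for image %d", image_index)
  out <- matrix(0, pm$cropped_dims[image_index, 1], pm$cropped_dims[image_index, 2])
  p <- pm$p
  for (k in sel) {
    r <- pm$origins$row[k]; cc <- pm$origins$col[k]
    out[r + seq_len(p), cc + seq_len(p)] <- matrix(pm$X[, k], p, p)
  }
  out
}
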