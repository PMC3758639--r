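# Image file I/O: PNG and TIFF via the png/tiff packages (suggested),
# plus a self-contained PGM (P2/P5) reader and writer.

#' Read an image file
#'
#' Supports PNG, TIFF and PGM (both ASCII `P2` and binary `P5`).  Colour
#' images are reduced to luminance with [rgb_to_luminance()] when
#' `as_gray = TRUE` (the default); otherwise the raw array is returned.
#'
#' @param path file path; format inferred from the extension
#' @param as_gray logical; reduce RGB input to the luma channel
#' @return a [raw_image()] (or an RGB array when `as_gray = FALSE` and the
#'   file has colour channels)
#' @export
read_image <- function(path, as_gray = TRUE) {
  ext <- tolower(tools::file_ext(path))
  arr <- switch(ext,
    png = {
      if (!requireNamespace("png", quietly = TRUE)) .stopf("package 'png' required")
      png::readPNG(path)
    },
    tif = , tiff = {
      if (!requireNamespace("tiff", quietly = TRUE)) .stopf("package 'tiff' required")
      tiff::readTIFF(path)
    },
    pgm = return(.read_pgm(path)),
    .stopf("unsupported image extension '%s'", ext))
  if (is.matrix(arr)) return(raw_image(.clip01(arr)))
  if (length(dim(arr)) == 3L && dim(arr)[3] >= 3L) {
    if (as_gray) return(rgb_to_luminance(arr[, , 1:3, drop = FALSE]))
    return(arr)
  }
  raw_image(.clip01(arr[, , 1]))
}

#' Write an image file
#'
#' @param image a [raw_image()] or numeric matrix in \[0, 1\]
#' @param path output path; `.png`, `.tif(f)` or `.pgm`
#' @return `path`, invisibly
#' @export
write_image <- function(image, path) {
  x <- .clip01(.px(image))
  ext <- tolower(tools::file_ext(path))
  switch(ext,
    png = {
      if (!requireNamespace("png", quietly = TRUE)) .stopf("package 'png' required")
      png::writePNG(x, path)
    },
    tif = , tiff = {
      if (!requireNamespace("tiff", quietly = TRUE)) .stopf("package 'tiff' required")
      tiff::writeTIFF(x, path)
    },
    pgm = .write_pgm(x, path),
    .stopf("unsupported image extension '%s'", ext))
  invisible(path)
}

.read_pgm <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  tokens <- character(0)
  # header: magic, width, height, maxval; '#' starts a comment
  while (length(tokens) < 4L) {
    line <- readLines(con, n = 1L)
    line <- sub("#.*$", "", line)
    tokens <- c(tokens, strsplit(trimws(line), "\\s+")[[1]])
    tokens <- tokens[nzchar(tokens)]
  }
  magic <- tokens[1]
  w <- as.integer(tokens[2]); h <- as.integer(tokens[3])
  maxval <- as.integer(tokens[4])
  npix <- w * h
  if (magic == "P5") {
    vals <- as.integer(readBin(con, "raw", n = npix))
  } else if (magic == "P2") {
    vals <- scan(con, integer(), n = npix, quiet = TRUE)
  } else .stopf("not a PGM file (magic '%s')", magic)
  raw_image(matrix(vals / maxval, h, w, byrow = TRUE))
}

.write_pgm <- function(x, path) {
  vals <- round(255 * t(x))  # row-major order
  con <- file(path, "wb")
  on.exit(close(con))
  writeChar(sprintf("P5\n%d %d\n255\n", ncol(x), nrow(x)), con, eos = NULL)
  writeBin(as.raw(as.integer(vals)), con)
  invisible(path)
}
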