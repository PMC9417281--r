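#' Calibrated grayscale micrograph
#'
#' Thin container for a 2-D intensity array plus the two pieces of metadata
#' the pipeline needs: the pixel calibration and the contrast polarity of the
#' imaging modality (bright-field TEM: particles darker than background;
#' annular dark-field STEM: particles brighter).
#'
#' Pixels are stored as a numeric matrix indexed `[y, x]` (row = y, column
#' = x, origin at the top-left; pixel centers at integer coordinates).
#'
#' @param pixels numeric matrix of finite intensities (arbitrary units).
#' @param pixel_size calibration, nm per pixel (> 0).
#' @param modality `"bright_field"` or `"dark_field"`.
#' @return object of class `gray_image`.
#' @export
gray_image <- function(pixels, pixel_size = 1,
                       modality = c("bright_field", "dark_field")) {
  modality <- match.arg(modality)
  pixels <- as.matrix(pixels)
  if (!all(is.finite(pixels))) stop("all pixel values must be finite")
  if (!is.numeric(pixel_size) || pixel_size <= 0) stop("pixel_size must be > 0")
  structure(list(pixels = pixels, pixel_size = pixel_size,
                 modality = modality),
            class = "gray_image")
}

#' @export
print.gray_image <- function(x, ...) {
  cat(sprintf("<gray_image> %d x %d px, %.3g nm/px, %s\n",
              nrow(x$pixels), ncol(x$pixels), x$pixel_size, x$modality))
  invisible(x)
}

#' Read a micrograph from TIFF or PNG
#'
#' Multi-channel images are averaged to a single grayscale channel. TIFF
#' files written by [write_micrograph()] round-trip exactly (32-bit float).
#'
#' @param path file path (`.tif`, `.tiff` or `.png`).
#' @param pixel_size calibration, nm per pixel.
#' @param modality contrast polarity, see [gray_image()].
#' @return a `gray_image`.
#' @export
read_micrograph <- function(path, pixel_size = 1,
                            modality = c("bright_field", "dark_field")) {
  modality <- match.arg(modality)
  ext <- tolower(tools::file_ext(path))
  px <- switch(ext,
    tif = , tiff = tiff::readTIFF(path),
    png = {
      if (!requireNamespace("png", quietly = TRUE))
        stop("reading PNG requires the 'png' package")
      png::readPNG(path)
    },
    stop("unsupported image format: .", ext)
  )
  if (length(dim(px)) == 3L) px <- apply(px, c(1L, 2L), mean)
  gray_image(px, pixel_size = pixel_size, modality = modality)
}

#' Write a micrograph as 32-bit float TIFF
#' @param image a `gray_image`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_micrograph <- function(image, path) {
  stopifnot(inherits(image, "gray_image"))
  tiff::writeTIFF(image$pixels, path, bits.per.sample = 32L,
                  reduce = FALSE)
  invisible(path)
}
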