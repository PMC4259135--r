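#' Read an 8-bit grayscale image
#'
#' Reads a PNG or TIFF file (by extension) into a numeric matrix on the
#' 0--255 scale.  Colour images are converted to grayscale by averaging
#' the colour channels; an alpha channel is ignored.
#'
#' @param path File path ending in `.png`, `.tif` or `.tiff`.
#' @return Numeric matrix of intensities in `[0, 255]`.
#' @export
read_gray_image <- function(path) {
  if (!file.exists(path)) {
    stop(errorCondition(sprintf("input image not found: %s", path),
                        class = c("ivus_io_error", "error")))
  }
  ext <- tolower(tools::file_ext(path))
  arr <- tryCatch(
    switch(ext,
           png = png::readPNG(path),
           tif = ,
           tiff = tiff::readTIFF(path),
           stop_invalid(sprintf("unsupported image extension '%s'", ext))),
    error = function(e) {
      if (inherits(e, "ivus_invalid_argument")) stop(e)
      stop(errorCondition(sprintf("failed to decode %s: %s", path,
                                  conditionMessage(e)),
                          class = c("ivus_io_error", "error")))
    })
  if (length(dim(arr)) == 3L) {
    nch <- min(dim(arr)[3], 3L)  # drop alpha
    arr <- apply(arr[, , seq_len(nch), drop = FALSE], c(1, 2), mean)
  }
  arr * 255
}

#' Write a matrix as an 8-bit grayscale image
#'
#' Intensities are clipped to `[0, 255]` and quantised to 8 bits at
#' export; upstream processing keeps floating-point values.
#'
#' @param pixels Numeric matrix on the 0--255 scale.
#' @param path Output path ending in `.png`, `.tif` or `.tiff`.
#' @return `path`, invisibly.
#' @export
write_gray_image <- function(pixels, path) {
  z <- pmin(pmax(pixels, 0), 255) / 255
  ext <- tolower(tools::file_ext(path))
  switch(ext,
         png = png::writePNG(z, path),
         tif = ,
         tiff = tiff::writeTIFF(z, path, bits.per.sample = 8L),
         stop_invalid(sprintf("unsupported image extension '%s'", ext)))
  invisible(path)
}

#' Write a separability map as a 32-bit float TIFF
#'
#' @param map A [separability_map()] result.
#' @param path Output `.tif`/`.tiff` path.
#' @return `path`, invisibly.
#' @export
write_float_tiff <- function(map, path) {
  values <- if (is.list(map) && !is.null(map$values)) map$values else map
  tiff::writeTIFF(values, path, bits.per.sample = 32L, reduce = FALSE)
  invisible(path)
}
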