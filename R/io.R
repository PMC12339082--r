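#' Read a single-channel 8-bit qBEI image
#'
#' Accepts TIFF or PNG by file extension and returns the raw gray levels as
#' an integer matrix on the 0-255 scale.
#'
#' @param path image file path.
#' @return integer matrix of gray levels.
#' @export
read_qbei_image <- function(path) {
  if (!file.exists(path))
    oq_stop(sprintf("cannot read image '%s'", path), "oq_io_error")
  ext <- tolower(tools::file_ext(path))
  img <- switch(ext,
    tif = , tiff = tiff::readTIFF(path),
    png = png::readPNG(path),
    oq_stop(sprintf("unsupported image format '.%s'", ext), "oq_format_error"))
  if (length(dim(img)) == 3L) {
    if (dim(img)[3] == 1L) img <- img[, , 1L]
    else oq_stop("multi-channel input: qBEI rasters must be single-channel",
                 "oq_format_error")
  }
  m <- round(img * 255)
  storage.mode(m) <- "integer"
  m
}

#' Write a raw 8-bit gray-level image
#'
#' @param raw integer matrix of gray levels (0-255).
#' @param path output path; `.tif`/`.tiff` or `.png`.
#' @return `path`, invisibly.
#' @export
write_qbei_image <- function(raw, path) {
  stopifnot(is.matrix(raw))
  img <- pmin(pmax(raw, 0), 255) / 255
  ext <- tolower(tools::file_ext(path))
  switch(ext,
    tif = , tiff = tiff::writeTIFF(img, path, bits.per.sample = 8L),
    png = png::writePNG(img, path),
    oq_stop(sprintf("unsupported image format '.%s'", ext), "oq_format_error"))
  invisible(path)
}

#' Serialize a calcium map as a 32-bit float TIFF for inspection
#'
#' Values are stored scaled by 1/45 (the physical ceiling of the calcium
#' scale, pure hydroxyapatite) so they fit the unit range of the TIFF
#' container; off-sample pixels are written as 1.0 exactly, which is outside
#' the on-sample range after scaling (on-sample Ca is clipped to < 45).
#'
#' @param camap a [ca_map()].
#' @param path output `.tif` path.
#' @return `path`, invisibly.
#' @export
write_camap_tiff <- function(camap, path) {
  stopifnot(inherits(camap, "ca_map"))
  v <- camap$values / 45
  v[is.na(v)] <- 1
  v[v >= 1] <- 1 - 1e-7
  tiff::writeTIFF(v, path, bits.per.sample = 32L)
  invisible(path)
}

#' Read back a calcium map written by [write_camap_tiff()]
#' @param path `.tif` path.
#' @param pixel_size pixel edge length in micrometers.
#' @return a [ca_map()].
#' @export
read_camap_tiff <- function(path, pixel_size = 0.88) {
  v <- tiff::readTIFF(path)
  if (length(dim(v)) == 3L) v <- v[, , 1L]
  off <- v >= 1 - 2e-7
  v <- v * 45
  v[off] <- NA_real_
  ca_map(v, pixel_size = pixel_size)
}
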