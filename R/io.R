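#' Read an RGB raster (PNG or TIFF)
#'
#' @param path file path; format chosen by extension.
#' @return \code{H x W x C} numeric array on the 0..255 scale (alpha
#'   channel, if present, is dropped; grayscale becomes \code{H x W x 1}).
#' @export
read_raster <- function(path) {
  ext <- tolower(tools::file_ext(path))
  img <- switch(ext,
    png = png::readPNG(path),
    tif = , tiff = tiff::readTIFF(path),
    stop("read_raster: unsupported format '", ext, "' (use PNG or TIFF)"))
  if (is.matrix(img)) dim(img) <- c(dim(img), 1L)
  if (dim(img)[3] == 4L) img <- img[, , 1:3, drop = FALSE]
  img * 255
}

#' Write an RGB raster (PNG or TIFF)
#'
#' @param image \code{H x W x C} array on the 0..255 scale.
#' @param path output path; format chosen by extension.
#' @return \code{path}, invisibly.
#' @export
write_raster <- function(image, path) {
  ext <- tolower(tools::file_ext(path))
  img <- pmin(pmax(image / 255, 0), 1)
  ok <- switch(ext,
    png = png::writePNG(img, path),
    tif = , tiff = tiff::writeTIFF(img, path, bits.per.sample = 8L),
    stop("write_raster: unsupported format '", ext, "'"))
  if (!file.exists(path))
    stop("write_raster: failed to write ", path)
  invisible(path)
}

#' Read a binary lodging mask
#'
#' On disk masks are single-channel \{0, 255\} rasters; in memory they are
#' \{0, 1\} matrices (1 = lodged).
#'
#' @param path PNG/TIFF path.
#' @return \code{H x W} matrix over \{0, 1\}.
#' @export
read_mask <- function(path) {
  img <- read_raster(path)
  (img[, , 1] >= 128) * 1
}

#' Write a binary lodging mask
#'
#' @param mask \code{H x W} matrix over \{0, 1\}.
#' @param path output PNG/TIFF path (stored as \{0, 255\}).
#' @return \code{path}, invisibly.
#' @export
write_mask <- function(mask, path) {
  if (!all(mask %in% c(0, 1)))
    stop("write_mask: mask must be binary {0, 1}")
  write_raster(array(mask * 255, dim = c(dim(mask), 1L)), path)
}

#' Write a dataset manifest
#'
#' Plain-text tab-separated table, one row per tile (image path, mask path,
#' origin, augmentation tag, split, ...). Byte-identical for identical
#' inputs, so seeded dataset builds are reproducible file-for-file.
#'
#' @param manifest a data.frame.
#' @param path output TSV path.
#' @return \code{path}, invisibly.
#' @export
write_manifest <- function(manifest, path) {
  write.table(manifest, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a dataset manifest written by [write_manifest()]
#'
#' Relative image/mask paths are resolved against the manifest's own
#' directory.
#'
#' @param path TSV path.
#' @return data.frame.
#' @export
read_manifest <- function(path) {
  mf <- read.table(path, sep = "\t", header = TRUE, stringsAsFactors = FALSE)
  base <- dirname(path)
  for (col in intersect(c("image", "mask"), names(mf))) {
    rel <- !grepl("^(/|[A-Za-z]:)", mf[[col]])
    mf[[col]][rel] <- file.path(base, mf[[col]][rel])
  }
  mf
}
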