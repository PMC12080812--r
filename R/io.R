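#' @importFrom tiff readTIFF writeTIFF
#' @importFrom jsonlite toJSON fromJSON write_json read_json
NULL

# TIFF samples are scaled to [0,1]; the scale factor and the voxel
# calibration travel in a JSON sidecar (<path>.json) next to the image.
writeTiffMeta <- function(path, pixelSize, zSpacing = NA, scale = 1,
                          channel = "") {
  jsonlite::write_json(list(pixel_size_um = pixelSize,
                            z_spacing_um = zSpacing,
                            intensity_scale = scale, channel = channel),
                       paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
}

readTiffMeta <- function(path) {
  pages <- tiff::readTIFF(path, all = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  side <- paste0(path, ".json")
  meta <- if (file.exists(side)) jsonlite::read_json(side) else list()
  list(pages = pages, meta = meta)
}

#' Write / read an image stack as multi-page TIFF
#'
#' Intensities are stored as 16-bit samples scaled to the stack maximum;
#' the scale factor, pixel size, plane spacing and channel travel in a JSON
#' sidecar (`<path>.json`) so that [readStack()] restores the original
#' values (up to 16-bit quantization).
#'
#' @param stack an [ImageStack-class].
#' @param path file path.
#' @export
writeStack <- function(stack, path) {
  stopifnot(is(stack, "ImageStack"))
  v <- stack@voxels
  sc <- max(v, 1e-12)
  pages <- lapply(seq_len(dim(v)[3]), function(k) v[, , k] / sc)
  tiff::writeTIFF(pages, path, bits.per.sample = 16L)
  writeTiffMeta(path, stack@pixelSize, stack@zSpacing, sc, stack@channel)
  invisible(path)
}

#' @rdname writeStack
#' @return `readStack()` returns an [ImageStack-class].
#' @export
readStack <- function(path) {
  r <- readTiffMeta(path)
  v <- simplify2array(r$pages)
  if (length(dim(v)) == 2L) dim(v) <- c(dim(v), 1L)
  sc <- if (!is.null(r$meta$intensity_scale)) r$meta$intensity_scale else 1
  ImageStack(v * sc,
             pixelSize = if (!is.null(r$meta$pixel_size_um)) r$meta$pixel_size_um else 1,
             zSpacing = if (!is.null(r$meta$z_spacing_um) && !is.na(r$meta$z_spacing_um)) r$meta$z_spacing_um else 1,
             channel = if (!is.null(r$meta$channel)) r$meta$channel else "")
}

#' Write / read a single-plane image as TIFF
#' @param img an [Image2D-class].
#' @param path file path.
#' @export
writeImage2D <- function(img, path) {
  stopifnot(is(img, "Image2D"))
  sc <- max(img@pixels, 1e-12)
  tiff::writeTIFF(img@pixels / sc, path, bits.per.sample = 16L)
  writeTiffMeta(path, img@pixelSize, NA, sc, img@bitDepth)
  invisible(path)
}

#' @rdname writeImage2D
#' @return `readImage2D()` returns an [Image2D-class].
#' @export
readImage2D <- function(path) {
  r <- readTiffMeta(path)
  sc <- if (!is.null(r$meta$intensity_scale)) r$meta$intensity_scale else 1
  bd <- if (!is.null(r$meta$channel) && identical(r$meta$channel, "8bit")) "8bit" else "float"
  Image2D(matrix(as.numeric(r$pages[[1]]), nrow(r$pages[[1]])) * sc,
          pixelSize = if (!is.null(r$meta$pixel_size_um)) r$meta$pixel_size_um else 1,
          bitDepth = bd)
}

#' Write / read a binary mask as TIFF
#' @param mask a [BinaryMask2D-class].
#' @param path file path.
#' @export
writeMask <- function(mask, path) {
  stopifnot(is(mask, "BinaryMask2D"))
  tiff::writeTIFF(mask@pixels * 1.0, path, bits.per.sample = 8L)
  writeTiffMeta(path, mask@pixelSize)
  invisible(path)
}

#' @rdname writeMask
#' @return `readMask()` returns a [BinaryMask2D-class].
#' @export
readMask <- function(path) {
  r <- readTiffMeta(path)
  BinaryMask2D(r$pages[[1]] > 0.5,
               pixelSize = if (!is.null(r$meta$pixel_size_um)) r$meta$pixel_size_um else 1)
}

#' Write / read a 16-bit label image as TIFF
#' @param labels integer matrix of per-pixel ground-truth labels (0 = none).
#' @param pixelSize um/pixel.
#' @param path file path.
#' @export
writeLabels <- function(labels, pixelSize, path) {
  stopifnot(max(labels) < 65536)
  tiff::writeTIFF(labels / 65535, path, bits.per.sample = 16L)
  writeTiffMeta(path, pixelSize)
  invisible(path)
}

#' @rdname writeLabels
#' @return `readLabels()` returns a list with `labels` and `pixelSize`.
#' @export
readLabels <- function(path) {
  r <- readTiffMeta(path)
  list(labels = matrix(as.integer(round(r$pages[[1]] * 65535)),
                       nrow(r$pages[[1]])),
       pixelSize = if (!is.null(r$meta$pixel_size_um)) r$meta$pixel_size_um else 1)
}
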