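#' @useDynLib microgliaMorph, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @import methods
NULL

#' Calibrated fluorescence image stack
#'
#' A 3D grid of non-negative intensities with lateral pixel size and axial
#' plane spacing in micrometres, as acquired for a single channel
#' (e.g. Iba1, vGluT2, C1q).
#'
#' @slot voxels 3D numeric array (rows x cols x planes) of intensities.
#' @slot pixelSize lateral pixel size, um/pixel (x = y).
#' @slot zSpacing axial spacing between planes, um.
#' @slot channel channel name (free text).
#' @export
setClass("ImageStack",
  representation(voxels = "array", pixelSize = "numeric",
                 zSpacing = "numeric", channel = "character"))

setValidity("ImageStack", function(object) {
  d <- dim(object@voxels)
  if (length(d) != 3L || any(d < 1L)) return("voxels must be a 3D array with all extents >= 1")
  if (!all(is.finite(object@voxels))) return("intensities must be finite")
  if (any(object@voxels < 0)) return("intensities must be non-negative")
  if (length(object@pixelSize) != 1L || object@pixelSize <= 0) return("pixelSize must be a single positive number")
  if (length(object@zSpacing) != 1L || object@zSpacing <= 0) return("zSpacing must be a single positive number")
  TRUE
})

#' Calibrated 2D intensity image
#'
#' @slot pixels numeric matrix of intensities.
#' @slot pixelSize um/pixel.
#' @slot bitDepth `"float"` for raw intensities or `"8bit"` after conversion
#'   (values then lie in \[0, 255\]).
#' @export
setClass("Image2D",
  representation(pixels = "matrix", pixelSize = "numeric",
                 bitDepth = "character"))

setValidity("Image2D", function(object) {
  if (!all(is.finite(object@pixels))) return("intensities must be finite")
  if (length(object@pixelSize) != 1L || object@pixelSize <= 0) return("pixelSize must be a single positive number")
  if (identical(object@bitDepth, "8bit") &&
      (any(object@pixels < 0) || any(object@pixels > 255)))
    return("8-bit image values must lie in [0, 255]")
  TRUE
})

#' Calibrated binary mask
#'
#' Foreground is `TRUE`; connectivity convention is 8-connected throughout.
#'
#' @slot pixels logical matrix.
#' @slot pixelSize um/pixel.
#' @export
setClass("BinaryMask2D",
  representation(pixels = "matrix", pixelSize = "numeric"))

setValidity("BinaryMask2D", function(object) {
  if (!is.logical(object@pixels)) return("mask pixels must be logical")
  if (anyNA(object@pixels)) return("mask pixels must not contain NA")
  if (length(object@pixelSize) != 1L || object@pixelSize <= 0) return("pixelSize must be a single positive number")
  TRUE
})

#' Topological skeleton graph
#'
#' Pixel-level 8-connected topology of a one-pixel-wide skeleton: every
#' skeleton pixel is classified by its neighbour degree as endpoint
#' (degree 1), slab (degree 2) or junction (degree >= 3); branches run
#' between endpoint/junction nodes and carry euclidean lengths in um
#' (1 pixel per axial step, sqrt(2) per diagonal step, times the pixel size).
#'
#' @slot pixels data.frame with columns `x`, `y` (pixel coordinates),
#'   `degree`, `role`, `component`.
#' @slot branches data.frame with columns `branch`, `component`,
#'   `end1_type`, `end2_type` (`"endpoint"`, `"junction"` or `"none"`),
#'   `length_um`, `n_endpoints` (endpoint-type ends of this branch).
#' @slot pixelSize um/pixel.
#' @export
setClass("SkeletonGraph",
  representation(pixels = "data.frame", branches = "data.frame",
                 pixelSize = "numeric"))

setValidity("SkeletonGraph", function(object) {
  if (nrow(object@branches) && any(object@branches$length_um < 0))
    return("branch lengths must be >= 0")
  if (length(object@pixelSize) != 1L || object@pixelSize <= 0)
    return("pixelSize must be a single positive number")
  TRUE
})

# ---- constructors ----

#' @describeIn ImageStack-class constructor.
#' @param voxels 3D array.
#' @param pixelSize um/pixel.
#' @param zSpacing um.
#' @param channel channel name.
#' @export
ImageStack <- function(voxels, pixelSize, zSpacing, channel = "") {
  new("ImageStack", voxels = voxels, pixelSize = pixelSize,
      zSpacing = zSpacing, channel = channel)
}

#' @describeIn Image2D-class constructor.
#' @param pixels numeric matrix.
#' @param pixelSize um/pixel.
#' @param bitDepth `"float"` or `"8bit"`.
#' @export
Image2D <- function(pixels, pixelSize, bitDepth = "float") {
  storage.mode(pixels) <- "double"
  new("Image2D", pixels = pixels, pixelSize = pixelSize, bitDepth = bitDepth)
}

#' @describeIn BinaryMask2D-class constructor.
#' @param pixels logical (or coercible) matrix.
#' @param pixelSize um/pixel.
#' @export
BinaryMask2D <- function(pixels, pixelSize) {
  mode(pixels) <- "logical"
  new("BinaryMask2D", pixels = pixels, pixelSize = pixelSize)
}

# ---- accessors ----

#' Lateral pixel size in micrometres
#' @param x an image, mask or skeleton object.
#' @export
setGeneric("pixelSize", function(x) standardGeneric("pixelSize"))

#' Axial plane spacing in micrometres
#' @param x an [ImageStack-class].
#' @export
setGeneric("zSpacing", function(x) standardGeneric("zSpacing"))

#' Raw pixel data of an image or mask
#' @param x an image, mask or stack object.
#' @export
setGeneric("pixelData", function(x) standardGeneric("pixelData"))

#' @rdname pixelSize
setMethod("pixelSize", "ImageStack", function(x) x@pixelSize)
#' @rdname pixelSize
setMethod("pixelSize", "Image2D", function(x) x@pixelSize)
#' @rdname pixelSize
setMethod("pixelSize", "BinaryMask2D", function(x) x@pixelSize)
#' @rdname pixelSize
setMethod("pixelSize", "SkeletonGraph", function(x) x@pixelSize)
#' @rdname zSpacing
setMethod("zSpacing", "ImageStack", function(x) x@zSpacing)
#' @rdname pixelData
setMethod("pixelData", "ImageStack", function(x) x@voxels)
#' @rdname pixelData
setMethod("pixelData", "Image2D", function(x) x@pixels)
#' @rdname pixelData
setMethod("pixelData", "BinaryMask2D", function(x) x@pixels)

#' Branch table of a skeleton graph
#' @param x a [SkeletonGraph-class].
#' @export
setGeneric("branches", function(x) standardGeneric("branches"))
#' @rdname branches
setMethod("branches", "SkeletonGraph", function(x) x@branches)

#' Pixel classification table of a skeleton graph
#' @param x a [SkeletonGraph-class].
#' @export
setGeneric("skeletonPixels", function(x) standardGeneric("skeletonPixels"))
#' @rdname skeletonPixels
setMethod("skeletonPixels", "SkeletonGraph", function(x) x@pixels)

# ---- show ----

setMethod("show", "ImageStack", function(object) {
  d <- dim(object@voxels)
  cat(sprintf("ImageStack: %d x %d px, %d planes | %.4f um/px, dz = %g um%s\n",
              d[1], d[2], d[3], object@pixelSize, object@zSpacing,
              if (nzchar(object@channel)) paste0(" | ", object@channel) else ""))
})

setMethod("show", "Image2D", function(object) {
  d <- dim(object@pixels)
  cat(sprintf("Image2D (%s): %d x %d px | %.4f um/px | range [%g, %g]\n",
              object@bitDepth, d[1], d[2], object@pixelSize,
              min(object@pixels), max(object@pixels)))
})

setMethod("show", "BinaryMask2D", function(object) {
  d <- dim(object@pixels)
  cat(sprintf("BinaryMask2D: %d x %d px | %.4f um/px | %d foreground px\n",
              d[1], d[2], object@pixelSize, sum(object@pixels)))
})

setMethod("show", "SkeletonGraph", function(object) {
  cat(sprintf("SkeletonGraph: %d px, %d branches, %d endpoints, %d components | %.4f um/px\n",
              nrow(object@pixels), nrow(object@branches),
              sum(object@pixels$role == "endpoint"),
              length(unique(object@pixels$component)), object@pixelSize))
})
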