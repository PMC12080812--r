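#' @importFrom EBImage filter2 bwlabel computeFeatures.shape resize
NULL

# offsets of a disc of given pixel radius (dx^2 + dy^2 <= r^2), centre included
discOffsets <- function(radius) {
  r <- as.integer(ceiling(radius))
  g <- expand.grid(dx = -r:r, dy = -r:r)
  g <- g[g$dx^2 + g$dy^2 <= radius^2, , drop = FALSE]
  g
}

gaussianKernel <- function(sigma, r = max(1L, ceiling(3 * sigma))) {
  g <- stats::dnorm(-r:r, sd = sigma)
  k <- outer(g, g)
  k / sum(k)
}

gaussianBlur2D <- function(pix, sigma) {
  if (sigma <= 0) return(pix)
  # kernel must fit inside the image; tiny images get a truncated kernel
  r <- min(max(1L, ceiling(3 * sigma)), (min(dim(pix)) - 1L) %/% 2L)
  if (r < 1L) return(pix)
  as.matrix(EBImage::filter2(pix, gaussianKernel(sigma, r),
                             boundary = "replicate"))
}

#' Average groups of planes and trim a stack to a target z-span
#'
#' Consecutive groups of `groupSize` planes are averaged (leftover planes
#' that do not fill a full group are dropped), then the compressed stack is
#' cropped centrally to `zSpan` micrometres. The plane spacing of the result
#' is `groupSize` times the input spacing.
#'
#' @param stack an [ImageStack-class].
#' @param groupSize number of consecutive planes averaged per output plane.
#' @param zSpan target z-extent in um; must not exceed the compressed depth.
#' @return an [ImageStack-class].
#' @export
averageAndTrim <- function(stack, groupSize = 4L, zSpan = 40) {
  stopifnot(is(stack, "ImageStack"), groupSize >= 1L, zSpan > 0)
  v <- stack@voxels
  nz <- dim(v)[3]
  ng <- nz %/% groupSize
  if (ng < 1L) stop("stack has fewer planes than one group")
  newZ <- stack@zSpacing * groupSize
  avg <- array(0, c(dim(v)[1], dim(v)[2], ng))
  for (g in seq_len(ng)) {
    idx <- ((g - 1L) * groupSize + 1L):(g * groupSize)
    avg[, , g] <- apply(v[, , idx, drop = FALSE], c(1, 2), mean)
  }
  depth <- ng * newZ
  if (zSpan > depth + 1e-9) stop("requested z-span exceeds stack depth after averaging")
  nKeep <- max(1L, round(zSpan / newZ))
  start <- (ng - nKeep) %/% 2L + 1L
  ImageStack(avg[, , start:(start + nKeep - 1L), drop = FALSE],
             stack@pixelSize, newZ, stack@channel)
}

#' Maximum-intensity projection
#'
#' Projects a stack onto a single plane by taking the per-pixel maximum over z.
#'
#' @param stack an [ImageStack-class].
#' @return an [Image2D-class].
#' @export
maxProject <- function(stack) {
  stopifnot(is(stack, "ImageStack"))
  Image2D(apply(stack@voxels, c(1, 2), max), stack@pixelSize)
}

#' Convert to 8-bit by min-max rescaling
#'
#' Linearly maps the intensity range \[min, max\] onto \[0, 255\] and rounds
#' half-up. A constant image maps to all zeros (documented convention: there
#' is no contrast to stretch).
#'
#' @param img an [Image2D-class].
#' @return an 8-bit [Image2D-class].
#' @export
to8bit <- function(img) {
  stopifnot(is(img, "Image2D"))
  p <- img@pixels
  rng <- range(p)
  if (rng[1] == rng[2]) {
    out <- array(0, dim(p))
  } else {
    out <- floor((p - rng[1]) / (rng[2] - rng[1]) * 255 + 0.5)
  }
  Image2D(matrix(out, nrow(p)), img@pixelSize, bitDepth = "8bit")
}

#' Unsharp masking
#'
#' Edge enhancement by subtracting a weighted Gaussian blur:
#' `(I - w * G_sigma(I)) / (1 - w)`. On 8-bit input the result is clipped
#' back to \[0, 255\].
#'
#' @param img an [Image2D-class].
#' @param sigma Gaussian sigma in pixels.
#' @param weight mask weight in \[0, 1).
#' @return an [Image2D-class].
#' @export
unsharpMask <- function(img, sigma = 0.5, weight = 0.6) {
  stopifnot(is(img, "Image2D"), sigma > 0)
  if (weight < 0 || weight >= 1) stop("mask weight must lie in [0, 1)")
  blur <- gaussianBlur2D(img@pixels, sigma)
  out <- (img@pixels - weight * blur) / (1 - weight)
  if (identical(img@bitDepth, "8bit")) out <- pmin(pmax(out, 0), 255)
  Image2D(matrix(out, nrow(out)), img@pixelSize, img@bitDepth)
}

#' Despeckle (3x3 median filter)
#'
#' Removes impulse noise with a 3x3 median; image edges use replicate
#' padding.
#'
#' @param img an [Image2D-class].
#' @return an [Image2D-class].
#' @export
despeckle <- function(img) {
  stopifnot(is(img, "Image2D"))
  g <- expand.grid(dx = -1:1, dy = -1:1)
  out <- cpp_rank_filter(img@pixels, g$dx, g$dy, 0L)
  Image2D(out, img@pixelSize, img@bitDepth)
}

isodataThreshold <- function(counts) {
  # counts: 256-bin histogram on levels 0..255; classic IsoData iteration
  lev <- 0:255
  t <- sum(lev * counts) / sum(counts)
  repeat {
    lo <- counts[lev <= t]; hi <- counts[lev > t]
    m1 <- sum(lev[lev <= t] * lo) / sum(lo)
    m2 <- sum(lev[lev > t] * hi) / sum(hi)
    tNew <- (m1 + m2) / 2
    if (is.nan(tNew) || abs(tNew - t) < 1e-6) break
    t <- tNew
  }
  t
}

otsuThreshold <- function(counts) {
  # maximize between-class variance over the 256-bin histogram
  lev <- 0:255
  w <- cumsum(counts)
  mu <- cumsum(lev * counts)
  tot <- w[256]; muT <- mu[256]
  best <- -Inf; bestT <- 0
  for (t in 1:255) {              # threshold between level t-1 and t
    w0 <- w[t]; w1 <- tot - w0
    if (w0 == 0 || w1 == 0) next
    m0 <- mu[t] / w0; m1 <- (muT - mu[t]) / w1
    bc <- w0 * w1 * (m0 - m1)^2
    if (bc > best) { best <- bc; bestT <- t - 1 }
  }
  bestT
}

#' Global histogram thresholding
#'
#' Computes a global threshold on the 8-bit histogram and returns the
#' foreground mask (pixels strictly above threshold). Two methods:
#' \describe{
#'   \item{isodata}{iterates `t <- (mean(I <= t) + mean(I > t)) / 2` to
#'     convergence, then raises the threshold to at least the
#'     `isodataPercent` percentile of the intensity histogram (default 22).
#'     Both the raw and modified thresholds are attached as attributes
#'     `threshold_raw` and `threshold`.}
#'   \item{otsu}{maximizes between-class variance over the 256-bin
#'     histogram.}
#' }
#' Non-8-bit input is converted with [to8bit()] first for the histogram but
#' the mask is computed on the converted scale.
#'
#' @param img an [Image2D-class]; must not be constant.
#' @param method `"isodata"` or `"otsu"`.
#' @param isodataPercent percentile floor applied to the IsoData threshold.
#' @return a [BinaryMask2D-class] with attributes `threshold` and
#'   `threshold_raw` (in 8-bit levels).
#' @export
thresholdGlobal <- function(img, method = c("isodata", "otsu"),
                            isodataPercent = 22) {
  stopifnot(is(img, "Image2D"))
  method <- match.arg(method)
  if (!identical(img@bitDepth, "8bit")) img <- to8bit(img)
  p <- img@pixels
  if (min(p) == max(p)) stop("constant image: no threshold exists")
  counts <- tabulate(as.integer(p) + 1L, nbins = 256L)
  if (method == "otsu") {
    tRaw <- tFinal <- otsuThreshold(counts)
  } else {
    tRaw <- isodataThreshold(counts)
    tFinal <- max(tRaw, stats::quantile(p, isodataPercent / 100, names = FALSE))
  }
  mask <- BinaryMask2D(p > tFinal, img@pixelSize)
  attr(mask, "threshold") <- tFinal
  attr(mask, "threshold_raw") <- tRaw
  mask
}

#' Binary morphological closing
#'
#' Dilation followed by erosion with a (2r+1) x (2r+1) box structuring
#' element (the default r = 1 gives the 3x3 element of ImageJ's binary
#' Close); bridges small gaps between nearby foreground structures.
#' Edges use replicate padding; the operation is idempotent on its own
#' output.
#'
#' @param mask a [BinaryMask2D-class].
#' @param radius structuring-element radius in pixels.
#' @return a [BinaryMask2D-class].
#' @export
morphologicalClose <- function(mask, radius = 1L) {
  stopifnot(is(mask, "BinaryMask2D"))
  g <- expand.grid(dx = -radius:radius, dy = -radius:radius)
  m <- mask@pixels * 1.0
  dil <- cpp_rank_filter(m, g$dx, g$dy, 1L)
  ero <- cpp_rank_filter(dil, g$dx, g$dy, 2L)
  BinaryMask2D(ero > 0.5, mask@pixelSize)
}

#' Remove outlier pixels against the surrounding median
#'
#' For every pixel, the median over the disc of the given radius is
#' computed; if the pixel deviates from that median by strictly more than
#' `threshold` in the chosen polarity it is replaced by the median,
#' otherwise left unchanged. A deviation exactly equal to the threshold is
#' kept (strict inequality).
#'
#' @param img an [Image2D-class] (a 0/255 mask converted to Image2D also
#'   works and is the default placement in the skeleton pipeline).
#' @param radius disc radius in pixels.
#' @param threshold deviation threshold in intensity units.
#' @param polarity `"dark"` replaces pixels far below the median (smooths
#'   dark noise), `"bright"` pixels far above it.
#' @return an [Image2D-class].
#' @export
removeOutliers <- function(img, radius = 7, threshold = 50,
                           polarity = c("dark", "bright")) {
  stopifnot(is(img, "Image2D"), radius >= 1, threshold >= 0)
  polarity <- match.arg(polarity)
  g <- discOffsets(radius)
  out <- cpp_remove_outliers(img@pixels, g$dx, g$dy, threshold,
                             polarity == "bright")
  Image2D(out, img@pixelSize, img@bitDepth)
}

#' Rolling-ball background subtraction
#'
#' The background is estimated by grayscale opening with a non-flat
#' spherical-cap structuring element of the given radius (the ball "rolled"
#' under the intensity surface); the output is the input minus that
#' background, floored at zero. Structures narrower than the ball survive;
#' plateaus wider than the ball are removed.
#'
#' @param img an [Image2D-class].
#' @param radius ball radius in pixels.
#' @return an [Image2D-class] with `0 <= out <= img` everywhere.
#' @export
rollingBallSubtract <- function(img, radius) {
  stopifnot(is(img, "Image2D"), radius >= 1)
  g <- discOffsets(radius)
  h <- sqrt(pmax(0, radius^2 - g$dx^2 - g$dy^2))
  ero <- cpp_grey_morph(img@pixels, g$dx, g$dy, h, FALSE)
  bg <- cpp_grey_morph(ero, g$dx, g$dy, h, TRUE)
  bg <- pmin(bg, img@pixels)          # opening never exceeds the image
  Image2D(matrix(pmax(img@pixels - bg, 0), nrow(bg)), img@pixelSize,
          img@bitDepth)
}

#' Plane-wise Gaussian blur of a stack
#'
#' Applies a 2D Gaussian blur of the given sigma to every plane of the
#' stack (no axial mixing). `sigma = 0` is the identity.
#'
#' @param stack an [ImageStack-class].
#' @param sigma Gaussian sigma in pixels.
#' @return an [ImageStack-class].
#' @export
gaussianBlur3D <- function(stack, sigma = 1.0) {
  stopifnot(is(stack, "ImageStack"), sigma >= 0)
  if (sigma == 0) return(stack)
  v <- stack@voxels
  for (k in seq_len(dim(v)[3])) v[, , k] <- gaussianBlur2D(v[, , k], sigma)
  v[v < 0] <- 0
  ImageStack(v, stack@pixelSize, stack@zSpacing, stack@channel)
}

#' Maximum filter
#'
#' Replaces every pixel by the maximum over the disc of the given radius
#' (replicate padding); used to consolidate puncta before thresholding.
#'
#' @param img an [Image2D-class].
#' @param radius disc radius in pixels.
#' @return an [Image2D-class].
#' @export
maxFilter <- function(img, radius = 2) {
  stopifnot(is(img, "Image2D"), radius >= 1)
  g <- discOffsets(radius)
  Image2D(cpp_rank_filter(img@pixels, g$dx, g$dy, 1L), img@pixelSize,
          img@bitDepth)
}
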