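#' Label 8-connected foreground components
#'
#' @param m logical matrix.
#' @return integer matrix of labels (0 = background).
#' @keywords internal
label8 <- function(m) {
  lab <- EBImage::bwlabel(m * 1)           # 4-connected pass
  lab <- matrix(as.integer(lab), nrow(m))
  # merge labels that touch diagonally
  w <- which(m, arr.ind = TRUE)
  if (!nrow(w)) return(lab)
  pairs <- NULL
  for (o in list(c(1, 1), c(1, -1))) {
    i2 <- w[, 1] + o[1]; j2 <- w[, 2] + o[2]
    ok <- i2 >= 1 & i2 <= nrow(m) & j2 >= 1 & j2 <= ncol(m)
    ok[ok] <- m[cbind(i2[ok], j2[ok])]
    if (any(ok))
      pairs <- rbind(pairs, cbind(lab[w[ok, , drop = FALSE]],
                                  lab[cbind(i2[ok], j2[ok])]))
  }
  nl <- max(lab)
  if (!is.null(pairs)) {
    pairs <- pairs[pairs[, 1] != pairs[, 2], , drop = FALSE]
    if (nrow(pairs)) {
      g <- igraph::make_empty_graph(nl, directed = FALSE)
      g <- igraph::add_edges(g, as.vector(t(pairs)))
      memb <- as.integer(igraph::components(g)$membership)
      lab[lab > 0] <- memb[lab[lab > 0]]
    }
  }
  # renumber consecutively
  u <- sort(unique(lab[lab > 0]))
  if (length(u)) lab[lab > 0] <- match(lab[lab > 0], u)
  lab
}

#' Detect synaptic puncta on a single plane
#'
#' Synapse-counting workflow on a despeckled mid-stack plane: rolling-ball
#' background subtraction, maximum filtering, Otsu thresholding, connected
#' components (8-connected), then two sequential size gates (first in
#' pixels, then in square micrometres) and a hull-free particle circularity
#' gate (`4 * pi * area / perimeter^2`, clamped to 1). All gate bounds are
#' inclusive.
#'
#' @param plane an [Image2D-class] (already despeckled upstream).
#' @param ballRadius rolling-ball radius in pixels.
#' @param maxFilterRadius maximum-filter radius in pixels.
#' @param sizePx two-element pixel-count gate (inclusive).
#' @param sizeUm2 two-element area gate in um^2 (inclusive).
#' @param circularity two-element circularity gate (inclusive).
#' @return a list of class `PunctaSet`: `puncta` (data.frame: x, y,
#'   area_px, area_um2, mean_intensity, circularity), `field_area_um2`,
#'   `density_per_mm2`, plus the parameters used.
#' @export
detectPuncta <- function(plane, ballRadius = 10, maxFilterRadius = 2,
                         sizePx = c(100, 7500), sizeUm2 = c(6, 100),
                         circularity = c(0, 1)) {
  stopifnot(is(plane, "Image2D"))
  ps <- plane@pixelSize
  fieldArea <- prod(dim(plane@pixels)) * ps^2
  emptySet <- function() {
    out <- list(puncta = data.frame(x = numeric(), y = numeric(),
                                    area_px = integer(), area_um2 = numeric(),
                                    mean_intensity = numeric(),
                                    circularity = numeric()),
                field_area_um2 = fieldArea, density_per_mm2 = 0,
                pixel_size_um = ps)
    class(out) <- "PunctaSet"
    out
  }
  if (min(plane@pixels) == max(plane@pixels)) {
    warning("constant plane: no puncta detectable")
    return(emptySet())
  }
  sub <- rollingBallSubtract(plane, ballRadius)
  filt <- maxFilter(sub, maxFilterRadius)
  mask <- tryCatch(thresholdGlobal(filt, "otsu"), error = function(e) NULL)
  if (is.null(mask)) {
    warning("thresholding failed: no puncta detectable")
    return(emptySet())
  }
  lab <- label8(mask@pixels)
  nl <- max(lab)
  if (nl == 0L) return(emptySet())
  # the max filter consolidates fragmented puncta for detection but dilates
  # them; particle measurements use the un-dilated pixels above the same
  # threshold (max filtering preserves the global min/max, so the 8-bit
  # mapping is shared)
  thr <- attr(mask, "threshold")
  fine <- to8bit(sub)@pixels > thr
  lab[!fine] <- 0L
  u <- sort(unique(lab[lab > 0]))
  if (!length(u)) return(emptySet())
  lab[lab > 0] <- match(lab[lab > 0], u)
  nl <- length(u)
  shp <- EBImage::computeFeatures.shape(lab)
  w <- which(lab > 0, arr.ind = TRUE)
  lw <- lab[lab > 0]
  areaPx <- tabulate(lw, nbins = nl)
  cx <- tapply(w[, 1], lw, mean)
  cy <- tapply(w[, 2], lw, mean)
  meanInt <- tapply(plane@pixels[lab > 0], lw, mean)
  per <- shp[, "s.perimeter"]
  circ <- pmin(4 * pi * areaPx / pmax(per, 1e-9)^2, 1)
  areaUm2 <- areaPx * ps^2
  keep <- areaPx >= sizePx[1] & areaPx <= sizePx[2] &
    areaUm2 >= sizeUm2[1] & areaUm2 <= sizeUm2[2] &
    circ >= circularity[1] & circ <= circularity[2]
  out <- list(puncta = data.frame(x = as.numeric(cx[keep]),
                                  y = as.numeric(cy[keep]),
                                  area_px = areaPx[keep],
                                  area_um2 = areaUm2[keep],
                                  mean_intensity = as.numeric(meanInt[keep]),
                                  circularity = circ[keep]),
              field_area_um2 = fieldArea,
              density_per_mm2 = sum(keep) / (fieldArea * 1e-6),
              pixel_size_um = ps)
  class(out) <- "PunctaSet"
  out
}

#' @export
print.PunctaSet <- function(x, ...) {
  cat(sprintf("PunctaSet: %d puncta in %.4f mm^2 (%.1f per mm^2)\n",
              nrow(x$puncta), x$field_area_um2 * 1e-6, x$density_per_mm2))
  invisible(x)
}

#' Puncta density per square millimetre
#'
#' @param set a `PunctaSet` (or a bare count).
#' @param fieldAreaUm2 acquisition area in um^2.
#' @return puncta per mm^2.
#' @export
punctaDensity <- function(set, fieldAreaUm2) {
  count <- if (inherits(set, "PunctaSet")) nrow(set$puncta) else set
  if (fieldAreaUm2 <= 0) stop("field area must be positive")
  count / (fieldAreaUm2 * 1e-6)
}

#' Peak-plane mean intensity of a stack
#'
#' Subtracts the background of every plane with a rolling ball of the given
#' radius, computes per-plane mean intensities, and reports the plane with
#' the highest mean and its value; ties resolve to the lowest plane index.
#'
#' @param stack an [ImageStack-class].
#' @param ballRadius rolling-ball radius in pixels.
#' @return a list of class `IntensityResult`: `plane_means`, `peak_plane`,
#'   `peak_mean`.
#' @export
peakPlaneIntensity <- function(stack, ballRadius = 50) {
  stopifnot(is(stack, "ImageStack"))
  nz <- dim(stack@voxels)[3]
  means <- vapply(seq_len(nz), function(k) {
    img <- Image2D(stack@voxels[, , k], stack@pixelSize)
    mean(rollingBallSubtract(img, ballRadius)@pixels)
  }, 0)
  out <- list(plane_means = means, peak_plane = which.max(means),
              peak_mean = max(means))
  class(out) <- "IntensityResult"
  out
}

#' @export
print.IntensityResult <- function(x, ...) {
  cat(sprintf("IntensityResult: peak plane %d, mean %.3f (of %d planes)\n",
              x$peak_plane, x$peak_mean, length(x$plane_means)))
  invisible(x)
}

#' Convert a cell count in an imaging volume to cells per cubic millimetre
#'
#' @param count number of cells counted through the volume.
#' @param volumeUm three-element (x, y, z) extent in um.
#' @param sigFigs optional significant figures for the reported value
#'   (e.g. 2 to match printed density conventions); `NULL` returns the
#'   exact value.
#' @return cells per mm^3.
#' @export
cellsToDensity <- function(count, volumeUm, sigFigs = NULL) {
  stopifnot(length(volumeUm) == 3L)
  if (any(volumeUm <= 0)) stop("volume extents must be positive")
  d <- count / (prod(volumeUm) * 1e-9)
  if (!is.null(sigFigs)) d <- signif(d, sigFigs)
  d
}
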