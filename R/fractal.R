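#' Single-cell silhouette
#'
#' A binary mask containing exactly one 8-connected cell silhouette, with
#' provenance keys for per-animal aggregation.
#'
#' @slot mask logical matrix (foreground = cell).
#' @slot pixelSize um/pixel.
#' @slot cellId cell identifier.
#' @slot animal animal/field identifier.
#' @export
setClass("CellSilhouette",
  representation(mask = "matrix", pixelSize = "numeric",
                 cellId = "character", animal = "character"))

setValidity("CellSilhouette", function(object) {
  if (!is.logical(object@mask)) return("mask must be logical")
  if (!any(object@mask)) return("silhouette must be nonempty")
  if (nComponents8(object@mask) != 1L)
    return("silhouette must be a single 8-connected component")
  TRUE
})

#' @describeIn CellSilhouette-class constructor.
#' @param mask logical matrix.
#' @param pixelSize um/pixel.
#' @param cellId,animal identifiers.
#' @export
CellSilhouette <- function(mask, pixelSize, cellId = "cell", animal = "animal") {
  mode(mask) <- "logical"
  new("CellSilhouette", mask = mask, pixelSize = pixelSize,
      cellId = cellId, animal = animal)
}

setMethod("show", "CellSilhouette", function(object) {
  cat(sprintf("CellSilhouette %s/%s: %d x %d px, %d foreground px | %.4f um/px\n",
              object@animal, object@cellId, nrow(object@mask),
              ncol(object@mask), sum(object@mask), object@pixelSize))
})

#' @rdname pixelSize
setMethod("pixelSize", "CellSilhouette", function(x) x@pixelSize)

# number of 8-connected foreground components
nComponents8 <- function(m) {
  w <- which(m, arr.ind = TRUE)
  if (!nrow(w)) return(0L)
  pix <- data.frame(x = w[, 1], y = w[, 2])
  ed <- NULL
  key <- function(x, y) paste(x, y)
  idx <- seq_len(nrow(pix)); names(idx) <- key(pix$x, pix$y)
  for (o in list(c(1, 0), c(0, 1), c(1, 1), c(1, -1))) {
    nb <- idx[key(pix$x + o[1], pix$y + o[2])]
    hit <- which(!is.na(nb))
    if (length(hit)) ed <- rbind(ed, cbind(hit, unname(nb[hit])))
  }
  g <- igraph::make_empty_graph(nrow(pix), directed = FALSE)
  if (!is.null(ed)) g <- igraph::add_edges(g, as.vector(t(ed)))
  igraph::components(g)$no
}

#' Outline of a silhouette
#'
#' The one-pixel-thick boundary: foreground pixels having at least one
#' background 4-neighbour (pixels on the image border count their missing
#' neighbours as background).
#'
#' @param cell a [CellSilhouette-class] (or [BinaryMask2D-class]).
#' @return a [BinaryMask2D-class] holding the outline.
#' @export
outlineSilhouette <- function(cell) {
  m <- if (is(cell, "CellSilhouette")) cell@mask else cell@pixels
  ps <- pixelSize(cell)
  if (!any(m)) stop("empty mask has no outline")
  pad <- matrix(FALSE, nrow(m) + 2L, ncol(m) + 2L)
  pad[2:(nrow(m) + 1L), 2:(ncol(m) + 1L)] <- m
  i <- 2:(nrow(m) + 1L); j <- 2:(ncol(m) + 1L)
  interior <- pad[i - 1L, j] & pad[i + 1L, j] & pad[i, j - 1L] & pad[i, j + 1L]
  BinaryMask2D(m & !interior, ps)
}

boxOrigins <- list(c(0, 0), c(0.5, 0), c(0, 0.5), c(0.5, 0.5))

#' Box-counting fractal dimension
#'
#' Counts, for a geometric series of box sizes (ratio 2, from
#' `maxBoxFraction` of the longest bounding-box side down to 1 pixel) and
#' for each grid origin, the number of boxes containing at least one
#' foreground pixel. The per-origin dimension is minus the least-squares
#' slope of `log N` against `log box size`; the reported dimension is the
#' mean over origins. Grid origins are the fixed fractional offsets
#' (0,0), (1/2,0), (0,1/2), (1/2,1/2) of the largest box, applied as the
#' same absolute grid shift at every scale.
#'
#' @param outline a [BinaryMask2D-class] (typically the outline from
#'   [outlineSilhouette()]; pass a filled mask for region counting).
#' @param nOrigins number of grid origins (1 to 4).
#' @param maxBoxFraction largest box size as a fraction of the longest
#'   bounding-box side.
#' @param minScales minimum number of box scales required for a fit.
#' @return a list with `D_f`, per-origin `fits` (data.frame: origin, slope,
#'   r_squared), `box_sizes`, `origins`.
#' @export
boxCountDimension <- function(outline, nOrigins = 4L, maxBoxFraction = 0.45,
                              minScales = 5L) {
  stopifnot(is(outline, "BinaryMask2D"), nOrigins >= 1L, nOrigins <= 4L)
  w <- which(outline@pixels, arr.ind = TRUE)
  if (nrow(w) < 2L) stop("need at least 2 foreground pixels")
  x <- w[, 1] - min(w[, 1]); y <- w[, 2] - min(w[, 2])
  side <- max(max(x), max(y)) + 1L
  eMax <- floor(maxBoxFraction * side)
  if (eMax < 1L) stop("silhouette too small for the requested box series")
  sizes <- 2L^(floor(log2(eMax)):0L)    # geometric, ratio 2, down to 1 px
  if (length(sizes) < minScales)
    stop(sprintf("only %d box scales available (need >= %d); silhouette too small",
                 length(sizes), minScales))
  fits <- lapply(seq_len(nOrigins), function(k) {
    # grid origin: fixed fractional offset of the largest box, the same
    # absolute shift at every scale (a pure translation of the grid)
    ox <- floor(boxOrigins[[k]][1] * sizes[1])
    oy <- floor(boxOrigins[[k]][2] * sizes[1])
    counts <- vapply(sizes, function(eps) {
      length(unique((x + ox) %/% eps * 1e9 + (y + oy) %/% eps))
    }, 0L)
    # the largest box sits deepest in the finite-size regime, and scales
    # covered by only a handful of boxes carry a strong discretization
    # bias; both stay out of the fit when enough scales remain
    use <- counts >= 8L & seq_along(sizes) > 1L
    if (sum(use) < minScales) use <- rep(TRUE, length(sizes))
    fit <- stats::lm(log(counts[use]) ~ log(sizes[use]))
    data.frame(origin = k, slope = -unname(stats::coef(fit)[2]),
               r_squared = suppressWarnings(summary(fit))$r.squared)
  })
  fits <- do.call(rbind, fits)
  list(D_f = mean(fits$slope), fits = fits, box_sizes = sizes,
       origins = boxOrigins[seq_len(nOrigins)])
}

# shoelace area and perimeter of a polygon given vertex coordinates
polyArea <- function(px, py) {
  n <- length(px)
  abs(sum(px * py[c(2:n, 1)] - px[c(2:n, 1)] * py)) / 2
}
polyPerimeter <- function(px, py) {
  n <- length(px)
  sum(sqrt(diff(c(px, px[1]))^2 + diff(c(py, py[1]))^2))
}

#' Convex-hull shape descriptors
#'
#' Builds the convex hull of the foreground pixel centres and reports its
#' perimeter (pixels), area (pixels squared), span ratio (longest point
#' pair distance within the hull divided by the maximum extent measured
#' orthogonal to that chord) and circularity (`4 * pi * area / perimeter^2`,
#' 1 for a circle, smaller for elongated hulls).
#'
#' @param cell a [CellSilhouette-class] or [BinaryMask2D-class].
#' @return a list with `hull_perimeter`, `hull_area`, `span_ratio`,
#'   `circularity`, and `hull` (vertex coordinates). Collinear-only input
#'   yields `span_ratio = Inf` with a warning and `circularity = NA`.
#' @export
hullMetrics <- function(cell) {
  m <- if (is(cell, "CellSilhouette")) cell@mask else cell@pixels
  w <- which(m, arr.ind = TRUE)
  if (nrow(w) < 3L) {
    warning("fewer than 3 foreground pixels: degenerate hull")
    return(list(hull_perimeter = NA_real_, hull_area = 0,
                span_ratio = Inf, circularity = NA_real_, hull = w))
  }
  h <- grDevices::chull(w[, 1], w[, 2])
  hx <- w[h, 1]; hy <- w[h, 2]
  area <- polyArea(hx, hy)
  if (area <= 0) {
    warning("collinear silhouette: span ratio undefined (Inf)")
    return(list(hull_perimeter = polyPerimeter(hx, hy), hull_area = 0,
                span_ratio = Inf, circularity = NA_real_,
                hull = cbind(hx, hy)))
  }
  per <- polyPerimeter(hx, hy)
  # longest chord over hull vertices
  d2 <- outer(hx, hx, "-")^2 + outer(hy, hy, "-")^2
  im <- which(d2 == max(d2), arr.ind = TRUE)[1, ]
  chord <- sqrt(max(d2))
  u <- c(hx[im[2]] - hx[im[1]], hy[im[2]] - hy[im[1]]) / chord
  proj <- hx * (-u[2]) + hy * u[1]
  orth <- max(proj) - min(proj)
  list(hull_perimeter = per, hull_area = area,
       span_ratio = chord / orth,
       circularity = 4 * pi * area / per^2,
       hull = cbind(hx, hy))
}

#' Fractal and hull morphometry for a set of cells
#'
#' Computes, for every silhouette, the box-counting fractal dimension (on
#' the outline by default; `countMode = "filled"` counts the filled mask),
#' the outline perimeter, and the hull descriptors, returning one row per
#' cell keyed by animal and cell id. Per-cell failures are recorded as NA
#' rows with a warning, not raised.
#'
#' @param cells list of [CellSilhouette-class].
#' @param countMode `"outline"` (default) or `"filled"`.
#' @param nOrigins,maxBoxFraction passed to [boxCountDimension()].
#' @return data.frame with columns `animal`, `cell`, `D_f`, `fit_r2`,
#'   `hull_perimeter_px`, `hull_area_px2`, `span_ratio`, `circularity`,
#'   `outline_perimeter_px`.
#' @export
analyzeCells <- function(cells, countMode = c("outline", "filled"),
                         nOrigins = 4L, maxBoxFraction = 0.45) {
  countMode <- match.arg(countMode)
  rows <- lapply(cells, function(cell) {
    out <- data.frame(animal = cell@animal, cell = cell@cellId,
                      D_f = NA_real_, fit_r2 = NA_real_,
                      hull_perimeter_px = NA_real_, hull_area_px2 = NA_real_,
                      span_ratio = NA_real_, circularity = NA_real_,
                      outline_perimeter_px = NA_real_)
    tryCatch({
      outl <- outlineSilhouette(cell)
      target <- if (countMode == "outline") outl else
        BinaryMask2D(cell@mask, cell@pixelSize)
      bc <- boxCountDimension(target, nOrigins, maxBoxFraction)
      hm <- hullMetrics(cell)
      out$D_f <- bc$D_f
      out$fit_r2 <- mean(bc$fits$r_squared)
      out$hull_perimeter_px <- hm$hull_perimeter
      out$hull_area_px2 <- hm$hull_area
      out$span_ratio <- hm$span_ratio
      out$circularity <- hm$circularity
      out$outline_perimeter_px <- sum(outl@pixels)
      out
    }, error = function(e) {
      warning(sprintf("cell %s/%s failed: %s", cell@animal, cell@cellId,
                      conditionMessage(e)))
      out
    })
  })
  do.call(rbind, rows)
}

#' Per-animal averages of cell metrics
#'
#' @param metrics the table from [analyzeCells()].
#' @return data.frame of per-animal means of the numeric metric columns.
#' @export
averageByAnimal <- function(metrics) {
  num <- vapply(metrics, is.numeric, TRUE)
  agg <- stats::aggregate(metrics[num], by = list(animal = metrics$animal),
                          FUN = mean, na.rm = TRUE)
  agg
}
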