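#' Cell-shape specification for the synthetic microglia generator
#'
#' Parameterizes the morphological continuum from intricately ramified
#' (many long, branching processes) through deramified to rod-like
#' (elongated, bipolar) cells.
#'
#' @param nPrimaryProcesses number of primary processes leaving the soma.
#' @param branchProbability probability in \[0, 1) that a process splits in
#'   two after each segment.
#' @param meanSegmentLength mean segment length in um (> 2).
#' @param elongation axial stretch factor >= 1 (1 = isotropic; large values
#'   give rod-like, bipolar shapes).
#' @param somaRadius soma radius in um.
#' @param seed RNG seed.
#' @return a list of class `CellSpec`.
#' @export
cellSpec <- function(nPrimaryProcesses = 5L, branchProbability = 0.35,
                     meanSegmentLength = 12, elongation = 1,
                     somaRadius = 3, seed = 1L) {
  if (nPrimaryProcesses < 0) stop("nPrimaryProcesses must be >= 0")
  if (branchProbability < 0 || branchProbability >= 1)
    stop("branchProbability must lie in [0, 1)")
  if (elongation < 1) stop("elongation must be >= 1")
  if (meanSegmentLength <= 0 || somaRadius <= 0)
    stop("lengths must be positive")
  structure(list(nPrimaryProcesses = as.integer(nPrimaryProcesses),
                 branchProbability = branchProbability,
                 meanSegmentLength = meanSegmentLength,
                 elongation = elongation, somaRadius = somaRadius,
                 seed = as.integer(seed)), class = "CellSpec")
}

# shifted exponential segment lengths: a hard floor plus an exponential
# tail, preserving the requested mean (arbitrarily short terminal segments
# are not biologically plausible and would collide with the 1 um spur-trim
# rule by construction)
drawSegmentLength <- function(mean, floor = 4) {
  floor <- min(floor, mean / 2)
  floor + stats::rexp(1, 1 / max(mean - floor, 1e-6))
}

#' Grow a synthetic microglia with known ground truth
#'
#' Grows a stochastic process tree from the soma centre: the requested
#' number of trunks at random angles, each advancing in segments of
#' (shifted) exponential length and splitting in two with the branch
#' probability after every segment, up to `maxGenerations` splits. All
#' coordinates are then stretched by the elongation factor along the
#' cell's principal axis, and the silhouette is rasterized by dilating the
#' centerline with a 2-pixel process radius plus the soma disc.
#'
#' @param spec a [cellSpec()].
#' @param pixelSize um/pixel for rasterization.
#' @param processRadiusPx process radius for rasterization, pixels.
#' @param maxGenerations cap on successive splits.
#' @param labelId positive integer label.
#' @return a list of class `CellTruth`: `segments` (data.frame id, parent,
#'   x0, y0, x1, y1, gen, in um relative to the soma centre), `n_tips`,
#'   `total_process_length` (um, centerlines rooted at the soma centre),
#'   `silhouette` ([BinaryMask2D-class]), `center_px`, `soma_radius`,
#'   `label_id`, `spec`.
#' @export
makeCell <- function(spec, pixelSize = 370 / 1024, processRadiusPx = 2L,
                     maxGenerations = 5L, labelId = 1L) {
  stopifnot(inherits(spec, "CellSpec"))
  if (pixelSize <= 0) stop("pixel size must be positive")
  set.seed(spec$seed)
  segs <- list()
  queue <- list()
  # primary processes radiate at jittered regular angles (ramified microglia
  # spread their trunks; regular spacing also keeps trunk stubs separable)
  if (spec$nPrimaryProcesses > 0) {
    rot <- stats::runif(1, 0, 2 * pi)
    n0 <- spec$nPrimaryProcesses
    for (k in seq_len(n0))
      queue[[k]] <- list(pos = c(0, 0),
                         dir = rot + 2 * pi * (k - 1 + stats::runif(1, -0.22, 0.22)) / n0,
                         gen = 0L, parent = 0L)
  }
  # processes are grown self-avoiding: a candidate segment is rejected when
  # (away from its own junction) it comes within `clearUm` of previously
  # accepted centerline, or re-enters the soma; otherwise dilated silhouettes
  # of distinct processes would fuse and tips would not be recoverable
  clearUm <- 2.6
  startClearUm <- 3
  cloud <- matrix(numeric(0), 0, 2)
  sampleSeg <- function(p0, p1) {
    len <- sqrt(sum((p1 - p0)^2))
    t <- seq(0, 1, length.out = max(2L, ceiling(len / 0.5) + 1L))
    cbind(p0[1] + t * (p1[1] - p0[1]), p0[2] + t * (p1[2] - p0[2]))
  }
  while (length(queue)) {
    q <- queue[[1]]; queue <- queue[-1]
    maxTries <- if (q$gen == 0L) 60L else 12L
    best <- NULL; bestClear <- -Inf
    for (try in seq_len(maxTries)) {
      len <- drawSegmentLength(spec$meanSegmentLength)
      # primary processes must clear the soma so their stubs survive thinning
      if (q$gen == 0L) len <- max(len, spec$somaRadius + 6)
      dir <- q$dir + stats::runif(1, -0.1, 0.1)
      end <- q$pos + len * c(cos(dir), sin(dir))
      pts <- sampleSeg(q$pos, end)
      far <- sqrt((pts[, 1] - q$pos[1])^2 + (pts[, 2] - q$pos[2])^2) >
        startClearUm
      minClear <- Inf
      if (any(far)) {
        sel <- pts[far, , drop = FALSE]
        if (nrow(cloud))
          minClear <- min(sqrt(outer(sel[, 1], cloud[, 1], "-")^2 +
                               outer(sel[, 2], cloud[, 2], "-")^2))
        if (q$gen > 0L)
          minClear <- min(minClear,
                          min(sqrt(sel[, 1]^2 + sel[, 2]^2)) -
                            spec$somaRadius - 2.5 + clearUm)
      }
      if (minClear >= clearUm) { best <- list(end = end, dir = dir, pts = pts); break }
      if (minClear > bestClear) { bestClear <- minClear
                                  best <- list(end = end, dir = dir, pts = pts,
                                               reject = TRUE) }
    }
    # non-trunk processes that cannot be placed are dropped (the branch
    # point then simply continues with one child); trunks always grow so
    # the primary-process count is honoured
    if (!is.null(best$reject) && q$gen > 0L) next
    id <- length(segs) + 1L
    segs[[id]] <- data.frame(id = id, parent = q$parent,
                             x0 = q$pos[1], y0 = q$pos[2],
                             x1 = best$end[1], y1 = best$end[2], gen = q$gen)
    cloud <- rbind(cloud, best$pts)
    if (q$gen < maxGenerations &&
        stats::runif(1) < spec$branchProbability) {
      spread <- stats::runif(1, 0.6, 1.0)
      for (s in c(-1, 1))
        queue[[length(queue) + 1L]] <-
          list(pos = best$end, dir = best$dir + s * spread, gen = q$gen + 1L,
               parent = id)
    }
  }
  segments <- if (length(segs)) do.call(rbind, segs) else
    data.frame(id = integer(), parent = integer(), x0 = numeric(),
               y0 = numeric(), x1 = numeric(), y1 = numeric(),
               gen = integer())
  # anisotropic stretch along the cell's own principal axis (rod-like
  # microglia elongate along their existing orientation), so increasing the
  # factor always amplifies the dominant axis
  if (spec$elongation > 1 && nrow(segments)) {
    pts <- rbind(cbind(segments$x0, segments$y0),
                 cbind(segments$x1, segments$y1))
    ev <- eigen(stats::cov(pts))$vectors[, 1]
    u <- ev / sqrt(sum(ev^2))
    stretch <- function(x, y) {
      d <- (spec$elongation - 1) * (x * u[1] + y * u[2])
      cbind(x + d * u[1], y + d * u[2])
    }
    s0 <- stretch(segments$x0, segments$y0)
    s1 <- stretch(segments$x1, segments$y1)
    segments$x0 <- s0[, 1]; segments$y0 <- s0[, 2]
    segments$x1 <- s1[, 1]; segments$y1 <- s1[, 2]
  }
  finalizeCellTruth(segments, spec, pixelSize, processRadiusPx, labelId)
}

# recompute tips, lengths and silhouette from a segment table
finalizeCellTruth <- function(segments, spec, pixelSize, processRadiusPx,
                              labelId) {
  nChildren <- if (nrow(segments))
    tabulate(segments$parent[segments$parent > 0], nbins = nrow(segments))
  else integer(0)
  nTips <- sum(nChildren == 0)
  segLen <- if (nrow(segments))
    sqrt((segments$x1 - segments$x0)^2 + (segments$y1 - segments$y0)^2)
  else numeric(0)
  ras <- rasterizeCell(segments, spec$somaRadius, pixelSize, processRadiusPx)
  structure(list(segments = segments, n_tips = nTips,
                 total_process_length = sum(segLen),
                 silhouette = ras$mask, center_px = ras$center_px,
                 soma_radius = spec$somaRadius, label_id = labelId,
                 pixel_size = pixelSize, process_radius_px = processRadiusPx,
                 spec = spec), class = "CellTruth")
}

#' Rasterize a cell's centerline tree into a silhouette mask
#'
#' @param segments segment table in um (columns x0, y0, x1, y1).
#' @param somaRadius soma radius in um.
#' @param pixelSize um/pixel; must be positive.
#' @param processRadiusPx dilation radius for the processes, pixels.
#' @return list with `mask` (a [BinaryMask2D-class]) and `center_px`, the
#'   pixel coordinates of the soma centre.
#' @export
rasterizeCell <- function(segments, somaRadius, pixelSize,
                          processRadiusPx = 2L) {
  if (pixelSize <= 0) stop("pixel size must be positive")
  margin <- processRadiusPx + 2L
  xs <- c(0, segments$x0, segments$x1, -somaRadius, somaRadius)
  ys <- c(0, segments$y0, segments$y1, -somaRadius, somaRadius)
  xmin <- min(xs); ymin <- min(ys)
  toPx <- function(x, y)
    cbind(round((x - xmin) / pixelSize) + margin + 1L,
          round((y - ymin) / pixelSize) + margin + 1L)
  nr <- round((max(xs) - xmin) / pixelSize) + 2L * margin + 2L
  nc <- round((max(ys) - ymin) / pixelSize) + 2L * margin + 2L
  m <- matrix(0, nr, nc)
  if (nrow(segments)) {
    for (k in seq_len(nrow(segments))) {
      len <- sqrt((segments$x1[k] - segments$x0[k])^2 +
                  (segments$y1[k] - segments$y0[k])^2)
      t <- seq(0, 1, length.out = max(2L, ceiling(len / (pixelSize / 2)) + 1L))
      p <- toPx(segments$x0[k] + t * (segments$x1[k] - segments$x0[k]),
                segments$y0[k] + t * (segments$y1[k] - segments$y0[k]))
      m[p] <- 1
    }
    g <- discOffsets(processRadiusPx)
    m <- cpp_rank_filter(m, g$dx, g$dy, 1L)
  }
  ctr <- toPx(0, 0)
  rad <- somaRadius / pixelSize
  ii <- pmax(1, ctr[1] - ceiling(rad)):pmin(nr, ctr[1] + ceiling(rad))
  jj <- pmax(1, ctr[2] - ceiling(rad)):pmin(nc, ctr[2] + ceiling(rad))
  d2 <- outer((ii - ctr[1])^2, (jj - ctr[2])^2, "+")
  m[ii, jj][d2 <= rad^2] <- 1
  list(mask = BinaryMask2D(m > 0, pixelSize), center_px = as.integer(ctr))
}

#' Remove terminal tips from a synthetic cell (deramification)
#'
#' Deletes `nRemove` leaf segments (deepest generation first, then highest
#' id) and rebuilds the truth; emulates the progressive loss of fine
#' processes along the ageing / ocular-hypertension axis.
#'
#' @param truth a `CellTruth` from [makeCell()].
#' @param nRemove number of leaf segments to delete.
#' @return a new `CellTruth`.
#' @export
deramify <- function(truth, nRemove) {
  stopifnot(inherits(truth, "CellTruth"))
  segments <- truth$segments
  for (i in seq_len(nRemove)) {
    if (!nrow(segments)) break
    nChildren <- tabulate(match(segments$parent, segments$id),
                          nbins = nrow(segments))
    leaves <- which(nChildren == 0)
    pick <- leaves[order(-segments$gen[leaves], -segments$id[leaves])][1]
    segments <- segments[-pick, , drop = FALSE]
  }
  finalizeCellTruth(segments, truth$spec, truth$pixel_size,
                    truth$process_radius_px, truth$label_id)
}

#' Field specification for rendering synthetic image stacks
#'
#' Defaults match the acquisition geometry emulated throughout: a
#' 370 x 370 um field sampled at 1024 x 1024 pixels (0.3613 um/pixel) with
#' 1 um plane spacing and a 40 um z-span.
#'
#' @param fieldSizeUm (x, y, z) extent in um.
#' @param pixelSize um/pixel.
#' @param zSpacing um between planes.
#' @param nCells number of cells to place (used by cohort helpers).
#' @param backgroundLevel background intensity.
#' @param amplitude per-cell signal amplitude above background.
#' @param photonScale Poisson photon-noise scale (0 disables; larger =
#'   less relative noise).
#' @param readNoiseSd additive Gaussian read-noise sd (0 disables).
#' @param psfSigmaUm Gaussian PSF sigma in um (0 disables blurring).
#' @param cellZSpanUm contiguous z-extent of each cell, um.
#' @param seed RNG seed.
#' @return a list of class `FieldSpec`.
#' @export
fieldSpec <- function(fieldSizeUm = c(370, 370, 40), pixelSize = 370 / 1024,
                      zSpacing = 1, nCells = 23L, backgroundLevel = 5,
                      amplitude = 150, photonScale = 1, readNoiseSd = 2,
                      psfSigmaUm = 0.25, cellZSpanUm = 12, seed = 1L) {
  if (any(fieldSizeUm <= 0) || pixelSize <= 0 || zSpacing <= 0)
    stop("all extents must be positive")
  if (nCells < 0) stop("nCells must be >= 0")
  structure(list(fieldSizeUm = fieldSizeUm, pixelSize = pixelSize,
                 zSpacing = zSpacing, nCells = as.integer(nCells),
                 backgroundLevel = backgroundLevel, amplitude = amplitude,
                 photonScale = photonScale, readNoiseSd = readNoiseSd,
                 psfSigmaUm = psfSigmaUm, cellZSpanUm = cellZSpanUm,
                 seed = as.integer(seed)), class = "FieldSpec")
}

#' Render synthetic cells into a noisy image stack with ground-truth labels
#'
#' Places each cell silhouette at a random non-overlapping position (one
#' retry-bounded placement per cell), assigns it a contiguous z-extent,
#' adds the per-cell amplitude on silhouette voxels over the background,
#' blurs each plane with the Gaussian PSF, and applies Poisson photon noise
#' plus additive Gaussian read noise. Deterministic given the spec seed.
#'
#' @param spec a [fieldSpec()].
#' @param cells list of `CellTruth` objects from [makeCell()].
#' @param maxTries placement retries per cell before failing.
#' @return a list: `stack` ([ImageStack-class]), `labels` (integer matrix of
#'   per-pixel ground-truth labels), `placements` (data.frame).
#' @export
renderField <- function(spec, cells, maxTries = 200L) {
  stopifnot(inherits(spec, "FieldSpec"))
  set.seed(spec$seed)
  ps <- spec$pixelSize
  nx <- round(spec$fieldSizeUm[1] / ps)
  ny <- round(spec$fieldSizeUm[2] / ps)
  nz <- max(1L, round(spec$fieldSizeUm[3] / spec$zSpacing))
  labels <- matrix(0L, nx, ny)
  sig <- matrix(0, nx, ny)          # per-pixel amplitude mask (2D occupancy)
  zr <- matrix(0L, length(cells), 2)
  placements <- list()
  for (ci in seq_along(cells)) {
    m <- cells[[ci]]$silhouette@pixels
    ri <- nrow(m); cj <- ncol(m)
    if (ri > nx || cj > ny) stop("cell larger than field")
    placed <- FALSE
    for (try in seq_len(maxTries)) {
      r0 <- sample.int(nx - ri + 1L, 1L)
      c0 <- sample.int(ny - cj + 1L, 1L)
      block <- labels[r0:(r0 + ri - 1L), c0:(c0 + cj - 1L)]
      if (!any(block[m] != 0L)) {
        labels[r0:(r0 + ri - 1L), c0:(c0 + cj - 1L)][m] <-
          as.integer(cells[[ci]]$label_id)
        placed <- TRUE
        span <- max(1L, min(nz, round(spec$cellZSpanUm / spec$zSpacing)))
        z0 <- sample.int(nz - span + 1L, 1L)
        zr[ci, ] <- c(z0, z0 + span - 1L)
        placements[[ci]] <- data.frame(label = cells[[ci]]$label_id,
                                       row = r0, col = c0,
                                       z_start = z0, z_end = z0 + span - 1L)
        break
      }
    }
    if (!placed) stop(sprintf("could not place cell %d without collision after %d tries",
                              ci, maxTries))
  }
  v <- array(spec$backgroundLevel, c(nx, ny, nz))
  for (ci in seq_along(cells)) {
    sel <- labels == cells[[ci]]$label_id
    for (k in zr[ci, 1]:zr[ci, 2])
      v[, , k][sel] <- v[, , k][sel] + spec$amplitude
  }
  if (spec$psfSigmaUm > 0) {
    sig_px <- spec$psfSigmaUm / ps
    for (k in seq_len(nz)) v[, , k] <- gaussianBlur2D(v[, , k], sig_px)
  }
  if (spec$photonScale > 0)
    v[] <- stats::rpois(length(v), pmax(v, 0) * spec$photonScale) /
      spec$photonScale
  if (spec$readNoiseSd > 0)
    v[] <- v + stats::rnorm(length(v), 0, spec$readNoiseSd)
  v[v < 0] <- 0
  list(stack = ImageStack(v, ps, spec$zSpacing, "synthetic"),
       labels = labels,
       placements = do.call(rbind, placements))
}

#' Synthetic punctate terminal field with ground truth
#'
#' Samples non-overlapping bright discs to the requested density in a flat
#' background.
#'
#' @param densityPerMm2 puncta per mm^2 (>= 0).
#' @param spec a [fieldSpec()] (x/y extent and pixel size are used).
#' @param sizeRangeUm2 uniform range of disc areas in um^2.
#' @param maxTries placement retries per disc.
#' @return list: `image` ([Image2D-class]), `truth` (data.frame x, y,
#'   radius_px, area_um2).
#' @export
makePunctaField <- function(densityPerMm2, spec, sizeRangeUm2 = c(10, 40),
                            maxTries = 500L) {
  stopifnot(inherits(spec, "FieldSpec"), densityPerMm2 >= 0)
  set.seed(spec$seed)
  ps <- spec$pixelSize
  nx <- round(spec$fieldSizeUm[1] / ps); ny <- round(spec$fieldSizeUm[2] / ps)
  areaMm2 <- spec$fieldSizeUm[1] * spec$fieldSizeUm[2] * 1e-6
  n <- round(densityPerMm2 * areaMm2)
  img <- matrix(spec$backgroundLevel, nx, ny)
  if (n == 0)
    return(list(image = Image2D(img, ps), truth = data.frame(
      x = numeric(), y = numeric(), radius_px = numeric(),
      area_um2 = numeric())))
  areas <- stats::runif(n, sizeRangeUm2[1], sizeRangeUm2[2])
  rpx <- sqrt(areas / pi) / ps
  xs <- ys <- numeric(n)
  for (i in seq_len(n)) {
    ok <- FALSE
    for (try in seq_len(maxTries)) {
      cx <- stats::runif(1, rpx[i] + 2, nx - rpx[i] - 1)
      cy <- stats::runif(1, rpx[i] + 2, ny - rpx[i] - 1)
      if (i == 1 || all(sqrt((xs[seq_len(i - 1)] - cx)^2 +
                             (ys[seq_len(i - 1)] - cy)^2) >
                        rpx[seq_len(i - 1)] + rpx[i] + 3)) {
        ok <- TRUE; break
      }
    }
    if (!ok) stop("requested puncta density undeliverable without overlap")
    xs[i] <- cx; ys[i] <- cy
  }
  for (i in seq_len(n)) {
    ii <- max(1, floor(xs[i] - rpx[i])):min(nx, ceiling(xs[i] + rpx[i]))
    jj <- max(1, floor(ys[i] - rpx[i])):min(ny, ceiling(ys[i] + rpx[i]))
    d2 <- outer((ii - xs[i])^2, (jj - ys[i])^2, "+")
    img[ii, jj][d2 <= rpx[i]^2] <- spec$backgroundLevel + spec$amplitude
  }
  list(image = Image2D(img, ps),
       truth = data.frame(x = xs, y = ys, radius_px = rpx, area_um2 = areas))
}

#' Synthetic longitudinal intraocular pressure series
#'
#' Monthly pressures for both eyes from 3 months of age to `endMonth`.
#' Control (D2control) trajectories stay flat near 12 mmHg; ocular
#' hypertensive (D2) trajectories rise after ~6 months to means near
#' 19-20 mmHg. The two eyes of an animal share the animal-level latent
#' trajectory and the per-visit deviation, plus small independent eye
#' noise, so bilateral cumulative exposures are highly correlated.
#'
#' @param strain `"D2"` or `"D2control"`.
#' @param seed RNG seed (`NULL` to use the current RNG state, e.g. inside
#'   cohort simulation).
#' @param animal animal id.
#' @param endMonth final age in months (9 or 12 in the emulated design).
#' @param visitNoiseSd per-visit shared (animal-level) noise sd, mmHg.
#' @param eyeNoiseSd per-eye independent noise sd, mmHg.
#' @return data.frame: `animal`, `strain`, `eye`, `age_days`, `iop`.
#' @export
makeIOPSeries <- function(strain = c("D2", "D2control"), seed = NULL,
                          animal = "A1", endMonth = 12,
                          visitNoiseSd = 1.2, eyeNoiseSd = 0.6) {
  strain <- match.arg(strain)
  if (!is.null(seed)) set.seed(seed)
  months <- seq(3, endMonth)
  days <- round(months * 30.44)
  base <- stats::rnorm(1, if (strain == "D2") 12.3 else 12.0, 0.9)
  latent <- rep(base, length(months))
  if (strain == "D2") {
    amp <- stats::rnorm(1, 7.5, 3)
    latent <- base + amp * pmin(pmax((months - 6) / 3, 0), 1)
  }
  visit <- latent + stats::rnorm(length(months), 0, visitNoiseSd)
  out <- do.call(rbind, lapply(c("left", "right"), function(eye) {
    data.frame(animal = animal, strain = strain, eye = eye,
               age_days = days,
               iop = pmax(visit + stats::rnorm(length(months), 0, eyeNoiseSd), 5))
  }))
  rownames(out) <- NULL
  out
}

#' Metric names understood by the cohort generator
#' @export
cohortMetricNames <- c("endpoints_per_cell", "branch_length_per_cell",
                       "D_f", "span_ratio", "circularity", "hull_perimeter",
                       "vglut2_density", "c1q_peak", "iba1_count",
                       "neun_density")

#' Cohort specification
#'
#' @param nPerGroup animals per strain x age cell.
#' @param strains,ages design levels (defaults: D2 and D2control at 4, 9,
#'   12 months).
#' @param effectMap named list; each element (named by a metric from
#'   `cohortMetricNames`) is a list with `intercept`, `slope` (scalar, or a
#'   vector named by strain for strain-specific slopes, per-AUC(IOP) units),
#'   and `noiseSd`.
#' @param seed RNG seed.
#' @return a list of class `CohortSpec`.
#' @export
cohortSpec <- function(nPerGroup = 6L, strains = c("D2", "D2control"),
                       ages = c(4, 9, 12), effectMap = list(), seed = 1L) {
  bad <- setdiff(names(effectMap), cohortMetricNames)
  if (length(bad)) stop("unknown metric(s) in effectMap: ",
                        paste(bad, collapse = ", "))
  structure(list(nPerGroup = as.integer(nPerGroup), strains = strains,
                 ages = ages, effectMap = effectMap,
                 seed = as.integer(seed)), class = "CohortSpec")
}

#' Simulate a cohort of animals with metrics tied to cumulative pressure
#'
#' For every animal a bilateral pressure series is generated to its age,
#' summarized as AUC(IOP) (mean of the two eyes), and each requested metric
#' is produced as `intercept + slope[strain] * AUC + Gaussian noise`.
#' Slopes of zero give null cohorts. Reproducible by seed.
#'
#' @param spec a [cohortSpec()].
#' @return data.frame: `animal`, `strain`, `age`, `auc_iop`, and one column
#'   per metric in the effect map.
#' @export
makeCohort <- function(spec) {
  stopifnot(inherits(spec, "CohortSpec"))
  set.seed(spec$seed)
  rows <- list()
  aid <- 0L
  for (strain in spec$strains) for (age in spec$ages)
    for (i in seq_len(spec$nPerGroup)) {
      aid <- aid + 1L
      id <- sprintf("%s_%dmo_%02d", strain, age, i)
      ser <- makeIOPSeries(strain, seed = NULL, animal = id, endMonth = age)
      auc <- mean(vapply(split(ser, ser$eye), function(s)
        aucTrapezoid(s$age_days, s$iop), 0))
      rec <- data.frame(animal = id, strain = strain, age = age,
                        auc_iop = auc)
      for (metric in names(spec$effectMap)) {
        em <- spec$effectMap[[metric]]
        slope <- if (length(em$slope) > 1L) em$slope[[strain]] else em$slope
        noiseSd <- if (is.null(em$noiseSd)) 0 else em$noiseSd
        rec[[metric]] <- em$intercept + slope * auc +
          stats::rnorm(1, 0, noiseSd)
      }
      rows[[aid]] <- rec
    }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Synthetic differential-expression table with exact ground truth
#'
#' Builds a gene table in which exactly `nUp` genes satisfy fold-change
#' >= 1.5 with q < 0.05, exactly `nDown` satisfy fold-change <= 1/1.5 with
#' q < 0.05, and every remaining gene fails at least one criterion.
#'
#' @param nGenes total genes.
#' @param nUp,nDown true up-/downregulated counts; `nUp + nDown <= nGenes`.
#' @param seed RNG seed.
#' @return data.frame: `gene`, `fold_change`, `q`, `direction_true`.
#' @export
makeDEGTable <- function(nGenes, nUp, nDown, seed = 1L) {
  if (nUp < 0 || nDown < 0 || nGenes < 0) stop("counts must be non-negative")
  if (nUp + nDown > nGenes) stop("nUp + nDown must not exceed nGenes")
  set.seed(seed)
  nNull <- nGenes - nUp - nDown
  fc <- c(1.5 * exp(stats::rexp(nUp, 3)),
          1 / (1.5 * exp(stats::rexp(nDown, 3))))
  q <- stats::runif(nUp + nDown, 1e-5, 0.049)
  dir <- c(rep("up", nUp), rep("down", nDown))
  if (nNull) {
    nSmall <- nNull %/% 2
    fcN <- c(exp(stats::runif(nSmall, log(1 / 1.45), log(1.45))),
             exp(stats::runif(nNull - nSmall, log(1 / 4), log(4))))
    qN <- c(stats::runif(nSmall, 0, 1),
            stats::runif(nNull - nSmall, 0.05, 1))
    fc <- c(fc, fcN); q <- c(q, qN)
    dir <- c(dir, rep("null", nNull))
  }
  ord <- sample.int(nGenes)
  data.frame(gene = sprintf("gene%05d", seq_len(nGenes)),
             fold_change = fc[ord], q = q[ord],
             direction_true = dir[ord])
}
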