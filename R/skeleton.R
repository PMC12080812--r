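#' @importFrom igraph graph_from_edgelist make_empty_graph add_edges components degree
NULL

#' Skeletonize a binary mask
#'
#' Reduces the mask to a one-pixel-wide centerline by iterative
#' topology-preserving thinning (two-subiteration scheme plus a staircase
#' cleanup pass), preserving the number of 8-connected components. An empty
#' mask yields an empty skeleton.
#'
#' @param mask a [BinaryMask2D-class].
#' @return a [BinaryMask2D-class] holding the skeleton.
#' @export
skeletonizeMask <- function(mask) {
  stopifnot(is(mask, "BinaryMask2D"))
  m <- mask@pixels * 1L
  storage.mode(m) <- "integer"
  BinaryMask2D(cpp_thin(m) > 0L, mask@pixelSize)
}

# 8-neighbour adjacency of skeleton pixels: matrix with columns (a, b, step)
# where step is 1 for axial and sqrt(2) for diagonal moves. Diagonal edges
# short-cutting an existing orthogonal connection are dropped (standard
# skeleton-graph convention, avoids spurious triangles).
skeletonAdjacency <- function(pix) {
  key <- function(x, y) paste(x, y)
  idx <- seq_len(nrow(pix))
  names(idx) <- key(pix$x, pix$y)
  edges <- list()
  for (o in list(c(1, 0), c(0, 1), c(1, 1), c(1, -1))) {
    nb <- idx[key(pix$x + o[1], pix$y + o[2])]
    hit <- which(!is.na(nb))
    if (!length(hit)) next
    if (all(o != 0)) {
      a <- !is.na(idx[key(pix$x[hit] + o[1], pix$y[hit])])
      b <- !is.na(idx[key(pix$x[hit], pix$y[hit] + o[2])])
      hit <- hit[!(a | b)]
    }
    if (length(hit))
      edges[[length(edges) + 1L]] <-
        cbind(hit, unname(nb[hit]), if (all(o != 0)) sqrt(2) else 1)
  }
  if (length(edges)) do.call(rbind, edges) else NULL
}

#' Build the skeleton graph of a one-pixel-wide skeleton
#'
#' Classifies every skeleton pixel by its 8-neighbourhood degree (endpoint
#' = degree 1, slab = degree 2, junction = degree >= 3, isolated = degree
#' 0), clusters adjacent junction pixels into junction nodes, and traces
#' branches between endpoint/junction nodes. Branch length accumulates 1
#' pixel per axial step and sqrt(2) per diagonal step, times the pixel
#' size. Input that is not one pixel wide (contains a solid 2x2 block)
#' raises an error naming an offending pixel.
#'
#' @param skel a [BinaryMask2D-class] skeleton.
#' @return a [SkeletonGraph-class].
#' @export
buildSkeletonGraph <- function(skel) {
  stopifnot(is(skel, "BinaryMask2D"))
  m <- skel@pixels
  ps <- skel@pixelSize
  w <- which(m, arr.ind = TRUE)
  pix <- data.frame(x = as.integer(w[, 1]), y = as.integer(w[, 2]))
  emptyBranches <- data.frame(branch = integer(), component = integer(),
                              end1_type = character(), end2_type = character(),
                              length_um = numeric(), n_endpoints = integer())
  if (!nrow(pix)) {
    pix$degree <- integer(); pix$role <- character(); pix$component <- integer()
    return(new("SkeletonGraph", pixels = pix, branches = emptyBranches,
               pixelSize = ps))
  }
  n <- nrow(pix)
  ed <- skeletonAdjacency(pix)
  if (is.null(ed)) {
    pix$degree <- 0L
    adjTo <- rep(list(integer(0)), n)
    adjW <- rep(list(numeric(0)), n)
  } else {
    from <- c(ed[, 1], ed[, 2]); to <- c(ed[, 2], ed[, 1])
    wts <- rep(ed[, 3] * ps, 2)
    pix$degree <- tabulate(from, nbins = n)
    ord <- order(from)
    adjTo <- split(to[ord], factor(from[ord], levels = seq_len(n)))
    adjW <- split(wts[ord], factor(from[ord], levels = seq_len(n)))
  }
  pix$role <- c("isolated", "endpoint", "slab")[pmin(pix$degree, 2L) + 1L]
  pix$role[pix$degree >= 3L] <- "junction"
  # thinness validation: a 1-px skeleton may contain 2x2 junction clusters
  # (several branches meeting), but never a 3x3 solid block nor a 2x2 block
  # with a non-junction pixel (the signature of a thick line)
  if (nrow(m) > 1 && ncol(m) > 1) {
    blk <- m[-nrow(m), -ncol(m)] & m[-1, -ncol(m)] & m[-nrow(m), -1] & m[-1, -1]
    if (any(blk)) {
      if (nrow(m) > 2 && ncol(m) > 2) {
        b3 <- blk[-nrow(blk), -ncol(blk)] & blk[-1, -ncol(blk)] &
          blk[-nrow(blk), -1] & blk[-1, -1]
        if (any(b3)) {
          p3 <- which(b3, arr.ind = TRUE)[1, ]
          stop(sprintf("skeleton is not 1 pixel wide at pixel (%d, %d)",
                       p3[1], p3[2]))
        }
      }
      degMat <- matrix(0L, nrow(m), ncol(m))
      degMat[cbind(pix$x, pix$y)] <- pix$degree
      for (bi in seq_len(sum(blk))) {
        p2 <- which(blk, arr.ind = TRUE)[bi, ]
        d4 <- degMat[p2[1] + 0:1, p2[2] + 0:1]
        if (any(d4 < 3L))
          stop(sprintf("skeleton is not 1 pixel wide at pixel (%d, %d)",
                       p2[1], p2[2]))
      }
    }
  }
  g <- igraph::make_empty_graph(n, directed = FALSE)
  if (!is.null(ed)) g <- igraph::add_edges(g, as.vector(t(ed[, 1:2, drop = FALSE])))
  pix$component <- as.integer(igraph::components(g)$membership)

  isJ <- pix$role == "junction"
  jcluster <- rep(NA_integer_, n)
  if (any(isJ) && !is.null(ed)) {
    jed <- ed[isJ[ed[, 1]] & isJ[ed[, 2]], , drop = FALSE]
    jids <- which(isJ)
    gj <- igraph::make_empty_graph(length(jids), directed = FALSE)
    if (nrow(jed))
      gj <- igraph::add_edges(gj, as.vector(t(matrix(match(jed[, 1:2], jids),
                                                     ncol = 2))))
    jcluster[jids] <- as.integer(igraph::components(gj)$membership)
  }

  rows <- list()
  keep <- which(!isJ)
  if (length(keep)) {
    remap <- rep(NA_integer_, n); remap[keep] <- seq_along(keep)
    sed <- if (is.null(ed)) NULL else
      ed[!isJ[ed[, 1]] & !isJ[ed[, 2]], , drop = FALSE]
    gs <- igraph::make_empty_graph(length(keep), directed = FALSE)
    if (!is.null(sed) && nrow(sed))
      gs <- igraph::add_edges(gs, as.vector(t(matrix(remap[sed[, 1:2]], ncol = 2))))
    cmp <- igraph::components(gs)
    cm <- cmp$membership
    dsub <- igraph::degree(gs)
    edgeComp <- if (!is.null(sed) && nrow(sed)) cm[remap[sed[, 1]]] else integer(0)
    innerLen <- vapply(seq_len(cmp$no), function(cc)
      if (length(edgeComp)) sum(sed[edgeComp == cc, 3]) * ps else 0, 0)
    for (cc in seq_len(cmp$no)) {
      verts <- keep[cm == cc]
      nv <- length(verts)
      ne <- sum(edgeComp == cc)
      len <- innerLen[cc]
      if (ne >= nv) {                       # closed loop without junctions
        endTypes <- c("none", "none")
      } else {
        ends <- verts[dsub[remap[verts]] <= 1L]
        endTypes <- character(0)
        for (v in ends) {
          nbr <- adjTo[[v]]
          jn <- which(isJ[nbr])
          if (length(jn)) {
            # one attachment per adjacent junction cluster, min step each
            cls <- jcluster[nbr[jn]]
            for (cl in unique(cls)) {
              len <- len + min(adjW[[v]][jn[cls == cl]])
              endTypes <- c(endTypes, "junction")
            }
          }
          if (pix$degree[v] == 1L) endTypes <- c(endTypes, "endpoint")
        }
        endTypes <- c(endTypes, "none", "none")[1:2]
      }
      rows[[length(rows) + 1L]] <-
        data.frame(branch = 0L, component = pix$component[verts[1]],
                   end1_type = endTypes[1], end2_type = endTypes[2],
                   length_um = len,
                   n_endpoints = sum(endTypes == "endpoint"))
    }
  }
  # direct branches between adjacent but distinct junction clusters
  if (!is.null(ed)) {
    jj <- ed[isJ[ed[, 1]] & isJ[ed[, 2]], , drop = FALSE]
    if (nrow(jj)) {
      c1 <- jcluster[jj[, 1]]; c2 <- jcluster[jj[, 2]]
      cross <- which(c1 != c2)
      if (length(cross)) {
        pairKey <- paste(pmin(c1[cross], c2[cross]), pmax(c1[cross], c2[cross]))
        for (pk in unique(pairKey)) {
          sel <- cross[pairKey == pk]
          rows[[length(rows) + 1L]] <-
            data.frame(branch = 0L, component = pix$component[jj[sel[1], 1]],
                       end1_type = "junction", end2_type = "junction",
                       length_um = min(jj[sel, 3]) * ps, n_endpoints = 0L)
        }
      }
    }
  }
  br <- if (length(rows)) do.call(rbind, rows) else emptyBranches
  if (nrow(br)) br$branch <- seq_len(nrow(br))
  new("SkeletonGraph", pixels = pix, branches = br, pixelSize = ps)
}

#' Trim spurious branches and summarize per-cell morphometry
#'
#' Applies the two trim rules to the branch table: terminal branches (those
#' with at least one endpoint-type end) shorter than `minLengthUm` are
#' excluded, and all branches of connected components possessing fewer than
#' two endpoints (isolated single pixels, closed loops) are excluded. Both
#' rules are evaluated on the original table and applied jointly, so the
#' result does not depend on their order. Only terminal branches are
#' length-trimmed; short internal edges are kept so the graph is never
#' disconnected by trimming. Totals and per-cell averages are computed over
#' the surviving branches.
#'
#' @param graph a [SkeletonGraph-class].
#' @param nCells number of cells in the field (>= 1); per-cell values are
#'   totals divided by this count. Cell counting is an input, not automatic.
#' @param minLengthUm spur-trim threshold in um.
#' @return a one-row data.frame with columns `n_cells`,
#'   `total_branch_length_um`, `n_endpoints`, `branch_length_per_cell_um`,
#'   `endpoints_per_cell`.
#' @export
pruneAndSummarize <- function(graph, nCells, minLengthUm = 1) {
  stopifnot(is(graph, "SkeletonGraph"))
  if (length(nCells) != 1L || is.na(nCells) || nCells < 1)
    stop("nCells must be a count >= 1")
  br <- graph@branches
  if (nrow(br)) {
    compEndpoints <- tapply(br$n_endpoints, br$component, sum)
    spur <- br$n_endpoints >= 1L & br$length_um < minLengthUm
    fragment <- compEndpoints[as.character(br$component)] < 2L
    br <- br[!spur & !fragment, , drop = FALSE]
  }
  total <- sum(br$length_um)
  nEnd <- sum(br$n_endpoints)
  data.frame(n_cells = nCells,
             total_branch_length_um = total,
             n_endpoints = nEnd,
             branch_length_per_cell_um = total / nCells,
             endpoints_per_cell = nEnd / nCells)
}

#' Global skeleton analysis pipeline
#'
#' End-to-end morphometry of a microglia (Iba1) stack: plane averaging and
#' z-trim (optional), maximum-intensity projection, 8-bit conversion,
#' unsharp masking (sigma 0.5 px, weight 0.6), despeckling before and after
#' global IsoData thresholding (22 percent floor), morphological closing,
#' outlier removal (radius 7 px, threshold 50, dark polarity, applied to
#' the 0/255 mask), skeletonization, skeleton-graph construction, spur
#' trimming and per-cell summarization.
#'
#' @param stack an [ImageStack-class] (Iba1 channel).
#' @param nCells Iba1+ cell count in the field (counted through the stack).
#' @param groupSize plane-averaging group size (1 = no averaging).
#' @param zSpan optional z-trim target in um (`NULL` = no trim).
#' @param isodataPercent percentile floor for the IsoData threshold.
#' @param saveDir optional directory; when given, intermediate images are
#'   written there as TIFF.
#' @return the summary data.frame of [pruneAndSummarize()].
#' @export
runGlobalSkeletonPipeline <- function(stack, nCells, groupSize = 1L,
                                      zSpan = NULL, isodataPercent = 22,
                                      saveDir = NULL) {
  stopifnot(is(stack, "ImageStack"))
  if (!is.null(zSpan) || groupSize > 1L) {
    if (is.null(zSpan)) zSpan <- dim(stack@voxels)[3] %/% groupSize *
        stack@zSpacing * groupSize
    stack <- averageAndTrim(stack, groupSize, zSpan)
  }
  img <- maxProject(stack)
  img <- to8bit(img)
  img <- unsharpMask(img, 0.5, 0.6)
  img <- despeckle(img)
  # a featureless (constant) projection has nothing to threshold: an empty
  # field legitimately yields zero totals
  mask <- tryCatch(thresholdGlobal(img, "isodata", isodataPercent),
                   error = function(e) {
                     if (!grepl("constant", conditionMessage(e))) stop(e)
                     warning("featureless projection: empty mask")
                     BinaryMask2D(img@pixels > Inf, pixelSize(img))
                   })
  maskImg <- despeckle(Image2D(mask@pixels * 255, pixelSize(mask), "8bit"))
  mask <- BinaryMask2D(maskImg@pixels > 127, pixelSize(mask))
  mask <- morphologicalClose(mask, 1L)
  maskImg <- removeOutliers(Image2D(mask@pixels * 255, pixelSize(mask), "8bit"),
                            7, 50, "dark")
  mask <- BinaryMask2D(maskImg@pixels > 127, pixelSize(mask))
  skel <- skeletonizeMask(mask)
  if (!is.null(saveDir)) {
    dir.create(saveDir, showWarnings = FALSE, recursive = TRUE)
    writeImage2D(img, file.path(saveDir, "preprocessed.tif"))
    writeMask(mask, file.path(saveDir, "mask.tif"))
    writeMask(skel, file.path(saveDir, "skeleton.tif"))
  }
  graph <- buildSkeletonGraph(skel)
  pruneAndSummarize(graph, nCells)
}
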