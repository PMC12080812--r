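# Independent brute-force oracles and small fixture builders. These are
# deliberately naive re-derivations (loops, exhaustive scans) so they share
# no code path with the package implementations they check.

clamp <- function(v, lo, hi) pmin(pmax(v, lo), hi)

# replicate-padded neighbourhood values at (i, j) for an offset set
nbhdVals <- function(m, i, j, off) {
  vapply(seq_len(nrow(off)), function(k) {
    m[clamp(i + off[k, 1], 1, nrow(m)), clamp(j + off[k, 2], 1, ncol(m))]
  }, 0)
}

bruteFilter <- function(m, off, fun) {
  out <- m
  for (i in seq_len(nrow(m))) for (j in seq_len(ncol(m)))
    out[i, j] <- fun(nbhdVals(m, i, j, off))
  out
}

boxOff <- function(r) as.matrix(expand.grid(-r:r, -r:r))
discOff <- function(r) {
  g <- expand.grid(-ceiling(r):ceiling(r), -ceiling(r):ceiling(r))
  as.matrix(g[g[, 1]^2 + g[, 2]^2 <= r^2, ])
}

bruteRemoveOutliers <- function(m, radius, thr, bright) {
  off <- discOff(radius)
  out <- m
  for (i in seq_len(nrow(m))) for (j in seq_len(ncol(m))) {
    med <- median(nbhdVals(m, i, j, off))
    dev <- if (bright) m[i, j] - med else med - m[i, j]
    if (dev > thr) out[i, j] <- med
  }
  out
}

bruteClose <- function(m, r = 1L) {
  off <- boxOff(r)
  dil <- bruteFilter(m * 1, off, max)
  bruteFilter(dil, off, min) > 0.5
}

# exhaustive Otsu scan on the 256-level histogram of an 8-bit image
bruteOtsu <- function(pix8) {
  counts <- tabulate(as.integer(pix8) + 1L, nbins = 256L)
  lev <- 0:255
  best <- -Inf; bestT <- 0
  for (t in 0:254) {
    w0 <- sum(counts[lev <= t]); w1 <- sum(counts[lev > t])
    if (w0 == 0 || w1 == 0) next
    m0 <- sum(lev[lev <= t] * counts[lev <= t]) / w0
    m1 <- sum(lev[lev > t] * counts[lev > t]) / w1
    bc <- w0 * w1 * (m0 - m1)^2
    if (bc > best) { best <- bc; bestT <- t }
  }
  bestT
}

# literal box count: loop over every grid cell and test for foreground
bruteBoxCount <- function(mask, eps, ox, oy) {
  w <- which(mask, arr.ind = TRUE)
  x <- w[, 1] - min(w[, 1]); y <- w[, 2] - min(w[, 2])
  n <- 0L
  for (bx in unique((x + ox) %/% eps)) for (by in unique((y + oy) %/% eps)) {
    if (any((x + ox) %/% eps == bx & (y + oy) %/% eps == by)) n <- n + 1L
  }
  n
}

# rotating-calipers style span ratio over every foreground pixel pair
bruteSpanRatio <- function(mask) {
  w <- which(mask, arr.ind = TRUE)
  h <- chull(w[, 1], w[, 2])
  p <- w[h, , drop = FALSE]
  best <- 0; dir <- c(1, 0)
  for (a in seq_len(nrow(p))) for (b in seq_len(nrow(p))) {
    d <- sqrt(sum((p[a, ] - p[b, ])^2))
    if (d > best) { best <- d; dir <- (p[b, ] - p[a, ]) / d }
  }
  perp <- c(-dir[2], dir[1])
  proj <- p %*% perp
  best / (max(proj) - min(proj))
}

# textbook nested one-way SS table: groups g, animals a, cell values y
bruteNestedF <- function(y, g, a) {
  g <- as.character(g); a <- paste(g, a)
  grand <- mean(y)
  gm <- tapply(y, g, mean); gn <- tapply(y, g, length)
  am <- tapply(y, a, mean); an <- tapply(y, a, length)
  aGroup <- tapply(g, a, `[`, 1)
  ssG <- sum(gn * (gm - grand)^2)
  ssA <- sum(an * (am - gm[aGroup])^2)
  dfG <- length(gm) - 1
  dfA <- length(am) - length(gm)
  Fg <- (ssG / dfG) / (ssA / dfA)
  list(F = Fg, df1 = dfG, df2 = dfA,
       p = pf(Fg, dfG, dfA, lower.tail = FALSE))
}

# right-angle Sierpinski prefractal mask of the given depth (side 2^depth)
sierpinskiMask <- function(depth) {
  m <- matrix(TRUE, 1, 1)
  for (i in seq_len(depth)) {
    z <- matrix(FALSE, nrow(m), ncol(m))
    m <- rbind(cbind(m, m), cbind(m, z))
  }
  m
}

discMask <- function(radius, pad = 5L) {
  n <- 2L * (radius + pad) + 1L
  c0 <- radius + pad + 1L
  outer(seq_len(n), seq_len(n),
        function(i, j) (i - c0)^2 + (j - c0)^2 <= radius^2)
}

# random 8-connected blob grown by a lattice random walk
randomBlob <- function(seed, steps = 60L, side = 24L) {
  set.seed(seed)
  m <- matrix(FALSE, side, side)
  p <- c(side %/% 2, side %/% 2)
  m[p[1], p[2]] <- TRUE
  for (s in seq_len(steps)) {
    p <- clamp(p + sample(c(-1L, 0L, 1L), 2, replace = TRUE), 2, side - 1)
    m[p[1], p[2]] <- TRUE
  }
  m
}

# 8-connected component count by literal flood fill
compCount8 <- function(m) {
  seen <- matrix(FALSE, nrow(m), ncol(m))
  n <- 0L
  for (i in seq_len(nrow(m))) for (j in seq_len(ncol(m))) {
    if (!m[i, j] || seen[i, j]) next
    n <- n + 1L
    stack <- list(c(i, j)); seen[i, j] <- TRUE
    while (length(stack)) {
      p <- stack[[length(stack)]]; stack[[length(stack)]] <- NULL
      for (a in -1:1) for (b in -1:1) {
        ii <- p[1] + a; jj <- p[2] + b
        if (ii >= 1 && jj >= 1 && ii <= nrow(m) && jj <= ncol(m) &&
            m[ii, jj] && !seen[ii, jj]) {
          seen[ii, jj] <- TRUE
          stack[[length(stack) + 1L]] <- c(ii, jj)
        }
      }
    }
  }
  n
}
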