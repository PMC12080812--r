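test_that("averageAndTrim compresses and crops the z-axis", {
  v <- array(rep(1:50, each = 16), c(4, 4, 50))
  st <- ImageStack(v, 1, 1)
  tr <- averageAndTrim(st, groupSize = 1L, zSpan = 40)
  expect_equal(dim(pixelData(tr))[3], 40L)
  expect_equal(zSpacing(tr), 1)

  const <- averageAndTrim(ImageStack(array(7, c(3, 3, 8)), 1, 1), 2L, 4)
  expect_true(all(pixelData(const) == 7))

  v2 <- array(0, c(2, 2, 4))
  for (k in 1:4) v2[, , k] <- c(0, 2, 4, 6)[k]
  av <- averageAndTrim(ImageStack(v2, 1, 1), 2L, 4)
  expect_equal(pixelData(av)[1, 1, ], c(1, 5))
  expect_equal(zSpacing(av), 2)

  expect_error(averageAndTrim(st, 1L, 60), "z-span")
})

test_that("maxProject equals the per-pixel maximum over planes", {
  set.seed(1)
  v <- array(runif(4 * 4 * 3), c(4, 4, 3))
  proj <- pixelData(maxProject(ImageStack(v, 0.5, 1)))
  brute <- matrix(0, 4, 4)
  for (i in 1:4) for (j in 1:4) brute[i, j] <- max(v[i, j, ])
  expect_equal(proj, brute)
  one <- ImageStack(array(v[, , 1], c(4, 4, 1)), 0.5, 1)
  expect_equal(pixelData(maxProject(one)), v[, , 1])
})

test_that("to8bit rescales min-max to [0,255] with half-up rounding", {
  img <- Image2D(matrix(c(0, 1000, 0, 1000), 2), 1)
  expect_equal(sort(unique(as.vector(pixelData(to8bit(img))))), c(0, 255))
  expect_true(all(pixelData(to8bit(Image2D(matrix(5, 3, 3), 1))) == 0))
  tri <- Image2D(matrix(c(0, 500, 1000, 0), 2), 1)
  expect_equal(pixelData(to8bit(tri))[2, 1], 128)  # 127.5 rounds half-up
})

test_that("unsharpMask matches its formula and degenerates correctly", {
  const <- Image2D(matrix(42, 8, 8), 1)
  expect_equal(pixelData(unsharpMask(const)), pixelData(const))
  set.seed(2)
  img <- Image2D(matrix(runif(64, 0, 255), 8), 1)
  expect_equal(pixelData(unsharpMask(img, weight = 0)), pixelData(img))
  # single bright pixel against explicit brute-force Gaussian convolution
  imp <- matrix(0, 11, 11); imp[6, 6] <- 100
  got <- pixelData(unsharpMask(Image2D(imp, 1), sigma = 0.5, weight = 0.6))
  r <- 2L; g <- dnorm(-r:r, sd = 0.5); k <- outer(g, g); k <- k / sum(k)
  blur <- matrix(0, 11, 11)
  for (i in 1:11) for (j in 1:11) {
    s <- 0
    for (a in -r:r) for (b in -r:r)
      s <- s + k[a + r + 1, b + r + 1] *
        imp[clamp(i + a, 1, 11), clamp(j + b, 1, 11)]
    blur[i, j] <- s
  }
  expect_equal(got, (imp - 0.6 * blur) / 0.4, tolerance = 1e-8)
  expect_error(unsharpMask(img, weight = 1), "weight")
})

test_that("despeckle is the 3x3 median with replicate padding", {
  imp <- matrix(0, 7, 7); imp[4, 4] <- 200
  expect_true(all(pixelData(despeckle(Image2D(imp, 1))) == 0))
  const <- Image2D(matrix(3, 5, 5), 1)
  expect_equal(pixelData(despeckle(const)), pixelData(const))
  set.seed(3)
  m <- matrix(sample(0:255, 25, TRUE), 5)
  expect_equal(pixelData(despeckle(Image2D(m, 1))),
               bruteFilter(m, boxOff(1L), median))
})

test_that("thresholdGlobal separates modes and matches the exhaustive Otsu scan", {
  m <- matrix(c(rep(10, 8), rep(200, 8)), 4)
  msk <- thresholdGlobal(Image2D(m, 1), "otsu")
  expect_equal(pixelData(msk), m == 200)

  for (s in 1:5) {
    set.seed(s)
    m <- matrix(round(c(rnorm(60, 60, 12), rnorm(40, 190, 15))), 10)
    m <- clamp(m, 0, 255)
    msk <- thresholdGlobal(Image2D(m, 1, "8bit"), "otsu")
    expect_equal(attr(msk, "threshold"), bruteOtsu(m))
  }
  expect_error(thresholdGlobal(Image2D(matrix(9, 3, 3), 1)), "constant")
})

test_that("isodata iteration fixes the midpoint of a symmetric histogram", {
  # uniform 0..255 histogram is symmetric about 127.5: the iteration stays
  # there, and the 22nd-percentile floor does not raise it
  m <- matrix(rep(0:255, 2), 32)
  msk <- thresholdGlobal(Image2D(m, 1, "8bit"), "isodata", 22)
  expect_equal(attr(msk, "threshold_raw"), 127.5, tolerance = 1e-6)
  expect_equal(attr(msk, "threshold"), 127.5, tolerance = 1e-6)
  # a low isodata threshold is floored at the stated percentile
  m2 <- matrix(c(rep(0, 50), rep(4, 400), rep(255, 62)), 16)
  msk2 <- thresholdGlobal(Image2D(m2, 1, "8bit"), "isodata", 22)
  expect_gte(attr(msk2, "threshold"), quantile(m2, 0.22))
})

test_that("morphologicalClose bridges gaps, is idempotent, matches brute force", {
  m <- matrix(FALSE, 7, 12)
  m[4, 2:5] <- TRUE; m[4, 7:11] <- TRUE      # 1-px gap at column 6
  cl <- morphologicalClose(BinaryMask2D(m, 1))
  expect_true(cl@pixels[4, 6])

  solid <- matrix(FALSE, 10, 10); solid[3:8, 3:8] <- TRUE
  expect_equal(morphologicalClose(BinaryMask2D(solid, 1))@pixels, solid)

  for (s in 1:5) {
    set.seed(s)
    m <- matrix(runif(64) < 0.4, 8)
    got <- morphologicalClose(BinaryMask2D(m, 1))@pixels
    expect_equal(got, bruteClose(m))
    expect_equal(morphologicalClose(BinaryMask2D(got, 1))@pixels, got)
  }
})

test_that("removeOutliers applies the strict median-deviation rule", {
  m <- matrix(0, 9, 9); m[5, 5] <- 100
  out <- removeOutliers(Image2D(m, 1), 3, 50, "bright")
  expect_equal(out@pixels[5, 5], 0)

  m2 <- matrix(0, 9, 9); m2[5, 5] <- 50     # deviation == threshold: kept
  out2 <- removeOutliers(Image2D(m2, 1), 3, 50, "bright")
  expect_equal(out2@pixels[5, 5], 50)

  for (s in 1:4) {
    set.seed(s)
    m <- matrix(sample(0:255, 81, TRUE), 9)
    for (pol in c("bright", "dark"))
      expect_equal(removeOutliers(Image2D(m, 1), 2.5, 40, pol)@pixels,
                   bruteRemoveOutliers(m, 2.5, 40, pol == "bright"))
  }
})

test_that("rollingBallSubtract removes plateaus, keeps spikes, stays bounded", {
  const <- rollingBallSubtract(Image2D(matrix(17, 12, 12), 1), 3)
  expect_true(all(const@pixels == 0))

  m <- matrix(20, 15, 15); m[8, 8] <- 120
  sub <- rollingBallSubtract(Image2D(m, 1), 3)
  # the cap rides fractionally up onto the single-pixel spike (contact with
  # the surrounding flat surface), so background is 20 + (r - sqrt(r^2 - 1))
  expect_equal(sub@pixels[8, 8], 100 - (3 - sqrt(8)), tolerance = 1e-9)

  plateau <- matrix(0, 30, 30); plateau[5:26, 5:26] <- 80
  subP <- rollingBallSubtract(Image2D(plateau, 1), 4)
  expect_true(all(subP@pixels[12:19, 12:19] == 0))

  set.seed(4)
  m <- matrix(runif(400, 0, 255), 20)
  out <- rollingBallSubtract(Image2D(m, 1), 5)@pixels
  expect_true(all(out >= 0) && all(out <= m + 1e-9))
})

test_that("gaussianBlur3D blurs plane-wise and reproduces the analytic kernel", {
  st <- ImageStack(array(9, c(6, 6, 3)), 1, 1)
  expect_equal(pixelData(gaussianBlur3D(st, 0)), pixelData(st))
  expect_equal(pixelData(gaussianBlur3D(st, 1)), pixelData(st), tolerance = 1e-9)

  v <- array(0, c(15, 15, 2)); v[8, 8, 1] <- 1
  out <- pixelData(gaussianBlur3D(ImageStack(v, 1, 1), 1))
  r <- 3L; g <- dnorm(-r:r, sd = 1); k <- outer(g, g) / sum(outer(g, g))
  expect_equal(out[(8 - r):(8 + r), (8 - r):(8 + r), 1], k, tolerance = 1e-6)
  expect_true(all(out[, , 2] == 0))
})

test_that("filters are translation-equivariant on image interiors", {
  set.seed(5)
  base <- matrix(runif(900, 0, 255), 30)
  shift <- function(m) rbind(m[-1, ], m[1, ])[, c(2:30, 1)]
  for (f in list(function(im) despeckle(im),
                 function(im) removeOutliers(im, 2, 30, "bright"),
                 function(im) unsharpMask(im, 0.8, 0.4))) {
    a <- f(Image2D(shift(base), 1))@pixels
    b <- shift(f(Image2D(base, 1))@pixels)
    expect_equal(a[5:25, 5:25], b[5:25, 5:25], tolerance = 1e-9)
  }
})
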