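test_that("cellSpec enforces its parameter invariants", {
  expect_error(cellSpec(nPrimaryProcesses = -1), "nPrimaryProcesses")
  expect_error(cellSpec(branchProbability = 1), "branchProbability")
  expect_error(cellSpec(elongation = 0.5), "elongation")
  expect_error(makeCell(cellSpec(), pixelSize = 0), "pixel size")
})

test_that("makeCell produces consistent ground truth", {
  # degenerate tree: soma only
  soma <- makeCell(cellSpec(nPrimaryProcesses = 0, seed = 1))
  expect_equal(soma$n_tips, 0)
  expect_equal(soma$total_process_length, 0)
  expect_true(any(pixelData(soma$silhouette)))

  # no branching: tips equal trunks, length is the sum of drawn trunks
  for (s in 1:5) {
    tr <- makeCell(cellSpec(nPrimaryProcesses = 6, branchProbability = 0,
                            seed = s))
    expect_equal(tr$n_tips, 6)
    expect_equal(nrow(tr$segments), 6)
    segLen <- with(tr$segments, sqrt((x1 - x0)^2 + (y1 - y0)^2))
    expect_equal(tr$total_process_length, sum(segLen))
  }

  # silhouette is one 8-connected component (CellSilhouette validity)
  tr <- makeCell(cellSpec(seed = 4))
  expect_s4_class(CellSilhouette(pixelData(tr$silhouette),
                                 pixelSize(tr$silhouette)), "CellSilhouette")

  # determinism
  a <- makeCell(cellSpec(seed = 42)); b <- makeCell(cellSpec(seed = 42))
  expect_identical(pixelData(a$silhouette), pixelData(b$silhouette))
  expect_identical(a$segments, b$segments)

  # elongated variant of the same seed has a strictly larger span ratio
  iso <- makeCell(cellSpec(elongation = 1, seed = 9))
  rod <- makeCell(cellSpec(elongation = 4, seed = 9))
  expect_gt(hullMetrics(rod$silhouette)$span_ratio,
            hullMetrics(iso$silhouette)$span_ratio)
})

test_that("renderField places cells exactly and reproducibly", {
  cells <- lapply(1:4, function(i)
    makeCell(cellSpec(nPrimaryProcesses = 4, seed = 200 + i), labelId = i))
  fs <- fieldSpec(fieldSizeUm = c(150, 150, 10), nCells = 4,
                  backgroundLevel = 0, photonScale = 0, readNoiseSd = 0,
                  psfSigmaUm = 0, cellZSpanUm = 6, seed = 5)
  fld <- renderField(fs, cells)

  # noiseless rendering: binarized max-projection equals the union of
  # silhouettes (the label image)
  proj <- pixelData(maxProject(fld$stack))
  expect_equal(proj > 0, fld$labels > 0)
  expect_equal(sort(unique(as.vector(fld$labels[fld$labels > 0]))), 1:4)

  # bit-for-bit determinism including noise
  fsN <- fieldSpec(fieldSizeUm = c(100, 100, 8), nCells = 2, seed = 6)
  f1 <- renderField(fsN, cells[1:2])
  f2 <- renderField(fsN, cells[1:2])
  expect_identical(pixelData(f1$stack), pixelData(f2$stack))
  expect_identical(f1$labels, f2$labels)

  # impossible packing fails after bounded retries
  big <- lapply(1:30, function(i)
    makeCell(cellSpec(nPrimaryProcesses = 6, seed = i), labelId = i))
  tiny <- fieldSpec(fieldSizeUm = c(60, 60, 5), nCells = 30, seed = 7)
  expect_error(renderField(tiny, big, maxTries = 10L), "collision|larger")
})

test_that("the default imaging volume carries realistic microglia numbers", {
  cells <- lapply(1:23, function(i)
    makeCell(cellSpec(nPrimaryProcesses = sample(3:6, 1),
                      branchProbability = 0.3, seed = 3000 + i), labelId = i))
  fs <- fieldSpec(fieldSizeUm = c(370, 370, 4), nCells = 23,
                  photonScale = 0, readNoiseSd = 0, psfSigmaUm = 0, seed = 8)
  fld <- renderField(fs, cells)
  labs <- sort(unique(as.vector(fld$labels[fld$labels > 0])))
  expect_equal(length(labs), 23)
  # the count through the nominal acquisition volume converts to the
  # reported density scale
  expect_equal(cellsToDensity(23, c(370, 370, 40), sigFigs = 2), 4200)
})

test_that("makePunctaField delivers the requested density or fails loudly", {
  fs <- fieldSpec(fieldSizeUm = c(100, 100, 1), seed = 2)
  none <- makePunctaField(0, fs)
  expect_equal(nrow(none$truth), 0)
  expect_true(all(none$image@pixels == none$image@pixels[1, 1]))

  area <- 370 * 370 * 1e-6
  fs2 <- fieldSpec(seed = 3)
  pf <- makePunctaField(50 / area, fs2, sizeRangeUm2 = c(10, 20))
  expect_equal(nrow(pf$truth), 50)
  expect_equal(punctaDensity(nrow(pf$truth), 370 * 370), 365.23, tolerance = 1e-4)

  expect_error(makePunctaField(5e4, fieldSpec(fieldSizeUm = c(50, 50, 1),
                                              seed = 4),
                               sizeRangeUm2 = c(90, 100)),
               "overlap")
})

test_that("pressure trajectories match the emulated colony", {
  # control mean stays in the normotensive range across seeds
  for (s in 1:6) {
    ctl <- makeIOPSeries("D2control", seed = s, endMonth = 12)
    expect_lt(abs(mean(ctl$iop) - 11.6), 3 * 1.4)
  }
  # hypertensive animals rise after 6 months toward ~20 mmHg
  d2m <- vapply(1:20, function(s) {
    x <- makeIOPSeries("D2", seed = 100 + s, endMonth = 9)
    mean(x$iop[x$age_days > 250])
  }, 0)
  expect_gt(mean(d2m), 16)
  expect_lt(mean(d2m), 24)

  # bilateral cumulative exposure is tightly correlated by construction
  set.seed(13)
  auc <- t(vapply(1:40, function(i) {
    s <- makeIOPSeries(sample(c("D2", "D2control"), 1), seed = NULL,
                       endMonth = 12)
    vapply(split(s, s$eye), function(e) aucTrapezoid(e$age_days, e$iop), 0)
  }, c(left = 0, right = 0)))
  expect_gt(fitRegression(auc[, 1], auc[, 2])$r_squared, 0.9)
})

test_that("makeCohort ties metrics to cumulative pressure as specified", {
  expect_error(cohortSpec(effectMap = list(bogus_metric = list())), "unknown")

  # zero slope, zero noise: downstream regression recovers slope 0 exactly
  co0 <- makeCohort(cohortSpec(5, effectMap = list(
    D_f = list(intercept = 1.4, slope = 0, noiseSd = 0)), seed = 2))
  r0 <- fitRegression(co0$auc_iop, co0$D_f)
  expect_equal(r0$slope, 0)
  expect_equal(r0$f, 0)
  expect_equal(r0$p, 1)

  # slope recovery: fitted slope within 3 SE of truth in >= 95% of replicates
  hits <- mean(vapply(1:60, function(i) {
    co <- makeCohort(cohortSpec(7, ages = 9, effectMap = list(
      endpoints_per_cell = list(intercept = 20, slope = -0.002,
                                noiseSd = 1.2)), seed = 5000 + i))
    r <- fitRegression(co$auc_iop, co$endpoints_per_cell)
    se <- (r$slope_ci[2] - r$slope_ci[1]) / (2 * qt(0.975, r$n - 2))
    abs(r$slope + 0.002) < 3 * se
  }, TRUE))
  expect_gte(hits, 0.95)

  # reproducible by seed
  expect_identical(makeCohort(cohortSpec(3, seed = 9)),
                   makeCohort(cohortSpec(3, seed = 9)))
})

test_that("makeDEGTable builds tables with exact truth counts", {
  tab <- makeDEGTable(500, 20, 5, seed = 3)
  expect_equal(degFilter(tab)$n_up, 20)
  expect_equal(degFilter(tab)$n_down, 5)
  expect_true(all(tab$fold_change > 0))
  expect_true(all(tab$q >= 0 & tab$q <= 1))

  zero <- makeDEGTable(100, 0, 0, seed = 4)
  expect_equal(degFilter(zero)$n_up, 0)
  expect_equal(degFilter(zero)$n_down, 0)

  expect_error(makeDEGTable(10, 8, 8, seed = 1), "exceed")
  expect_error(makeDEGTable(10, -1, 0, seed = 1), "non-negative")
  expect_identical(makeDEGTable(200, 7, 3, seed = 8),
                   makeDEGTable(200, 7, 3, seed = 8))
})
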