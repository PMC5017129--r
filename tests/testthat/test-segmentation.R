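test_that("rolling ball removes flat backgrounds completely", {
  expect_true(all(rollingBall(matrix(7, 20, 20), 5) == 0))
})

test_that("rolling ball keeps an isolated bright pixel intact", {
  img <- matrix(0, 64, 64); img[30, 33] <- 42
  out <- rollingBall(img, 50)
  expect_equal(out[30, 33], 42, tolerance = 1e-9)
  expect_equal(sum(out), 42, tolerance = 1e-9)  # everything else stays 0
})

test_that("rolling ball commutes with additive constants", {
  set.seed(6)
  img <- matrix(runif(32 * 32, 0, 10), 32)
  expect_equal(rollingBall(img + 3.7, 6), rollingBall(img, 6),
               tolerance = 1e-10)
})

test_that("rolling ball background is the brute-force grayscale opening", {
  set.seed(7)
  img <- matrix(runif(24 * 24, 0, 5), 24)
  r <- 4L
  expect_equal(rollingBall(img, r), pmax(img - bfOpen(img, r), 0),
               tolerance = 1e-12)
})

test_that("rolling ball rejects non-finite input", {
  img <- matrix(1, 8, 8); img[3, 3] <- NA
  expect_error(rollingBall(img, 2), "finite")
})

test_that("band-pass rejects DC entirely and zeroes the mean", {
  expect_lt(max(abs(bandpassFilter(matrix(3, 32, 32), 0.2, 4, 0.1))), 1e-10)
  set.seed(8)
  img <- matrix(runif(48 * 48, 0, 7), 48)
  expect_lt(abs(mean(bandpassFilter(img, 0.2, 4, 0.1))), 1e-10)
})

test_that("band-pass preserves in-band sinusoids and kills out-of-band ones", {
  n <- 512; px <- 0.1                   # 51.2 um frame
  x <- outer(rep(1, n), seq_len(n) - 1)
  # in-band: 40 cycles per frame = 1.28 um period, exactly on the FFT grid
  sIn <- sin(2 * pi * 40 * x / n)
  fIn <- bandpassFilter(sIn, 0.2, 4, px)
  expect_equal(sd(fIn) / sd(sIn), 1, tolerance = 0.1)
  # far above the high cutoff: 1 cycle per frame = 51.2 um period (> 10x 4 um)
  sOut <- sin(2 * pi * 1 * x / n)
  fOut <- bandpassFilter(sOut, 0.2, 4, px)
  expect_lte(sd(fOut) / sd(sOut), 0.1)
})

test_that("adaptive threshold matches brute-force local means on a 5x5 toy", {
  img <- matrix(0, 5, 5); img[2:4, 2:4] <- 100
  got <- adaptiveThreshold(img, 3L, 0)
  ref <- img > bfBoxMean(img, 3L)
  expect_identical(got, ref)
})

test_that("adaptive threshold limits behave", {
  img <- matrix(4, 9, 9)
  expect_false(any(adaptiveThreshold(img, 3L, 0.5)))   # nothing above mean+c
  set.seed(9)
  img2 <- matrix(runif(15 * 15), 15)
  expect_false(any(adaptiveThreshold(img2, 5L, 1e9)))  # offset -> infinity
})

test_that("cleanup removes specks, honours closing, labels 8-connected", {
  p0 <- segmentationParams(openingRadius = 1L, closingRadius = 0L,
                           minObjectArea = 0)
  speck <- matrix(FALSE, 16, 16); speck[8, 8] <- TRUE
  expect_equal(nObjects(cleanupAndLabel(speck, p0)), 0L)

  # two 5x5 blobs, 5 px apart edge to edge
  m <- matrix(FALSE, 30, 40)
  m[11:15, 8:12] <- TRUE; m[11:15, 18:22] <- TRUE
  p1 <- segmentationParams(openingRadius = 1L, closingRadius = 1L,
                           minObjectArea = 0)
  p4 <- segmentationParams(openingRadius = 1L, closingRadius = 5L,
                           minObjectArea = 0)
  expect_equal(nObjects(cleanupAndLabel(m, p1)), 2L)
  expect_equal(nObjects(cleanupAndLabel(m, p4)), 1L)
  # cross-check both against brute-force open/close morphology
  for (p in list(p1, p4)) {
    ref <- bfClose(bfOpen(m * 1, p$openingRadius), p$closingRadius) > 0.5
    expect_identical(labelMatrix(cleanupAndLabel(m, p)) > 0L, ref)
  }
  expect_equal(nObjects(cleanupAndLabel(matrix(FALSE, 8, 8), p1)), 0L)
})

test_that("minimum object area filters small components in um^2", {
  m <- matrix(FALSE, 20, 20)
  m[2:3, 2:3] <- TRUE          # 4 px = 0.04 um^2 at 0.1 um/px
  m[10:15, 10:15] <- TRUE      # 36 px = 0.36 um^2
  p <- segmentationParams(openingRadius = 0L, closingRadius = 0L,
                          minObjectArea = 0.1)
  out <- cleanupAndLabel(m, p, pixelSize = 0.1)
  expect_equal(nObjects(out), 1L)
  expect_true(all(labelMatrix(out)[2:3, 2:3] == 0L))
})

test_that("segmenting a high-SNR cell recovers the placed objects", {
  spec <- simCellSpec(balancedMix, objectCount = 10, seed = 21,
                      photonScale = 2000)
  sim <- renderStack(list(spec), nSlices = 5)
  seg <- segmentCell(sim$stack, sim$rois[[1]])
  expect_equal(nObjects(seg), 10L)
  # determinism: identical labelled mask on a second run
  seg2 <- segmentCell(sim$stack, sim$rois[[1]])
  expect_identical(labelMatrix(seg), labelMatrix(seg2))
})

test_that("zero signal yields a valid empty segmentation with a warning", {
  spec <- simCellSpec(balancedMix, objectCount = 5, seed = 22,
                      photonScale = 0, readNoiseSd = 1)
  sim <- renderStack(list(spec), nSlices = 3, frameDim = c(128L, 128L))
  roi <- CellROI(cbind(c(20, 100, 100, 20), c(20, 20, 100, 100)), "c", 0.1)
  expect_warning(seg <- segmentCell(sim$stack, roi), "no mitochondrial")
  expect_equal(nObjects(seg), 0L)
})

test_that("an ROI outside the frame is rejected", {
  stk <- ImageStack(array(runif(64 * 64 * 2), c(64, 64, 2)))
  roi <- CellROI(cbind(c(10, 200, 200), c(10, 10, 50)), "bad", 0.1)
  expect_error(segmentCell(stk, roi), "outside")
})

test_that("segmentation recall and precision hold across seeds", {
  hits <- 0L; trueN <- 0L; segN <- 0L
  for (seed in 101:110) {
    spec <- simCellSpec(balancedMix, objectCount = 12, seed = seed)
    sim <- renderStack(list(spec), nSlices = 5)
    seg <- suppressWarnings(segmentCell(sim$stack, sim$rois[[1]]))
    lab <- labelMatrix(seg)
    trueN <- trueN + nrow(sim$truth)
    segN <- segN + nObjects(seg)
    for (k in seq_along(sim$masks)) {
      mk <- sim$masks[[k]]
      sub <- lab[mk$top + seq_len(nrow(mk$mask)) - 1L,
                 mk$left + seq_len(ncol(mk$mask)) - 1L]
      if (any(sub[mk$mask] > 0L)) hits <- hits + 1L
    }
  }
  expect_gte(hits / trueN, 0.9)          # recall
  expect_lte(segN - hits, 0.1 * trueN)   # spurious components
})
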