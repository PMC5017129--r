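test_that("archetype validation enforces the invariants", {
  expect_error(morphArchetype("punctate", c(0, 1), c(0.3, 0.5)), "positive")
  expect_error(morphArchetype("punctate", c(0.3, 0.8), c(0.3, 0.5),
                              c(1L, 2L)), "branch")
  expect_error(morphArchetype("intermediate", c(3, 1), c(0.3, 0.5)),
               "increasing")
  a <- archetypePresets()
  expect_lt(a$punctate$lengthRange[2], a$intermediate$lengthRange[1] + 0.21)
  expect_lt(a$intermediate$lengthRange[2], a$filamentous$lengthRange[1])
})

test_that("a circular punctate archetype rasterizes to the disk area", {
  arch <- morphArchetype("punctate", c(0.5, 0.5), c(0.5, 0.5))
  obj <- generateObject(arch, seed = 3, pixelSize = 0.1)
  expect_equal(obj$areaUm2, pi * 0.25^2, tolerance = 0.2)
  expect_equal(max(mitomorph:::.label8(obj$mask)), 1L)
})

test_that("an unbranched 8 um filament's true skeleton measures 8 um", {
  arch <- morphArchetype("filamentous", c(8, 8), c(0.5, 0.5),
                         c(0L, 0L), curvature = 0.3)
  lens <- vapply(1:5, function(s) {
    obj <- generateObject(arch, seed = s, pixelSize = 0.1)
    skeletonStats(obj$mask, 0.1)$lengthUm
  }, numeric(1))
  expect_true(all(abs(lens - 8) / 8 <= 0.15))
})

test_that("object generation is a pure function of archetype and seed", {
  arch <- archetypePresets()$filamentous
  o1 <- generateObject(arch, seed = 11)
  o2 <- generateObject(arch, seed = 11)
  expect_identical(o1$mask, o2$mask)
  expect_identical(o1$lengthUm, o2$lengthUm)
  o3 <- generateObject(arch, seed = 12)
  expect_false(identical(o1$mask, o3$mask))
})

test_that("generated geometry honours the archetype ranges", {
  for (cl in c("punctate", "intermediate", "filamentous")) {
    arch <- archetypePresets()[[cl]]
    for (s in 1:10) {
      obj <- generateObject(arch, seed = s * 7)
      expect_gte(obj$lengthUm, arch$lengthRange[1])
      expect_lte(obj$lengthUm, arch$lengthRange[2])
      expect_gte(obj$nBranches, arch$branchCountRange[1])
      expect_lte(obj$nBranches, arch$branchCountRange[2])
    }
  }
})

test_that("cell spec validation rejects bad mixtures and optics", {
  expect_error(simCellSpec(c(0.5, 0.5, 0.5)), "summing to 1")
  expect_error(simCellSpec(c(-0.1, 0.6, 0.5)), "nonnegative")
  expect_error(simCellSpec(balancedMix, objectCount = 0), "objectCount")
  expect_error(simCellSpec(balancedMix, psfSigma = -1), ">= 0")
})

test_that("rendering is deterministic and rejects bad inputs", {
  spec <- simCellSpec(balancedMix, objectCount = 6, seed = 31)
  s1 <- renderStack(list(spec), nSlices = 3, frameDim = c(160L, 160L))
  s2 <- renderStack(list(spec), nSlices = 3, frameDim = c(160L, 160L))
  expect_identical(intensities(s1$stack), intensities(s2$stack))
  expect_identical(s1$truth, s2$truth)
  expect_error(renderStack(list(), 3), "nonempty")
  expect_error(renderStack(list(spec), 0), "nSlices")
})

test_that("the noiseless limit returns the blurred ground truth exactly", {
  spec <- simCellSpec(balancedMix, objectCount = 4, seed = 41,
                      photonScale = Inf, readNoiseSd = 0)
  sim <- renderStack(list(spec), nSlices = 3, frameDim = c(192L, 192L))
  a <- intensities(sim$stack)
  # rebuild the expected signal from the returned masks, depths, amplitudes
  expected <- array(0, dim(a))
  for (k in seq_along(sim$masks)) {
    mk <- sim$masks[[k]]
    pad <- 30L
    crop <- matrix(0, nrow(mk$mask) + 2L * pad, ncol(mk$mask) + 2L * pad)
    crop[pad + seq_len(nrow(mk$mask)), pad + seq_len(ncol(mk$mask))] <-
      mk$mask * sim$truth$amp[k]
    for (s in 1:3) {
      sigma <- (spec$psfSigma + spec$defocusGain *
                  abs((s - 1) * spec$zStep - sim$truth$zUm[k])) / 0.1
      expected[, , s] <- mitomorph:::addCrop(
        expected[, , s], mitomorph:::gaussianBlur(crop, sigma),
        mk$top - pad, mk$left - pad)
    }
  }
  expect_equal(a, pmax(expected, 0), tolerance = 1e-6)
})

test_that("per-slice sharpness peaks at the object's focal plane", {
  arch <- archetypePresets()$intermediate
  obj <- generateObject(arch, seed = 5)
  nSl <- 7L
  spec <- simCellSpec(balancedMix, seed = 5, photonScale = Inf,
                      readNoiseSd = 0)
  # place the object at the depth of slice 3 (z = 1.0 um)
  pad <- 40L
  crop <- matrix(0, nrow(obj$mask) + 2L * pad, ncol(obj$mask) + 2L * pad)
  crop[pad + seq_len(nrow(obj$mask)), pad + seq_len(ncol(obj$mask))] <-
    obj$mask
  sharpness <- vapply(seq_len(nSl), function(s) {
    sigma <- (spec$psfSigma + spec$defocusGain *
                abs((s - 1) * spec$zStep - 1.0)) / 0.1
    lapEnergy(mitomorph:::gaussianBlur(crop, sigma))
  }, numeric(1))
  expect_equal(which.max(sharpness), 3L)
})

test_that("objects land inside the polygon with disjoint footprints", {
  spec <- simCellSpec(balancedMix, objectCount = 15, seed = 51)
  sim <- renderStack(list(spec), nSlices = 3)
  expect_equal(sim$placementFailures, 0L)
  occupancy <- matrix(0L, 416, 416)
  v <- sim$rois[[1]]@vertices
  inside <- mitomorph:::rasterizePolygon(v, 416, 416)
  for (mk in sim$masks) {
    idx <- which(mk$mask, arr.ind = TRUE)
    idx[, 1] <- idx[, 1] + mk$top - 1L
    idx[, 2] <- idx[, 2] + mk$left - 1L
    expect_true(all(inside[idx]))
    occupancy[idx] <- occupancy[idx] + 1L
  }
  expect_lte(max(occupancy), 1L)   # hard-core placement: no overlaps
})

test_that("ground-truth labels follow the requested mixture at n = 1000", {
  # miniature archetypes for all three classes: the property under test is
  # the label sampling, so geometry is kept small to fit 1000 objects
  small <- list(
    punctate = morphArchetype("punctate", c(0.4, 0.5), c(0.35, 0.45)),
    intermediate = morphArchetype("intermediate", c(0.6, 0.8), c(0.3, 0.4)),
    filamentous = morphArchetype("filamentous", c(0.8, 1.0), c(0.3, 0.4)))
  mix <- c(0.6, 0.25, 0.15)
  truth <- do.call(rbind, lapply(1:4, function(i) {
    spec <- simCellSpec(mix, objectCount = 250, seed = 60 + i,
                        archetypes = small)
    renderStack(list(spec), nSlices = 1, minSepUm = 0.2)$truth
  }))
  fr <- prop.table(table(factor(truth$classLabel,
                                levels = c("punctate", "intermediate",
                                           "filamentous"))))
  n <- nrow(truth)
  expect_equal(n, 1000L)
  hw <- 1.96 * sqrt(mix * (1 - mix) / n)
  expect_true(all(abs(as.numeric(fr) - mix) <= hw + 0.01))
})

test_that("the benchmark table is labelled, complete and reproducible", {
  b1 <- makeBenchmark(24, mixture = balancedMix, seed = 71)
  b2 <- makeBenchmark(24, mixture = balancedMix, seed = 71)
  expect_identical(b1, b2)
  expect_equal(nrow(b1), 24L)
  expect_true(all(b1$label %in% c("punctate", "intermediate",
                                  "filamentous")))
  b3 <- makeBenchmark(12, mixture = c(1, 0, 0), seed = 72)
  expect_true(all(b3$label == "punctate"))
  expect_true(all(!b3$missed))
})
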