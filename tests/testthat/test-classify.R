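# a quick synthetic descriptor table, no imaging: three well-separated
# clusters in skeleton length / branch space with plausible other columns
fakeBenchmark <- function(n = 150, seed = 1) {
  set.seed(seed)
  per <- n / 3
  lab <- rep(c("punctate", "intermediate", "filamentous"), each = per)
  len <- c(runif(per, 0.1, 0.6), runif(per, 1.3, 2.8), runif(per, 5, 11))
  data.frame(
    areaUm2 = len * 0.4 + runif(n, 0.05, 0.15),
    perimeterUm = len * 2 + 0.5, majorAxisUm = len + 0.3,
    minorAxisUm = 0.4 + runif(n, 0, 0.1),
    eccentricity = pmin(len / (len + 0.3), 0.99),
    solidity = runif(n, 0.7, 1), formFactor = pmax(0.05, 1 - len / 12),
    skeletonLengthUm = len,
    branchPoints = c(rep(0, 2 * per), rbinom(per, 2, 0.4)),
    aspectRatio = (len + 0.3) / 0.45, label = lab)
}

test_that("training is reproducible and records metadata", {
  b <- fakeBenchmark()
  m1 <- trainClassifier(b, nTrees = 100, seed = 7)
  m2 <- trainClassifier(b, nTrees = 100, seed = 7)
  probe <- fakeBenchmark(60, seed = 99)
  expect_identical(classifyObjects(m1, probe)$classLabel,
                   classifyObjects(m2, probe)$classLabel)
  expect_identical(m1@trainingHash, m2@trainingHash)
  expect_equal(m1@nTrees, 100L)
  expect_lt(m1@oobError, 0.1)
})

test_that("a missing class aborts training with the class named", {
  b <- fakeBenchmark()
  expect_error(trainClassifier(b[b$label != "filamentous", ]),
               "filamentous")
})

test_that("too few examples per class is rejected", {
  b <- fakeBenchmark(30)   # 10 per class < default 30
  expect_error(trainClassifier(b), "at least 30")
})

test_that("duplicated training data leaves decisions unchanged", {
  b <- fakeBenchmark()
  probe <- fakeBenchmark(90, seed = 5)
  m1 <- trainClassifier(b, nTrees = 150, seed = 3)
  m2 <- trainClassifier(rbind(b, b), nTrees = 150, seed = 3)
  agree <- mean(classifyObjects(m1, probe)$classLabel ==
                  classifyObjects(m2, probe)$classLabel)
  expect_gte(agree, 0.97)
})

test_that("a model round-trips through serialization unchanged", {
  b <- fakeBenchmark()
  m <- trainClassifier(b, nTrees = 100, seed = 2)
  f <- withr::local_tempfile(fileext = ".rds")
  saveRDS(m, f)
  m2 <- readRDS(f)
  probe <- fakeBenchmark(60, seed = 4)
  expect_identical(classifyObjects(m, probe)$classLabel,
                   classifyObjects(m2, probe)$classLabel)
})

test_that("prediction keeps probabilities and is order-invariant", {
  b <- fakeBenchmark()
  m <- trainClassifier(b, nTrees = 100, seed = 2)
  probe <- fakeBenchmark(90, seed = 11)
  out <- classifyObjects(m, probe)
  pr <- as.matrix(out[, c("p.punctate", "p.intermediate", "p.filamentous")])
  expect_equal(rowSums(pr), rep(1, nrow(pr)), tolerance = 1e-9)
  perm <- sample(nrow(probe))
  out2 <- classifyObjects(m, probe[perm, ])
  expect_identical(out2$classLabel, out$classLabel[perm])
})

test_that("prediction on an empty table returns an empty labelled table", {
  m <- trainClassifier(fakeBenchmark(), nTrees = 50, seed = 1)
  out <- classifyObjects(m, fakeBenchmark(0)[0, ])
  expect_equal(nrow(out), 0L)
  expect_true("classLabel" %in% names(out))
})

test_that("prediction rejects tables lacking the trained descriptors", {
  m <- trainClassifier(fakeBenchmark(), nTrees = 50, seed = 1)
  bad <- fakeBenchmark(30, seed = 2)
  bad$skeletonLengthUm <- NULL
  expect_error(classifyObjects(m, bad), "skeletonLengthUm")
})

test_that("the threshold rule implements the stated class boundaries", {
  df <- data.frame(
    skeletonLengthUm = c(0.5, 2, 3, 5, 0.99, 1.0, 4.01),
    branchPoints = c(0, 0, 2, 0, 0, 0, 0))
  got <- classifyRuleBased(df)$classLabel
  expect_equal(got, c("punctate", "intermediate", "filamentous",
                      "filamentous", "punctate", "intermediate",
                      "filamentous"))
})

test_that("rule thresholds are configurable", {
  df <- data.frame(skeletonLengthUm = 2, branchPoints = 0)
  expect_equal(classifyRuleBased(df, punctateMax = 2.5)$classLabel,
               "punctate")
})
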