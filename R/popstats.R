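# Per-cell and per-population phenotype summaries and the comparison
# statistics: class fractions, total mitochondrial area, density, the
# morphology-change metric, longitudinal stability, Pearson correlation and
# Friedman's rank sums test.

#' Summarize one cell's mitochondrial phenotype
#'
#' Aggregates the classified objects of one cell into counts and fractions
#' per morphology class, total mitochondrial area (um^2) and density
#' (mitochondrial area / cell area). The fraction basis is object count by
#' default; \code{weighting = "area"} weights each object by its area
#' instead (the two conventions bracket what published per-cell fractions
#' may mean).
#'
#' @param objects data.frame of classified objects of one cell (needs
#'   \code{classLabel} and \code{areaUm2}).
#' @param roi the cell's [CellROI-class] (for the cell area).
#' @param weighting \code{"count"} or \code{"area"}.
#' @return one-row data.frame: \code{cellId}, per-class counts
#'   (\code{n.punctate} ...), fractions (\code{f.punctate} ...),
#'   \code{nObjects}, \code{totalAreaUm2}, \code{cellAreaUm2},
#'   \code{density}, \code{empty}. For a cell with zero objects the
#'   fractions are \code{NA} and \code{empty} is \code{TRUE}.
#' @examples
#' objs <- data.frame(classLabel = rep(c("punctate", "filamentous"), c(4, 6)),
#'                    areaUm2 = rep(c(0.2, 2), c(4, 6)))
#' roi <- CellROI(cbind(c(0, 100, 100, 0), c(0, 0, 100, 100)), "c1", 0.1)
#' summarizeCell(objs, roi)
#' @export
summarizeCell <- function(objects, roi, weighting = c("count", "area")) {
  weighting <- match.arg(weighting)
  stopifnot(is(roi, "CellROI"))
  n <- nrow(objects)
  cellA <- cellArea(roi)
  counts <- table(factor(objects$classLabel, levels = MITO_CLASSES))
  totalA <- if (n) sum(objects$areaUm2) else 0
  if (n == 0L) {
    fr <- setNames(rep(NA_real_, 3), MITO_CLASSES)
  } else if (weighting == "count") {
    fr <- as.numeric(counts) / n
  } else {
    fr <- as.numeric(tapply(objects$areaUm2,
                            factor(objects$classLabel,
                                   levels = MITO_CLASSES), sum,
                            default = 0)) / totalA
  }
  out <- data.frame(cellId = roi@cellId,
                    n.punctate = as.integer(counts[1]),
                    n.intermediate = as.integer(counts[2]),
                    n.filamentous = as.integer(counts[3]),
                    f.punctate = fr[1], f.intermediate = fr[2],
                    f.filamentous = fr[3],
                    nObjects = n, totalAreaUm2 = totalA,
                    cellAreaUm2 = cellA,
                    density = totalA / cellA, empty = n == 0L)
  rownames(out) <- NULL
  out
}

#' Population-level phenotype summary
#'
#' Stacks per-cell phenotype rows for one sample and derives the population
#' readouts: per-class mean fraction and SD (over non-empty cells), mean
#' total mitochondrial area and mean density.
#'
#' @param cells data.frame of [summarizeCell()] rows.
#' @param sampleId sample identifier.
#' @return list of class \code{PopulationSummary}: \code{sampleId},
#'   \code{cells}, \code{meanFractions} (sums to 1), \code{sdFractions},
#'   \code{meanTotalArea}, \code{meanDensity}, \code{nCells}.
#' @export
populationSummary <- function(cells, sampleId = "sample1") {
  stopifnot(is.data.frame(cells), nrow(cells) >= 1L)
  use <- !cells$empty
  fr <- as.matrix(cells[use, paste0("f.", MITO_CLASSES), drop = FALSE])
  structure(list(sampleId = sampleId, cells = cells,
                 meanFractions = setNames(colMeans(fr), MITO_CLASSES),
                 sdFractions = setNames(apply(fr, 2, sd), MITO_CLASSES),
                 meanTotalArea = mean(cells$totalAreaUm2[use]),
                 meanDensity = mean(cells$density[use]),
                 nCells = nrow(cells)),
            class = "PopulationSummary")
}

#' @export
print.PopulationSummary <- function(x, ...) {
  cat(sprintf("PopulationSummary '%s': %d cell(s)\n", x$sampleId, x$nCells))
  cat(sprintf("  mean fractions: punctate %.1f%%, intermediate %.1f%%, filamentous %.1f%%\n",
              100 * x$meanFractions[1], 100 * x$meanFractions[2],
              100 * x$meanFractions[3]))
  cat(sprintf("  mean total mito area %.1f um^2, mean density %.3f\n",
              x$meanTotalArea, x$meanDensity))
  invisible(x)
}

#' Total mitochondrial morphology change between two populations
#'
#' The morphology-change metric: per class, the change in mean population
#' percentage from the pre to the post condition; the total change is the
#' sum over the three classes of the absolute per-class changes, in
#' percentage points (range 0 to 200). \code{mode = "relative"} instead
#' expresses each class change relative to its pre-treatment percentage.
#'
#' @param pre,post \code{PopulationSummary} objects.
#' @param mode \code{"absolute"} (percentage points, default) or
#'   \code{"relative"} (percent of the pre value).
#' @return list of class \code{ChangeResult}: \code{perClass} (signed
#'   changes), \code{total} (sum of absolute changes), \code{mode}.
#' @examples
#' mk <- function(f) {
#'   cells <- data.frame(cellId = "c", n.punctate = 0, n.intermediate = 0,
#'     n.filamentous = 0, f.punctate = f[1], f.intermediate = f[2],
#'     f.filamentous = f[3], nObjects = 10, totalAreaUm2 = 1,
#'     cellAreaUm2 = 10, density = .1, empty = FALSE)
#'   populationSummary(cells)
#' }
#' changeMetric(mk(c(.4, .2, .4)), mk(c(.6, .2, .2)))$total  # 40
#' @export
changeMetric <- function(pre, post, mode = c("absolute", "relative")) {
  mode <- match.arg(mode)
  stopifnot(inherits(pre, "PopulationSummary"),
            inherits(post, "PopulationSummary"))
  if (!identical(names(pre$meanFractions), names(post$meanFractions)))
    stop("pre and post summaries have different class sets")
  d <- 100 * (post$meanFractions - pre$meanFractions)
  if (mode == "relative")
    d <- d / pmax(100 * pre$meanFractions, .Machine$double.eps) * 100
  structure(list(perClass = d, total = sum(abs(d)), mode = mode,
                 pre = pre$sampleId, post = post$sampleId),
            class = "ChangeResult")
}

#' @export
print.ChangeResult <- function(x, ...) {
  cat(sprintf("Morphology change %s -> %s (%s): total %.1f points\n",
              x$pre, x$post, x$mode, x$total))
  print(round(x$perClass, 2))
  invisible(x)
}

#' Correct measured class fractions for classifier confusion
#'
#' Given the class-conditional confusion matrix \code{C} (rows = true class,
#' columns = assigned class, rows summing to 1) measured on a labelled
#' benchmark, the expected measured fraction vector is \code{t(C) p} for
#' true mixture \code{p}. This inverts that relation, clamps negative
#' solutions to zero and renormalizes to the simplex.
#'
#' @param fractions measured class-fraction vector (punctate, intermediate,
#'   filamentous).
#' @param confusion 3 x 3 row-stochastic confusion matrix, rows = truth.
#' @return corrected fraction vector summing to 1.
#' @examples
#' C <- matrix(c(.9, .1, 0, .05, .95, 0, 0, .1, .9), 3, byrow = TRUE)
#' correctClassFractions(c(.4, .3, .3), C)
#' @export
correctClassFractions <- function(fractions, confusion) {
  stopifnot(length(fractions) == 3L, all(dim(confusion) == c(3L, 3L)))
  p <- solve(t(confusion), as.numeric(fractions))
  p <- pmax(p, 0)
  setNames(p / sum(p), MITO_CLASSES)
}

#' Pearson product-moment correlation
#'
#' Correlation between a phenotype readout and an external per-sample
#' measurement (e.g. oxygen-consumption or acidification rates). Delegates
#' to the standard product-moment test; zero variance in either variable is
#' reported as an undefined correlation rather than an error.
#'
#' @param x,y numeric vectors of equal length >= 3.
#' @return list: \code{r}, \code{p.value}, \code{n}.
#' @examples
#' pearsonCorrelation(1:4, c(2, 1, 4, 3))$r   # 0.6
#' @export
pearsonCorrelation <- function(x, y) {
  if (length(x) != length(y)) stop("'x' and 'y' must have equal length")
  if (length(x) < 3L) stop("need at least 3 paired observations")
  if (anyNA(x) || anyNA(y)) stop("missing values not allowed")
  if (sd(x) == 0 || sd(y) == 0) {
    warning("zero variance: correlation undefined")
    return(list(r = NA_real_, p.value = NA_real_, n = length(x)))
  }
  ct <- cor.test(x, y, method = "pearson")
  list(r = unname(ct$estimate), p.value = ct$p.value, n = length(x))
}

# all within-block rank assignments for the exact permutation distribution
friedmanPermutationP <- function(mat, statObs, nPerm = 20000L,
                                 permSeed = 1L) {
  k <- ncol(mat); n <- nrow(mat)
  ranks <- t(apply(mat, 1, rank))
  stat_of <- function(r) {
    # same tie-corrected statistic as stats::friedman.test
    Rj <- colSums(r)
    ties <- apply(r, 1, function(x) sum(table(x)^3 - table(x)))
    denom <- n * k * (k + 1) - sum(ties) / (k - 1)
    if (denom <= 0) return(0)   # every block fully tied
    (12 * sum((Rj - n * (k + 1) / 2)^2)) / denom
  }
  allPermutations <- function(k) {
    if (k == 1L) return(matrix(1L, 1, 1))
    sub <- allPermutations(k - 1L)
    do.call(rbind, lapply(seq_len(k), function(i)
      cbind(i, sub + (sub >= i))))
  }
  perms <- factorial(k)
  if (perms^n <= 100000) {
    # full enumeration over per-block column permutations
    pm <- as.matrix(expand.grid(rep(list(seq_len(perms)), n)))
    base <- allPermutations(k)
    stats_all <- apply(pm, 1, function(idx) {
      r <- ranks
      for (b in seq_len(n)) r[b, ] <- r[b, base[idx[b], ]]
      stat_of(r)
    })
    mean(stats_all >= statObs - 1e-12)
  } else {
    set.seed(permSeed)
    stats_all <- replicate(nPerm, {
      r <- ranks
      for (b in seq_len(n)) r[b, ] <- r[b, sample.int(k)]
      stat_of(r)
    })
    (1 + sum(stats_all >= statObs - 1e-12)) / (nPerm + 1)
  }
}

#' Friedman's rank sums test
#'
#' Nonparametric comparison of \code{k} related conditions across \code{n}
#' blocks: within-block ranks (average ranks for ties), the tie-corrected
#' chi-square statistic and its asymptotic p-value. For 10 or fewer blocks
#' an exact/permutation p-value is also reported (full enumeration of the
#' within-block column permutations when feasible, otherwise a seeded Monte
#' Carlo sample).
#'
#' @param mat numeric matrix, blocks x conditions, no missing values;
#'   >= 2 blocks and >= 2 conditions.
#' @param permutation compute the permutation p-value (default: automatic,
#'   when blocks <= 10).
#' @param nPerm Monte Carlo sample size when enumeration is infeasible.
#' @return list: \code{statistic}, \code{df}, \code{p.value} (chi-square
#'   approximation), \code{p.permutation} (or NA).
#' @examples
#' m <- matrix(c(1, 2, 3, 2, 3, 4, 1, 3, 5, 2, 1, 4), 4, 3, byrow = TRUE)
#' friedmanRankTest(m)$statistic
#' @export
friedmanRankTest <- function(mat, permutation = NULL, nPerm = 20000L) {
  mat <- as.matrix(mat)
  if (anyNA(mat)) stop("missing entries not allowed")
  if (nrow(mat) < 2L || ncol(mat) < 2L)
    stop("need >= 2 blocks and >= 2 conditions")
  ft <- friedman.test(mat)
  if (is.null(permutation)) permutation <- nrow(mat) <= 10L
  pPerm <- NA_real_
  statObs <- unname(ft$statistic)
  if (is.nan(statObs)) {   # all columns identical within every block
    statObs <- 0
    pChi <- 1
  } else pChi <- ft$p.value
  if (permutation)
    pPerm <- friedmanPermutationP(mat, statObs, nPerm = nPerm)
  list(statistic = statObs, df = unname(ft$parameter), p.value = pChi,
       p.permutation = pPerm)
}

#' Longitudinal stability of a population phenotype
#'
#' Tracks the per-class mean fractions of time-ordered population summaries
#' and tests whether the distribution of per-cell fractions changes across
#' timepoints, class by class, with Friedman's test (timepoints as
#' conditions; cells paired by acquisition index, truncating to the
#' smallest common cell count). Per-class p-values are Bonferroni-combined
#' into an overall p-value.
#'
#' @param summaries list of \code{PopulationSummary}, time order.
#' @return list: \code{trajectories} (data.frame: timepoint, class, mean,
#'   sd), \code{perClassP}, \code{p.value}.
#' @export
stabilityReport <- function(summaries) {
  if (length(summaries) < 2L) stop("need at least 2 timepoints")
  stopifnot(all(vapply(summaries, inherits, TRUE, "PopulationSummary")))
  traj <- do.call(rbind, lapply(seq_along(summaries), function(t)
    data.frame(timepoint = t, class = MITO_CLASSES,
               mean = unname(summaries[[t]]$meanFractions),
               sd = unname(summaries[[t]]$sdFractions))))
  nMin <- min(vapply(summaries, function(s) sum(!s$cells$empty), 1L))
  perClassP <- vapply(MITO_CLASSES, function(cl) {
    m <- vapply(summaries, function(s)
      s$cells[!s$cells$empty, paste0("f.", cl)][seq_len(nMin)],
      numeric(nMin))
    friedmanRankTest(m, permutation = FALSE)$p.value
  }, numeric(1))
  list(trajectories = traj, perClassP = perClassP,
       p.value = min(1, 3 * min(perClassP)))
}
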