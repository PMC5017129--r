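# Independent brute-force oracles. Deliberately naive: direct evaluation of
# the definitions, no shared code with the package internals they check.

# symmetric (half-sample) reflection index, duplicated edge
bfReflect <- function(i, n) {
  i <- ((i - 1) %% (2 * n)) + 1
  ifelse(i > n, 2 * n + 1 - i, i)
}

bfBoxMean <- function(img, window) {
  r <- (window - 1) / 2
  out <- matrix(0, nrow(img), ncol(img))
  for (i in seq_len(nrow(img))) for (j in seq_len(ncol(img))) {
    acc <- 0
    for (di in -r:r) for (dj in -r:r)
      acc <- acc + img[bfReflect(i + di, nrow(img)),
                       bfReflect(j + dj, ncol(img))]
    out[i, j] <- acc / window^2
  }
  out
}

bfDiscExtreme <- function(img, radius, fun) {
  out <- matrix(0, nrow(img), ncol(img))
  offs <- NULL
  for (di in -radius:radius) for (dj in -radius:radius)
    if (di^2 + dj^2 <= radius^2) offs <- rbind(offs, c(di, dj))
  for (i in seq_len(nrow(img))) for (j in seq_len(ncol(img))) {
    ii <- i + offs[, 1]; jj <- j + offs[, 2]
    ok <- ii >= 1 & ii <= nrow(img) & jj >= 1 & jj <= ncol(img)
    out[i, j] <- fun(img[cbind(ii[ok], jj[ok])])
  }
  out
}
bfErode  <- function(img, r) bfDiscExtreme(img, r, min)
bfDilate <- function(img, r) bfDiscExtreme(img, r, max)
bfOpen   <- function(img, r) bfDilate(bfErode(img, r), r)
bfClose  <- function(img, r) bfErode(bfDilate(img, r), r)

# Friedman chi-square via the textbook rank formula (no tie correction;
# use on tie-free matrices only)
bfFriedmanStat <- function(mat) {
  n <- nrow(mat); k <- ncol(mat)
  R <- t(apply(mat, 1, rank))
  12 / (n * k * (k + 1)) * sum(colSums(R)^2) - 3 * n * (k + 1)
}

# total Laplacian energy of an image (4-neighbour kernel, interior only)
lapEnergy <- function(m) {
  i <- 2:(nrow(m) - 1); j <- 2:(ncol(m) - 1)
  L <- m[i - 1, j] + m[i + 1, j] + m[i, j - 1] + m[i, j + 1] - 4 * m[i, j]
  sum(L^2)
}

balancedMix <- c(1, 1, 1) / 3

# small synthetic population summary built directly from fraction rows
summaryFromFractions <- function(fr, sampleId = "s") {
  cells <- data.frame(
    cellId = sprintf("c%d", seq_len(nrow(fr))),
    n.punctate = 0L, n.intermediate = 0L, n.filamentous = 0L,
    f.punctate = fr[, 1], f.intermediate = fr[, 2], f.filamentous = fr[, 3],
    nObjects = 10L, totalAreaUm2 = 1, cellAreaUm2 = 10, density = 0.1,
    empty = FALSE)
  populationSummary(cells, sampleId)
}

# naive O(N^2) DFT band-pass on a small matrix: independently restates the
# transfer function (flat passband, Gaussian skirts sigma = cutoff/3, DC = 0)
bfBandpass <- function(img, low, high, px) {
  nr <- nrow(img); nc <- ncol(img)
  F <- matrix(0i, nr, nc)
  for (u in 0:(nr - 1)) for (v in 0:(nc - 1)) {
    s <- 0i
    for (i in 0:(nr - 1)) for (j in 0:(nc - 1))
      s <- s + img[i + 1, j + 1] * exp(-2i * pi * (u * i / nr + v * j / nc))
    F[u + 1, v + 1] <- s
  }
  H <- matrix(0, nr, nc)
  for (u in 0:(nr - 1)) for (v in 0:(nc - 1)) {
    fu <- if (u / nr > 0.5) u / nr - 1 else u / nr
    fv <- if (v / nc > 0.5) v / nc - 1 else v / nc
    rho <- sqrt(fu^2 + fv^2) / px
    rLo <- 1 / high; rHi <- 1 / low
    H[u + 1, v + 1] <-
      if (u == 0 && v == 0) 0
      else if (rho < rLo) exp(-(rho - rLo)^2 / (2 * (rLo / 3)^2))
      else if (rho > rHi) exp(-(rho - rHi)^2 / (2 * (rHi / 3)^2))
      else 1
  }
  G <- F * H
  out <- matrix(0, nr, nc)
  for (i in 0:(nr - 1)) for (j in 0:(nc - 1)) {
    s <- 0i
    for (u in 0:(nr - 1)) for (v in 0:(nc - 1))
      s <- s + G[u + 1, v + 1] * exp(2i * pi * (u * i / nr + v * j / nc))
    out[i + 1, j + 1] <- Re(s) / (nr * nc)
  }
  out
}
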