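# Low-level 2-D filters shared by fusion and segmentation. All local windows
# use symmetric (half-sample) reflection at the borders: pixel -k mirrors
# pixel k+1, so edge pixels are duplicated. This is the convention every
# windowed operation in the package (and its brute-force test oracles) follows.

reflectIndex <- function(n, r) {
  # index vector of length n + 2r implementing symmetric reflection
  if (r >= n) stop("window too large for image (reflection pad >= image size)")
  c(rev(seq_len(r)), seq_len(n), n:(n - r + 1L))
}

padReflect <- function(m, r) {
  if (r == 0L) return(m)
  m[reflectIndex(nrow(m), r), reflectIndex(ncol(m), r), drop = FALSE]
}

#' Local box mean with reflected borders
#'
#' Mean over a \code{window x window} neighbourhood at every pixel, computed
#' with an integral image; borders are handled by symmetric reflection.
#'
#' @param image numeric matrix.
#' @param window odd integer >= 3, neighbourhood side in pixels.
#' @return matrix of local means, same size as \code{image}.
#' @keywords internal
boxMean <- function(image, window) {
  window <- as.integer(window)
  if (window < 3L || window %% 2L == 0L)
    stop("'window' must be an odd integer >= 3")
  r <- window %/% 2L
  p <- padReflect(image, r)
  # integral image with a leading zero row/column
  s <- rbind(0, apply(p, 2, cumsum))
  s <- cbind(0, t(apply(s, 1, cumsum)))
  nr <- nrow(image); nc <- ncol(image)
  i1 <- seq_len(nr); i2 <- i1 + 2L * r
  j1 <- seq_len(nc); j2 <- j1 + 2L * r
  (s[i2 + 1L, j2 + 1L, drop = FALSE] - s[i1, j2 + 1L, drop = FALSE] -
     s[i2 + 1L, j1, drop = FALSE] + s[i1, j1, drop = FALSE]) / window^2
}

# 4-neighbour discrete Laplacian with reflected borders.
laplacianFilter <- function(image) {
  p <- padReflect(image, 1L)
  nr <- nrow(image); nc <- ncol(image)
  i <- seq_len(nr) + 1L; j <- seq_len(nc) + 1L
  p[i - 1L, j] + p[i + 1L, j] + p[i, j - 1L] + p[i, j + 1L] - 4 * p[i, j]
}

# Gaussian blur of a matrix via EBImage (used by the simulator on
# zero-padded crops, where boundary handling is immaterial). Inputs smaller
# than the Gaussian kernel are zero-padded up and cropped back.
gaussianBlur <- function(m, sigmaPx) {
  if (sigmaPx <= 0) return(m)
  ks <- 2L * ceiling(3 * sigmaPx) + 1L
  nr <- nrow(m); nc <- ncol(m)
  if (nr < ks || nc < ks) {
    big <- matrix(0, max(nr, ks), max(nc, ks))
    big[seq_len(nr), seq_len(nc)] <- m
    out <- as.matrix(EBImage::gblur(big, sigma = sigmaPx))
    return(out[seq_len(nr), seq_len(nc), drop = FALSE])
  }
  as.matrix(EBImage::gblur(m, sigma = sigmaPx))
}

# Grayscale/flat disc morphology (Rcpp backends). Border convention:
# the structuring element is clipped at the image edge (min/max over the
# in-image part of the disc), the natural finite-support definition.
discErode  <- function(image, radius) .discErode(image, as.integer(radius))
discDilate <- function(image, radius) .discDilate(image, as.integer(radius))
discOpen   <- function(image, radius) discDilate(discErode(image, radius), radius)
discClose  <- function(image, radius) discErode(discDilate(image, radius), radius)
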