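# Segmentation of the fused image into mitochondrial components:
# rolling-ball background subtraction -> FFT band-pass -> adaptive local-mean
# threshold -> binary open/close cleanup -> 8-connected labelling.

#' Segmentation parameter set
#'
#' Bundles and validates all tunable segmentation parameters. Band-pass
#' cutoffs are expressed as spatial structure sizes in micrometres; everything
#' else in pixels or intensity units.
#'
#' @param ballRadius rolling-ball radius in pixels (default 50).
#' @param bandpassLow smallest structure size passed, um (default 0.2,
#'   about one mitochondrial width at typical sampling).
#' @param bandpassHigh largest structure size passed, um (default 4,
#'   the scale of mitochondrial clusters).
#' @param window adaptive-threshold local-mean window, odd pixels
#'   (default 51).
#' @param offset adaptive-threshold offset in intensity units; \code{NULL}
#'   (default) means estimate at run time as the larger of twice the robust
#'   noise SD of the filtered image (from the median absolute horizontal
#'   pixel difference) and \code{offsetFrac} of its 99.9th percentile.
#' @param offsetFrac signal fraction entering the automatic offset
#'   (default 0.1); keeps the cut meaningful on essentially noise-free
#'   images where the noise term vanishes.
#' @param openingRadius binary opening radius, px (default 1).
#' @param closingRadius binary closing radius, px (default 1).
#' @param minObjectArea smallest retained component, um^2 (default 0.2,
#'   below the image-domain footprint of the smallest resolvable object but
#'   above the size of threshold noise specks).
#' @return A named list of class \code{SegmentationParams}.
#' @examples
#' p <- segmentationParams(window = 31)
#' @export
segmentationParams <- function(ballRadius = 50L, bandpassLow = 0.2,
                               bandpassHigh = 4, window = 51L, offset = NULL,
                               offsetFrac = 0.1, openingRadius = 1L,
                               closingRadius = 1L, minObjectArea = 0.2) {
  window <- as.integer(window)
  if (ballRadius < 1) stop("'ballRadius' must be >= 1")
  if (!(bandpassLow > 0 && bandpassLow < bandpassHigh))
    stop("need 0 < bandpassLow < bandpassHigh")
  if (window < 3L || window %% 2L == 0L)
    stop("'window' must be an odd integer >= 3")
  if (openingRadius < 0 || closingRadius < 0) stop("radii must be >= 0")
  if (minObjectArea < 0) stop("'minObjectArea' must be >= 0")
  structure(list(ballRadius = as.integer(ballRadius),
                 bandpassLow = bandpassLow, bandpassHigh = bandpassHigh,
                 window = window, offset = offset, offsetFrac = offsetFrac,
                 openingRadius = as.integer(openingRadius),
                 closingRadius = as.integer(closingRadius),
                 minObjectArea = minObjectArea),
            class = "SegmentationParams")
}

#' Rolling-ball background subtraction
#'
#' Estimates the smooth background as the grayscale morphological opening of
#' the image with a flat disc structuring element of the given radius
#' (clipped at the borders) and subtracts it. The result is nonnegative:
#' opening never exceeds the image.
#'
#' @param image numeric matrix, finite values.
#' @param ballRadius disc radius in pixels (>= 1; default 50).
#' @return background-subtracted matrix, same size.
#' @examples
#' img <- matrix(5, 32, 32); img[16, 16] <- 20
#' out <- rollingBall(img, 8)   # flat background removed, peak retained
#' @export
rollingBall <- function(image, ballRadius = 50L) {
  if (ballRadius < 1) stop("'ballRadius' must be >= 1")
  if (anyNA(image) || any(!is.finite(image)))
    stop("image contains non-finite pixels")
  bg <- discOpen(image, ballRadius)
  pmax(image - bg, 0)
}

# Radial band-pass transfer function on the FFT grid: 1 inside the passband,
# Gaussian skirts (sigma = cutoff/3) outside, DC forced to zero.
bandpassTransfer <- function(nr, nc, low, high, pixelSize) {
  fy <- (seq_len(nr) - 1) / nr
  fx <- (seq_len(nc) - 1) / nc
  fy <- ifelse(fy > 0.5, fy - 1, fy) / pixelSize   # cycles per um
  fx <- ifelse(fx > 0.5, fx - 1, fx) / pixelSize
  rho <- sqrt(outer(fy^2, fx^2, "+"))
  rhoLo <- 1 / high   # low-frequency cutoff (largest structures passed)
  rhoHi <- 1 / low    # high-frequency cutoff (smallest structures passed)
  H <- matrix(1, nr, nc)
  lo <- rho < rhoLo
  H[lo] <- exp(-(rho[lo] - rhoLo)^2 / (2 * (rhoLo / 3)^2))
  hi <- rho > rhoHi
  H[hi] <- exp(-(rho[hi] - rhoHi)^2 / (2 * (rhoHi / 3)^2))
  H[1, 1] <- 0
  H
}

#' FFT band-pass filter
#'
#' Multiplies the image spectrum by a radially symmetric transfer function
#' that passes spatial periods between \code{low} and \code{high} micrometres
#' at unit gain, rolls off with Gaussian skirts outside the band (avoiding
#' the ringing of an ideal annulus), and suppresses DC entirely, so the
#' output has exactly zero mean.
#'
#' @param image numeric matrix.
#' @param low,high passband limits as structure sizes in um, 0 < low < high.
#' @param pixelSize micrometres per pixel.
#' @return filtered matrix (zero mean).
#' @examples
#' img <- matrix(rnorm(64 * 64), 64)
#' f <- bandpassFilter(img, 0.2, 4, pixelSize = 0.1)
#' abs(mean(f)) < 1e-12
#' @export
bandpassFilter <- function(image, low, high, pixelSize) {
  if (!(low > 0 && low < high)) stop("need 0 < low < high")
  if (pixelSize <= 0) stop("'pixelSize' must be positive")
  H <- bandpassTransfer(nrow(image), ncol(image), low, high, pixelSize)
  Re(fft(fft(image) * H, inverse = TRUE)) / length(image)
}

#' Adaptive local-mean thresholding
#'
#' A pixel is foreground iff its intensity exceeds the mean of its
#' \code{window x window} neighbourhood (reflected borders) by more than
#' \code{offset}.
#'
#' @param image numeric matrix.
#' @param window odd integer >= 3.
#' @param offset intensity offset added to the local mean.
#' @return logical matrix.
#' @examples
#' img <- matrix(0, 9, 9); img[4:6, 4:6] <- 1
#' adaptiveThreshold(img, 5, 0.1)
#' @export
adaptiveThreshold <- function(image, window, offset) {
  image > boxMean(image, window) + offset
}

# Robust noise scale from horizontal first differences:
# sd = 1.4826 / sqrt(2) * median(|img[i, j+1] - img[i, j]|).
# Differencing cancels the (PSF-band-limited) signal while passing the
# pixel-scale noise, so the estimate does not inflate when much of the frame
# is covered by object halos, unlike a plain MAD of the intensities.
estimateNoiseSD <- function(image) {
  d <- image[, -1, drop = FALSE] - image[, -ncol(image), drop = FALSE]
  1.4826 / sqrt(2) * median(abs(d))
}

#' Morphological cleanup and connected-component labelling
#'
#' Applies binary opening then closing with flat discs, labels the result
#' with 8-connectivity, and removes components smaller than
#' \code{minObjectArea} (um^2). Surviving labels are renumbered consecutively
#' in scan order.
#'
#' @param mask logical matrix.
#' @param params a [segmentationParams()] list (uses \code{openingRadius},
#'   \code{closingRadius}, \code{minObjectArea}).
#' @param pixelSize micrometres per pixel (converts the area floor to pixels).
#' @return A [LabeledMask-class].
#' @examples
#' m <- matrix(FALSE, 16, 16); m[4:7, 4:7] <- TRUE
#' cleanupAndLabel(m, segmentationParams(minObjectArea = 0), pixelSize = 0.1)
#' @export
cleanupAndLabel <- function(mask, params = segmentationParams(),
                            pixelSize = 0.1) {
  stopifnot(is.logical(mask))
  m <- mask * 1
  if (params$openingRadius > 0L) m <- discOpen(m, params$openingRadius)
  if (params$closingRadius > 0L) m <- discClose(m, params$closingRadius)
  lab <- .label8(m > 0.5)
  minPx <- params$minObjectArea / pixelSize^2
  if (max(lab) > 0L) {
    sizes <- tabulate(lab, nbins = max(lab))
    keep <- which(sizes >= minPx)
    remap <- integer(max(lab))
    remap[keep] <- seq_along(keep)
    lab[lab > 0L] <- remap[lab[lab > 0L]]
    n <- length(keep)
  } else n <- 0L
  new("LabeledMask", labels = lab, nObjects = as.integer(n),
      pixelSize = pixelSize)
}

# Rasterize a polygon (0-based x,y vertices, y-down) onto an nr x nc pixel
# grid: a pixel is inside iff its centre (col-1, row-1) satisfies the
# even-odd rule. Points exactly on an edge count as inside.
rasterizePolygon <- function(vertices, nr, nc) {
  px <- as.vector(col(matrix(0, nr, nc))) - 1
  py <- as.vector(row(matrix(0, nr, nc))) - 1
  vx <- vertices[, 1]; vy <- vertices[, 2]
  n <- length(vx)
  inside <- rep(FALSE, length(px))
  j <- n
  for (i in seq_len(n)) {
    crosses <- ((vy[i] > py) != (vy[j] > py)) &
      (px < (vx[j] - vx[i]) * (py - vy[i]) / (vy[j] - vy[i]) + vx[i])
    inside <- xor(inside, crosses)
    j <- i
  }
  matrix(inside, nr, nc)
}

#' Segment one cell from a Z-stack
#'
#' Composes the full per-cell pipeline: all-in-focus fusion, rolling-ball
#' background subtraction, FFT band-pass, adaptive thresholding (restricted
#' to the cell ROI), and open/close cleanup with 8-connected labelling.
#'
#' @param stack an [ImageStack-class] (mitochondrial channel).
#' @param roi a [CellROI-class]; \code{NULL} analyses the whole frame.
#' @param params a [segmentationParams()] list.
#' @param smoothRadius fusion index-smoothing radius, px.
#' @param window fusion focus window, px.
#' @return A [LabeledMask-class] restricted to the ROI. Zero components is a
#'   valid outcome and is reported with a warning.
#' @export
segmentCell <- function(stack, roi = NULL, params = segmentationParams(),
                        smoothRadius = 5L, window = 9L) {
  stopifnot(is(stack, "ImageStack"))
  d <- dim(intensities(stack))
  fused <- fuseStack(stack, focusMeasure(stack, window = window),
                     smoothRadius = smoothRadius)$image
  img <- rollingBall(fused, params$ballRadius)
  img <- bandpassFilter(img, params$bandpassLow, params$bandpassHigh,
                        pixelSize(stack))
  offset <- params$offset
  if (is.null(offset))
    offset <- max(2 * estimateNoiseSD(img),
                  params$offsetFrac * quantile(img, 0.999, names = FALSE))
  mask <- adaptiveThreshold(img, params$window, offset)
  if (!is.null(roi)) {
    stopifnot(is(roi, "CellROI"))
    v <- roi@vertices
    if (any(v[, 1] < -0.5 | v[, 1] > d[2] - 0.5 |
            v[, 2] < -0.5 | v[, 2] > d[1] - 0.5))
      stop("ROI polygon extends outside the image frame")
    mask <- mask & rasterizePolygon(v, d[1], d[2])
  }
  out <- cleanupAndLabel(mask, params, pixelSize(stack))
  if (nObjects(out) == 0L)
    warning("no mitochondrial components found in this cell")
  out
}
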