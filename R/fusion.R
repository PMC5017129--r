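# All-in-focus (extended depth of field) fusion: per pixel, find the slice in
# which the local image is sharpest and take that slice's intensity.

#' Per-pixel focus scoring of a Z-stack
#'
#' Scores every pixel of every slice with a variance-of-Laplacian sharpness
#' measure: each slice is lightly Gaussian-smoothed (\code{preSigma}, which
#' stops photon shot noise from masquerading as sharpness on bright but
#' defocused structures), filtered with the 4-neighbour Laplacian, and the
#' local variance of the result is taken over a \code{window x window}
#' neighbourhood (reflected borders). The sharpest slice per pixel is the
#' arg-max across slices, ties resolved to the lowest slice index.
#'
#' @param stack an [ImageStack-class].
#' @param window odd integer >= 3; local-variance window side in pixels
#'   (default 9).
#' @param preSigma Gaussian pre-smoothing sigma in pixels applied before
#'   scoring only (default 1; 0 disables). Fusion always samples the
#'   original intensities.
#' @return A [FocusMap-class] holding the score array and selected-slice map.
#' @examples
#' stk <- ImageStack(array(runif(64 * 64 * 3), c(64, 64, 3)))
#' fm <- focusMeasure(stk)
#' @seealso [fuseStack()]
#' @export
focusMeasure <- function(stack, window = 9L, preSigma = 1) {
  stopifnot(is(stack, "ImageStack"))
  window <- as.integer(window)
  if (window < 3L || window %% 2L == 0L)
    stop("'window' must be an odd integer >= 3")
  a <- intensities(stack)
  nz <- dim(a)[3]
  scores <- array(0, dim(a))
  for (k in seq_len(nz)) {
    s <- if (preSigma > 0) gaussianBlur(a[, , k], preSigma) else a[, , k]
    L <- laplacianFilter(s)
    scores[, , k] <- boxMean(L^2, window) - boxMean(L, window)^2
  }
  sel <- matrix(1L, dim(a)[1], dim(a)[2])
  if (nz > 1L) {
    best <- scores[, , 1]
    for (k in 2:nz) {
      better <- scores[, , k] > best   # strict: ties keep the lower index
      sel[better] <- k
      best[better] <- scores[, , k][better]
    }
  }
  new("FocusMap", scores = scores, selected = sel, window = window)
}

# Majority (modal) smoothing of an integer slice-index map over a square
# window of half-width radius; ties go to the smaller index.
majoritySmooth <- function(sel, nz, radius) {
  if (radius <= 0L || nz == 1L) return(sel)
  window <- 2L * as.integer(radius) + 1L
  counts <- lapply(seq_len(nz), function(k)
    boxMean((sel == k) * 1, window))
  best <- counts[[1]]
  out <- matrix(1L, nrow(sel), ncol(sel))
  for (k in seq_len(nz)[-1]) {
    better <- counts[[k]] > best
    out[better] <- k
    best[better] <- counts[[k]][better]
  }
  out
}

#' Fuse a Z-stack into a single all-in-focus image
#'
#' Collapses the stack by taking, at each pixel, the intensity of the slice
#' selected by the focus map. The selected-index map is first majority-
#' smoothed over a square window of half-width \code{smoothRadius} (0
#' disables), which suppresses salt-and-pepper slice switching inside
#' objects while preserving region-wise selection.
#'
#' @param stack an [ImageStack-class].
#' @param focus a [FocusMap-class] computed from the same stack (defaults to
#'   \code{focusMeasure(stack)}).
#' @param smoothRadius half-width in pixels of the majority filter applied to
#'   the selected-index map (default 5; 0 = off).
#' @return list with \code{image} (fused matrix, same units as the input) and
#'   \code{selected} (the smoothed slice-index matrix actually used).
#' @examples
#' stk <- ImageStack(array(runif(64 * 64 * 3), c(64, 64, 3)))
#' fused <- fuseStack(stk)$image
#' @export
fuseStack <- function(stack, focus = focusMeasure(stack), smoothRadius = 5L) {
  stopifnot(is(stack, "ImageStack"), is(focus, "FocusMap"))
  a <- intensities(stack)
  if (!identical(dim(focus@scores), dim(a)))
    stop("focus map and stack dimensions differ")
  nz <- dim(a)[3]
  sel <- majoritySmooth(focus@selected, nz, smoothRadius)
  idx <- cbind(as.vector(row(sel)), as.vector(col(sel)), as.vector(sel))
  out <- matrix(a[idx], nrow(sel), ncol(sel))
  list(image = out, selected = sel)
}
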