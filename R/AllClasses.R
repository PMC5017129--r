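#' Calibrated fluorescence Z-stack
#'
#' Container for a single-channel (or channel-tagged multi-channel) Z-series:
#' a 3-D nonnegative intensity array in (y, x, z) order plus the spatial
#' calibration needed to express measurements in micrometres.
#'
#' @slot intensities numeric array, \code{height x width x n_slices},
#'   nonnegative. For multi-channel data use one \code{ImageStack} per channel.
#' @slot pixelSize lateral calibration, micrometres per pixel (> 0).
#' @slot zStep axial spacing between consecutive slices, micrometres (> 0;
#'   irrelevant when there is a single slice).
#' @slot channel free-text channel tag (e.g. \code{"mito"}, \code{"nuc"}).
#'
#' @seealso [ImageStack()] for the user-facing constructor,
#'   [focusMeasure()] and [fuseStack()] which consume stacks.
#' @exportClass ImageStack
setClass("ImageStack",
  representation(intensities = "array", pixelSize = "numeric",
                 zStep = "numeric", channel = "character"),
  prototype(pixelSize = 0.1, zStep = 0.5, channel = "mito"))

setValidity("ImageStack", function(object) {
  d <- dim(object@intensities)
  if (length(d) != 3L)
    return("'intensities' must be a 3-D array (height x width x n_slices)")
  if (d[3] < 1L) return("stack needs at least one slice")
  if (anyNA(object@intensities) || any(!is.finite(object@intensities)))
    return("intensities must be finite")
  if (any(object@intensities < 0)) return("intensities must be nonnegative")
  if (length(object@pixelSize) != 1L || object@pixelSize <= 0)
    return("'pixelSize' must be a single positive number (um/px)")
  if (length(object@zStep) != 1L || object@zStep <= 0)
    return("'zStep' must be a single positive number (um)")
  TRUE
})

#' Construct an ImageStack
#'
#' @param intensities 3-D numeric array (height x width x n_slices), or a
#'   matrix which is treated as a single-slice stack.
#' @param pixelSize micrometres per pixel.
#' @param zStep micrometres between slices.
#' @param channel channel tag.
#' @return An [ImageStack-class] object.
#' @examples
#' stk <- ImageStack(array(runif(32 * 32 * 3), c(32, 32, 3)),
#'                   pixelSize = 0.1, zStep = 0.5)
#' nSlices(stk)
#' @export
ImageStack <- function(intensities, pixelSize = 0.1, zStep = 0.5,
                       channel = "mito") {
  if (is.matrix(intensities))
    intensities <- array(intensities, c(dim(intensities), 1L))
  new("ImageStack", intensities = intensities, pixelSize = pixelSize,
      zStep = zStep, channel = channel)
}

#' @describeIn ImageStack intensity array accessor
#' @param x,object an \code{ImageStack}
#' @export
setGeneric("intensities", function(x) standardGeneric("intensities"))

#' @rdname ImageStack
#' @export
setMethod("intensities", "ImageStack", function(x) x@intensities)

#' @rdname ImageStack
#' @export
setGeneric("pixelSize", function(x) standardGeneric("pixelSize"))

#' @rdname ImageStack
#' @export
setMethod("pixelSize", "ImageStack", function(x) x@pixelSize)

#' @rdname ImageStack
#' @export
setGeneric("zStep", function(x) standardGeneric("zStep"))

#' @rdname ImageStack
#' @export
setMethod("zStep", "ImageStack", function(x) x@zStep)

#' @rdname ImageStack
#' @export
setGeneric("nSlices", function(x) standardGeneric("nSlices"))

#' @rdname ImageStack
#' @export
setMethod("nSlices", "ImageStack", function(x) dim(x@intensities)[3])

#' @rdname ImageStack
#' @export
setMethod("show", "ImageStack", function(object) {
  d <- dim(object@intensities)
  cat(sprintf(
    "ImageStack '%s': %d x %d px, %d slice(s), %.3g um/px, z-step %.3g um\n",
    object@channel, d[1], d[2], d[3], object@pixelSize, object@zStep))
})

#' Per-pixel focus scores and slice selection for a Z-stack
#'
#' Produced by [focusMeasure()]. \code{scores} holds the per-slice sharpness
#' score at every pixel; \code{selected} the (1-based) index of the sharpest
#' slice at every pixel.
#'
#' @slot scores numeric array, height x width x n_slices.
#' @slot selected integer matrix, height x width; at each pixel the index of a
#'   slice attaining the per-pixel maximum score (ties resolved to the lowest
#'   index).
#' @slot window odd integer, side of the local-variance window used.
#' @exportClass FocusMap
setClass("FocusMap",
  representation(scores = "array", selected = "matrix", window = "integer"))

setValidity("FocusMap", function(object) {
  d <- dim(object@scores)
  if (length(d) != 3L) return("'scores' must be 3-D")
  if (!identical(dim(object@selected), d[1:2]))
    return("'selected' must match scores in height/width")
  if (any(object@selected < 1L) || any(object@selected > d[3]))
    return("'selected' indices out of slice range")
  TRUE
})

#' @rdname FocusMap-class
#' @param object a \code{FocusMap}
#' @export
setMethod("show", "FocusMap", function(object) {
  d <- dim(object@scores)
  cat(sprintf("FocusMap: %d x %d px over %d slice(s), window %d px\n",
              d[1], d[2], d[3], object@window))
})

#' Polygonal single-cell region of interest
#'
#' A closed polygon (pixel coordinates, y-down image convention) assigning
#' pixels to one cell, with the calibration needed to report the cell area in
#' square micrometres. Vertices are stored 0-based to match the on-disk JSON
#' convention; rasterization handles the shift to R's 1-based grid.
#'
#' @slot vertices numeric matrix with columns x, y (0-based pixel coords,
#'   in order, not repeating the first vertex).
#' @slot cellId identifier.
#' @slot pixelSize micrometres per pixel.
#' @exportClass CellROI
setClass("CellROI",
  representation(vertices = "matrix", cellId = "character",
                 pixelSize = "numeric"))

setValidity("CellROI", function(object) {
  v <- object@vertices
  if (ncol(v) != 2L || nrow(v) < 3L)
    return("'vertices' must be an n x 2 matrix with n >= 3")
  if (anyNA(v)) return("vertices must be finite")
  if (length(object@pixelSize) != 1L || object@pixelSize <= 0)
    return("'pixelSize' must be positive")
  TRUE
})

#' Construct a CellROI
#'
#' @param vertices n x 2 matrix of polygon vertices (x, y), 0-based pixel
#'   coordinates, y-down.
#' @param cellId cell identifier.
#' @param pixelSize micrometres per pixel.
#' @return A [CellROI-class] object.
#' @examples
#' roi <- CellROI(cbind(c(0, 40, 40, 0), c(0, 0, 40, 40)), "cell1", 0.1)
#' cellArea(roi) # 16 um^2
#' @export
CellROI <- function(vertices, cellId = "cell1", pixelSize = 0.1) {
  new("CellROI", vertices = as.matrix(vertices), cellId = as.character(cellId),
      pixelSize = pixelSize)
}

#' @describeIn CellROI polygon area in square micrometres (shoelace formula)
#' @param x,object a \code{CellROI}
#' @export
setGeneric("cellArea", function(x) standardGeneric("cellArea"))

#' @rdname CellROI
#' @export
setMethod("cellArea", "CellROI", function(x) {
  v <- x@vertices
  n <- nrow(v)
  j <- c(2:n, 1)
  abs(sum(v[, 1] * v[j, 2] - v[j, 1] * v[, 2])) / 2 * x@pixelSize^2
})

#' @rdname CellROI
#' @export
setMethod("show", "CellROI", function(object) {
  cat(sprintf("CellROI '%s': %d vertices, area %.1f um^2\n", object@cellId,
              nrow(object@vertices), cellArea(object)))
})

#' Labelled segmentation mask
#'
#' Result of segmenting one fused image (or one cell): an integer label image
#' where 0 is background and 1..nObjects index 8-connected mitochondrial
#' components, each at least the configured minimum area.
#'
#' @slot labels integer matrix (height x width), background 0, labels
#'   consecutive from 1.
#' @slot nObjects number of components.
#' @slot pixelSize micrometres per pixel.
#' @exportClass LabeledMask
setClass("LabeledMask",
  representation(labels = "matrix", nObjects = "integer",
                 pixelSize = "numeric"))

setValidity("LabeledMask", function(object) {
  l <- object@labels
  if (!is.integer(l)) return("'labels' must be an integer matrix")
  if (any(l < 0L)) return("labels must be nonnegative")
  n <- object@nObjects
  if (length(n) != 1L || n < 0L) return("'nObjects' must be a single count")
  if (n > 0L && !setequal(setdiff(unique(as.vector(l)), 0L), seq_len(n)))
    return("labels must be consecutive 1..nObjects")
  if (n == 0L && any(l > 0L)) return("nObjects = 0 but labels present")
  TRUE
})

#' @describeIn LabeledMask label-image accessor
#' @param x,object a \code{LabeledMask}
#' @export
setGeneric("labelMatrix", function(x) standardGeneric("labelMatrix"))

#' @rdname LabeledMask
#' @export
setMethod("labelMatrix", "LabeledMask", function(x) x@labels)

#' @rdname LabeledMask
#' @export
setGeneric("nObjects", function(x) standardGeneric("nObjects"))

#' @rdname LabeledMask
#' @export
setMethod("nObjects", "LabeledMask", function(x) x@nObjects)

#' @rdname LabeledMask
#' @export
setMethod("show", "LabeledMask", function(object) {
  cat(sprintf("LabeledMask: %d x %d px, %d object(s), %.3g um/px\n",
              nrow(object@labels), ncol(object@labels), object@nObjects,
              object@pixelSize))
})

#' Trained three-class mitochondrial shape classifier
#'
#' Wraps a random forest fitted on shape-descriptor vectors, together with the
#' metadata needed to reproduce and audit it: the descriptor names seen at
#' training time (enforced at prediction), the RNG seed, an MD5 hash of the
#' training table, and the out-of-bag confusion.
#'
#' @slot forest the fitted \code{randomForest} object.
#' @slot features character vector of descriptor names, order fixed.
#' @slot nTrees number of trees.
#' @slot seed RNG seed used for fitting.
#' @slot trainingHash MD5 hash of the serialized training table.
#' @slot oobError out-of-bag misclassification rate (fraction).
#' @slot oobConfusion 3 x 3 out-of-bag confusion matrix (rows = truth).
#' @exportClass MitoClassifier
setClass("MitoClassifier",
  representation(forest = "ANY", features = "character", nTrees = "integer",
                 seed = "integer", trainingHash = "character",
                 oobError = "numeric", oobConfusion = "matrix"))

#' @rdname MitoClassifier-class
#' @param object a \code{MitoClassifier}
#' @export
setMethod("show", "MitoClassifier", function(object) {
  cat(sprintf(paste0("MitoClassifier: %d trees on %d descriptors, ",
                     "OOB error %.2f%%\n  training hash %s\n"),
              object@nTrees, length(object@features), 100 * object@oobError,
              object@trainingHash))
})
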