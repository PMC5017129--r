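# Shape-descriptor extraction for segmented mitochondria. Ten standard
# region descriptors per object, all lengths calibrated to micrometres.

DESCRIPTOR_NAMES <- c("areaUm2", "perimeterUm", "majorAxisUm", "minorAxisUm",
                      "eccentricity", "solidity", "formFactor",
                      "skeletonLengthUm", "branchPoints", "aspectRatio")

# convex hull area over the pixel-centre point set (px^2); slightly under
# the true hull of the pixel squares, so the solidity ratio is clamped at 1
hullArea <- function(ij) {
  pts <- cbind(ij[, 2], ij[, 1])
  h <- grDevices::chull(pts)
  v <- pts[h, , drop = FALSE]
  n <- nrow(v)
  if (n < 3L) return(nrow(ij))
  j <- c(2:n, 1)
  abs(sum(v[, 1] * v[j, 2] - v[j, 1] * v[, 2])) / 2
}

#' Extract shape descriptors for every labelled object
#'
#' Computes, per component of a [LabeledMask-class], the descriptor vector
#' used for morphology classification: area and perimeter (um, via region
#' shape features), ellipse-equivalent major/minor axis and eccentricity
#' (from second-order central moments), solidity (area / convex hull area),
#' form factor (4 pi area / perimeter^2, clamped to (0, 1]), skeleton length
#' and branch-point count (see [skeletonStats()]), and aspect ratio.
#' Degenerate single-pixel objects get a one-pixel floor on perimeter and
#' axis lengths rather than failing.
#'
#' @param mask a [LabeledMask-class].
#' @param cellId optional cell identifier recorded on every row.
#' @return data.frame with one row per object: \code{objectId}, \code{cellId},
#'   centroid (\code{cx}, \code{cy}, pixel units, x = column), and the ten
#'   descriptors.
#' @examples
#' m <- matrix(FALSE, 32, 32); m[10:20, 10:20] <- TRUE
#' lm <- cleanupAndLabel(m, segmentationParams(openingRadius = 0,
#'   closingRadius = 0, minObjectArea = 0), pixelSize = 0.1)
#' extractDescriptors(lm)
#' @export
extractDescriptors <- function(mask, cellId = "cell1") {
  stopifnot(is(mask, "LabeledMask"))
  lab <- labelMatrix(mask)
  n <- nObjects(mask)
  px <- mask@pixelSize
  if (n == 0L) {
    out <- data.frame(objectId = integer(), cellId = character(),
                      cx = numeric(), cy = numeric())
    for (d in DESCRIPTOR_NAMES) out[[d]] <- numeric()
    return(out)
  }
  shp <- EBImage::computeFeatures.shape(lab)
  mom <- EBImage::computeFeatures.moment(lab, (lab > 0L) * 1)
  rows <- vector("list", n)
  for (k in seq_len(n)) {
    ij <- which(lab == k, arr.ind = TRUE)
    areaPx <- nrow(ij)
    perimPx <- max(shp[k, "s.perimeter"], 1)
    major <- max(mom[k, "m.majoraxis"], 1)
    ecc <- min(max(mom[k, "m.eccentricity"], 0), 1 - 1e-9)
    minor <- max(major * sqrt(1 - ecc^2), 1)
    sol <- min(areaPx / max(hullArea(ij), areaPx * 0 + 1e-9), 1)
    ff <- min(4 * pi * areaPx / perimPx^2, 1)
    sub <- lab[min(ij[, 1]):max(ij[, 1]), min(ij[, 2]):max(ij[, 2]),
               drop = FALSE] == k
    sks <- skeletonStats(sub, px)
    rows[[k]] <- data.frame(
      objectId = k, cellId = cellId,
      cx = mean(ij[, 2]), cy = mean(ij[, 1]),
      areaUm2 = areaPx * px^2, perimeterUm = perimPx * px,
      majorAxisUm = major * px, minorAxisUm = minor * px,
      eccentricity = ecc, solidity = sol, formFactor = ff,
      skeletonLengthUm = sks$lengthUm, branchPoints = sks$branchPoints,
      aspectRatio = major / minor)
  }
  do.call(rbind, rows)
}
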