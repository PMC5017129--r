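# Synthetic fluorescence Z-stack simulator. Generates cells containing
# mixtures of punctate (small ovoid), intermediate (short rod) and
# filamentous (long, possibly branched) mitochondria, images them through a
# Gaussian PSF whose width grows linearly with defocus, and applies the
# standard fluorescence camera noise model (Poisson shot noise + additive
# Gaussian read noise). Every object carries a generative ground-truth label,
# so the whole analysis pipeline can be validated end to end.

#' Morphology archetype
#'
#' Geometric recipe for one mitochondrial morphology class. The three
#' default archetypes are separable by construction (punctate lengths below
#' intermediate lengths below filamentous lengths).
#'
#' @param classLabel one of \code{"punctate"}, \code{"intermediate"},
#'   \code{"filamentous"}.
#' @param lengthRange two positive numbers, end-to-end length range in um.
#' @param widthRange two positive numbers, tube width range in um.
#' @param branchCountRange integer range of branch counts (must be
#'   \code{c(0, 0)} for punctate).
#' @param curvature dimensionless bend amplitude (0 = straight); the lateral
#'   bow is up to \code{0.3 * curvature} of the object length.
#' @return validated archetype list.
#' @examples
#' morphArchetype("intermediate", c(1, 3), c(0.3, 0.5))
#' @export
morphArchetype <- function(classLabel, lengthRange, widthRange,
                           branchCountRange = c(0L, 0L), curvature = 0.3) {
  classLabel <- match.arg(classLabel, MITO_CLASSES)
  if (any(lengthRange <= 0) || any(widthRange <= 0))
    stop("length and width ranges must be strictly positive")
  if (diff(lengthRange) < 0 || diff(widthRange) < 0 ||
      diff(branchCountRange) < 0)
    stop("ranges must be increasing")
  if (classLabel == "punctate" && any(branchCountRange != 0L))
    stop("punctate objects cannot branch")
  if (curvature < 0) stop("'curvature' must be >= 0")
  structure(list(classLabel = classLabel, lengthRange = lengthRange,
                 widthRange = widthRange,
                 branchCountRange = as.integer(branchCountRange),
                 curvature = curvature),
            class = "MorphArchetype")
}

#' Archetype presets
#'
#' \code{"default"} mirrors the field's verbal descriptions: punctate
#' 0.3-0.8 um ovoids (aspect < 2), intermediate 1-3 um rods, filamentous
#' 4-12 um curves with 0-3 branches. \code{"separated"} is a widened-margin
#' variant (0.4-0.6 / 1.8-2.8 / 6-10 um) used for the in-silico
#' validation where each class should be unambiguous even to a threshold
#' rule.
#'
#' @param type \code{"default"} or \code{"separated"}.
#' @return named list of three [morphArchetype()] objects.
#' @examples
#' archetypePresets()$filamentous
#' @export
archetypePresets <- function(type = c("default", "separated")) {
  type <- match.arg(type)
  if (type == "default")
    list(punctate = morphArchetype("punctate", c(0.3, 0.8), c(0.25, 0.8),
                                   c(0L, 0L), curvature = 0),
         intermediate = morphArchetype("intermediate", c(1, 3), c(0.3, 0.5),
                                       c(0L, 0L), curvature = 0.3),
         filamentous = morphArchetype("filamentous", c(4, 12), c(0.3, 0.5),
                                      c(0L, 3L), curvature = 0.5))
  else
    list(punctate = morphArchetype("punctate", c(0.4, 0.6), c(0.4, 0.6),
                                   c(0L, 0L), curvature = 0),
         intermediate = morphArchetype("intermediate", c(1.8, 2.8),
                                       c(0.35, 0.5), c(0L, 0L),
                                       curvature = 0.2),
         filamentous = morphArchetype("filamentous", c(6, 10), c(0.35, 0.5),
                                      c(0L, 2L), curvature = 0.4))
}

# Sample points along the object's centreline(s); spacing <= pixelSize / 2.
# Returns an n x 2 matrix of (x, y) um coordinates.
sampleCenterline <- function(L, curvature, theta, pixelSize, branches,
                             branchLen) {
  nseg <- max(2L, ceiling(L / (pixelSize / 2)))
  t <- seq(0, 1, length.out = nseg)
  a <- curvature * 0.3 * L
  dir <- c(cos(theta), sin(theta))
  prp <- c(-sin(theta), cos(theta))
  main <- cbind(t * L * dir[1] + a * sin(pi * t) * prp[1],
                t * L * dir[2] + a * sin(pi * t) * prp[2])
  pts <- main
  if (length(branches)) {
    for (b in seq_along(branches)) {
      tb <- branches[b]
      i0 <- max(2L, min(nseg - 1L, round(tb * nseg)))
      tang <- main[i0 + 1L, ] - main[i0 - 1L, ]
      phi <- atan2(tang[2], tang[1]) + branchLen[[b]]$angle
      lb <- branchLen[[b]]$len
      nb <- max(2L, ceiling(lb / (pixelSize / 2)))
      s <- seq(0, lb, length.out = nb)
      pts <- rbind(pts, cbind(main[i0, 1] + s * cos(phi),
                              main[i0, 2] + s * sin(phi)))
    }
  }
  pts
}

rasterizeTube <- function(pts, width, pixelSize) {
  r <- width / 2
  x0 <- min(pts[, 1]) - r - pixelSize
  y0 <- min(pts[, 2]) - r - pixelSize
  nc <- ceiling((max(pts[, 1]) + r + pixelSize - x0) / pixelSize) + 1L
  nr <- ceiling((max(pts[, 2]) + r + pixelSize - y0) / pixelSize) + 1L
  mask <- matrix(FALSE, nr, nc)
  R <- ceiling(r / pixelSize) + 1L
  off <- expand.grid(di = -R:R, dj = -R:R)
  np <- nrow(pts)
  ic <- floor((pts[, 2] - y0) / pixelSize - 0.5) + 1L
  jc <- floor((pts[, 1] - x0) / pixelSize - 0.5) + 1L
  ii <- rep(ic, each = nrow(off)) + rep(off$di, np)
  jj <- rep(jc, each = nrow(off)) + rep(off$dj, np)
  cxs <- (jj - 0.5) * pixelSize + x0
  cys <- (ii - 0.5) * pixelSize + y0
  d2 <- (cxs - rep(pts[, 1], each = nrow(off)))^2 +
    (cys - rep(pts[, 2], each = nrow(off)))^2
  ok <- d2 <= r^2 & ii >= 1L & ii <= nr & jj >= 1L & jj <= nc
  mask[cbind(ii[ok], jj[ok])] <- TRUE
  # crop tight
  rows <- range(which(rowSums(mask) > 0))
  cols <- range(which(colSums(mask) > 0))
  mask[rows[1]:rows[2], cols[1]:cols[2], drop = FALSE]
}

#' Generate one ground-truth mitochondrial object
#'
#' Draws geometry from the archetype and rasterizes it at \code{pixelSize}:
#' punctate objects are capsules (ovoids) of aspect below 2, intermediate
#' objects are unbranched, gently curved rods, filamentous objects are long
#' curves with up to the archetype's number of side branches, all dilated to
#' the drawn tube width. The mask is guaranteed to be one 8-connected
#' component; degenerate rasterizations are retried with jittered draws
#' (at most 10 times) before an error is raised.
#'
#' @param archetype a [morphArchetype()].
#' @param seed integer RNG seed; the same archetype and seed always give the
#'   identical mask.
#' @param pixelSize micrometres per pixel (default 0.1).
#' @return list: \code{mask} (logical matrix, tight crop), \code{classLabel},
#'   \code{lengthUm}, \code{widthUm}, \code{nBranches}, \code{areaUm2}.
#' @examples
#' obj <- generateObject(archetypePresets()$punctate, seed = 7)
#' obj$areaUm2
#' @export
generateObject <- function(archetype, seed, pixelSize = 0.1) {
  stopifnot(inherits(archetype, "MorphArchetype"))
  set.seed(as.integer(seed) %% .Machine$integer.max)
  for (attempt in 1:10) {
    L <- runif(1, archetype$lengthRange[1], archetype$lengthRange[2])
    W <- runif(1, archetype$widthRange[1], archetype$widthRange[2])
    if (archetype$classLabel == "punctate") {
      # ovoid: aspect ratio below 2
      W <- min(max(W, L / 2), L)
    } else {
      W <- min(W, L / 2)
    }
    nB <- if (diff(archetype$branchCountRange) == 0L)
      archetype$branchCountRange[1]
    else sample(archetype$branchCountRange[1]:archetype$branchCountRange[2], 1)
    theta <- runif(1, 0, pi)
    branches <- if (nB > 0L) runif(nB, 0.25, 0.75) else numeric()
    branchPar <- lapply(seq_len(nB), function(i)
      list(angle = sample(c(-1, 1), 1) * runif(1, pi / 5, pi / 2.2),
           len = runif(1, 0.2, 0.4) * L))
    core <- max(L - W, 0)
    pts <- if (core == 0) matrix(0, 1, 2)
    else sampleCenterline(core, archetype$curvature, theta, pixelSize,
                          branches, branchPar)
    mask <- rasterizeTube(pts, W, pixelSize)
    if (sum(mask) > 0L && max(.label8(mask)) == 1L)
      return(list(mask = mask, classLabel = archetype$classLabel,
                  lengthUm = L, widthUm = W, nBranches = as.integer(nB),
                  areaUm2 = sum(mask) * pixelSize^2))
  }
  stop("could not rasterize a valid object; archetype incompatible with ",
       "pixel size ", pixelSize)
}

#' Simulated-cell specification
#'
#' All parameters of one simulated cell: the morphology mixture, object
#' count, cell polygon, optics (Gaussian PSF with linear defocus growth) and
#' camera-noise model, and the RNG seed that makes the cell reproducible.
#' Defaults mirror typical high-NA fluorescence imaging of fixed cells:
#' 0.1 um pixels, 0.5 um Z-steps, 0.15 um in-focus PSF sigma.
#'
#' @param classMixture probability triple (punctate, intermediate,
#'   filamentous); must be nonnegative and sum to 1.
#' @param objectCount mitochondria per cell (default 30).
#' @param cellPolygon a [CellROI-class] or \code{NULL} for a default
#'   circular cell of radius 19 um centred in the frame (large enough to
#'   hold 30 non-overlapping objects even for filament-rich mixtures).
#' @param pixelSize um/px. @param zStep um between slices.
#' @param psfSigma in-focus lateral Gaussian blur sigma, um.
#' @param defocusGain extra blur sigma per um of defocus (um/um).
#' @param photonScale expected photons at unit object intensity;
#'   \code{Inf} disables shot noise.
#' @param readNoiseSd camera read noise SD in counts.
#' @param seed integer seed.
#' @param archetypes named list of the three archetypes
#'   (default [archetypePresets()]).
#' @return validated spec list.
#' @examples
#' sp <- simCellSpec(c(0.5, 0.3, 0.2), seed = 3)
#' @export
simCellSpec <- function(classMixture, objectCount = 30L, cellPolygon = NULL,
                        pixelSize = 0.1, zStep = 0.5, psfSigma = 0.15,
                        defocusGain = 0.4, photonScale = 200,
                        readNoiseSd = 2, seed = 1L,
                        archetypes = archetypePresets()) {
  if (length(classMixture) != 3L || any(classMixture < 0) ||
      abs(sum(classMixture) - 1) > 1e-8)
    stop("'classMixture' must be 3 nonnegative probabilities summing to 1")
  if (objectCount < 1L) stop("'objectCount' must be >= 1")
  if (any(c(pixelSize, zStep) <= 0))
    stop("'pixelSize' and 'zStep' must be positive")
  if (any(c(psfSigma, defocusGain, readNoiseSd) < 0) || photonScale < 0)
    stop("optics/noise parameters must be >= 0")
  structure(list(classMixture = setNames(as.numeric(classMixture),
                                         MITO_CLASSES),
                 objectCount = as.integer(objectCount),
                 cellPolygon = cellPolygon, pixelSize = pixelSize,
                 zStep = zStep, psfSigma = psfSigma,
                 defocusGain = defocusGain, photonScale = photonScale,
                 readNoiseSd = readNoiseSd, seed = as.integer(seed),
                 archetypes = archetypes),
            class = "SimCellSpec")
}

#' In-silico validation condition
#'
#' The rendering condition used to check that unambiguous artificial
#' mitochondria are classified correctly: well-separated archetypes (see
#' [archetypePresets()]), no photon or read noise, a minimal in-focus PSF
#' and no defocus growth. This emulates feeding ideal artificial shapes to
#' the classifier, as opposed to the default spec which emulates a real
#' acquisition.
#'
#' @param seed integer seed.
#' @return a [simCellSpec()].
#' @examples
#' sp <- insilicoSpec(seed = 5)
#' @export
insilicoSpec <- function(seed = 1L) {
  simCellSpec(c(1, 1, 1) / 3, photonScale = Inf, readNoiseSd = 0,
              psfSigma = 0.08, defocusGain = 0, seed = seed,
              archetypes = archetypePresets("separated"))
}

defaultCellPolygon <- function(frameDim, pixelSize, radiusUm = 19,
                               nVertices = 24L) {
  cx <- (frameDim[2] / 2) * pixelSize
  cy <- (frameDim[1] / 2) * pixelSize
  ang <- seq(0, 2 * pi, length.out = nVertices + 1L)[-(nVertices + 1L)]
  CellROI(cbind(cx + radiusUm * cos(ang), cy + radiusUm * sin(ang)) /
            pixelSize, "simcell", pixelSize)
}

pointInPolygon <- function(px, py, vertices) {
  vx <- vertices[, 1]; vy <- vertices[, 2]
  n <- length(vx); inside <- rep(FALSE, length(px)); j <- n
  for (i in seq_len(n)) {
    crosses <- ((vy[i] > py) != (vy[j] > py)) &
      (px < (vx[j] - vx[i]) * (py - vy[i]) / (vy[j] - vy[i]) + vx[i])
    inside <- xor(inside, crosses)
    j <- i
  }
  inside
}

# add a blurred object crop into a frame at integer top-left position,
# clipping at the frame edges
addCrop <- function(frame, crop, top, left) {
  nr <- nrow(frame); nc <- ncol(frame)
  i1 <- max(1L, top); i2 <- min(nr, top + nrow(crop) - 1L)
  j1 <- max(1L, left); j2 <- min(nc, left + ncol(crop) - 1L)
  if (i1 > i2 || j1 > j2) return(frame)
  frame[i1:i2, j1:j2] <- frame[i1:i2, j1:j2] +
    crop[(i1 - top + 1L):(i2 - top + 1L), (j1 - left + 1L):(j2 - left + 1L)]
  frame
}

#' Render simulated cells into a noisy Z-stack with ground truth
#'
#' Draws each cell's object labels from its class mixture, generates and
#' places the objects inside the cell polygon at random focal depths
#' spanning the stack, and renders every slice as the sum of the objects
#' blurred with \code{sigma = psfSigma + defocusGain * |z_slice - z_object|},
#' scaled by \code{photonScale}, Poisson-sampled and corrupted with Gaussian
#' read noise. Fully deterministic given the specs' seeds.
#'
#' Objects are placed entirely inside the cell polygon with a hard-core
#' separation (\code{minSepUm} between true mask boundaries, default
#' 1.2 um, about the optical footprint of the blur so that distinct objects
#' stay resolvable): in a fixed cell, distinct mitochondria occupy disjoint 2-D
#' footprints, and the segmentation stage deliberately does not split
#' touching objects. If a non-overlapping position cannot be found the
#' least-overlapping candidate is used and counted in the returned
#' \code{placementFailures}.
#'
#' @param cells list of [simCellSpec()] objects (all with the same pixel
#'   size and Z-step).
#' @param nSlices number of Z slices (>= 1).
#' @param frameDim frame height and width in pixels (default 416 x 416,
#'   i.e. 41.6 um at the default sampling, sized to the default cell).
#' @param nuclear if \code{TRUE}, also render a nuclear channel with one
#'   Gaussian blob per cell.
#' @param minSepUm minimum separation between true object footprints, um.
#' @return list: \code{stack} ([ImageStack-class]), \code{truth}
#'   (data.frame: objectId, cellId, classLabel, cx, cy, zUm, areaUm2, amp),
#'   \code{masks} (per-object list: logical crop + top/left offset),
#'   \code{rois} (list of [CellROI-class]), and \code{nuclear}
#'   (ImageStack or NULL).
#' @examples
#' out <- renderStack(list(simCellSpec(c(1, 1, 1) / 3, objectCount = 5,
#'   seed = 2)), nSlices = 3)
#' nrow(out$truth)
#' @export
renderStack <- function(cells, nSlices, frameDim = c(416L, 416L),
                        nuclear = FALSE, minSepUm = 1.2) {
  if (!is.list(cells) || length(cells) == 0L)
    stop("'cells' must be a nonempty list of simCellSpec objects")
  if (nSlices < 1L) stop("'nSlices' must be >= 1")
  px <- cells[[1]]$pixelSize; zs <- cells[[1]]$zStep
  signal <- array(0, c(frameDim[1], frameDim[2], nSlices))
  nuc <- if (nuclear) array(0, c(frameDim[1], frameDim[2], nSlices)) else NULL
  zSlices <- (seq_len(nSlices) - 1L) * zs
  truth <- list(); masks <- list(); rois <- list()
  oid <- 0L; placementFailures <- 0L
  for (ci in seq_along(cells)) {
    spec <- cells[[ci]]
    roi <- spec$cellPolygon
    if (is.null(roi)) roi <- defaultCellPolygon(frameDim, px)
    rois[[ci]] <- roi
    set.seed(spec$seed)
    labels <- sample(MITO_CLASSES, spec$objectCount, replace = TRUE,
                     prob = spec$classMixture)
    objSeeds <- sample.int(.Machine$integer.max - 1L, spec$objectCount)
    v <- roi@vertices
    inPoly <- rasterizePolygon(v, frameDim[1], frameDim[2])
    occupied <- matrix(FALSE, frameDim[1], frameDim[2])
    sepPx <- ceiling(minSepUm / px)
    objs <- lapply(seq_len(spec$objectCount), function(k)
      generateObject(spec$archetypes[[labels[k]]], objSeeds[k], px))
    # place big objects first: long filaments are hardest to fit
    placeOrder <- order(vapply(objs, function(o) sum(o$mask), 0),
                        decreasing = TRUE)
    for (k in placeOrder) {
      obj <- objs[[k]]
      # object footprint dilated by the separation, on a padded crop so the
      # halo is not clipped at the crop edge
      hp <- sepPx
      haloPad <- matrix(0, nrow(obj$mask) + 2L * hp, ncol(obj$mask) + 2L * hp)
      haloPad[hp + seq_len(nrow(obj$mask)), hp + seq_len(ncol(obj$mask))] <-
        obj$mask
      halo <- discDilate(haloPad, sepPx) > 0.5
      best <- NULL; bestOverlap <- Inf
      for (try in seq_len(200L)) {
        ox <- runif(1, min(v[, 1]), max(v[, 1]))
        oy <- runif(1, min(v[, 2]), max(v[, 2]))
        t0 <- round(oy - nrow(obj$mask) / 2) + 1L
        l0 <- round(ox - ncol(obj$mask) / 2) + 1L
        i2 <- t0 + nrow(obj$mask) - 1L; j2 <- l0 + ncol(obj$mask) - 1L
        if (t0 < 1L || l0 < 1L || i2 > frameDim[1] || j2 > frameDim[2])
          next
        if (!all(inPoly[t0:i2, l0:j2][obj$mask])) next
        # halo window clipped to the frame
        hi1 <- max(1L, t0 - hp); hi2 <- min(frameDim[1], i2 + hp)
        hj1 <- max(1L, l0 - hp); hj2 <- min(frameDim[2], j2 + hp)
        ov <- sum(occupied[hi1:hi2, hj1:hj2] &
                    halo[(hi1 - t0 + hp + 1L):(hi2 - t0 + hp + 1L),
                         (hj1 - l0 + hp + 1L):(hj2 - l0 + hp + 1L)])
        if (ov == 0L) { best <- c(t0, l0); bestOverlap <- 0L; break }
        if (ov < bestOverlap) { best <- c(t0, l0); bestOverlap <- ov }
      }
      if (is.null(best))
        stop("cell polygon too small for object ", k, " of cell ", ci)
      if (bestOverlap > 0L)
        placementFailures <- placementFailures + 1L
      top <- best[1]; left <- best[2]
      i2 <- top + nrow(obj$mask) - 1L; j2 <- left + ncol(obj$mask) - 1L
      occupied[top:i2, left:j2] <- occupied[top:i2, left:j2] | obj$mask
      zObj <- runif(1, 0, max(zSlices))
      amp <- runif(1, 0.7, 1.3)
      sigmaMax <- (spec$psfSigma + spec$defocusGain *
                     max(abs(zSlices - zObj))) / px
      pad <- ceiling(4 * sigmaMax) + 2L
      crop0 <- matrix(0, nrow(obj$mask) + 2L * pad,
                      ncol(obj$mask) + 2L * pad)
      crop0[pad + seq_len(nrow(obj$mask)), pad + seq_len(ncol(obj$mask))] <-
        obj$mask * amp
      for (s in seq_len(nSlices)) {
        sigmaPx <- (spec$psfSigma + spec$defocusGain *
                      abs(zSlices[s] - zObj)) / px
        signal[, , s] <- addCrop(signal[, , s],
                                 gaussianBlur(crop0, sigmaPx),
                                 top - pad, left - pad)
      }
      oid <- oid + 1L
      # centroid of the placed mask, frame pixel coordinates (x = column)
      ij <- which(obj$mask, arr.ind = TRUE)
      truth[[oid]] <- data.frame(
        objectId = oid, cellId = roi@cellId, classLabel = labels[k],
        cx = mean(ij[, 2]) + left - 1L, cy = mean(ij[, 1]) + top - 1L,
        zUm = zObj, areaUm2 = obj$areaUm2, amp = amp)
      masks[[oid]] <- list(mask = obj$mask, top = top, left = left)
    }
    if (nuclear) {
      nsig <- matrix(0, frameDim[1], frameDim[2])
      ncx <- mean(v[, 1]); ncy <- mean(v[, 2])
      yy <- outer(seq_len(frameDim[1]) - ncy, rep(1, frameDim[2]))
      xx <- outer(rep(1, frameDim[1]), seq_len(frameDim[2]) - ncx)
      nsig <- exp(-(xx^2 + yy^2) / (2 * (4 / px)^2))
      for (s in seq_len(nSlices)) nuc[, , s] <- nuc[, , s] + nsig
    }
  }
  # camera model, seeded independently of the geometry draws
  set.seed((cells[[1]]$seed + 987654L) %% .Machine$integer.max)
  spec1 <- cells[[1]]
  n <- length(signal)
  if (is.finite(spec1$photonScale)) {
    # gblur's FFT implementation can leave tiny negative ripples
    img <- rpois(n, spec1$photonScale * pmax(as.vector(signal), 0))
  } else {
    img <- as.vector(signal)
  }
  if (spec1$readNoiseSd > 0)
    img <- img + rnorm(n, 0, spec1$readNoiseSd)
  out <- array(pmax(img, 0), dim(signal))
  res <- list(stack = ImageStack(out, px, zs, "mito"),
              truth = do.call(rbind, truth), masks = masks, rois = rois,
              placementFailures = placementFailures, nuclear = NULL)
  if (nuclear)
    res$nuclear <- ImageStack(nuc, px, zs, "nuc")
  res
}

#' Simulate a cell population and analyze it end to end
#'
#' Renders \code{nCells} independent simulated cells at the given morphology
#' mixture (one frame per cell), runs the full pipeline (fusion,
#' segmentation, descriptor extraction, classification) on each, and
#' returns the per-cell phenotypes plus the population summary, together
#' with the generative ground truth for validation.
#'
#' @param mixture probability triple (punctate, intermediate, filamentous).
#' @param nCells number of cells.
#' @param model a [MitoClassifier-class], or \code{NULL} for the threshold
#'   rule.
#' @param seed master seed.
#' @param objectsPerCell objects per cell (default 30).
#' @param nSlices slices per stack (default 5).
#' @param params [segmentationParams()].
#' @param frameDim frame size in pixels.
#' @param sampleId label for the population summary.
#' @return list: \code{summary} (\code{PopulationSummary}), \code{cells}
#'   (per-cell rows), \code{objects} (classified objects), \code{truth}
#'   (stacked ground-truth tables), \code{trueFractions} (empirical label
#'   fractions actually drawn), \code{placementFailures}.
#' @examples \dontrun{
#' pop <- simulateAndAnalyze(c(.6, .2, .2), nCells = 5, seed = 3)
#' pop$summary
#' }
#' @export
simulateAndAnalyze <- function(mixture, nCells, model = NULL, seed = 1L,
                               objectsPerCell = 30L, nSlices = 5L,
                               params = segmentationParams(),
                               frameDim = c(416L, 416L),
                               sampleId = "simulated") {
  set.seed(as.integer(seed))
  cellSeeds <- sample.int(.Machine$integer.max - 1L, nCells)
  cellRows <- vector("list", nCells)
  objRows <- vector("list", nCells)
  truthRows <- vector("list", nCells)
  pf <- 0L
  for (i in seq_len(nCells)) {
    spec <- simCellSpec(mixture, objectCount = objectsPerCell,
                        seed = cellSeeds[i])
    sim <- renderStack(list(spec), nSlices = nSlices, frameDim = frameDim)
    pf <- pf + sim$placementFailures
    seg <- suppressWarnings(segmentCell(sim$stack, sim$rois[[1]], params))
    objs <- extractDescriptors(seg, cellId = sprintf("cell%04d", i))
    objs <- if (is.null(model)) classifyRuleBased(objs)
    else classifyObjects(model, objs)
    cellRows[[i]] <- summarizeCell(objs, sim$rois[[1]])
    cellRows[[i]]$cellId <- sprintf("cell%04d", i)
    objRows[[i]] <- objs
    tr <- sim$truth; tr$cellId <- sprintf("cell%04d", i)
    truthRows[[i]] <- tr
  }
  cells <- do.call(rbind, cellRows)
  truth <- do.call(rbind, truthRows)
  list(summary = populationSummary(cells, sampleId = sampleId),
       cells = cells, objects = do.call(rbind, objRows), truth = truth,
       trueFractions = prop.table(table(factor(truth$classLabel,
                                               levels = MITO_CLASSES))),
       placementFailures = pf)
}

#' Build a labelled benchmark of simulated mitochondria
#'
#' Renders \code{nObjects} isolated objects (classes drawn from
#' \code{mixture}) through the full imaging model, runs each through the
#' complete analysis pipeline (fusion, background subtraction, band-pass,
#' adaptive threshold, cleanup), and returns one row per object: the
#' measured descriptor vector plus the generative ground-truth label. This
#' is the training / evaluation set for the morphology classifier. Objects
#' lost in segmentation are kept as rows with missing descriptors and
#' \code{missed = TRUE}, so recall can be audited.
#'
#' @param nObjects number of objects (>= 3 x \code{minPerClass} to be usable
#'   for training).
#' @param mixture probability triple.
#' @param seed master seed.
#' @param spec a [simCellSpec()] providing optics/noise/pixel calibration
#'   (its mixture/count/polygon fields are ignored here).
#' @param nSlices slices per mini-stack (default 5).
#' @param params [segmentationParams()] used for the per-object pipeline.
#' @return data.frame: ten descriptors, \code{label} (truth),
#'   \code{trueAreaUm2}, \code{missed}.
#' @examples \dontrun{
#' bench <- makeBenchmark(120, c(1, 1, 1) / 3, seed = 1)
#' table(bench$label)
#' }
#' @export
makeBenchmark <- function(nObjects, mixture = c(1, 1, 1) / 3, seed = 1L,
                          spec = simCellSpec(c(1, 1, 1) / 3, seed = seed),
                          nSlices = 5L, params = segmentationParams()) {
  if (length(mixture) != 3L || any(mixture < 0) ||
      abs(sum(mixture) - 1) > 1e-8)
    stop("'mixture' must be 3 nonnegative probabilities summing to 1")
  px <- spec$pixelSize
  set.seed(as.integer(seed))
  labels <- sample(MITO_CLASSES, nObjects, replace = TRUE, prob = mixture)
  objSeeds <- sample.int(.Machine$integer.max - 1L, nObjects)
  zSpan <- (nSlices - 1L) * spec$zStep
  rows <- vector("list", nObjects)
  for (k in seq_len(nObjects)) {
    obj <- generateObject(spec$archetypes[[labels[k]]], objSeeds[k], px)
    set.seed(objSeeds[k])
    zObj <- runif(1, 0.25, 0.75) * zSpan
    margin <- 30L
    nr <- max(64L, nrow(obj$mask) + 2L * margin)
    nc <- max(64L, ncol(obj$mask) + 2L * margin)
    top <- (nr - nrow(obj$mask)) %/% 2L
    left <- (nc - ncol(obj$mask)) %/% 2L
    signal <- array(0, c(nr, nc, nSlices))
    sigmaMax <- (spec$psfSigma + spec$defocusGain * zSpan) / px
    pad <- ceiling(4 * sigmaMax) + 2L
    crop0 <- matrix(0, nrow(obj$mask) + 2L * pad, ncol(obj$mask) + 2L * pad)
    crop0[pad + seq_len(nrow(obj$mask)), pad + seq_len(ncol(obj$mask))] <-
      obj$mask * 1
    for (s in seq_len(nSlices)) {
      sigmaPx <- (spec$psfSigma + spec$defocusGain *
                    abs((s - 1L) * spec$zStep - zObj)) / px
      signal[, , s] <- addCrop(signal[, , s], gaussianBlur(crop0, sigmaPx),
                               top - pad + 1L, left - pad + 1L)
    }
    if (is.finite(spec$photonScale)) {
      img <- rpois(length(signal),
                   spec$photonScale * pmax(as.vector(signal), 0))
    } else img <- as.vector(signal)
    if (spec$readNoiseSd > 0)
      img <- img + rnorm(length(signal), 0, spec$readNoiseSd)
    stk <- ImageStack(array(pmax(img, 0), dim(signal)), px, spec$zStep)
    seg <- suppressWarnings(segmentCell(stk, roi = NULL, params = params))
    hit <- NA_integer_
    if (nObjects(seg) > 0L) {
      # component with the largest overlap with the true mask
      lab <- labelMatrix(seg)
      tm <- matrix(FALSE, nr, nc)
      tm[top + seq_len(nrow(obj$mask)), left + seq_len(ncol(obj$mask))] <-
        obj$mask
      ov <- tabulate(lab[tm], nbins = nObjects(seg))
      if (any(ov > 0L)) hit <- which.max(ov)
    }
    if (is.na(hit)) {
      row <- as.data.frame(as.list(setNames(rep(NA_real_,
        length(DESCRIPTOR_NAMES)), DESCRIPTOR_NAMES)))
      row$missed <- TRUE
    } else {
      desc <- extractDescriptors(seg)
      row <- desc[desc$objectId == hit, DESCRIPTOR_NAMES, drop = FALSE]
      row$missed <- FALSE
    }
    row$label <- labels[k]
    row$trueAreaUm2 <- obj$areaUm2
    rows[[k]] <- row
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
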