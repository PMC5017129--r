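# File formats: multi-page TIFF stacks with a JSON calibration sidecar,
# ROI polygons as JSON, object tables as CSV, run configuration as YAML.

#' Write / read an ImageStack as multi-page TIFF
#'
#' Slices are stored as 32-bit float TIFF pages; the calibration (pixel
#' size, Z-step, channel) goes to a JSON sidecar \code{<path>.meta.json} so
#' a round trip preserves the full object.
#'
#' @param stack an [ImageStack-class].
#' @param path TIFF file path.
#' @return \code{writeStack}: the path, invisibly. \code{readStack}: an
#'   [ImageStack-class].
#' @export
writeStack <- function(stack, path) {
  stopifnot(is(stack, "ImageStack"))
  a <- intensities(stack)
  mx <- max(a)
  pages <- lapply(seq_len(dim(a)[3]), function(k)
    a[, , k] / max(mx, 1e-12))
  tiff::writeTIFF(pages, path, bits.per.sample = 32L)
  jsonlite::write_json(list(pixelSize = pixelSize(stack), zStep = zStep(stack),
                            channel = stack@channel, scale = mx),
                       paste0(path, ".meta.json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' @rdname writeStack
#' @param pixelSize,zStep,channel calibration used when no sidecar exists.
#' @export
readStack <- function(path, pixelSize = 0.1, zStep = 0.5, channel = "mito") {
  pages <- tiff::readTIFF(path, all = TRUE)
  scale <- 1
  meta <- paste0(path, ".meta.json")
  if (file.exists(meta)) {
    m <- jsonlite::read_json(meta, simplifyVector = TRUE)
    pixelSize <- m$pixelSize; zStep <- m$zStep; channel <- m$channel
    scale <- m$scale
  }
  a <- array(0, c(dim(pages[[1]])[1:2], length(pages)))
  for (k in seq_along(pages)) {
    p <- pages[[k]]
    if (length(dim(p)) == 3L) p <- p[, , 1]
    a[, , k] <- p * scale
  }
  ImageStack(a, pixelSize, zStep, channel)
}

#' Write / read cell ROI polygons as JSON
#'
#' The on-disk convention: a list of polygons, each with a cell id and an
#' n x 2 vertex array in 0-based pixel coordinates, y-down, vertices in
#' order without repeating the first.
#'
#' @param rois list of [CellROI-class] objects.
#' @param path JSON file path.
#' @export
writeROI <- function(rois, path) {
  if (is(rois, "CellROI")) rois <- list(rois)
  jsonlite::write_json(
    list(pixelSize = rois[[1]]@pixelSize,
         polygons = lapply(rois, function(r)
           list(id = r@cellId, vertices = unname(r@vertices)))),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname writeROI
#' @export
readROI <- function(path) {
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  lapply(seq_len(nrow_or_len(j$polygons)), function(i) {
    p <- if (is.data.frame(j$polygons)) j$polygons[i, ] else j$polygons[[i]]
    v <- p$vertices
    if (is.list(v)) v <- do.call(rbind, v)
    if (is.list(p$vertices) && length(p$vertices) == 1L) v <- p$vertices[[1]]
    CellROI(matrix(unlist(v), ncol = 2), as.character(p$id), j$pixelSize)
  })
}

nrow_or_len <- function(x) if (is.data.frame(x)) nrow(x) else length(x)

#' Read an analysis run configuration (YAML)
#'
#' Schema (all keys optional; defaults shown by [segmentationParams()] and
#' [simCellSpec()]): \code{pixel_size}, \code{z_step}, \code{seed},
#' \code{segmentation:} \{\code{ball_radius}, \code{bandpass_low},
#' \code{bandpass_high}, \code{window}, \code{offset}, \code{opening_radius},
#' \code{closing_radius}, \code{min_object_area}\}, \code{fusion:}
#' \{\code{window}, \code{smooth_radius}\}, \code{classifier} (path to a
#' model RDS or \code{"rulebased"}).
#'
#' @param path YAML file.
#' @return list: \code{pixelSize}, \code{zStep}, \code{seed}, \code{params}
#'   ([segmentationParams()]), \code{fusionWindow}, \code{smoothRadius},
#'   \code{classifier}.
#' @export
readRunConfig <- function(path) {
  y <- if (is.null(path)) list() else yaml::read_yaml(path)
  s <- y$segmentation
  params <- segmentationParams(
    ballRadius = s$ball_radius %||% 50L,
    bandpassLow = s$bandpass_low %||% 0.2,
    bandpassHigh = s$bandpass_high %||% 4,
    window = s$window %||% 51L,
    offset = s$offset,
    openingRadius = s$opening_radius %||% 1L,
    closingRadius = s$closing_radius %||% 1L,
    minObjectArea = s$min_object_area %||% 0.05)
  list(pixelSize = y$pixel_size %||% 0.1, zStep = y$z_step %||% 0.5,
       seed = as.integer(y$seed %||% 1L), params = params,
       fusionWindow = as.integer(y$fusion$window %||% 9L),
       smoothRadius = as.integer(y$fusion$smooth_radius %||% 5L),
       classifier = y$classifier %||% "rulebased")
}

`%||%` <- function(a, b) if (is.null(a)) b else a
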