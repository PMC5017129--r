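# Orchestration: whole-sample analysis, simulation, training and reporting,
# each writing a machine-readable manifest so every artifact is reproducible.

writeManifest <- function(dir, inputs, config, seed) {
  jsonlite::write_json(
    list(inputs = inputs, seed = seed,
         parameterHash = md5Of(config),
         package = as.character(packageVersion("mitomorph")),
         rVersion = R.version.string),
    file.path(dir, "manifest.json"), auto_unbox = TRUE, digits = NA)
}

#' Analyze a set of Z-stacks with per-cell ROIs
#'
#' Runs the full pipeline (fusion, segmentation, descriptor extraction,
#' classification, per-cell and per-sample summaries) over matched stack /
#' ROI file pairs, writing \code{objects.csv}, \code{cells.csv},
#' \code{summary.csv} and \code{manifest.json} into \code{outDir}.
#' Unreadable inputs are reported per file and skipped; the function errors
#' at the end if any file failed.
#'
#' @param stackFiles character vector of TIFF stack paths.
#' @param roiFiles matched character vector of ROI JSON paths.
#' @param outDir output directory (created).
#' @param configFile optional YAML configuration ([readRunConfig()]).
#' @param model optional [MitoClassifier-class]; default uses the threshold
#'   rule ([classifyRuleBased()]).
#' @return invisibly, the per-sample \code{PopulationSummary}.
#' @export
runAnalyze <- function(stackFiles, roiFiles, outDir, configFile = NULL,
                       model = NULL) {
  stopifnot(length(stackFiles) == length(roiFiles))
  cfg <- readRunConfig(configFile)
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  allObjects <- list(); allCells <- list(); failures <- character()
  for (i in seq_along(stackFiles)) {
    res <- tryCatch({
      stack <- readStack(stackFiles[i], cfg$pixelSize, cfg$zStep)
      rois <- readROI(roiFiles[i])
      lapply(rois, function(roi) {
        seg <- suppressWarnings(segmentCell(
          stack, roi, cfg$params, smoothRadius = cfg$smoothRadius,
          window = cfg$fusionWindow))
        objs <- extractDescriptors(seg, cellId = roi@cellId)
        objs <- if (is.null(model)) classifyRuleBased(objs)
        else classifyObjects(model, objs)
        list(objects = objs, cell = summarizeCell(objs, roi))
      })
    }, error = function(e) e)
    if (inherits(res, "error")) {
      warning("failed on ", stackFiles[i], ": ", conditionMessage(res))
      failures <- c(failures, stackFiles[i])
      next
    }
    allObjects <- c(allObjects, lapply(res, `[[`, "objects"))
    allCells <- c(allCells, lapply(res, `[[`, "cell"))
  }
  if (length(failures))
    stop("analysis finished with failures: ",
         paste(failures, collapse = ", "))
  objects <- do.call(rbind, allObjects)
  cells <- do.call(rbind, allCells)
  write.csv(objects, file.path(outDir, "objects.csv"), row.names = FALSE)
  write.csv(cells, file.path(outDir, "cells.csv"), row.names = FALSE)
  summ <- populationSummary(cells, sampleId = basename(outDir))
  write.csv(data.frame(sampleId = summ$sampleId, class = MITO_CLASSES,
                       meanFraction = unname(summ$meanFractions),
                       sdFraction = unname(summ$sdFractions),
                       meanTotalArea = summ$meanTotalArea,
                       meanDensity = summ$meanDensity),
            file.path(outDir, "summary.csv"), row.names = FALSE)
  writeManifest(outDir, list(stacks = stackFiles, rois = roiFiles),
                cfg, cfg$seed)
  invisible(summ)
}

#' Simulate a sample and write it to disk
#'
#' Renders simulated cells ([renderStack()]) and writes the stack (TIFF +
#' calibration sidecar), the ROI polygons (JSON), the ground-truth object
#' table (CSV) and a manifest.
#'
#' @param cells list of [simCellSpec()].
#' @param nSlices slices per stack.
#' @param outDir output directory.
#' @param frameDim frame size in pixels.
#' @return invisibly, the [renderStack()] result.
#' @export
runSimulate <- function(cells, nSlices, outDir, frameDim = c(416L, 416L)) {
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  sim <- renderStack(cells, nSlices, frameDim)
  writeStack(sim$stack, file.path(outDir, "stack.tiff"))
  writeROI(sim$rois, file.path(outDir, "rois.json"))
  write.csv(sim$truth, file.path(outDir, "ground_truth.csv"),
            row.names = FALSE)
  writeManifest(outDir, list(), cells, cells[[1]]$seed)
  invisible(sim)
}

#' Train and save the morphology classifier
#'
#' @param benchmark labelled benchmark table ([makeBenchmark()] or a CSV of
#'   manually labelled objects read with \code{read.csv}).
#' @param path RDS path for the model (optional).
#' @inheritParams trainClassifier
#' @return the [MitoClassifier-class], invisibly if saved.
#' @export
runTrain <- function(benchmark, path = NULL, nTrees = 200L, seed = 1L) {
  model <- trainClassifier(benchmark, nTrees = nTrees, seed = seed)
  if (!is.null(path)) {
    saveRDS(model, path)
    return(invisible(model))
  }
  model
}

#' Figures for an analyzed sample
#'
#' Writes the standard readout figures for one or more analyzed samples:
#' per-class fraction distributions across cells, and (for pre/post pairs)
#' a heat map of the per-class percentage change.
#'
#' @param cellTables named list of per-cell data.frames (from
#'   \code{cells.csv}).
#' @param outDir directory for PNG output.
#' @param changes optional named list of \code{ChangeResult} objects for the
#'   change heat map.
#' @return invisibly, the paths written.
#' @export
runReport <- function(cellTables, outDir, changes = NULL) {
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  paths <- character()
  df <- do.call(rbind, lapply(names(cellTables), function(nm) {
    d <- cellTables[[nm]]
    if (nrow(d) == 0L) return(NULL)
    do.call(rbind, lapply(MITO_CLASSES, function(cl)
      data.frame(sample = nm, class = cl,
                 fraction = d[[paste0("f.", cl)]])))
  }))
  if (is.null(df) || nrow(df) == 0L) {
    warning("no cells to report; no figures written")
    return(invisible(paths))
  }
  p <- ggplot2::ggplot(df[!is.na(df$fraction), ],
                       ggplot2::aes(x = class, y = 100 * fraction,
                                    fill = class)) +
    ggplot2::geom_boxplot(outlier.size = 0.5) +
    ggplot2::facet_wrap(~sample) +
    ggplot2::labs(y = "% of mitochondria per cell", x = NULL) +
    ggplot2::theme_bw() + ggplot2::theme(legend.position = "none")
  f1 <- file.path(outDir, "class_fractions.png")
  ggplot2::ggsave(f1, p, width = 7, height = 4, dpi = 150)
  paths <- f1
  if (!is.null(changes) && length(changes)) {
    hm <- do.call(rbind, lapply(names(changes), function(nm)
      data.frame(sample = nm, class = names(changes[[nm]]$perClass),
                 change = unname(changes[[nm]]$perClass))))
    p2 <- ggplot2::ggplot(hm, ggplot2::aes(sample, class, fill = change)) +
      ggplot2::geom_tile() +
      ggplot2::scale_fill_gradient2(low = "blue", mid = "white",
                                    high = "red") +
      ggplot2::labs(fill = "pp change") + ggplot2::theme_bw()
    f2 <- file.path(outDir, "change_heatmap.png")
    ggplot2::ggsave(f2, p2, width = 6, height = 3, dpi = 150)
    paths <- c(paths, f2)
  }
  invisible(paths)
}
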