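# Three-class morphology classification (punctate / intermediate /
# filamentous): a random forest on the shape descriptors, plus a transparent
# threshold rule used as a cross-check and fallback.

md5Of <- function(x) {
  f <- tempfile()
  on.exit(unlink(f))
  # version fixed so the hash is stable across R sessions
  saveRDS(x, f, version = 2)
  unname(tools::md5sum(f))
}

#' Train the random-forest morphology classifier
#'
#' Fits a random forest on the ten shape descriptors of a labelled benchmark
#' table (e.g. from [makeBenchmark()] or a CSV of manually classified
#' objects). The fit is fully reproducible: the RNG seed and an MD5 hash of
#' the training table are stored in the model.
#'
#' @param benchmark data.frame containing the descriptor columns and a
#'   \code{label} column with values punctate / intermediate / filamentous.
#'   Rows with missing descriptors (segmentation misses) are dropped with a
#'   message.
#' @param nTrees number of trees (default 200).
#' @param seed RNG seed for the forest (default 1).
#' @param minPerClass minimum training examples required per class
#'   (default 30).
#' @return A [MitoClassifier-class].
#' @examples \dontrun{
#' bench <- makeBenchmark(300, c(1, 1, 1) / 3, seed = 1)
#' model <- trainClassifier(bench)
#' }
#' @seealso [classifyObjects()], [classifyRuleBased()]
#' @export
trainClassifier <- function(benchmark, nTrees = 200L, seed = 1L,
                            minPerClass = 30L) {
  stopifnot(is.data.frame(benchmark))
  missing_cols <- setdiff(c(DESCRIPTOR_NAMES, "label"), names(benchmark))
  if (length(missing_cols))
    stop("benchmark lacks columns: ", paste(missing_cols, collapse = ", "))
  ok <- stats::complete.cases(benchmark[, DESCRIPTOR_NAMES])
  if (!all(ok))
    message(sum(!ok), " objects without descriptors (segmentation misses) ",
            "excluded from training")
  benchmark <- benchmark[ok, , drop = FALSE]
  counts <- table(factor(benchmark$label, levels = MITO_CLASSES))
  absent <- names(counts)[counts == 0L]
  if (length(absent))
    stop("training data has no examples of class: ",
         paste(absent, collapse = ", "))
  if (any(counts < minPerClass))
    stop("need at least ", minPerClass, " examples per class; got ",
         paste(sprintf("%s=%d", names(counts), counts), collapse = ", "))
  x <- benchmark[, DESCRIPTOR_NAMES]
  y <- factor(benchmark$label, levels = MITO_CLASSES)
  set.seed(seed)
  rf <- randomForest::randomForest(
    x = x, y = y, ntree = as.integer(nTrees),
    mtry = floor(sqrt(length(DESCRIPTOR_NAMES))))
  conf <- rf$confusion[, MITO_CLASSES, drop = FALSE]
  new("MitoClassifier", forest = rf, features = DESCRIPTOR_NAMES,
      nTrees = as.integer(nTrees), seed = as.integer(seed),
      trainingHash = md5Of(list(x, as.character(y))),
      oobError = mean(rf$predicted != y),
      oobConfusion = as.matrix(conf))
}

#' Predict morphology classes for segmented objects
#'
#' Assigns each object the class with the highest forest vote fraction.
#' Exact ties are resolved in favour of the less elongated class (punctate
#' over intermediate over filamentous) and reported with a message. Class
#' probabilities (vote fractions) are retained.
#'
#' @param model a [MitoClassifier-class].
#' @param objects data.frame with the descriptor columns (as produced by
#'   [extractDescriptors()] or [makeBenchmark()]).
#' @return \code{objects} with added columns \code{classLabel} and
#'   \code{p.punctate}, \code{p.intermediate}, \code{p.filamentous}.
#' @export
classifyObjects <- function(model, objects) {
  stopifnot(is(model, "MitoClassifier"), is.data.frame(objects))
  if (nrow(objects) == 0L) {
    objects$classLabel <- character()
    for (cl in MITO_CLASSES) objects[[paste0("p.", cl)]] <- numeric()
    return(objects)
  }
  if (!all(model@features %in% names(objects)))
    stop("objects lack descriptor columns required by the model: ",
         paste(setdiff(model@features, names(objects)), collapse = ", "))
  prob <- stats::predict(model@forest, objects[, model@features],
                         type = "prob")
  prob <- prob[, MITO_CLASSES, drop = FALSE]
  # arg-max with precedence punctate < intermediate < filamentous on ties
  pick <- apply(prob, 1, function(p) which(p == max(p))[1])
  nties <- sum(apply(prob, 1, function(p) sum(p == max(p)) > 1))
  if (nties > 0)
    message(nties, " tie(s) resolved toward the less elongated class")
  objects$classLabel <- MITO_CLASSES[pick]
  for (cl in MITO_CLASSES) objects[[paste0("p.", cl)]] <- prob[, cl]
  objects
}

#' Threshold-rule morphology classification
#'
#' Transparent fallback and cross-check for the forest: objects with any
#' skeleton branch point or skeleton length above \code{filamentousMin} are
#' filamentous; otherwise skeleton length below \code{punctateMax} is
#' punctate and anything between is intermediate.
#'
#' @param objects data.frame with \code{skeletonLengthUm} and
#'   \code{branchPoints} columns.
#' @param punctateMax upper skeleton length for punctate, um (default 1).
#' @param filamentousMin lower skeleton length for filamentous, um
#'   (default 4).
#' @return \code{objects} with an added \code{classLabel} column.
#' @examples
#' df <- data.frame(skeletonLengthUm = c(0.5, 2, 3), branchPoints = c(0, 0, 2))
#' classifyRuleBased(df)$classLabel
#' @export
classifyRuleBased <- function(objects, punctateMax = 1, filamentousMin = 4) {
  stopifnot(all(c("skeletonLengthUm", "branchPoints") %in% names(objects)))
  lab <- ifelse(objects$branchPoints >= 1 |
                  objects$skeletonLengthUm > filamentousMin, "filamentous",
                ifelse(objects$skeletonLengthUm < punctateMax, "punctate",
                       "intermediate"))
  objects$classLabel <- lab
  objects
}
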