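#' @include AllClasses.R
NULL

#' ActionSampleSet: preprocessed per-view blobs with labels
#'
#' Intermediate product between preprocessing and feature extraction: for
#' each multiview time step, the detected [HumanBlob-class] of every view
#' (`NULL` where no subject was found) plus the ground-truth label. Feature
#' extraction at any `(L, alpha)` can be re-run from this without repeating
#' segmentation.
#'
#' @slot samples list; each element is a per-view list of
#'   [HumanBlob-class]/`NULL`.
#' @slot labels character vector aligned with `samples`.
#' @export
setClass("ActionSampleSet",
  slots = c(samples = "list", labels = "character"),
  validity = function(object) {
    if (length(object@samples) != length(object@labels))
      return("samples and labels lengths differ")
    TRUE
  })

setMethod("show", "ActionSampleSet", function(object) {
  cat(sprintf("ActionSampleSet: %d samples\n", length(object@samples)))
  print(table(object@labels))
})

#' Preprocess a corpus into per-view blobs
#'
#' Builds one background model per view from the corpus' background frames,
#' then runs the full segmentation chain ([detectSubject()]) on every action
#' frame of every sample and view. Views without a detected subject carry
#' `NULL` and are dropped from fusion later (the view count shrinks rather
#' than annihilating the product).
#'
#' @param corpus an [ActionCorpus-class].
#' @param tau foreground threshold (default 15).
#' @param denoiseRadius morphology radius (default 1).
#' @param armStrength arm-rejection scale (default 0.05).
#' @param verbose log per-frame skips.
#' @return An [ActionSampleSet-class].
#' @export
processCorpus <- function(corpus, tau = 15, denoiseRadius = 1L,
                          armStrength = 0.05, verbose = FALSE) {
  stopifnot(is(corpus, "ActionCorpus"))
  models <- lapply(corpus@backgrounds, buildBackgroundModel)
  samples <- list()
  labels <- character(0)
  for (i in seq_along(corpus@samples)) {
    s <- corpus@samples[[i]]
    nFrames <- length(s$views[[1]])
    for (t in seq_len(nFrames)) {
      blobs <- lapply(names(s$views), function(v) {
        fr <- s$views[[v]][[t]]
        blob <- detectSubject(fr, models[[v]], tau = tau,
                              denoiseRadius = denoiseRadius,
                              armStrength = armStrength)
        if (is.null(blob) && verbose)
          message("no subject in sample ", i, " frame ", t, " view ", v)
        blob
      })
      names(blobs) <- names(s$views)
      samples[[length(samples) + 1L]] <- blobs
      labels <- c(labels, s$label)
    }
  }
  new("ActionSampleSet", samples = samples, labels = labels)
}

#' Extract fused feature vectors from preprocessed samples
#'
#' Computes per-view [layerProfile()]s at the requested layer count and
#' alpha, fuses them across views ([fuseViews()]), and assembles the
#' classifier matrix. Samples where no view yields a profile (no subject, or
#' blob shorter than `layers` rows) are dropped.
#'
#' @param sampleSet an [ActionSampleSet-class].
#' @param layers odd layer count L (default 3).
#' @param alpha blend weight (default 0.9).
#' @param flavor `"depth"` (weighted mass of dimension) or `"nondepth"`.
#' @param convention alpha blend convention (see [weightedDensity()]).
#' @return List with `x` (feature matrix, `layers + 1` columns), `labels`
#'   (character), `viewsUsed` (integer per sample).
#' @export
extractFeatures <- function(sampleSet, layers = 3L, alpha = 0.9,
                            flavor = c("depth", "nondepth"),
                            convention = "printed") {
  flavor <- match.arg(flavor)
  stopifnot(is(sampleSet, "ActionSampleSet"))
  rows <- list(); labs <- character(0); used <- integer(0)
  for (i in seq_along(sampleSet@samples)) {
    profiles <- lapply(sampleSet@samples[[i]], function(b) {
      if (is.null(b)) return(NULL)
      layerProfile(b, layers = layers, alpha = alpha, convention = convention)
    })
    fused <- fuseViews(profiles)
    if (is.null(fused)) next
    rows[[length(rows) + 1L]] <- featureVector(fused, flavor = flavor)
    labs <- c(labs, sampleSet@labels[i])
    used <- c(used, fused@viewsUsed)
  }
  if (length(rows) == 0L) stop("no usable samples after feature extraction")
  x <- do.call(rbind, rows)
  colnames(x) <- c(sprintf("layer%+d", seq.int(-(layers - 1) / 2,
                                               (layers - 1) / 2)), "Pm")
  list(x = x, labels = labs, viewsUsed = used)
}

#' Write extracted features to CSV
#'
#' @param features output of [extractFeatures()].
#' @param path CSV path.
#' @return `path`, invisibly.
#' @export
writeFeatureCSV <- function(features, path) {
  df <- as.data.frame(features$x)
  df$viewsUsed <- features$viewsUsed
  df$label <- features$labels
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Run the full recognition pipeline
#'
#' Executes preprocessing, layered feature extraction, multiview fusion, and
#' classification in order, on a generated or on-disk corpus. With a single
#' corpus a stratified split (default 70/30, fixed seed) separates training
#' and testing; alternatively an explicit `testCorpus` mirrors a
#' two-scenario train/test design. When `outDir` is given, the features CSV,
#' serialized model, evaluation report JSON, and a run log recording every
#' applied parameter are written there.
#'
#' @param corpus an [ActionCorpus-class] or a corpus directory path.
#' @param testCorpus optional held-out corpus (same forms).
#' @param outDir optional artifact directory.
#' @param layers,alpha,flavor,convention feature parameters.
#' @param tau,denoiseRadius,armStrength preprocessing parameters.
#' @param method `"ann"` or `"svm"`.
#' @param trainFraction split fraction when no `testCorpus` is given.
#' @param seed RNG seed for split and training.
#' @param verbose log skipped frames.
#' @return List with `model` ([ActionModel-class]), `report`
#'   ([EvalReport-class]), `features`, and `testIndex`.
#' @examples
#' \donttest{
#' cfg <- sceneConfig(backgroundFrames = 40L)
#' corpus <- generateCorpus(cfg, samplesPerClass = 10L, seed = 7L)
#' res <- runPipeline(corpus, method = "svm", seed = 7L)
#' res$report
#' }
#' @export
runPipeline <- function(corpus, testCorpus = NULL, outDir = NULL,
                        layers = 3L, alpha = 0.9, flavor = "depth",
                        convention = "printed", tau = 15,
                        denoiseRadius = 1L, armStrength = 0.05,
                        method = c("ann", "svm"), trainFraction = 0.7,
                        seed = 1L, verbose = FALSE) {
  method <- match.arg(method)
  if (is.character(corpus)) corpus <- readCorpus(corpus)
  if (layers %% 2L != 1L) stop("layers must be odd (got ", layers, ")")
  logLines <- c(
    sprintf("[%s] pipeline start", format(Sys.time(), "%Y-%m-%dT%H:%M:%S")),
    sprintf("parameters: layers=%d alpha=%g flavor=%s convention=%s", layers,
            alpha, flavor, convention),
    sprintf("parameters: tau=%g denoiseRadius=%d armStrength=%g method=%s seed=%d",
            tau, denoiseRadius, armStrength, method, seed))
  sset <- processCorpus(corpus, tau = tau, denoiseRadius = denoiseRadius,
                        armStrength = armStrength, verbose = verbose)
  feats <- extractFeatures(sset, layers = layers, alpha = alpha,
                           flavor = flavor, convention = convention)
  if (is.null(testCorpus)) {
    train <- stratifiedSplit(feats$labels, trainFraction, seed)
    xTrain <- feats$x[train, , drop = FALSE]; yTrain <- feats$labels[train]
    xTest <- feats$x[!train, , drop = FALSE]; yTest <- feats$labels[!train]
    testIndex <- which(!train)
  } else {
    if (is.character(testCorpus)) testCorpus <- readCorpus(testCorpus)
    ssetTest <- processCorpus(testCorpus, tau = tau,
                              denoiseRadius = denoiseRadius,
                              armStrength = armStrength, verbose = verbose)
    featsTest <- extractFeatures(ssetTest, layers = layers, alpha = alpha,
                                 flavor = flavor, convention = convention)
    xTrain <- feats$x; yTrain <- feats$labels
    xTest <- featsTest$x; yTest <- featsTest$labels
    testIndex <- seq_along(yTest)
  }
  model <- trainActionModel(xTrain, yTrain, method = method, layers = layers,
                            alpha = alpha, flavor = flavor, seed = seed)
  report <- evaluateModel(model, xTest, yTest)
  logLines <- c(logLines,
    sprintf("samples: %d train / %d test", length(yTrain), length(yTest)),
    sprintf("macro-average precision: %.4f%%", report@averagePrecision),
    sprintf("[%s] pipeline end", format(Sys.time(), "%Y-%m-%dT%H:%M:%S")))
  if (!is.null(outDir)) {
    dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
    writeFeatureCSV(feats, file.path(outDir, "features.csv"))
    saveRDS(list(format = "LayerFusion-model", version = 1L, model = model),
            file.path(outDir, "model.rds"))
    writeEvalReport(report, file.path(outDir, "report.json"))
    writeLines(logLines, file.path(outDir, "run.log"))
  }
  list(model = model, report = report, features = feats,
       testIndex = testIndex)
}
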