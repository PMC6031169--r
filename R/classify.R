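#' @include AllClasses.R
NULL

.asFeatureMatrix <- function(x) {
  if (is.list(x) && !is.data.frame(x)) {
    lens <- lengths(x)
    if (any(lens != lens[1]))
      stop("feature vectors have mixed lengths (", paste(unique(lens),
           collapse = ", "), ")")
    x <- do.call(rbind, x)
  }
  x <- as.matrix(x)
  storage.mode(x) <- "double"
  x
}

#' Train a posture classifier
#'
#' Trains either a single-hidden-layer back-propagation neural network (20
#' hidden nodes by default) or an RBF-kernel C-classification SVM on fused
#' feature vectors. Features are used exactly as given — no hidden rescaling:
#' layer features already lie in [0, 1] and the proportion value is passed
#' through unscaled. Training is deterministic for a fixed seed.
#'
#' @param x feature matrix (rows = samples) or list of equal-length vectors.
#' @param labels factor or character vector of action classes.
#' @param method `"ann"` or `"svm"`.
#' @param hiddenNodes ANN hidden-layer size (default 20).
#' @param layers,alpha,flavor feature-extraction settings recorded in the
#'   model for provenance.
#' @param seed RNG seed (ANN weight initialization).
#' @param maxit ANN training iterations (default 300).
#' @param decay ANN weight decay, the overfitting control (default 5e-4).
#' @param cost,gamma SVM hyperparameters; `gamma = NULL` uses the standard
#'   `1/ncol(x)` heuristic.
#' @return An [ActionModel-class].
#' @seealso [evaluateModel()], [sweepParameters()]
#' @export
trainActionModel <- function(x, labels, method = c("ann", "svm"),
                             hiddenNodes = 20L, layers = 3L, alpha = 0.9,
                             flavor = "depth", seed = 1L, maxit = 300L,
                             decay = 5e-4, cost = 1, gamma = NULL) {
  method <- match.arg(method)
  x <- .asFeatureMatrix(x)
  labels <- as.character(labels)
  if (nrow(x) != length(labels)) stop("x and labels lengths differ")
  labelSet <- actionClasses()[actionClasses() %in% unique(labels)]
  if (!all(labels %in% actionClasses()))
    labelSet <- sort(unique(labels))
  if (length(labelSet) < 2L)
    stop("training needs at least two classes (got ",
         length(labelSet), ")")
  y <- factor(labels, levels = labelSet)
  fit <- if (method == "ann") {
    set.seed(seed)
    nnet::nnet(x, nnet::class.ind(y), size = hiddenNodes, softmax = TRUE,
               maxit = maxit, decay = decay, trace = FALSE,
               MaxNWts = 100000L)
  } else {
    set.seed(seed)
    e1071::svm(x, y, type = "C-classification", kernel = "radial",
               cost = cost, gamma = if (is.null(gamma)) 1 / ncol(x) else gamma,
               scale = FALSE)
  }
  new("ActionModel", method = method, fit = fit,
      hiddenNodes = as.integer(hiddenNodes), layers = as.integer(layers),
      alpha = alpha, flavor = flavor, labelSet = labelSet,
      seed = as.integer(seed))
}

#' Predict action classes
#'
#' @param object an [ActionModel-class].
#' @param newdata feature matrix or list of feature vectors.
#' @return Factor of predicted classes (levels = the model's label set).
#' @export
setMethod("predict", "ActionModel", function(object, newdata) {
  x <- .asFeatureMatrix(newdata)
  if (object@method == "ann") {
    pr <- predict(object@fit, x)
    factor(object@labelSet[max.col(pr, ties.method = "first")],
           levels = object@labelSet)
  } else {
    factor(as.character(predict(object@fit, x)), levels = object@labelSet)
  }
})

#' Evaluate a classifier into a confusion/precision report
#'
#' Builds the confusion matrix (rows = true, columns = predicted) over the
#' model's label set and the per-class precisions `TP / (TP + FP) * 100`.
#' A class receiving no predictions has undefined precision; it is reported
#' as 0 and flagged so the macro average stays defined.
#'
#' @param model an [ActionModel-class].
#' @param x feature matrix or list of vectors.
#' @param labels true classes.
#' @return An [EvalReport-class].
#' @export
evaluateModel <- function(model, x, labels) {
  precisionReport(labels, predict(model, x), labelSet = model@labelSet)
}

#' Confusion matrix and precision report from label vectors
#'
#' The reporting core behind [evaluateModel()], usable on any pair of truth
#' and prediction vectors: confusion counts (rows = true, columns =
#' predicted), per-class precision `TP / (TP + FP) * 100` with the undefined
#' (no-prediction) case reported as 0 and flagged, and the macro average.
#'
#' @param truth true classes.
#' @param predicted predicted classes.
#' @param labelSet ordered class labels (default [actionClasses()]).
#' @return An [EvalReport-class].
#' @export
precisionReport <- function(truth, predicted, labelSet = actionClasses()) {
  truth <- factor(as.character(truth), levels = labelSet)
  predicted <- factor(as.character(predicted), levels = labelSet)
  conf <- table(true = truth, predicted = predicted)
  conf <- matrix(as.integer(conf), nrow(conf), ncol(conf),
                 dimnames = dimnames(conf))
  colTot <- colSums(conf)
  prec <- ifelse(colTot > 0, diag(conf) / colTot * 100, 0)
  undef <- colTot == 0
  new("EvalReport", confusion = conf, precision = as.numeric(prec),
      averagePrecision = mean(prec), undefined = undef)
}

#' Stratified train/test split
#'
#' Deterministic per-class split: a fixed fraction of each class goes to the
#' training set, sampled under the given seed.
#'
#' @param labels class labels.
#' @param trainFraction fraction per class assigned to training (default 0.7).
#' @param seed RNG seed.
#' @return Logical vector, TRUE for training rows.
#' @export
stratifiedSplit <- function(labels, trainFraction = 0.7, seed = 1L) {
  labels <- as.character(labels)
  train <- logical(length(labels))
  set.seed(seed)
  for (cl in unique(labels)) {
    idx <- which(labels == cl)
    nTrain <- max(1L, round(trainFraction * length(idx)))
    train[sample(idx, nTrain)] <- TRUE
  }
  train
}

#' Hyperparameter sweep over layer counts and alpha values
#'
#' Re-extracts features for every `(L, alpha)` combination from preprocessed
#' per-view blobs, trains each requested method on a stratified split, and
#' tabulates held-out macro-average precision — the layer-size and alpha
#' evaluation protocol.
#'
#' @param sampleSet preprocessed samples from [processCorpus()].
#' @param layerList odd layer counts to test (default `c(3, 5, 7)`).
#' @param alphaList alpha values to test (default `seq(0, 1, 0.1)`).
#' @param methods classifier methods (subset of `c("ann", "svm")`).
#' @param flavor feature flavor (default `"depth"`).
#' @param convention alpha blend convention.
#' @param trainFraction,seed split settings.
#' @return `data.frame` with columns `layers`, `alpha`, `method`,
#'   `averagePrecision` (one row per grid cell).
#' @export
sweepParameters <- function(sampleSet, layerList = c(3L, 5L, 7L),
                            alphaList = seq(0, 1, 0.1),
                            methods = c("ann", "svm"), flavor = "depth",
                            convention = "printed", trainFraction = 0.7,
                            seed = 1L) {
  grid <- expand.grid(layers = layerList, alpha = alphaList,
                      method = methods, stringsAsFactors = FALSE)
  res <- vapply(seq_len(nrow(grid)), function(i) {
    feats <- extractFeatures(sampleSet, layers = grid$layers[i],
                             alpha = grid$alpha[i], flavor = flavor,
                             convention = convention)
    if (length(unique(feats$labels)) < 2L) return(NA_real_)
    train <- stratifiedSplit(feats$labels, trainFraction, seed)
    model <- trainActionModel(feats$x[train, , drop = FALSE],
                              feats$labels[train], method = grid$method[i],
                              layers = grid$layers[i], alpha = grid$alpha[i],
                              flavor = flavor, seed = seed)
    rep <- evaluateModel(model, feats$x[!train, , drop = FALSE],
                         feats$labels[!train])
    rep@averagePrecision
  }, numeric(1))
  grid$averagePrecision <- res
  grid
}

#' Serialize an evaluation report to JSON
#'
#' @param report an [EvalReport-class].
#' @param path output path; `NULL` returns the JSON string.
#' @return The path (or JSON string), invisibly.
#' @export
writeEvalReport <- function(report, path = NULL) {
  obj <- list(
    confusion = report@confusion,
    classes = rownames(report@confusion),
    precision = as.list(stats::setNames(report@precision,
                                        rownames(report@confusion))),
    undefinedPrecision = as.list(stats::setNames(report@undefined,
                                                 rownames(report@confusion))),
    averagePrecision = report@averagePrecision)
  js <- jsonlite::toJSON(obj, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  if (is.null(path)) return(invisible(as.character(js)))
  writeLines(js, path)
  invisible(path)
}
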