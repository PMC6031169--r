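#' @import methods
NULL

#' The four profile-based action classes
#'
#' Canonical ordered label set used throughout the package: coarse whole-body
#' postures recognizable from silhouette and depth alone.
#'
#' @return Character vector of the four class labels, in canonical order.
#' @examples
#' actionClasses()
#' @export
actionClasses <- function() {
  c("standing_walking", "sitting", "stooping", "lying")
}

.checkPixels <- function(p) {
  if (!is.matrix(p) || nrow(p) < 1L || ncol(p) < 1L)
    return("pixels must be a non-empty matrix")
  if (anyNA(p) || any(p < 0L) || any(p > 255L))
    return("pixel values must lie in [0, 255]")
  if (any(p != as.integer(p)))
    return("pixel values must be integral (8-bit depth steps)")
  NULL
}

#' DepthFrame: one 8-bit depth image
#'
#' A single-channel depth image from one camera view at one time index.
#' Values run 0--255 from near to far (0 = nearest). Stored row = image y
#' (downward), column = image x (rightward), 1-based.
#'
#' @slot pixels integer matrix of depth values in [0, 255].
#' @slot frameIndex ordinal position within its stream.
#' @slot viewId camera/view identifier.
#' @export
setClass("DepthFrame",
  slots = c(pixels = "matrix", frameIndex = "integer", viewId = "character"),
  validity = function(object) {
    msg <- .checkPixels(object@pixels)
    if (!is.null(msg)) return(msg)
    if (length(object@frameIndex) != 1L || is.na(object@frameIndex))
      return("frameIndex must be a single integer")
    TRUE
  })

#' Construct a DepthFrame
#'
#' @param pixels numeric or integer matrix with values in [0, 255]
#'   (row = image row y, column = image column x).
#' @param frameIndex ordinal frame position (1-based).
#' @param viewId camera identifier string.
#' @return A [DepthFrame-class] object.
#' @examples
#' f <- DepthFrame(matrix(100L, 4, 6))
#' dim(pixels(f))
#' @export
DepthFrame <- function(pixels, frameIndex = 1L, viewId = "view1") {
  storage.mode(pixels) <- "integer"
  new("DepthFrame", pixels = pixels, frameIndex = as.integer(frameIndex),
      viewId = as.character(viewId))
}

#' ViewStream: an ordered depth-frame sequence from one camera
#'
#' @slot frames list of [DepthFrame-class], all sharing dimensions, with
#'   strictly increasing frame indices.
#' @slot viewId camera identifier.
#' @slot viewAngle camera azimuth in degrees (metadata; `NA` if unknown).
#' @slot backgroundCount number of leading background-only frames.
#' @export
setClass("ViewStream",
  slots = c(frames = "list", viewId = "character", viewAngle = "numeric",
            backgroundCount = "integer"),
  validity = function(object) {
    fr <- object@frames
    if (length(fr) == 0L) return("stream has no frames")
    if (!all(vapply(fr, is, logical(1), "DepthFrame")))
      return("frames must all be DepthFrame objects")
    dims <- vapply(fr, function(f) dim(f@pixels), integer(2))
    if (any(dims[1, ] != dims[1, 1]) || any(dims[2, ] != dims[2, 1]))
      return("all frames in a stream must share dimensions")
    idx <- vapply(fr, slot, integer(1), "frameIndex")
    if (any(diff(idx) <= 0L)) return("frame indices must strictly increase")
    if (object@backgroundCount < 0L) return("backgroundCount must be >= 0")
    if (object@backgroundCount > length(fr))
      return("backgroundCount exceeds stream length")
    TRUE
  })

#' Construct a ViewStream
#'
#' @param frames list of [DepthFrame-class] objects in temporal order.
#' @param viewId camera identifier.
#' @param viewAngle camera azimuth in degrees, or `NA`.
#' @param backgroundCount number of leading background-only frames.
#' @return A [ViewStream-class] object.
#' @export
ViewStream <- function(frames, viewId = "view1", viewAngle = NA_real_,
                       backgroundCount = 0L) {
  new("ViewStream", frames = frames, viewId = as.character(viewId),
      viewAngle = as.numeric(viewAngle),
      backgroundCount = as.integer(backgroundCount))
}

#' MultiViewSample: one synchronized time step across views
#'
#' @slot frames list with one [DepthFrame-class] per view.
#' @slot timeIndex the shared time step.
#' @slot label optional action class (`NA` if unlabeled).
#' @export
setClass("MultiViewSample",
  slots = c(frames = "list", timeIndex = "integer", label = "character"),
  validity = function(object) {
    if (length(object@frames) < 1L) return("a sample needs at least one view")
    if (!all(vapply(object@frames, is, logical(1), "DepthFrame")))
      return("frames must all be DepthFrame objects")
    if (!is.na(object@label) && !(object@label %in% actionClasses()))
      return("label must be one of actionClasses() or NA")
    TRUE
  })

#' BackgroundModel: per-pixel background depth statistics
#'
#' Summarizes the leading background-only frames of a static camera by a
#' per-pixel reference depth (lower median) and a robust spread (median
#' absolute deviation about the reference, in 8-bit steps).
#'
#' @slot reference matrix of per-pixel reference depths.
#' @slot spread matrix of per-pixel robust spreads.
#' @slot frameCount number of frames the model was built from.
#' @export
setClass("BackgroundModel",
  slots = c(reference = "matrix", spread = "matrix", frameCount = "integer"),
  validity = function(object) {
    if (!identical(dim(object@reference), dim(object@spread)))
      return("reference and spread must share dimensions")
    if (object@frameCount < 1L) return("frameCount must be >= 1")
    TRUE
  })

#' HumanBlob: the segmented subject in one frame
#'
#' Bounding boxes are 1-based inclusive `(x, y, w, h)` in full-frame
#' coordinates: columns `x..x+w-1`, rows `y..y+h-1`. `rawBbox` is the box
#' before arm rejection, `bbox` after. The mask and depth profile are cropped
#' to `bbox`; the depth profile is zero wherever the mask is zero.
#'
#' @slot rawBbox integer `(x, y, w, h)` before arm rejection.
#' @slot bbox integer `(x, y, w, h)` after arm rejection.
#' @slot mask binary matrix (`h` rows x `w` cols), 1 = subject.
#' @slot depthProfile masked depth values cropped to `bbox`.
#' @export
setClass("HumanBlob",
  slots = c(rawBbox = "integer", bbox = "integer", mask = "matrix",
            depthProfile = "matrix"),
  validity = function(object) {
    b <- object@bbox
    if (length(b) != 4L || b[3] < 1L || b[4] < 1L)
      return("bbox must be (x, y, w, h) with w, h >= 1")
    if (!identical(dim(object@mask), c(b[4], b[3])))
      return("mask dimensions must equal (h, w) of bbox")
    if (!identical(dim(object@depthProfile), dim(object@mask)))
      return("depthProfile dimensions must match mask")
    if (!all(object@mask %in% c(0, 1))) return("mask must be binary")
    if (any(object@depthProfile[object@mask == 0] != 0))
      return("depthProfile must be zero off-mask")
    if (sum(object@mask) == 0) return("blob mask must not be empty")
    if (!any(object@mask[1, ] > 0) || !any(object@mask[nrow(object@mask), ] > 0) ||
        !any(object@mask[, 1] > 0) || !any(object@mask[, ncol(object@mask)] > 0))
      return("bbox must be tight: every edge row/column touches the mask")
    TRUE
  })

#' LayerProfile: per-view layered features of one blob
#'
#' Holds, for the 2N+1 horizontal layers (k = -N top ... +N bottom), the raw
#' and normalized layer densities, raw (cm) and normalized real-range depths,
#' inverse depths, inverse-depth densities Q, weighted depth densities Z, the
#' blend weight alpha, and the width/height proportion value.
#'
#' @slot N maximum upper/lower layer count (layers = 2N+1).
#' @slot rhoRaw per-layer foreground pixel counts.
#' @slot rho normalized layer densities in [0, 1].
#' @slot depthRaw per-layer mean foreground depth converted to cm.
#' @slot depth max-normalized real-range depth in [0, 1].
#' @slot depthInv inverse depth in [0, 1] (1 = nearest layer).
#' @slot q inverse-depth density, `depthInv * rho`.
#' @slot z weighted depth density, alpha-blend of `q` and `rho`.
#' @slot alpha blend weight in [0, 1].
#' @slot convention `"printed"` or `"prose"` blend convention.
#' @slot proportion width/height ratio of the blob.
#' @export
setClass("LayerProfile",
  slots = c(N = "integer", rhoRaw = "numeric", rho = "numeric",
            depthRaw = "numeric", depth = "numeric", depthInv = "numeric",
            q = "numeric", z = "numeric", alpha = "numeric",
            convention = "character", proportion = "numeric"),
  validity = function(object) {
    L <- 2L * object@N + 1L
    lens <- c(length(object@rhoRaw), length(object@rho),
              length(object@depthRaw), length(object@depth),
              length(object@depthInv), length(object@q), length(object@z))
    if (any(lens != L)) return("all feature arrays must have length 2N+1")
    bounded <- c(object@rho, object@depth, object@depthInv, object@q, object@z)
    if (any(bounded < -1e-12) || any(bounded > 1 + 1e-12))
      return("normalized features must lie in [0, 1]")
    if (object@alpha < 0 || object@alpha > 1) return("alpha must be in [0, 1]")
    if (object@proportion <= 0) return("proportion value must be > 0")
    TRUE
  })

#' FusedFeatures: cross-view fused layer features
#'
#' @slot omega per-layer product of normalized densities across views
#'   (mass of dimension).
#' @slot omegaBar per-layer product of weighted depth densities across views
#'   (weighted mass of dimension).
#' @slot pMax maximum proportion value over views.
#' @slot viewsUsed number of views entering the products.
#' @export
setClass("FusedFeatures",
  slots = c(omega = "numeric", omegaBar = "numeric", pMax = "numeric",
            viewsUsed = "integer"),
  validity = function(object) {
    if (length(object@omega) != length(object@omegaBar))
      return("omega and omegaBar must share length")
    if (length(object@omega) %% 2L != 1L)
      return("fused features must cover 2N+1 layers")
    if (any(object@omega < 0) || any(object@omega > 1) ||
        any(object@omegaBar < 0) || any(object@omegaBar > 1))
      return("fused layer features must lie in [0, 1]")
    if (object@viewsUsed < 1L) return("at least one view must be used")
    TRUE
  })

#' ActionModel: a trained posture classifier
#'
#' @slot method `"ann"` (single-hidden-layer neural network) or `"svm"`
#'   (RBF-kernel C-classification SVM).
#' @slot fit the underlying fitted object ([nnet::nnet] or [e1071::svm]).
#' @slot hiddenNodes hidden-layer size (ANN only).
#' @slot layers number of layers L = 2N+1 the features were built with.
#' @slot alpha blend weight used in feature extraction.
#' @slot flavor `"depth"` or `"nondepth"` feature vector flavor.
#' @slot labelSet ordered class labels.
#' @slot seed RNG seed used at training.
#' @export
setClass("ActionModel",
  slots = c(method = "character", fit = "ANY", hiddenNodes = "integer",
            layers = "integer", alpha = "numeric", flavor = "character",
            labelSet = "character", seed = "integer"),
  validity = function(object) {
    if (!object@method %in% c("ann", "svm")) return("method must be ann or svm")
    if (object@layers %% 2L != 1L) return("layers must be odd")
    TRUE
  })

#' EvalReport: confusion matrix and precision summary
#'
#' Rows of the confusion matrix are true classes, columns predicted classes.
#' Per-class precision is TP / (TP + FP) in percent; a class that receives no
#' predictions has undefined precision, reported as 0 and flagged.
#'
#' @slot confusion integer confusion matrix (true x predicted).
#' @slot precision per-class precision, percent.
#' @slot averagePrecision macro-average precision, percent.
#' @slot undefined logical flags: TRUE where precision was undefined (0/0).
#' @export
setClass("EvalReport",
  slots = c(confusion = "matrix", precision = "numeric",
            averagePrecision = "numeric", undefined = "logical"),
  validity = function(object) {
    if (nrow(object@confusion) != ncol(object@confusion))
      return("confusion matrix must be square")
    if (any(object@confusion < 0)) return("confusion counts must be >= 0")
    if (any(object@precision < 0 | object@precision > 100))
      return("precision must lie in [0, 100]")
    TRUE
  })

#' SceneConfig: synthetic multiview scene parameters
#'
#' Describes the emulated capture setup: cameras 2 m above the floor tilted
#' 30 degrees below horizontal, subject 3--5.5 m away, configurable azimuth
#' separation between cameras, 8-bit depth with 0 = near and a background
#' plane at 240, and at least 40 leading background frames per sequence.
#'
#' @slot viewAngles camera azimuths in degrees (one per view, all distinct).
#' @slot cameraHeight camera height above floor, m.
#' @slot cameraTilt downward tilt below horizontal, degrees.
#' @slot distanceRange min/max subject distance from camera, m.
#' @slot frameWidth,frameHeight frame size in pixels.
#' @slot backgroundFrames leading background-only frames per sequence.
#' @slot framesPerAction action frames rendered per sample.
#' @slot maskFlipRate silhouette pixel flip probability in [0, 0.05].
#' @slot depthJitter depth noise s.d. in 8-bit steps.
#' @slot backgroundDepth background plane depth value.
#' @slot ambiguousSitting if TRUE, front-view sitting silhouettes mimic
#'   standing (the hidden-volume regime that needs the depth features).
#' @slot identicalGeometry if TRUE, all actions render with standing
#'   geometry (ablation: classes become indistinguishable).
#' @export
setClass("SceneConfig",
  slots = c(viewAngles = "numeric", cameraHeight = "numeric",
            cameraTilt = "numeric", distanceRange = "numeric",
            frameWidth = "integer", frameHeight = "integer",
            backgroundFrames = "integer", framesPerAction = "integer",
            maskFlipRate = "numeric", depthJitter = "numeric",
            backgroundDepth = "integer", ambiguousSitting = "logical",
            identicalGeometry = "logical"),
  validity = function(object) {
    if (length(object@viewAngles) < 1L) return("need at least one view")
    if (anyDuplicated(object@viewAngles)) return("view angles must be distinct")
    if (object@maskFlipRate < 0 || object@maskFlipRate > 0.05)
      return("maskFlipRate must lie in [0, 0.05]")
    if (object@backgroundFrames < 1L) return("backgroundFrames must be >= 1")
    if (length(object@distanceRange) != 2L ||
        object@distanceRange[1] > object@distanceRange[2])
      return("distanceRange must be (min, max)")
    if (object@frameWidth < 16L || object@frameHeight < 16L)
      return("frame size too small")
    TRUE
  })
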