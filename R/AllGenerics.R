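#' @include AllClasses.R
NULL

#' Accessors for depth-image and feature objects
#'
#' Small accessor family for the package's S4 containers: `pixels` returns
#' the depth matrix of a [DepthFrame-class]; `frameIndex` and `viewId` its
#' metadata; `frames` the frame list of a [ViewStream-class] or
#' [MultiViewSample-class]; `bbox` and `rawBbox` the (x, y, w, h) boxes of a
#' [HumanBlob-class]; `blobMask` and `depthProfile` its cropped binary mask
#' and masked depth; `featureVector` assembles the classifier input from a
#' [FusedFeatures-class]; `confusionMatrix`, `precisionByClass` and
#' `averagePrecision` read an [EvalReport-class].
#'
#' @param object an object of the documented classes.
#' @param ... passed on to methods.
#' @return The corresponding slot value (see above); `featureVector` returns
#'   a numeric vector of length `layers + 1`.
#' @name accessors
#' @aliases pixels frameIndex viewId frames bbox rawBbox blobMask
#'   depthProfile confusionMatrix precisionByClass averagePrecision
NULL

#' @rdname accessors
#' @export
setGeneric("pixels", function(object) standardGeneric("pixels"))
#' @rdname accessors
#' @export
setGeneric("frameIndex", function(object) standardGeneric("frameIndex"))
#' @rdname accessors
#' @export
setGeneric("viewId", function(object) standardGeneric("viewId"))
#' @rdname accessors
#' @export
setGeneric("frames", function(object) standardGeneric("frames"))
#' @rdname accessors
#' @export
setGeneric("bbox", function(object) standardGeneric("bbox"))
#' @rdname accessors
#' @export
setGeneric("rawBbox", function(object) standardGeneric("rawBbox"))
#' @rdname accessors
#' @export
setGeneric("blobMask", function(object) standardGeneric("blobMask"))
#' @rdname accessors
#' @export
setGeneric("depthProfile", function(object) standardGeneric("depthProfile"))
#' @rdname accessors
#' @export
setGeneric("featureVector", function(object, ...) standardGeneric("featureVector"))
#' @rdname accessors
#' @export
setGeneric("confusionMatrix", function(object) standardGeneric("confusionMatrix"))
#' @rdname accessors
#' @export
setGeneric("precisionByClass", function(object) standardGeneric("precisionByClass"))
#' @rdname accessors
#' @export
setGeneric("averagePrecision", function(object) standardGeneric("averagePrecision"))

#' @rdname accessors
setMethod("pixels", "DepthFrame", function(object) object@pixels)
#' @rdname accessors
setMethod("frameIndex", "DepthFrame", function(object) object@frameIndex)
#' @rdname accessors
setMethod("viewId", "DepthFrame", function(object) object@viewId)
#' @rdname accessors
setMethod("viewId", "ViewStream", function(object) object@viewId)
#' @rdname accessors
setMethod("frames", "ViewStream", function(object) object@frames)
#' @rdname accessors
setMethod("frames", "MultiViewSample", function(object) object@frames)
#' @rdname accessors
setMethod("bbox", "HumanBlob", function(object) object@bbox)
#' @rdname accessors
setMethod("rawBbox", "HumanBlob", function(object) object@rawBbox)
#' @rdname accessors
setMethod("blobMask", "HumanBlob", function(object) object@mask)
#' @rdname accessors
setMethod("depthProfile", "HumanBlob", function(object) object@depthProfile)
#' @rdname accessors
setMethod("confusionMatrix", "EvalReport", function(object) object@confusion)
#' @rdname accessors
setMethod("precisionByClass", "EvalReport", function(object) object@precision)
#' @rdname accessors
setMethod("averagePrecision", "EvalReport", function(object) object@averagePrecision)

#' Number of frames in a stream
#' @param object a [ViewStream-class].
#' @return integer frame count.
#' @export
nframes <- function(object) {
  stopifnot(is(object, "ViewStream"))
  length(object@frames)
}

setMethod("show", "DepthFrame", function(object) {
  d <- dim(object@pixels)
  cat(sprintf("DepthFrame %dx%d (w x h), view '%s', frame %d, depth range [%d, %d]\n",
              d[2], d[1], object@viewId, object@frameIndex,
              min(object@pixels), max(object@pixels)))
})

setMethod("show", "ViewStream", function(object) {
  d <- dim(object@frames[[1]]@pixels)
  cat(sprintf("ViewStream '%s': %d frames of %dx%d, %d background, angle %s\n",
              object@viewId, length(object@frames), d[2], d[1],
              object@backgroundCount,
              ifelse(is.na(object@viewAngle), "NA",
                     sprintf("%g deg", object@viewAngle))))
})

setMethod("show", "HumanBlob", function(object) {
  b <- object@bbox
  cat(sprintf("HumanBlob at (x=%d, y=%d) size %dx%d (w x h), %d foreground px\n",
              b[1], b[2], b[3], b[4], sum(object@mask)))
})

setMethod("show", "LayerProfile", function(object) {
  L <- 2L * object@N + 1L
  cat(sprintf("LayerProfile: %d layers (N=%d), alpha=%g (%s), P_v=%.3f\n",
              L, object@N, object@alpha, object@convention, object@proportion))
  cat("  rho:", paste(sprintf("%.3f", object@rho), collapse = " "), "\n")
  cat("  Z:  ", paste(sprintf("%.3f", object@z), collapse = " "), "\n")
})

setMethod("show", "FusedFeatures", function(object) {
  cat(sprintf("FusedFeatures over %d view(s), %d layers, P_m=%.3f\n",
              object@viewsUsed, length(object@omega), object@pMax))
})

setMethod("show", "ActionModel", function(object) {
  extra <- if (object@method == "ann")
    sprintf(", %d hidden nodes", object@hiddenNodes) else " (RBF kernel)"
  cat(sprintf("ActionModel: %s%s; L=%d, alpha=%g, flavor=%s\n",
              toupper(object@method), extra, object@layers, object@alpha,
              object@flavor))
})

setMethod("show", "EvalReport", function(object) {
  cat(sprintf("EvalReport: macro-average precision %.2f%%\n",
              object@averagePrecision))
  print(object@confusion)
  pc <- sprintf("%.2f%%%s", object@precision,
                ifelse(object@undefined, " (undefined -> 0)", ""))
  names(pc) <- rownames(object@confusion)
  print(pc, quote = FALSE)
})

setMethod("show", "SceneConfig", function(object) {
  cat(sprintf(paste0("SceneConfig: %d view(s) at [%s] deg, %dx%d px, ",
                     "%d background frames,\n  camera %.1f m / %g deg tilt, ",
                     "subject %.1f-%.1f m, flip %.3f, jitter %.1f\n"),
              length(object@viewAngles),
              paste(object@viewAngles, collapse = ", "),
              object@frameWidth, object@frameHeight, object@backgroundFrames,
              object@cameraHeight, object@cameraTilt,
              object@distanceRange[1], object@distanceRange[2],
              object@maskFlipRate, object@depthJitter))
})
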