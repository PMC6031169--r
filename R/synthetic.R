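#' @include AllClasses.R
NULL

#' Construct a SceneConfig
#'
#' Default conditions emulate the method's stated capture setup: two cameras
#' 90 degrees apart, 2 m above the floor, tilted 30 degrees below horizontal,
#' subject 3--5.5 m away, 40 leading background frames, background plane at
#' depth 240 (0 = near), 1% silhouette flip noise and 2-step depth jitter.
#'
#' @param viewAngles camera azimuths in degrees (default `c(0, 90)`).
#' @param cameraHeight camera height, m.
#' @param cameraTilt downward tilt, degrees.
#' @param distanceRange subject distance range, m.
#' @param frameWidth,frameHeight frame size, px.
#' @param backgroundFrames leading background-only frames.
#' @param framesPerAction action frames per sample.
#' @param maskFlipRate silhouette flip probability in [0, 0.05].
#' @param depthJitter depth noise s.d., 8-bit steps.
#' @param backgroundDepth background plane value.
#' @param ambiguousSitting render front-view sitting with a standing-like
#'   silhouette (depth alone carries the class).
#' @param identicalGeometry ablation switch: all classes render as standing.
#' @return A [SceneConfig-class].
#' @examples
#' sceneConfig(viewAngles = c(0, 90))
#' @export
sceneConfig <- function(viewAngles = c(0, 90), cameraHeight = 2,
                        cameraTilt = 30, distanceRange = c(3, 5.5),
                        frameWidth = 160L, frameHeight = 120L,
                        backgroundFrames = 40L, framesPerAction = 1L,
                        maskFlipRate = 0.01, depthJitter = 2,
                        backgroundDepth = 240L, ambiguousSitting = FALSE,
                        identicalGeometry = FALSE) {
  new("SceneConfig", viewAngles = as.numeric(viewAngles),
      cameraHeight = cameraHeight, cameraTilt = cameraTilt,
      distanceRange = as.numeric(distanceRange),
      frameWidth = as.integer(frameWidth),
      frameHeight = as.integer(frameHeight),
      backgroundFrames = as.integer(backgroundFrames),
      framesPerAction = as.integer(framesPerAction),
      maskFlipRate = maskFlipRate, depthJitter = depthJitter,
      backgroundDepth = as.integer(backgroundDepth),
      ambiguousSitting = ambiguousSitting,
      identicalGeometry = identicalGeometry)
}

#' Sample body parameters
#'
#' Draws a plausible adult body: stature 160--185 cm, shoulder width 40--48
#' cm, torso depth 22--28 cm, orientation from the five canonical azimuths
#' front (0), slant (45), side (90), rear-slant (135), rear (180) degrees.
#' Uses the current RNG state.
#'
#' @return Named list with `stature`, `shoulderWidth`, `torsoDepth`,
#'   `orientation` (degrees).
#' @export
sampleBodyParams <- function() {
  list(stature = stats::runif(1, 160, 185),
       shoulderWidth = stats::runif(1, 40, 48),
       torsoDepth = stats::runif(1, 22, 28),
       orientation = sample(c(0, 45, 90, 135, 180), 1))
}

# cm -> px conversion at a given camera distance (image-space pinhole scale)
.pxPerCm <- function(distance) 1.6 / distance

# paint an axis-aligned rectangle with a vertical depth ramp into the scene
.paintRect <- function(scene, mask, x0, x1, y0, y1, dTop, dBottom) {
  h <- nrow(scene); w <- ncol(scene)
  y0 <- max(1L, as.integer(round(y0))); y1 <- min(h, as.integer(round(y1)))
  x0 <- max(1L, as.integer(round(x0))); x1 <- min(w, as.integer(round(x1)))
  if (y1 < y0 || x1 < x0) return(list(scene = scene, mask = mask))
  rows <- y0:y1
  ramp <- if (length(rows) == 1L) dTop
          else dTop + (dBottom - dTop) * (seq_along(rows) - 1) / (length(rows) - 1)
  scene[rows, x0:x1] <- matrix(round(ramp), length(rows), x1 - x0 + 1L)
  mask[rows, x0:x1] <- 1L
  list(scene = scene, mask = mask)
}

# Compose the silhouette and depth of one action, noise-free, in image space.
# relAngle is the actor orientation relative to the camera azimuth; the
# projected body width blends shoulder width (frontal) and torso depth
# (lateral). Depth values: smaller = nearer; a mild top-to-bottom ramp
# stands in for the camera's downward tilt.
.renderBody <- function(action, relAngle, distance, body, config, cx) {
  h <- config@frameHeight; w <- config@frameWidth
  scene <- matrix(config@backgroundDepth, h, w)
  mask <- matrix(0L, h, w)
  if (config@identicalGeometry) action <- "standing_walking"
  s <- .pxPerCm(distance)
  rad <- relAngle * pi / 180
  frontness <- abs(cos(rad)); sideness <- abs(sin(rad))
  H <- max(12L, round(body$stature * s))
  W <- max(4L, round((body$shoulderWidth * frontness +
                      body$torsoDepth * sideness) * s))
  dv <- round(90 + (distance - config@distanceRange[1]) /
                max(0.5, diff(config@distanceRange)) * 110)
  dv <- min(225, max(40, dv))
  floorY <- round(h * (0.92 - 0.22 * (distance - config@distanceRange[1]) /
                         max(0.5, diff(config@distanceRange))))
  cxPx <- round(cx * w)
  out <- list(scene = scene, mask = mask)
  if (action == "standing_walking") {
    top <- floorY - H + 1L
    out <- .paintRect(out$scene, out$mask, cxPx - W / 2, cxPx + W / 2,
                      top, floorY, dv - 6, dv + 6)
  } else if (action == "sitting") {
    ambiguousFront <- config@ambiguousSitting && frontness > 0.9
    Hs <- round(if (ambiguousFront) 0.95 * H else 0.62 * H)
    top <- floorY - Hs + 1L
    torsoBottom <- top + round(0.50 * Hs)
    thighBottom <- top + round(0.72 * Hs)
    out <- .paintRect(out$scene, out$mask, cxPx - W / 2, cxPx + W / 2,
                      top, torsoBottom, dv - 4, dv)
    thighExt <- if (ambiguousFront) 0 else round(0.45 * H * sideness)
    out <- .paintRect(out$scene, out$mask, cxPx - W / 2,
                      cxPx + W / 2 + thighExt,
                      torsoBottom + 1L, thighBottom,
                      dv - 35 * frontness, dv - 35 * frontness)
    out <- .paintRect(out$scene, out$mask, cxPx - W * 0.28, cxPx + W * 0.28,
                      thighBottom + 1L, floorY, dv + 5, dv + 5)
  } else if (action == "stooping") {
    Hst <- round(0.58 * H)
    top <- floorY - Hst + 1L
    heapBottom <- top + round(0.45 * Hst)
    midBottom <- top + round(0.60 * Hst)
    out <- .paintRect(out$scene, out$mask, cxPx - W * 0.725, cxPx + W * 0.725,
                      top, heapBottom, dv - 28, dv - 10)
    out <- .paintRect(out$scene, out$mask, cxPx - W * 0.45, cxPx + W * 0.45,
                      heapBottom + 1L, midBottom, dv, dv)
    out <- .paintRect(out$scene, out$mask, cxPx - W * 0.275, cxPx + W * 0.275,
                      midBottom + 1L, floorY, dv + 6, dv + 6)
  } else if (action == "lying") {
    Hly <- max(10L, round(0.22 * H))
    Wly <- max(round(1.6 * Hly) + 2L,
               round(H * (0.55 + 0.35 * sideness)))
    top <- floorY - Hly + 1L
    out <- .paintRect(out$scene, out$mask, cxPx - Wly / 2, cxPx + Wly / 2,
                      top, floorY, dv, dv + 4)
  } else {
    stop("unknown action: ", action)
  }
  out$scene[out$scene < 1] <- 1
  out$scene[out$scene > 255] <- 255
  out
}

.addNoise <- function(scene, mask, config) {
  h <- nrow(scene); w <- ncol(scene)
  if (config@depthJitter > 0) {
    scene <- scene + round(stats::rnorm(h * w, 0, config@depthJitter))
  }
  if (config@maskFlipRate > 0) {
    flip <- matrix(stats::runif(h * w) < config@maskFlipRate, h, w)
    fgDepth <- round(stats::median(scene[mask == 1L]))
    if (!is.finite(fgDepth)) fgDepth <- 120
    scene[flip & mask == 0L] <- fgDepth
    scene[flip & mask == 1L] <- config@backgroundDepth
  }
  scene[scene < 0] <- 0L
  scene[scene > 255] <- 255L
  storage.mode(scene) <- "integer"
  scene
}

.renderBackgroundFrame <- function(config) {
  h <- config@frameHeight; w <- config@frameWidth
  scene <- matrix(as.numeric(config@backgroundDepth), h, w)
  if (config@depthJitter > 0)
    scene <- scene + round(stats::rnorm(h * w, 0, config@depthJitter))
  scene[scene < 0] <- 0; scene[scene > 255] <- 255
  storage.mode(scene) <- "integer"
  scene
}

#' Render a labeled action sequence for one camera view
#'
#' Composes the silhouette and depth gradients of one action as seen from a
#' given camera azimuth, quantized to 8-bit, with silhouette-flip and depth
#' jitter noise. Walking-style horizontal drift is applied across frames.
#' Deterministic for a fixed seed.
#'
#' @param action one of [actionClasses()].
#' @param body body parameters from [sampleBodyParams()] (or a compatible
#'   list).
#' @param viewAngle camera azimuth, degrees.
#' @param config a [SceneConfig-class].
#' @param distance subject distance, m (default: midpoint of the range).
#' @param cx horizontal subject position as a fraction of frame width.
#' @param nFrames number of frames (default `config@framesPerAction`).
#' @param seed RNG seed; `NULL` uses the current RNG state.
#' @return List of [DepthFrame-class] objects; attribute `"gtMask"` holds
#'   the noise-free ground-truth silhouette of the first frame.
#' @export
renderAction <- function(action, body, viewAngle, config,
                         distance = mean(config@distanceRange), cx = 0.5,
                         nFrames = config@framesPerAction, seed = NULL) {
  if (!action %in% actionClasses()) stop("unknown action: ", action)
  if (!is.null(seed)) set.seed(seed)
  relAngle <- body$orientation - viewAngle
  out <- vector("list", nFrames)
  gt <- NULL
  for (i in seq_len(nFrames)) {
    drift <- if (action == "standing_walking") 0.004 * (i - 1) else 0
    sc <- .renderBody(action, relAngle, distance, body, config, cx + drift)
    if (is.null(gt)) gt <- sc$mask
    noisy <- .addNoise(sc$scene, sc$mask, config)
    out[[i]] <- DepthFrame(noisy, frameIndex = i,
                           viewId = sprintf("view%g", viewAngle))
  }
  attr(out, "gtMask") <- gt
  out
}

#' ActionCorpus: a generated multiview labeled corpus
#'
#' @slot config the [SceneConfig-class] used.
#' @slot backgrounds per-view lists of background [DepthFrame-class]s
#'   (shared across samples: the cameras are static).
#' @slot samples list; each element has `label`, `meta` (orientation,
#'   distance, body) and `views`, a per-view list of action
#'   [DepthFrame-class]s.
#' @slot seed generator seed.
#' @export
setClass("ActionCorpus",
  slots = c(config = "SceneConfig", backgrounds = "list", samples = "list",
            seed = "integer"))

setMethod("show", "ActionCorpus", function(object) {
  labs <- vapply(object@samples, `[[`, character(1), "label")
  cat(sprintf("ActionCorpus: %d samples over %d view(s), seed %d\n",
              length(object@samples), length(object@config@viewAngles),
              object@seed))
  print(table(labs))
})

#' Generate a labeled multiview corpus
#'
#' Draws `samplesPerClass` samples of each of the four action classes, each
#' with its own body build, orientation, position, and distance, rendered
#' simultaneously from every configured view. Backgrounds (>= 40 frames per
#' view by default) are rendered once per view: the cameras are static. All
#' randomness flows from the single seed, so regeneration is byte-identical.
#'
#' If `dir` is given, the corpus is also written to disk in the standard
#' layout: one directory per (sample, view) holding the view's background
#' frames followed by its action frames as PGM, plus `labels.csv`
#' (`sequence, view, frame_index, label`) and `manifest.yaml` recording all
#' parameters and the seed.
#'
#' @param config a [SceneConfig-class].
#' @param samplesPerClass samples per action class (default 200).
#' @param seed generator seed.
#' @param dir optional output directory.
#' @param classes action classes to generate (default all four).
#' @return An [ActionCorpus-class] (invisibly carries the directory in
#'   attribute `"dir"` when written).
#' @seealso [readCorpus()], [processCorpus()]
#' @export
generateCorpus <- function(config = sceneConfig(), samplesPerClass = 200L,
                           seed = 1L, dir = NULL,
                           classes = actionClasses()) {
  set.seed(seed)
  backgrounds <- lapply(config@viewAngles, function(a)
    lapply(seq_len(config@backgroundFrames), function(i)
      DepthFrame(.renderBackgroundFrame(config), frameIndex = i,
                 viewId = sprintf("view%g", a))))
  names(backgrounds) <- sprintf("view%g", config@viewAngles)
  samples <- list()
  for (cl in classes) {
    for (i in seq_len(samplesPerClass)) {
      body <- sampleBodyParams()
      distance <- stats::runif(1, config@distanceRange[1],
                               config@distanceRange[2])
      cx <- stats::runif(1, 0.35, 0.65)
      views <- lapply(config@viewAngles, function(a)
        renderAction(cl, body, a, config, distance = distance, cx = cx))
      names(views) <- names(backgrounds)
      samples[[length(samples) + 1L]] <-
        list(label = cl, views = views,
             meta = list(orientation = body$orientation,
                         distance = distance, cx = cx))
    }
  }
  corpus <- new("ActionCorpus", config = config, backgrounds = backgrounds,
                samples = samples, seed = as.integer(seed))
  if (!is.null(dir)) writeCorpus(corpus, dir)
  corpus
}

#' Write an ActionCorpus to disk
#'
#' @param corpus an [ActionCorpus-class].
#' @param dir output directory (created).
#' @return `dir`, invisibly.
#' @export
writeCorpus <- function(corpus, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  cfg <- corpus@config
  labels <- NULL
  seqNames <- character(0)
  for (i in seq_along(corpus@samples)) {
    s <- corpus@samples[[i]]
    seqName <- sprintf("s%04d_%s", i, s$label)
    seqNames <- c(seqNames, seqName)
    for (v in names(s$views)) {
      vdir <- file.path(dir, seqName, v)
      dir.create(vdir, recursive = TRUE, showWarnings = FALSE)
      allFrames <- c(corpus@backgrounds[[v]], s$views[[v]])
      for (j in seq_along(allFrames))
        writeDepthFrame(allFrames[[j]], file.path(vdir, sprintf("%06d.pgm", j)))
      nAct <- length(s$views[[v]])
      labels <- rbind(labels, data.frame(
        sequence = seqName, view = v, frame_index = seq_len(nAct),
        label = s$label))
    }
  }
  utils::write.csv(labels, file.path(dir, "labels.csv"), row.names = FALSE)
  manifest <- list(
    views = lapply(seq_along(cfg@viewAngles), function(i)
      list(id = sprintf("view%g", cfg@viewAngles[i]),
           angle = cfg@viewAngles[i])),
    background_count = cfg@backgroundFrames,
    frames_per_action = cfg@framesPerAction,
    frame_width = cfg@frameWidth, frame_height = cfg@frameHeight,
    background_depth = cfg@backgroundDepth,
    camera_height_m = cfg@cameraHeight, camera_tilt_deg = cfg@cameraTilt,
    distance_range_m = cfg@distanceRange,
    mask_flip_rate = cfg@maskFlipRate, depth_jitter = cfg@depthJitter,
    ambiguous_sitting = cfg@ambiguousSitting,
    identical_geometry = cfg@identicalGeometry,
    seed = corpus@seed,
    labels_file = "labels.csv",
    sequences = as.list(seqNames))
  yaml::write_yaml(manifest, file.path(dir, "manifest.yaml"))
  invisible(dir)
}

#' Read a corpus written by writeCorpus
#'
#' Reconstructs an [ActionCorpus-class] from its manifest, labels file, and
#' frame files (background frames are taken from the first listed sequence
#' of each view; the cameras are static).
#'
#' @param dir corpus directory containing `manifest.yaml`.
#' @return An [ActionCorpus-class].
#' @export
readCorpus <- function(dir) {
  mf <- yaml::read_yaml(file.path(dir, "manifest.yaml"))
  labels <- utils::read.csv(file.path(dir, mf$labels_file))
  cfg <- sceneConfig(
    viewAngles = vapply(mf$views, `[[`, numeric(1), "angle"),
    cameraHeight = mf$camera_height_m, cameraTilt = mf$camera_tilt_deg,
    distanceRange = unlist(mf$distance_range_m),
    frameWidth = mf$frame_width, frameHeight = mf$frame_height,
    backgroundFrames = mf$background_count,
    framesPerAction = mf$frames_per_action,
    maskFlipRate = mf$mask_flip_rate, depthJitter = mf$depth_jitter,
    backgroundDepth = mf$background_depth,
    ambiguousSitting = isTRUE(mf$ambiguous_sitting),
    identicalGeometry = isTRUE(mf$identical_geometry))
  viewIds <- vapply(mf$views, `[[`, character(1), "id")
  bgN <- mf$background_count
  readSeqView <- function(seqName, v) {
    stream <- readDepthSequence(file.path(dir, seqName, v), viewId = v,
                                backgroundCount = bgN)
    stream
  }
  backgrounds <- lapply(viewIds, function(v) {
    st <- readSeqView(mf$sequences[[1]], v)
    st@frames[seq_len(bgN)]
  })
  names(backgrounds) <- viewIds
  samples <- lapply(mf$sequences, function(seqName) {
    lab <- unique(labels$label[labels$sequence == seqName])[1]
    views <- lapply(viewIds, function(v) {
      st <- readSeqView(seqName, v)
      st@frames[(bgN + 1L):length(st@frames)]
    })
    names(views) <- viewIds
    list(label = lab, views = views, meta = list())
  })
  new("ActionCorpus", config = cfg, backgrounds = backgrounds,
      samples = samples, seed = as.integer(mf$seed))
}
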