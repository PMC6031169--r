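#' @include AllClasses.R
NULL

.frameMatrix <- function(x) {
  if (is(x, "DepthFrame")) x@pixels else x
}

# lower median: for even n the smaller of the two central order statistics,
# so the reference is always an observed 8-bit value (quantile type 1).
.lowerMedian <- function(x) unname(stats::quantile(x, 0.5, type = 1, names = FALSE))

#' Build a per-pixel background model
#'
#' Summarizes the leading background-only frames of a static camera by the
#' per-pixel lower median depth and a robust spread (lower median of absolute
#' deviations about the reference). Deterministic for fixed input; with ties
#' (even frame counts) the lower of the two central values is taken.
#'
#' @param frames list of [DepthFrame-class] objects or depth matrices, or a
#'   [ViewStream-class] (its leading `backgroundCount` frames are used, or
#'   all frames if `backgroundCount` is 0).
#' @return A [BackgroundModel-class].
#' @seealso [extractForeground()]
#' @export
buildBackgroundModel <- function(frames) {
  if (is(frames, "ViewStream")) {
    b <- frames@backgroundCount
    frames <- if (b > 0L) frames@frames[seq_len(b)] else frames@frames
  }
  if (is.matrix(frames)) frames <- list(frames)
  if (length(frames) == 0L) stop("background model needs at least one frame")
  mats <- lapply(frames, .frameMatrix)
  d <- dim(mats[[1]])
  if (!all(vapply(mats, function(m) identical(dim(m), d), logical(1))))
    stop("background frames must share dimensions")
  n <- length(mats)
  if (n == 1L) {
    ref <- mats[[1]] + 0
    spr <- matrix(0, d[1], d[2])
  } else {
    stack <- matrix(unlist(mats, use.names = FALSE), nrow = d[1] * d[2], ncol = n)
    srt <- t(apply(stack, 1L, sort.int, method = "quick"))
    ref <- matrix(srt[, ceiling(n / 2)], d[1], d[2])
    dev <- abs(stack - as.vector(ref))
    srtDev <- t(apply(dev, 1L, sort.int, method = "quick"))
    spr <- matrix(srtDev[, ceiling(n / 2)], d[1], d[2])
  }
  new("BackgroundModel", reference = ref, spread = spr,
      frameCount = as.integer(n))
}

#' Extract the moving-foreground mask of a frame
#'
#' Default extractor: a pixel is foreground iff its absolute deviation from
#' the background reference exceeds `max(tau, spreadFactor * spread)`. The
#' extractor is pluggable: pass a function `(frame, model) -> binary matrix`
#' as `extractor` to substitute an adaptive mixture model or an externally
#' supplied mask (e.g. color-keyed segmentation).
#'
#' @param frame a [DepthFrame-class] or depth matrix.
#' @param model a [BackgroundModel-class] with matching dimensions.
#' @param tau absolute depth-difference threshold in 8-bit steps (default 15).
#' @param spreadFactor multiplier on the per-pixel spread (default 3).
#' @param extractor optional replacement extractor function.
#' @return Binary foreground matrix (1 = moving/foreground).
#' @examples
#' bg <- buildBackgroundModel(list(matrix(200L, 10, 10)))
#' fr <- matrix(200L, 10, 10); fr[3:5, 4:6] <- 80L
#' sum(extractForeground(fr, bg))
#' @export
extractForeground <- function(frame, model, tau = 15, spreadFactor = 3,
                              extractor = NULL) {
  m <- .frameMatrix(frame)
  if (!is.null(extractor)) {
    fg <- extractor(frame, model)
    storage.mode(fg) <- "integer"
    return(fg)
  }
  stopifnot(is(model, "BackgroundModel"))
  if (!identical(dim(m), dim(model@reference)))
    stop("frame and background model dimensions differ")
  thr <- pmax(tau, spreadFactor * model@spread)
  fg <- (abs(m - model@reference) > thr) * 1L
  storage.mode(fg) <- "integer"
  fg
}

# opening/closing with explicit zero padding: pixels outside the image are
# background (EBImage replicates the border instead, which would keep
# border-touching structures alive under erosion)
.morphPadded <- function(mask, kern, op) {
  pad <- max(dim(kern))
  nr <- nrow(mask); nc <- ncol(mask)
  big <- matrix(0L, nr + 2L * pad, nc + 2L * pad)
  big[pad + seq_len(nr), pad + seq_len(nc)] <- mask
  out <- op(big, kern)
  res <- (out[pad + seq_len(nr), pad + seq_len(nc), drop = FALSE] > 0) * 1L
  storage.mode(res) <- "integer"
  res
}

#' Morphological noise removal on a binary mask
#'
#' Opening then closing with a square structuring element of side `2r + 1`;
#' `r = 0` is the identity. Removes isolated speckle and fills small holes.
#'
#' @param mask binary matrix.
#' @param radius structuring-element radius `r >= 0` (default 1).
#' @return Denoised binary matrix.
#' @export
denoiseMask <- function(mask, radius = 1L) {
  stopifnot(radius >= 0)
  if (radius == 0L) return(mask)
  kern <- matrix(1L, 2L * radius + 1L, 2L * radius + 1L)
  opened <- .morphPadded(mask, kern, EBImage::opening)
  .morphPadded(opened, kern, EBImage::closing)
}

#' Mask a depth frame (AND of mask and depth)
#'
#' @param mask binary matrix.
#' @param frame [DepthFrame-class] or depth matrix of the same size.
#' @return Depth matrix equal to the frame where `mask == 1`, else 0.
#' @export
maskedDepth <- function(mask, frame) {
  m <- .frameMatrix(frame)
  if (!identical(dim(mask), dim(m)))
    stop("mask and frame dimensions differ")
  out <- m * (mask != 0)
  storage.mode(out) <- "integer"
  out
}

#' 8-connected component labeling
#'
#' EBImage's `bwlabel` uses 4-connectivity; labels are merged across diagonal
#' adjacencies with a union-find so that diagonally touching pixels share a
#' component, then relabeled 1..n.
#'
#' @param mask binary matrix.
#' @return Integer matrix of component labels (0 = background).
#' @keywords internal
labelComponents <- function(mask) {
  lab <- EBImage::bwlabel(mask != 0)
  lab <- matrix(as.integer(round(lab)), nrow(mask), ncol(mask))
  nlab <- max(lab)
  if (nlab <= 1L) return(lab)
  nr <- nrow(lab); nc <- ncol(lab)
  parent <- seq_len(nlab)
  findRoot <- function(i) {
    while (parent[i] != i) i <- parent[i]
    i
  }
  unite <- function(a, b) {
    ra <- findRoot(a); rb <- findRoot(b)
    if (ra != rb) parent[max(ra, rb)] <<- min(ra, rb)
  }
  collectPairs <- function(a, b) {
    sel <- a > 0L & b > 0L & a != b
    if (any(sel)) unique(cbind(a[sel], b[sel])) else NULL
  }
  prs <- rbind(
    if (nr > 1L && nc > 1L) collectPairs(lab[-nr, -nc], lab[-1, -1]),   # down-right
    if (nr > 1L && nc > 1L) collectPairs(lab[-nr, -1], lab[-1, -nc]))   # down-left
  if (!is.null(prs)) for (i in seq_len(nrow(prs))) unite(prs[i, 1], prs[i, 2])
  root <- vapply(seq_len(nlab), findRoot, integer(1))
  dense <- match(root, sort(unique(root)))
  out <- lab
  out[lab > 0L] <- dense[lab[lab > 0L]]
  out
}

.tightBbox <- function(mask) {
  rows <- which(rowSums(mask) > 0)
  cols <- which(colSums(mask) > 0)
  c(x = cols[1], y = rows[1],
    w = cols[length(cols)] - cols[1] + 1L,
    h = rows[length(rows)] - rows[1] + 1L)
}

# largest-area 8-connected component as a binary matrix; ties broken by the
# component whose topmost-then-leftmost pixel comes first
.selectComponent <- function(mask) {
  if (sum(mask != 0) == 0L) return(NULL)
  lab <- labelComponents(mask)
  areas <- tabulate(lab[lab > 0L])
  best <- which(areas == max(areas))
  if (length(best) > 1L) {
    firstPix <- t(vapply(best, function(l) {
      idx <- which(lab == l, arr.ind = TRUE)
      idx[order(idx[, 1], idx[, 2])[1], ]
    }, integer(2)))
    best <- best[order(firstPix[, 1], firstPix[, 2])[1]]
  }
  comp <- (lab == best) * 1L
  storage.mode(comp) <- "integer"
  comp
}

#' Locate the subject: largest connected component's bounding box
#'
#' Finds the largest-area 8-connected component of the mask; ties are broken
#' by the topmost-then-leftmost component. Returns its tight bounding box.
#' An empty mask yields `NULL`, the "no subject" signal (callers skip the
#' frame).
#'
#' @param mask binary matrix.
#' @return Integer `(x, y, w, h)` (1-based inclusive) or `NULL`.
#' @export
locateBlob <- function(mask) {
  comp <- .selectComponent(mask)
  if (is.null(comp)) return(NULL)
  as.integer(.tightBbox(comp))
}

#' Assemble a HumanBlob from a frame and its foreground mask
#'
#' Selects the largest 8-connected component (the single-subject assumption),
#' crops its tight bounding box, and masks the depth values. Pixels of other
#' components inside the box are excluded.
#'
#' @param frame [DepthFrame-class] or depth matrix.
#' @param mask binary foreground matrix (same size).
#' @return A [HumanBlob-class], or `NULL` if the mask is empty.
#' @export
extractBlob <- function(frame, mask) {
  comp <- .selectComponent(mask)
  if (is.null(comp)) return(NULL)
  bb <- as.integer(.tightBbox(comp))
  rows <- bb[2]:(bb[2] + bb[4] - 1L)
  cols <- bb[1]:(bb[1] + bb[3] - 1L)
  cmask <- comp[rows, cols, drop = FALSE]
  storage.mode(cmask) <- "integer"
  dp <- maskedDepth(cmask, .frameMatrix(frame)[rows, cols, drop = FALSE])
  new("HumanBlob", rawBbox = bb, bbox = bb, mask = cmask, depthProfile = dp)
}

#' Reject arm/hand parts from a blob
#'
#' The layered profile describes the trunk; thin protruding arms distort the
#' per-layer densities. Arms are suppressed by morphological opening of the
#' blob mask with a square element of side `max(1, round(strength * H_h))`
#' (default strength 0.05), after which the box is re-tightened and the depth
#' profile re-masked. `strength = 0` disables the step. The operation never
#' enlarges the mask; if it empties it, `NULL` (no subject) is returned.
#'
#' @param blob a [HumanBlob-class].
#' @param strength opening-element scale relative to blob height.
#' @return A [HumanBlob-class] with arms removed, or `NULL`.
#' @export
removeArms <- function(blob, strength = 0.05) {
  stopifnot(is(blob, "HumanBlob"), strength >= 0)
  if (strength == 0) return(blob)
  side <- max(1L, as.integer(round(strength * blob@bbox[4])))
  if (side == 1L) return(blob)
  kern <- matrix(1L, side, side)
  opened <- .morphPadded(blob@mask, kern, EBImage::opening)
  if (sum(opened) == 0L) return(NULL)
  # opening may split the silhouette; keep the largest remaining piece
  lab <- labelComponents(opened)
  areas <- tabulate(lab[lab > 0L])
  comp <- (lab == which.max(areas)) * 1L
  bbLocal <- .tightBbox(comp)
  rows <- bbLocal[2]:(bbLocal[2] + bbLocal[4] - 1L)
  cols <- bbLocal[1]:(bbLocal[1] + bbLocal[3] - 1L)
  cmask <- comp[rows, cols, drop = FALSE]
  storage.mode(cmask) <- "integer"
  dp <- maskedDepth(cmask, blob@depthProfile[rows, cols, drop = FALSE])
  newBbox <- as.integer(c(blob@bbox[1] + bbLocal[1] - 1L,
                          blob@bbox[2] + bbLocal[2] - 1L,
                          bbLocal[3], bbLocal[4]))
  new("HumanBlob", rawBbox = blob@rawBbox, bbox = newBbox, mask = cmask,
      depthProfile = dp)
}

#' Full single-frame preprocessing chain
#'
#' Foreground extraction against a background model, morphological noise
#' removal, largest-blob location, arm rejection, and depth masking — the
#' standard path from a raw depth frame to a [HumanBlob-class].
#'
#' @param frame [DepthFrame-class] or depth matrix.
#' @param model [BackgroundModel-class] for the frame's view.
#' @param tau foreground threshold in 8-bit steps (default 15).
#' @param denoiseRadius opening/closing radius (default 1).
#' @param armStrength arm-rejection opening scale (default 0.05).
#' @param extractor optional pluggable foreground extractor
#'   (see [extractForeground()]).
#' @return A [HumanBlob-class], or `NULL` when no subject is found.
#' @export
detectSubject <- function(frame, model, tau = 15, denoiseRadius = 1L,
                          armStrength = 0.05, extractor = NULL) {
  fg <- extractForeground(frame, model, tau = tau, extractor = extractor)
  fg <- denoiseMask(fg, radius = denoiseRadius)
  blob <- extractBlob(frame, fg)
  if (is.null(blob)) return(NULL)
  removeArms(blob, strength = armStrength)
}
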