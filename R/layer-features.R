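#' @include AllClasses.R
NULL

# Degree-6 regression mapping 8-bit depth steps to real distance in cm,
# coefficients ordered from x^6 down to the constant term.
.DEPTH_POLY <- c(1.2512e-10, -1.0370e-7, 3.5014e-5, -0.0061, 0.5775,
                 -27.6342, 5.6759e2)

#' Convert an 8-bit depth value to real distance (cm)
#'
#' Depth sensors report quantized disparity-like values whose relation to
#' metric distance is nonlinear: one step near the camera spans far less real
#' distance than one step far away. A fitted degree-6 polynomial maps the
#' 8-bit value to centimeters; it is evaluated in double precision using
#' Horner's scheme, exactly as fitted, without clamping (the polynomial is
#' not monotone over the whole 0--255 range; its fitted calibration domain is
#' the sensor's working range).
#'
#' @param x depth value(s) in [0, 255] (real values allowed, e.g. layer
#'   means).
#' @return Distance(s) in cm.
#' @examples
#' depthToCm(0)    # 567.59, the calibration constant
#' depthToCm(128)
#' @export
depthToCm <- function(x) {
  if (any(is.na(x)) || any(x < 0) || any(x > 255))
    stop("depth values must lie in [0, 255]")
  y <- rep(.DEPTH_POLY[1], length(x))
  for (i in 2:7) y <- y * x + .DEPTH_POLY[i]
  y
}

#' Layer row bounds of a blob
#'
#' Splits the `H_h` rows of a blob's bounding box into `2N + 1` equal-height
#' horizontal layers indexed `k = -N` (top) to `+N` (bottom). The bounds are
#' `y_T[k] = floor(H_h (k + N) / (2N + 1)) + 1` and
#' `y_B[k] = floor(H_h (k + N + 1) / (2N + 1))`, 1-based inclusive blob rows;
#' flooring before the `+1` makes the ranges a contiguous exact partition of
#' `1..H_h`.
#'
#' @param Hh blob height in rows (`>= 2N + 1`).
#' @param N maximum upper/lower layer count (`>= 0`).
#' @return Integer matrix with `2N + 1` rows and columns `yT`, `yB`;
#'   rownames give the layer index `k`.
#' @examples
#' layerBounds(30, 1)
#' @export
layerBounds <- function(Hh, N) {
  stopifnot(N >= 0, Hh >= 1)
  L <- 2L * N + 1L
  if (Hh < L)
    stop("too few rows: blob height ", Hh, " cannot carry ", L, " layers")
  k <- seq.int(-N, N)
  yT <- floor(Hh * (k + N) / L) + 1L
  yB <- floor(Hh * (k + N + 1) / L)
  out <- cbind(yT = as.integer(yT), yB = as.integer(yB))
  rownames(out) <- as.character(k)
  out
}

.maxNormalize <- function(v) {
  mx <- max(v)
  if (mx <= 0) return(rep(0, length(v)))
  v / mx
}

#' Per-layer silhouette density
#'
#' `rho'[k]` counts the foreground pixels of the blob mask whose row falls in
#' layer `k`; `rho[k]` is `rho'[k]` normalized by its maximum over the
#' layers of the same blob, so fused views are comparable regardless of the
#' subject's distance. An all-empty profile normalizes to zeros.
#'
#' @param blob a [HumanBlob-class] (or a binary mask matrix).
#' @param bounds layer bounds from [layerBounds()] built for the blob height.
#' @return List with `rhoRaw` (counts) and `rho` (normalized, in [0, 1]).
#' @export
layerDensity <- function(blob, bounds) {
  mask <- if (is(blob, "HumanBlob")) blob@mask else blob
  rowCounts <- rowSums(mask != 0)
  rhoRaw <- vapply(seq_len(nrow(bounds)), function(i)
    sum(rowCounts[bounds[i, "yT"]:bounds[i, "yB"]]), numeric(1))
  list(rhoRaw = rhoRaw, rho = .maxNormalize(rhoRaw))
}

#' Per-layer real-range depth
#'
#' For each non-empty layer, the mean foreground depth value (layer depth sum
#' divided by the layer's raw pixel count) is converted to centimeters with
#' [depthToCm()], giving `D'[k]`; empty layers contribute `D'[k] = 0` so that
#' downstream normalization stays defined. `D[k]` is `D'[k]` normalized by
#' its maximum over layers.
#'
#' @param blob a [HumanBlob-class] (its masked depth profile is used).
#' @param bounds layer bounds from [layerBounds()].
#' @param rhoRaw raw per-layer counts from [layerDensity()].
#' @return List with `depthRaw` (cm) and `depth` (normalized, in [0, 1]).
#' @export
layerRealDepth <- function(blob, bounds, rhoRaw) {
  dp <- if (is(blob, "HumanBlob")) blob@depthProfile else blob
  rowTotals <- rowSums(dp)
  depthRaw <- vapply(seq_len(nrow(bounds)), function(i) {
    if (rhoRaw[i] <= 0) return(0)
    meanVal <- sum(rowTotals[bounds[i, "yT"]:bounds[i, "yB"]]) / rhoRaw[i]
    depthToCm(meanVal)
  }, numeric(1))
  list(depthRaw = depthRaw, depth = .maxNormalize(depthRaw))
}

#' Inverse depth of layers
#'
#' Min-max flip of the normalized real-range depth:
#' `D_i[k] = (D[k] - max D) / (min D - max D)`, so the layer nearest the
#' camera scores 1 and the farthest 0. This reveals the "hidden volume" of
#' body parts pointing at the camera (thighs when sitting front-on, the back
#' when stooping). A flat profile (`max D == min D`) maps to all zeros.
#'
#' @param depth normalized depth values in [0, 1].
#' @return Inverse depth values in [0, 1].
#' @export
inverseDepth <- function(depth) {
  mx <- max(depth); mn <- min(depth)
  if (mx == mn) return(rep(0, length(depth)))
  (depth - mx) / (mn - mx)
}

#' Weighted depth density of layers
#'
#' `Q[k] = D_i[k] * rho[k]` is the inverse-depth density; the weighted depth
#' density blends it with the plain density under the weight `alpha`. Two
#' conventions are exposed: `"printed"` computes
#' `Z = (1 - alpha) Q + alpha rho`, `"prose"` swaps the weights
#' (`Z = alpha Q + (1 - alpha) rho`, i.e. `alpha` is the share given to the
#' inverse-depth term). Default `"printed"`.
#'
#' @param rho normalized layer densities.
#' @param depthInv inverse depths from [inverseDepth()].
#' @param alpha blend weight in [0, 1] (default 0.9).
#' @param convention `"printed"` or `"prose"`.
#' @return List with `q` and `z`, both in [0, 1].
#' @export
weightedDensity <- function(rho, depthInv, alpha = 0.9,
                            convention = c("printed", "prose")) {
  convention <- match.arg(convention)
  if (length(alpha) != 1L || is.na(alpha) || alpha < 0 || alpha > 1)
    stop("alpha must be a single value in [0, 1]")
  q <- depthInv * rho
  z <- if (convention == "printed") (1 - alpha) * q + alpha * rho
       else alpha * q + (1 - alpha) * rho
  list(q = q, z = z)
}

#' Proportion value of a blob
#'
#' The width/height ratio `P_v = W_h / H_h` of the blob's bounding box, the
#' global feature separating horizontal postures (lying, `P_v` large) from
#' vertical ones.
#'
#' @param blob a [HumanBlob-class], or a numeric `(x, y, w, h)` box.
#' @return `P_v` as a real number.
#' @export
proportionValue <- function(blob) {
  bb <- if (is(blob, "HumanBlob")) blob@bbox else blob
  if (bb[4] <= 0) stop("blob height must be >= 1")
  bb[3] / bb[4]
}

#' Full per-view layered feature profile
#'
#' Computes the complete layered description of one blob: layer bounds,
#' densities, real-range depths, inverse depths, `Q`, `Z`, and the proportion
#' value, packaged as a [LayerProfile-class].
#'
#' @param blob a [HumanBlob-class].
#' @param layers odd number of layers `L = 2N + 1` (default 3).
#' @param alpha blend weight for [weightedDensity()] (default 0.9).
#' @param convention `"printed"` or `"prose"` (see [weightedDensity()]).
#' @return A [LayerProfile-class], or `NULL` if the blob is shorter than
#'   `layers` rows (treated as "no subject" for this configuration).
#' @examples
#' mask <- matrix(1L, 30, 10)
#' frame <- matrix(100L, 40, 40); frame[5:34, 3:12] <- 60L
#' blob <- extractBlob(frame, {m <- matrix(0L, 40, 40); m[5:34, 3:12] <- 1L; m})
#' layerProfile(blob, layers = 3)
#' @export
layerProfile <- function(blob, layers = 3L, alpha = 0.9,
                         convention = c("printed", "prose")) {
  convention <- match.arg(convention)
  stopifnot(is(blob, "HumanBlob"))
  if (layers %% 2L != 1L || layers < 1L) stop("layers must be odd and >= 1")
  N <- (as.integer(layers) - 1L) %/% 2L
  if (blob@bbox[4] < layers) return(NULL)
  bounds <- layerBounds(blob@bbox[4], N)
  dens <- layerDensity(blob, bounds)
  dep <- layerRealDepth(blob, bounds, dens$rhoRaw)
  di <- inverseDepth(dep$depth)
  wd <- weightedDensity(dens$rho, di, alpha = alpha, convention = convention)
  new("LayerProfile", N = N, rhoRaw = dens$rhoRaw, rho = dens$rho,
      depthRaw = dep$depthRaw, depth = dep$depth, depthInv = di,
      q = wd$q, z = wd$z, alpha = alpha, convention = convention,
      proportion = proportionValue(blob))
}
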