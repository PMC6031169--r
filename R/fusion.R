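#' @include AllClasses.R
NULL

.checkViewList <- function(lst, what) {
  if (length(lst) == 0L) stop("need at least one view to fuse ", what)
  lens <- lengths(lst)
  if (any(lens != lens[1]))
    stop("per-view ", what, " arrays must share length (got ",
         paste(lens, collapse = ", "), ")")
  invisible(lens[1])
}

#' Fuse layer densities across views (mass of dimension)
#'
#' `omega[k]` is the per-layer product of the normalized densities over all
#' views. With a single view it is the identity; any view with `rho[k] = 0`
#' annihilates layer `k`.
#'
#' @param rhoPerView list of per-view normalized density vectors (equal
#'   lengths).
#' @return Numeric `omega` vector.
#' @export
fuseDensity <- function(rhoPerView) {
  .checkViewList(rhoPerView, "density")
  Reduce(`*`, rhoPerView)
}

#' Fuse weighted depth densities across views (weighted mass of dimension)
#'
#' `omegaBar[k]` is the per-layer product of the weighted depth densities
#' `Z[k]` over all views.
#'
#' @param zPerView list of per-view `Z` vectors (equal lengths).
#' @return Numeric `omegaBar` vector.
#' @export
fuseWeighted <- function(zPerView) {
  .checkViewList(zPerView, "weighted density")
  Reduce(`*`, zPerView)
}

#' Maximum proportion value over views
#'
#' @param pPerView numeric vector (or list) of per-view proportion values.
#' @return The maximum, `P_m`.
#' @export
maxProportion <- function(pPerView) {
  p <- unlist(pPerView, use.names = FALSE)
  if (length(p) == 0L) stop("need at least one view's proportion value")
  max(p)
}

#' Fuse per-view layer profiles into one FusedFeatures object
#'
#' Views where no subject was detected should be dropped by the caller
#' before fusing (passing `NULL` entries drops them here, with the view
#' count shrinking accordingly) rather than contributing zeros that would
#' annihilate every layer.
#'
#' @param profiles list of [LayerProfile-class] objects (NULLs are dropped).
#' @return A [FusedFeatures-class], or `NULL` if no view has a profile.
#' @export
fuseViews <- function(profiles) {
  profiles <- Filter(Negate(is.null), profiles)
  if (length(profiles) == 0L) return(NULL)
  stopifnot(all(vapply(profiles, is, logical(1), "LayerProfile")))
  omega <- fuseDensity(lapply(profiles, slot, "rho"))
  omegaBar <- fuseWeighted(lapply(profiles, slot, "z"))
  pMax <- maxProportion(vapply(profiles, slot, numeric(1), "proportion"))
  new("FusedFeatures", omega = omega, omegaBar = omegaBar, pMax = pMax,
      viewsUsed = length(profiles))
}

#' @describeIn fuseViews Assemble the classifier feature vector
#'   `[layer -N .. +N, P_m]` (length `2N + 2`) from fused features; flavor
#'   `"depth"` uses `omegaBar`, `"nondepth"` uses `omega`.
#' @param object a [FusedFeatures-class].
#' @param flavor `"depth"` or `"nondepth"`.
#' @export
setMethod("featureVector", "FusedFeatures",
  function(object, flavor = c("depth", "nondepth")) {
    flavor <- match.arg(flavor)
    layerPart <- if (flavor == "depth") object@omegaBar else object@omega
    c(layerPart, object@pMax)
  })
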