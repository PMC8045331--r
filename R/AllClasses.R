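#' @useDynLib ctvMargins, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @import methods
NULL

#' A 3D binary mask on a voxel grid with physical geometry
#'
#' \code{BinaryVolume} holds a boolean occupancy array together with the
#' affine geometry that places every voxel in patient coordinates: the voxel
#' spacing in mm, the physical position of the center of voxel
#' \code{[1, 1, 1]}, and an orthonormal matrix whose columns map the three
#' index axes to patient axes. The patient coordinate convention throughout
#' the package is LPS (+x Left, +y Posterior, +z Superior), the dominant
#' convention in radiotherapy imaging.
#'
#' The index-to-physical mapping is
#' \code{physical = origin + axisDirections \%*\% (spacing * (index - 1))}
#' with 1-based voxel indices.
#'
#' @slot occupancy logical 3D array; \code{TRUE} = foreground.
#' @slot spacing numeric(3), mm per voxel along each index axis, all > 0.
#' @slot origin numeric(3), mm, physical position of the center of voxel
#'   \code{[1, 1, 1]}.
#' @slot axisDirections 3x3 orthonormal matrix (columns are unit vectors,
#'   determinant +-1).
#'
#' @seealso [BinaryVolume()], [gridCompatible()], [extractSurface()],
#'   [occupancyAt()]
#' @export
setClass("BinaryVolume",
  representation(
    occupancy = "array",
    spacing = "numeric",
    origin = "numeric",
    axisDirections = "matrix"
  )
)

setValidity("BinaryVolume", function(object) {
  msgs <- character(0)
  occ <- object@occupancy
  if (!is.logical(occ) || length(dim(occ)) != 3L)
    msgs <- c(msgs, "occupancy must be a logical 3D array")
  if (length(object@spacing) != 3L || any(!is.finite(object@spacing)) ||
      any(object@spacing <= 0))
    msgs <- c(msgs, "spacing must be three positive finite values (mm)")
  if (length(object@origin) != 3L || any(!is.finite(object@origin)))
    msgs <- c(msgs, "origin must be three finite values (mm)")
  A <- object@axisDirections
  if (!is.numeric(A) || !all(dim(A) == c(3L, 3L))) {
    msgs <- c(msgs, "axisDirections must be a 3x3 numeric matrix")
  } else {
    if (max(abs(crossprod(A) - diag(3))) > 1e-9)
      msgs <- c(msgs, "axisDirections must be orthonormal (tolerance 1e-9)")
  }
  if (length(msgs)) msgs else TRUE
})

#' A labeled direction in patient coordinates
#'
#' A unit vector in LPS patient coordinates together with a short label
#' (e.g. \code{"SA"} for superior-anterior) and a route-of-spread class used
#' for study-level pooling (e.g. \code{"intraosseous"}, \code{"extraosseous"}).
#'
#' @slot label character(1), non-empty; must be unique within one case.
#' @slot vector numeric(3), unit length (tolerance 1e-9), LPS coordinates.
#' @slot routeClass character(1), free-form route-of-spread class.
#'
#' @seealso [DirectionSpec()], [directionFromLabel()]
#' @export
setClass("DirectionSpec",
  representation(label = "character", vector = "numeric",
                 routeClass = "character")
)

setValidity("DirectionSpec", function(object) {
  msgs <- character(0)
  if (length(object@label) != 1L || !nzchar(object@label))
    msgs <- c(msgs, "label must be a single non-empty string")
  v <- object@vector
  if (length(v) != 3L || any(!is.finite(v)))
    msgs <- c(msgs, "vector must be three finite values")
  else if (abs(sqrt(sum(v^2)) - 1) > 1e-9)
    msgs <- c(msgs, "vector must be unit length (tolerance 1e-9)")
  if (length(object@routeClass) != 1L)
    msgs <- c(msgs, "routeClass must be a single string")
  if (length(msgs)) msgs else TRUE
})

#' Surface voxels of a binary volume
#'
#' The discretized surface of a mask: every foreground voxel with at least
#' one 6-connected neighbor that is background or outside the grid, reported
#' as physical voxel-center coordinates plus the corresponding 1-based voxel
#' indices.
#'
#' @slot points numeric matrix, n x 3, physical mm coordinates (LPS).
#' @slot indices integer matrix, n x 3, 1-based voxel indices.
#'
#' @seealso [extractSurface()]
#' @export
setClass("SurfacePointSet",
  representation(points = "matrix", indices = "matrix")
)

setValidity("SurfacePointSet", function(object) {
  if (nrow(object@points) != nrow(object@indices))
    return("points and indices must have the same number of rows")
  if (ncol(object@points) != 3L || ncol(object@indices) != 3L)
    return("points and indices must have 3 columns")
  if (anyDuplicated(object@indices))
    return("duplicate surface voxels")
  TRUE
})

#' Expansion vectors cast in one direction
#'
#' The set of expansion vectors obtained by casting a ray parallel to one
#' direction from every GTV surface point: each vector runs from the GTV
#' boundary crossing to the CTV boundary crossing along the ray. Rays that
#' re-enter the GTV interior (or cross a barrier mask) before reaching the
#' CTV boundary are rejected and only counted; surface points that already
#' lie outside the CTV contribute a clamped zero-length vector.
#'
#' @slot direction the [DirectionSpec-class] that was cast.
#' @slot starts,ends numeric n x 3 matrices, physical mm endpoints of the
#'   retained vectors (clamped vectors have \code{start == end}).
#' @slot lengths numeric(n), vector lengths in mm, >= 0.
#' @slot nCandidates number of surface points examined.
#' @slot nRejectedInterior rays rejected for GTV-interior crossing.
#' @slot nRejectedBarrier rays rejected for barrier crossing.
#' @slot nClamped vectors clamped to zero length (start outside the CTV).
#' @slot nFailed rays whose GTV exit could not be bracketed (grazing rays);
#'   these are logged, not silently dropped.
#'
#' @seealso [directionalMargin()], [castExpansionVector()]
#' @export
setClass("ExpansionVectorSet",
  representation(
    direction = "DirectionSpec",
    starts = "matrix", ends = "matrix", lengths = "numeric",
    nCandidates = "integer", nRejectedInterior = "integer",
    nRejectedBarrier = "integer", nClamped = "integer", nFailed = "integer"
  )
)

setValidity("ExpansionVectorSet", function(object) {
  msgs <- character(0)
  n <- length(object@lengths)
  if (nrow(object@starts) != n || nrow(object@ends) != n)
    msgs <- c(msgs, "starts/ends must have one row per length")
  if (any(object@lengths < 0))
    msgs <- c(msgs, "lengths must be non-negative")
  if (n > 0) {
    d <- object@ends - object@starts
    len <- sqrt(rowSums(d^2))
    if (max(abs(len - object@lengths)) > 1e-6)
      msgs <- c(msgs, "lengths must equal |end - start| within 1e-6 mm")
    # vectors below the caster's crossing resolution are zero-length in
    # substance; their fp direction is cancellation noise
    nz <- object@lengths > 1e-7
    if (any(nz)) {
      u <- d[nz, , drop = FALSE] / len[nz]
      cosang <- pmin(1, pmax(-1, u %*% object@direction@vector))
      if (max(acos(cosang)) > 1e-6)
        msgs <- c(msgs, "vectors must be parallel to the direction (1e-6 rad)")
    }
  }
  if (object@nCandidates <
      n + object@nRejectedInterior + object@nRejectedBarrier)
    msgs <- c(msgs, "candidate count below retained + rejected counts")
  if (length(msgs)) msgs else TRUE
})

#' Directional margin of a GTV/CTV pair
#'
#' The directional margin in one direction: the median of the expansion
#' vector lengths (even count: mean of the two central order statistics),
#' together with the full vector set for diagnostics.
#'
#' @slot direction the [DirectionSpec-class] evaluated.
#' @slot marginMm median expansion vector length, mm.
#' @slot vectorSet the underlying [ExpansionVectorSet-class].
#' @slot nUsed number of vectors entering the median (accepted + clamped).
#'
#' @seealso [directionalMargin()]
#' @export
setClass("DirectionalMarginResult",
  representation(direction = "DirectionSpec", marginMm = "numeric",
                 vectorSet = "ExpansionVectorSet", nUsed = "integer")
)

setValidity("DirectionalMarginResult", function(object) {
  msgs <- character(0)
  ls <- object@vectorSet@lengths
  if (object@nUsed < 1L || object@nUsed != length(ls))
    msgs <- c(msgs, "nUsed must equal the number of retained vectors (>= 1)")
  if (length(ls)) {
    if (abs(object@marginMm - stats::median(ls)) > 1e-9)
      msgs <- c(msgs, "marginMm must equal the median vector length")
    if (object@marginMm < min(ls) - 1e-12 || object@marginMm > max(ls) + 1e-12)
      msgs <- c(msgs, "marginMm must lie within [min, max] of the lengths")
  }
  if (length(msgs)) msgs else TRUE
})

#' Interobserver margin deviation in one direction
#'
#' Per-expert directional margins against a common GTV and their coefficient
#' of variation (sample SD / mean), the direction-dependent interobserver
#' variability measure. When every expert margin is zero the CV is defined
#' as 0.
#'
#' @slot direction the [DirectionSpec-class] evaluated.
#' @slot perExpertMarginsMm numeric(K), K >= 2, per-expert margins in mm.
#' @slot cv coefficient of variation, dimensionless, >= 0.
#'
#' @seealso [marginDeviation()]
#' @export
setClass("MarginDeviationResult",
  representation(direction = "DirectionSpec",
                 perExpertMarginsMm = "numeric", cv = "numeric")
)

setValidity("MarginDeviationResult", function(object) {
  m <- object@perExpertMarginsMm
  if (length(m) < 2L) return("at least two expert margins are required")
  mu <- mean(m)
  expected <- if (mu > 0) stats::sd(m) / mu else 0
  if (abs(object@cv - expected) > 1e-9)
    return("cv must equal sample SD / mean of the per-expert margins")
  TRUE
})

#' STAPLE consensus of an expert mask ensemble
#'
#' Result of the STAPLE expectation-maximization estimate of a consensus
#' segmentation: the voxel-wise posterior probability of foreground, the
#' per-rater sensitivity/specificity estimates, and the consensus mask
#' obtained by thresholding the posterior.
#'
#' @slot probabilityMap numeric 3D array in [0, 1], posterior foreground
#'   probability per voxel (0 outside the dilated union bounding box).
#' @slot sensitivities,specificities numeric(K) per-rater performance
#'   estimates in (0, 1].
#' @slot consensusMask [BinaryVolume-class]; foreground iff posterior >=
#'   \code{threshold}.
#' @slot threshold the posterior threshold used.
#' @slot nIterations EM iterations performed.
#' @slot converged logical; TRUE when the mean absolute posterior change
#'   fell below the tolerance.
#'
#' @seealso [stapleConsensus()]
#' @export
setClass("StapleResult",
  representation(
    probabilityMap = "array", sensitivities = "numeric",
    specificities = "numeric", consensusMask = "BinaryVolume",
    threshold = "numeric", nIterations = "integer", converged = "logical"
  )
)

setValidity("StapleResult", function(object) {
  p <- object@probabilityMap
  if (any(p < -1e-12 | p > 1 + 1e-12))
    return("probabilityMap values must lie in [0, 1]")
  if (!identical(dim(p), dim(object@consensusMask@occupancy)))
    return("probabilityMap and consensusMask dimensions differ")
  if (!identical(unname(object@consensusMask@occupancy),
                 unname(p >= object@threshold)))
    return("consensusMask must be probabilityMap >= threshold")
  TRUE
})

#' Per-case directional margin analysis
#'
#' One case's results: per configured direction, the consensus margin (GTV
#' vs consensus CTV), the margin deviation (GTV vs each expert CTV), and
#' ray-casting diagnostics, with per-direction failures recorded rather than
#' aborting the case.
#'
#' @slot caseId character(1) case identifier.
#' @slot table data.frame with one row per configured direction; columns
#'   \code{case_id}, \code{direction_label}, \code{route_class},
#'   \code{consensus_margin_mm}, \code{margin_cv}, \code{n_vectors},
#'   \code{n_rejected_interior}, \code{n_rejected_barrier}, \code{n_clamped},
#'   \code{status}, \code{message}.
#' @slot details named list of per-direction result objects
#'   ([DirectionalMarginResult-class] / [MarginDeviationResult-class]) for
#'   directions that succeeded.
#'
#' @seealso [runCase()], [summarizeStudy()]
#' @export
setClass("CaseResult",
  representation(caseId = "character", table = "data.frame",
                 details = "list")
)

#' Analytic phantom with known ground-truth margins
#'
#' A synthetic GTV/CTV pair generated from analytic shapes: the GTV is a
#' distance-function solid rasterized at voxel centers and the CTV is the
#' exact direction-dependent physical expansion of the same analytic shape
#' (not a morphological dilation of the mask), so the true margin in each
#' requested direction is known in mm independent of the grid resolution.
#'
#' @slot gtv,ctv [BinaryVolume-class] masks on a common grid.
#' @slot truth data.frame with columns \code{label}, \code{route_class},
#'   \code{vx}, \code{vy}, \code{vz}, \code{true_margin_mm},
#'   \code{barrier_excluded} for every requested direction.
#' @slot shape list describing the analytic GTV (type + dimensions, mm).
#' @slot expansion list describing the expansion rule.
#' @slot barrier \code{NULL} or a [BinaryVolume-class] barrier mask.
#'
#' @seealso [makePhantom()], [makeExpertEnsemble()]
#' @export
setClass("Phantom",
  representation(gtv = "BinaryVolume", ctv = "BinaryVolume",
                 truth = "data.frame", shape = "list", expansion = "list",
                 barrier = "ANY")
)
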