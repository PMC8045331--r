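# ---- analytic shapes -------------------------------------------------------
# All shapes are signed-distance solids evaluated at voxel centers; outside
# the solid the signed distance is the exact Euclidean distance, so an
# isotropic physical expansion by m mm is exactly {sdf <= m}.

.sdfSphere <- function(P, center, radius) {
  sqrt(rowSums(sweep(P, 2L, center, `-`)^2)) - radius
}

.sdfBox <- function(P, lower, upper) {
  q <- pmax(sweep(-P, 2L, lower, `+`), sweep(P, 2L, -upper, `+`))
  outside <- sqrt(rowSums(pmax(q, 0)^2))
  inside <- pmin(apply(q, 1L, max), 0)
  outside + inside
}

.sdfSlab <- function(P, axis, lower, upper) {
  x <- P[, axis]
  pmax(lower - x, x - upper)
}

# U shape = union of base box and two prongs separated along x, open at +z.
.ushapeBoxes <- function(size) {
  lo <- size$lower; hi <- size$upper
  w <- size$prongWidth; h <- size$baseHeight
  list(
    base = list(lower = lo, upper = c(hi[1], hi[2], lo[3] + h)),
    left = list(lower = c(lo[1], lo[2], lo[3] + h),
                upper = c(lo[1] + w, hi[2], hi[3])),
    right = list(lower = c(hi[1] - w, lo[2], lo[3] + h),
                 upper = hi)
  )
}

.sdfUshape <- function(P, size) {
  boxes <- .ushapeBoxes(size)
  do.call(pmin, lapply(boxes, function(b) .sdfBox(P, b$lower, b$upper)))
}

.shapeSdf <- function(shape, size, P) {
  switch(shape,
    sphere = .sdfSphere(P, size$center, size$radius),
    box = .sdfBox(P, size$lower, size$upper),
    slab = .sdfSlab(P, size$axis, size$lower, size$upper),
    ushape = .sdfUshape(P, size),
    ctvStop("ctv_label_parse", sprintf("unknown phantom shape \"%s\"", shape))
  )
}

# Normalize an expansion rule to list(type, margins).
.checkExpansion <- function(shape, expansion) {
  type <- expansion$type
  m <- as.numeric(expansion$margins)
  ok <- switch(type,
    isotropic = length(m) == 1L,
    peraxis = length(m) == 3L && shape %in% c("sphere", "box", "slab"),
    signed = length(m) == 6L && shape %in% c("box", "slab"),
    FALSE)
  if (!isTRUE(ok))
    ctvStop("ctv_label_parse",
            sprintf("expansion type \"%s\" with %d margin(s) is not supported for shape \"%s\"",
                    type, length(m), shape))
  if (any(m < 0)) ctvStop("ctv_label_parse", "margins must be non-negative")
  list(type = type, margins = m)
}

# Signed margins as (lowerGrowth, upperGrowth) 3-vectors.
.signedGrowth <- function(expansion) {
  m <- expansion$margins
  switch(expansion$type,
    isotropic = list(lo = rep(m, 3), hi = rep(m, 3)),
    peraxis = list(lo = m, hi = m),
    signed = list(lo = m[c(1, 3, 5)], hi = m[c(2, 4, 6)])
  )
}

# Is a point inside the analytically expanded solid?
.insideExpanded <- function(shape, size, expansion, P) {
  type <- expansion$type
  m <- expansion$margins
  if (type == "isotropic")
    return(.shapeSdf(shape, size, P) <= m)
  g <- .signedGrowth(expansion)
  if (shape == "sphere") { # peraxis: ellipsoid with grown semi-axes
    rel <- sweep(P, 2L, size$center, `-`)
    ax <- size$radius + m
    rowSums(sweep(rel, 2L, ax, `/`)^2) <= 1
  } else if (shape == "box") {
    .sdfBox(P, size$lower - g$lo, size$upper + g$hi) <= 0
  } else { # slab
    a <- size$axis
    .sdfSlab(P, a, size$lower - g$lo[a], size$upper + g$hi[a]) <= 0
  }
}

# Analytic bounding box of the expanded solid (per axis; Inf = unbounded,
# i.e. the slab's in-plane axes, which simply fill the grid).
.ctvBounds <- function(shape, size, expansion) {
  g <- .signedGrowth(expansion)
  switch(shape,
    sphere = {
      r <- size$radius + if (expansion$type == "isotropic")
        rep(expansion$margins, 3) else expansion$margins
      list(lo = size$center - r, hi = size$center + r)
    },
    box = list(lo = size$lower - g$lo, hi = size$upper + g$hi),
    slab = {
      lo <- rep(-Inf, 3); hi <- rep(Inf, 3); a <- size$axis
      lo[a] <- size$lower - g$lo[a]; hi[a] <- size$upper + g$hi[a]
      list(lo = lo, hi = hi)
    },
    ushape = list(lo = size$lower - expansion$margins,
                  hi = size$upper + expansion$margins)
  )
}

# True margin applied along a unit direction d, NA when the expansion rule
# does not define a single analytic margin off the principal axes.
.truthMargin <- function(shape, size, expansion, d) {
  if (expansion$type == "isotropic") return(expansion$margins)
  axis <- which(abs(abs(d) - 1) < 1e-9)
  if (shape == "sphere") { # ellipsoid: pole-to-pole gap along any direction
    m <- expansion$margins
    return(1 / sqrt(sum(d^2 / (size$radius + m)^2)) - size$radius)
  }
  if (length(axis) != 1L) return(NA_real_)
  g <- .signedGrowth(expansion)
  if (d[axis] > 0) g$hi[axis] else g$lo[axis]
}

.barrierRegion <- function(barrier, P) {
  n <- barrier$normal / vnorm(barrier$normal)
  as.numeric(P %*% n) >= barrier$offsetMm
}

#' Generate an analytic phantom with known directional margins
#'
#' Builds a GTV mask from an analytic solid and a CTV mask from the exact
#' direction-dependent physical expansion of the same solid (distance
#' -function thresholding at voxel centers, not morphological dilation), so
#' the applied margin is known exactly in mm for every requested direction.
#'
#' Shapes and their \code{size} fields (all mm):
#' \describe{
#'   \item{sphere}{\code{radius}, \code{center}.}
#'   \item{box}{\code{lower}, \code{upper} corner coordinates.}
#'   \item{slab}{\code{axis} (1-3), \code{lower}, \code{upper}; the slab
#'     spans the full grid along the other two axes. \code{extentMm}
#'     (list of 2 ranges) sets the in-plane grid extent.}
#'   \item{ushape}{\code{lower}, \code{upper}, \code{prongWidth},
#'     \code{baseHeight}: a base box with two prongs along +z separated
#'     along x (a concave solid for interior-rejection tests).}
#' }
#'
#' Expansion rules (\code{expansion = list(type, margins)}):
#' \describe{
#'   \item{isotropic}{one margin, exact Euclidean expansion (any shape).}
#'   \item{peraxis}{three margins; sphere becomes the ellipsoid with grown
#'     semi-axes, box/slab bounds grow symmetrically per axis.}
#'   \item{signed}{six margins (x-, x+, y-, y+, z-, z+); box/slab bounds
#'     grow per signed axis, as in an asymmetric slab expansion.}
#' }
#'
#' @param shape one of \code{"sphere"}, \code{"box"}, \code{"slab"},
#'   \code{"ushape"}.
#' @param size named list of shape dimensions, see Details.
#' @param expansion expansion rule, see Details.
#' @param spacing numeric(3) voxel spacing in mm (default 0.5 mm isotropic).
#' @param directions list of directions ([DirectionSpec-class], labels, or
#'   numeric(3)) for which ground-truth margins are tabulated.
#' @param barrier \code{NULL} or \code{list(normal, offsetMm)} defining the
#'   half-space \code{<p, normal> >= offsetMm}; the expansion is clipped to
#'   its complement and the half-space is returned as a barrier mask.
#' @param padMm background clearance added around the analytic CTV bounds
#'   when the grid is auto-sized.
#' @param grid optional [BinaryVolume-class] template fixing the grid; an
#'   error of class \code{ctv_clearance_error} is raised when the analytic
#'   CTV would exceed it.
#' @return a [Phantom-class].
#' @examples
#' ph <- makePhantom("sphere", size = list(radius = 10, center = c(0, 0, 0)),
#'                   expansion = list(type = "isotropic", margins = 5),
#'                   directions = list("L", "P"))
#' phantomTruth(ph)
#' @export
makePhantom <- function(shape = c("sphere", "box", "slab", "ushape"),
                        size = list(), expansion = list(type = "isotropic",
                                                        margins = 5),
                        spacing = c(0.5, 0.5, 0.5), directions = list(),
                        barrier = NULL, padMm = 2, grid = NULL) {
  shape <- match.arg(shape)
  spacing <- as.numeric(spacing)
  if (shape == "sphere" && is.null(size$center)) size$center <- c(0, 0, 0)
  expansion <- .checkExpansion(shape, expansion)
  bounds <- .ctvBounds(shape, size, expansion)

  if (is.null(grid)) {
    lo <- bounds$lo; hi <- bounds$hi
    if (shape == "slab") {
      ext <- size$extentMm
      if (is.null(ext)) ext <- list(c(-4, 4), c(-4, 4))
      others <- setdiff(1:3, size$axis)
      lo[others] <- c(ext[[1]][1], ext[[2]][1])
      hi[others] <- c(ext[[1]][2], ext[[2]][2])
    }
    lo <- lo - padMm; hi <- hi + padMm
    n <- pmax(1L, as.integer(ceiling((hi - lo) / spacing)))
    origin <- lo + spacing / 2
  } else {
    if (max(abs(grid@axisDirections - diag(3))) > 1e-9)
      ctvStop("ctv_geometry_mismatch",
              "makePhantom requires a grid aligned with the patient axes")
    n <- dim(grid@occupancy); origin <- grid@origin
    spacing <- grid@spacing
    .checkClearance(bounds, origin, spacing, n)
  }

  centers <- .voxelCenters(n, origin, spacing)
  gtvIn <- .shapeSdf(shape, size, centers) <= 0
  ctvIn <- .insideExpanded(shape, size, expansion, centers)
  barrierVol <- NULL
  if (!is.null(barrier)) {
    inB <- .barrierRegion(barrier, centers)
    if (any(gtvIn & inB))
      ctvStop("ctv_clearance_error",
              "the barrier half-space intersects the GTV")
    ctvIn <- gtvIn | (ctvIn & !inB)
    barrierVol <- BinaryVolume(array(inB, n), spacing, origin)
  }
  gtv <- BinaryVolume(array(gtvIn, n), spacing, origin)
  ctv <- BinaryVolume(array(ctvIn, n), spacing, origin)

  dirs <- lapply(directions, asDirectionSpec)
  truth <- do.call(rbind, c(list(
    data.frame(label = character(0), route_class = character(0),
               vx = numeric(0), vy = numeric(0), vz = numeric(0),
               true_margin_mm = numeric(0), barrier_excluded = logical(0))),
    lapply(dirs, function(ds) {
      d <- ds@vector
      excl <- !is.null(barrier) &&
        sum(d * barrier$normal / vnorm(barrier$normal)) > 1e-9
      data.frame(label = ds@label, route_class = ds@routeClass,
                 vx = d[1], vy = d[2], vz = d[3],
                 true_margin_mm = .truthMargin(shape, size, expansion, d),
                 barrier_excluded = excl)
    })))
  new("Phantom", gtv = gtv, ctv = ctv, truth = truth,
      shape = list(type = shape, size = size), expansion = expansion,
      barrier = barrierVol)
}

.voxelCenters <- function(n, origin, spacing) {
  ax <- lapply(1:3, function(a) origin[a] + (seq_len(n[a]) - 1) * spacing[a])
  cbind(rep(ax[[1]], times = n[2] * n[3]),
        rep(rep(ax[[2]], each = n[1]), times = n[3]),
        rep(ax[[3]], each = n[1] * n[2]))
}

.checkClearance <- function(bounds, origin, spacing, n) {
  gridLo <- origin - spacing / 2
  gridHi <- origin + (n - 1) * spacing + spacing / 2
  finite <- is.finite(bounds$lo) | is.finite(bounds$hi)
  bad <- (bounds$lo < gridLo + spacing) | (bounds$hi > gridHi - spacing)
  if (any(bad & finite))
    ctvStop("ctv_clearance_error",
            "the analytic CTV would exceed the grid (leave at least one voxel of background clearance)")
  invisible(TRUE)
}

#' Simulate an expert CTV ensemble around a true margin
#'
#' Draws K per-expert margins from a normal distribution with mean
#' \code{trueMarginMm} and SD \code{marginSdMm}, truncated at 0 (negative
#' draws are redrawn), and expands the phantom's analytic GTV isotropically
#' by each draw on the phantom's grid. This emulates a panel of experts who
#' agree on the route of spread but disagree on the margin magnitude; it
#' does not model spatially correlated contouring differences.
#'
#' @param phantom a [Phantom-class]; the analytic shape is required because
#'   the expert CTVs are exact physical expansions, not mask dilations.
#' @param trueMarginMm mean expansion in mm (> 0).
#' @param marginSdMm SD of the expert margins in mm (>= 0).
#' @param K number of experts (>= 2).
#' @param seed integer seed; draws are reproducible from it.
#' @return list of K [BinaryVolume-class] CTVs with attribute
#'   \code{"marginsMm"} holding the drawn margins.
#' @examples
#' ph <- makePhantom("slab", size = list(axis = 1, lower = 0, upper = 10),
#'                   expansion = list(type = "isotropic", margins = 7),
#'                   spacing = c(1, 1, 1), padMm = 16)
#' ens <- makeExpertEnsemble(ph, trueMarginMm = 7, marginSdMm = 2, K = 9,
#'                           seed = 1)
#' attr(ens, "marginsMm")
#' @export
makeExpertEnsemble <- function(phantom, trueMarginMm, marginSdMm, K, seed) {
  if (K < 2L)
    ctvStop("ctv_insufficient_experts", "K must be at least 2")
  if (missing(seed))
    ctvStop("ctv_label_parse", "a seed is required for reproducible draws")
  stopifnot(trueMarginMm > 0, marginSdMm >= 0)
  set.seed(as.integer(seed))
  m <- stats::rnorm(K, trueMarginMm, marginSdMm)
  while (any(m < 0)) # truncation at 0
    m[m < 0] <- stats::rnorm(sum(m < 0), trueMarginMm, marginSdMm)

  shape <- phantom@shape$type
  size <- phantom@shape$size
  gtv <- phantom@gtv
  n <- dim(gtv@occupancy)
  centers <- .voxelCenters(n, gtv@origin, gtv@spacing)
  gtvIn <- as.vector(gtv@occupancy)
  inB <- if (is.null(phantom@barrier)) NULL else
    as.vector(phantom@barrier@occupancy)
  vols <- lapply(m, function(mj) {
    exp_j <- list(type = "isotropic", margins = mj)
    .checkClearance(.ctvBounds(shape, size, exp_j), gtv@origin, gtv@spacing, n)
    inside <- .insideExpanded(shape, size, exp_j, centers)
    if (!is.null(inB)) inside <- gtvIn | (inside & !inB)
    BinaryVolume(array(inside, n), gtv@spacing, gtv@origin)
  })
  attr(vols, "marginsMm") <- m
  vols
}

#' Gallery of shipped phantom specifications
#'
#' Named phantom constructors used throughout the package's validation
#' suite: an isotropically expanded sphere, a sphere-to-ellipsoid per-axis
#' expansion, an asymmetric slab (opposing-direction margins 7 mm / 2 mm),
#' a concave U shape whose across-the-gap rays must be interior-rejected,
#' and a sphere with a half-space barrier.
#'
#' @param name \code{NULL} to list the available names, or one of them.
#' @param spacing voxel spacing passed through to [makePhantom()].
#' @return character vector of names, or a [Phantom-class].
#' @export
phantomGallery <- function(name = NULL, spacing = c(0.5, 0.5, 0.5)) {
  specs <- list(
    sphere_iso = function(sp) makePhantom(
      "sphere", size = list(radius = 10, center = c(0, 0, 0)),
      expansion = list(type = "isotropic", margins = 5), spacing = sp,
      directions = list("L", "P", "S")),
    sphere_ellipsoid = function(sp) makePhantom(
      "sphere", size = list(radius = 10, center = c(0, 0, 0)),
      expansion = list(type = "peraxis", margins = c(2, 4, 6)), spacing = sp,
      directions = list("L", "P", "S")),
    slab_asym = function(sp) makePhantom(
      "slab", size = list(axis = 1, lower = 0, upper = 10),
      expansion = list(type = "signed", margins = c(2, 7, 0, 0, 0, 0)),
      spacing = sp, directions = list(
        DirectionSpec("x+", c(1, 0, 0)), DirectionSpec("x-", c(-1, 0, 0)))),
    ushape = function(sp) makePhantom(
      "ushape", size = list(lower = c(0, 0, 0), upper = c(20, 10, 20),
                            prongWidth = 6, baseHeight = 6),
      expansion = list(type = "isotropic", margins = 4), spacing = sp,
      directions = list(DirectionSpec("x+", c(1, 0, 0)))),
    sphere_barrier = function(sp) makePhantom(
      "sphere", size = list(radius = 10, center = c(0, 0, 0)),
      expansion = list(type = "isotropic", margins = 5), spacing = sp,
      barrier = list(normal = c(0, 0, 1), offsetMm = 12),
      directions = list("S", "I"))
  )
  if (is.null(name)) return(names(specs))
  if (!name %in% names(specs))
    ctvStop("ctv_label_parse", sprintf("unknown phantom \"%s\"", name))
  specs[[name]](spacing)
}

#' @rdname ctvMargins-accessors
#' @export
setMethod("gtvVolume", "Phantom", function(object) object@gtv)

#' @rdname ctvMargins-accessors
#' @export
setMethod("ctvVolume", "Phantom", function(object) object@ctv)

#' @rdname ctvMargins-accessors
#' @export
setMethod("phantomTruth", "Phantom", function(object) object@truth)

setMethod("show", "Phantom", function(object) {
  cat(sprintf("Phantom: %s GTV, %s expansion\n", object@shape$type,
              object@expansion$type))
  d <- dim(object@gtv@occupancy)
  cat(sprintf("  grid: %d x %d x %d voxels at %s mm%s\n", d[1], d[2], d[3],
              paste(format(object@gtv@spacing), collapse = " x "),
              if (is.null(object@barrier)) "" else ", with barrier"))
  if (nrow(object@truth)) {
    cat("  ground truth:\n")
    print(object@truth, row.names = FALSE)
  }
})
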