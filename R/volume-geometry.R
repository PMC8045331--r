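#' Create a binary volume
#'
#' Construct a [BinaryVolume-class] from an occupancy array and physical
#' geometry. Numeric arrays are coerced with \code{!= 0} (nonzero =
#' foreground).
#'
#' @param occupancy logical or numeric 3D array.
#' @param spacing numeric(3), mm per voxel along each index axis (> 0).
#' @param origin numeric(3), mm, physical LPS position of the center of voxel
#'   \code{[1, 1, 1]}.
#' @param axisDirections 3x3 orthonormal matrix mapping index axes to patient
#'   axes; defaults to the identity (index axes aligned with LPS axes).
#' @return a [BinaryVolume-class].
#' @examples
#' occ <- array(FALSE, c(10, 10, 10)); occ[4:7, 4:7, 4:7] <- TRUE
#' vol <- BinaryVolume(occ, spacing = c(1, 1, 2))
#' vol
#' @export
BinaryVolume <- function(occupancy, spacing = c(1, 1, 1),
                         origin = c(0, 0, 0), axisDirections = diag(3)) {
  if (is.numeric(occupancy)) {
    d <- dim(occupancy)
    occupancy <- array(occupancy != 0, dim = d)
  }
  new("BinaryVolume", occupancy = occupancy,
      spacing = as.numeric(spacing), origin = as.numeric(origin),
      axisDirections = unname(axisDirections))
}

#' @rdname ctvMargins-accessors
#' @export
setMethod("occupancy", "BinaryVolume", function(object) object@occupancy)

#' @rdname ctvMargins-accessors
#' @export
setMethod("voxelSpacing", "BinaryVolume", function(object) object@spacing)

#' @rdname ctvMargins-accessors
#' @export
setMethod("gridOrigin", "BinaryVolume", function(object) object@origin)

#' @rdname ctvMargins-accessors
#' @export
setMethod("axisDirections", "BinaryVolume", function(object) object@axisDirections)

#' @describeIn BinaryVolume grid dimensions (voxels per axis).
#' @param x a \code{BinaryVolume}.
#' @export
setMethod("dim", "BinaryVolume", function(x) dim(x@occupancy))

setMethod("show", "BinaryVolume", function(object) {
  d <- dim(object@occupancy)
  cat(sprintf("BinaryVolume: %d x %d x %d voxels, spacing %s mm\n",
              d[1], d[2], d[3],
              paste(format(object@spacing, digits = 4), collapse = " x ")))
  cat(sprintf("  origin (LPS mm): %s\n",
              paste(format(object@origin, digits = 6), collapse = ", ")))
  aligned <- max(abs(object@axisDirections - diag(3))) < 1e-9
  cat(sprintf("  axes: %s\n",
              if (aligned) "grid-aligned with LPS" else "oblique/rotated"))
  cat(sprintf("  foreground: %d voxels (%.2f%%)\n", sum(object@occupancy),
              100 * mean(object@occupancy)))
})

#' Map voxel indices to physical coordinates
#'
#' @param vol a [BinaryVolume-class].
#' @param index numeric matrix (n x 3) or vector(3) of 1-based voxel indices
#'   (may be fractional).
#' @return numeric matrix (n x 3) of physical LPS coordinates in mm.
#' @seealso [physicalToIndex()]
#' @export
indexToPhysical <- function(vol, index) {
  idx <- rbind(index)
  storage.mode(idx) <- "double"
  mm <- sweep(idx - 1, 2L, vol@spacing, `*`) %*% t(vol@axisDirections)
  sweep(mm, 2L, vol@origin, `+`)
}

#' Map physical coordinates to (continuous) voxel indices
#'
#' @param vol a [BinaryVolume-class].
#' @param points numeric matrix (n x 3) or vector(3) of physical LPS mm
#'   coordinates.
#' @return numeric matrix (n x 3) of continuous 1-based voxel indices.
#' @seealso [indexToPhysical()]
#' @export
physicalToIndex <- function(vol, points) {
  p <- rbind(points)
  storage.mode(p) <- "double"
  rel <- sweep(p, 2L, vol@origin, `-`) %*% vol@axisDirections
  sweep(rel, 2L, vol@spacing, `/`) + 1
}

#' Test whether two volumes share the same grid
#'
#' Two volumes are grid-compatible iff their shapes agree exactly and
#' spacing, origin and axis directions agree within \code{tol} (default
#' 1e-6 mm), guarding against silent misregistration between masks.
#'
#' @param a,b [BinaryVolume-class] objects.
#' @param tol numeric tolerance in mm.
#' @return logical(1).
#' @export
gridCompatible <- function(a, b, tol = 1e-6) {
  identical(dim(a@occupancy), dim(b@occupancy)) &&
    max(abs(a@spacing - b@spacing)) <= tol &&
    max(abs(a@origin - b@origin)) <= tol &&
    max(abs(a@axisDirections - b@axisDirections)) <= tol
}

stopIfIncompatible <- function(a, b, what = c("volume", "volume")) {
  if (!gridCompatible(a, b))
    ctvStop("ctv_geometry_mismatch",
            sprintf("grids of %s and %s are not compatible (shape/spacing/origin/axes must agree within 1e-6 mm)",
                    what[1], what[2]))
  invisible(TRUE)
}

# Physical diagonal of the grid extent: marching cap for the ray caster.
gridDiagonalMm <- function(vol) {
  vnorm(dim(vol@occupancy) * vol@spacing)
}

#' Sub-voxel occupancy query
#'
#' Trilinear interpolation of the 0/1 voxel values at arbitrary physical
#' points. Grid nodes are voxel centers; nodes beyond the grid contribute
#' background (0), so the field decays to 0 within one voxel beyond the
#' outermost voxel centers and is continuous everywhere. "Inside" is defined
#' as occupancy >= 0.5, which localizes the mask boundary at sub-voxel
#' (mm-level) precision.
#'
#' @param vol a [BinaryVolume-class].
#' @param points numeric matrix (n x 3) or vector(3) of physical LPS mm
#'   coordinates; points outside the grid are allowed and return 0.
#' @return numeric(n) occupancies in [0, 1].
#' @examples
#' occ <- array(FALSE, c(5, 5, 5)); occ[3, 3, 3] <- TRUE
#' vol <- BinaryVolume(occ)
#' occupancyAt(vol, c(2, 2, 2))    # foreground voxel center -> 1
#' occupancyAt(vol, c(2.5, 2, 2))  # midway to a background center -> 0.5
#' @export
occupancyAt <- function(vol, points) {
  u <- physicalToIndex(vol, points) - 1 # 0-based for the C++ kernel
  cpp_trilinear(as.double(vol@occupancy), dim(vol@occupancy), u)
}

#' Extract the surface voxels of a mask
#'
#' Returns exactly the foreground voxels with at least one 6-connected
#' neighbor that is background or outside the grid, with their physical
#' centers. These voxel centers are the ray-cast anchors for
#' [directionalMargin()].
#'
#' @param vol a [BinaryVolume-class] with at least one foreground voxel.
#' @return a [SurfacePointSet-class].
#' @examples
#' occ <- array(FALSE, c(7, 7, 7)); occ[3:5, 3:5, 3:5] <- TRUE
#' nrow(extractSurface(BinaryVolume(occ))@points) # 26: all but the center
#' @export
extractSurface <- function(vol) {
  occ <- vol@occupancy
  if (!any(occ))
    ctvStop("ctv_empty_volume", "cannot extract the surface of an empty mask")
  n <- dim(occ)
  interior <- occ
  for (axis in 1:3) {
    for (by in c(-1L, 1L)) {
      interior <- interior & shiftArray(occ, axis, by)
      if (!any(interior)) break
    }
  }
  surf <- occ & !interior
  idx <- which(surf, arr.ind = TRUE)
  dimnames(idx) <- NULL
  new("SurfacePointSet", points = indexToPhysical(vol, idx),
      indices = idx)
}

# result[i] = a[i + by] along `axis`, FALSE beyond the grid
shiftArray <- function(a, axis, by) {
  n <- dim(a)
  out <- array(FALSE, n)
  src <- dst <- list(seq_len(n[1]), seq_len(n[2]), seq_len(n[3]))
  if (by > 0) {
    dst[[axis]] <- seq_len(n[axis] - by)
    src[[axis]] <- seq_len(n[axis] - by) + by
  } else {
    dst[[axis]] <- seq_len(n[axis] + by) - by
    src[[axis]] <- seq_len(n[axis] + by)
  }
  out[dst[[1]], dst[[2]], dst[[3]]] <- a[src[[1]], src[[2]], src[[3]]]
  out
}
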