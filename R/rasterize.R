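# Even-odd crossing count of points against one closed polygon.
# px/py: point coordinates; poly: V x 2 vertex matrix (closure implied).
# A point is inside when a ray in +x crosses the edges an odd number of
# times; the half-open vertex rule makes the test deterministic.
.crossings <- function(px, py, poly) {
  nv <- nrow(poly)
  cn <- integer(length(px))
  j <- nv
  for (i in seq_len(nv)) {
    x1 <- poly[j, 1]; y1 <- poly[j, 2]
    x2 <- poly[i, 1]; y2 <- poly[i, 2]
    if (y1 != y2) {
      straddle <- (y1 > py) != (y2 > py)
      if (any(straddle)) {
        xi <- x1 + (py - y1) * (x2 - x1) / (y2 - y1)
        cn <- cn + as.integer(straddle & px < xi)
      }
    }
    j <- i
  }
  cn
}

#' Rasterize planar contours onto a voxel grid
#'
#' Converts per-slice closed polygons (physical mm, in-plane x/y with the
#' slice position along the grid's third axis) into a binary mask: a voxel
#' is foreground iff its center lies strictly inside an odd number of
#' polygons on its slice (even-odd rule), so a polygon containing a smaller
#' hole polygon rasterizes as an annulus. Slices with no polygons are all
#' background.
#'
#' @param slices list of slices, each \code{list(position = <mm>, polygons =
#'   list(<V x 2 matrix>, ...))}; see [readContours()] for the file format.
#' @param grid a [BinaryVolume-class] template defining the target geometry;
#'   must be aligned with the patient axes. Each slice position must match
#'   exactly one slice index within half a slice thickness, otherwise an
#'   error of class \code{ctv_geometry_mismatch} is raised.
#' @return a [BinaryVolume-class] on the template grid.
#' @examples
#' grid <- BinaryVolume(array(FALSE, c(20, 20, 3)), origin = c(0.5, 0.5, 0))
#' sq <- rbind(c(0, 0), c(10, 0), c(10, 10), c(0, 10))
#' vol <- rasterizeContours(list(list(position = 1, polygons = list(sq))),
#'                          grid)
#' sum(occupancy(vol)) # 100 voxel centers strictly inside the square
#' @export
rasterizeContours <- function(slices, grid) {
  if (max(abs(grid@axisDirections - diag(3))) > 1e-9)
    ctvStop("ctv_geometry_mismatch",
            "rasterization requires a grid aligned with the patient axes")
  n <- dim(grid@occupancy)
  occ <- array(FALSE, n)
  cx <- grid@origin[1] + (seq_len(n[1]) - 1) * grid@spacing[1]
  cy <- grid@origin[2] + (seq_len(n[2]) - 1) * grid@spacing[2]
  px <- rep(cx, times = n[2])
  py <- rep(cy, each = n[1])
  for (s in slices) {
    if (length(s$polygons) == 0L) next
    k <- round((s$position - grid@origin[3]) / grid@spacing[3]) + 1
    zk <- grid@origin[3] + (k - 1) * grid@spacing[3]
    if (k < 1 || k > n[3] ||
        abs(s$position - zk) > grid@spacing[3] / 2 + 1e-9)
      ctvStop("ctv_geometry_mismatch",
              sprintf("slice position %g mm does not match any grid slice",
                      s$position))
    cn <- integer(length(px))
    for (poly in s$polygons) {
      poly <- rbind(poly)
      if (nrow(poly) < 3L)
        ctvStop("ctv_degenerate_contour",
                "polygons must have at least 3 vertices")
      cn <- cn + .crossings(px, py, poly)
    }
    occ[, , k] <- occ[, , k] | matrix(cn %% 2L == 1L, n[1], n[2])
  }
  BinaryVolume(occ, grid@spacing, grid@origin, grid@axisDirections)
}
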