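#' Ray-casting controls
#'
#' Numerical parameters of the expansion-vector caster. The marching step is
#' a fraction of the smallest voxel spacing; boundary crossings are refined
#' by bisection with a fixed iteration count, giving a crossing resolution
#' of \code{stepFraction * min(spacing) / 2^bisectIterations} (well below
#' 0.01 mm at clinical spacings). A short grace zone past the GTV exit
#' avoids false interior-rejections from interpolation jitter right at the
#' departure point.
#'
#' @param stepFraction marching step as a fraction of \code{min(spacing)}.
#' @param graceMm re-entry checks only apply strictly beyond
#'   \code{start + graceMm} (mm).
#' @param bisectIterations bisection refinements of each boundary crossing.
#' @param minVectorsWarn emit a warning when fewer vectors than this enter
#'   the median (medians of very few rays are unstable).
#' @return a named list of control parameters.
#' @export
castControl <- function(stepFraction = 0.1, graceMm = 0.05,
                        bisectIterations = 30L, minVectorsWarn = 10L) {
  stopifnot(stepFraction > 0, graceMm >= 0, bisectIterations >= 1)
  list(stepFraction = stepFraction, graceMm = graceMm,
       bisectIterations = as.integer(bisectIterations),
       minVectorsWarn = as.integer(minVectorsWarn))
}

# Shared worker: cast rays from 1-based surface voxel indices along one
# direction. Returns the raw per-ray status and arclength brackets.
castRays <- function(gtv, ctv, direction, indices, barrier = NULL,
                     control = castControl()) {
  stopIfIncompatible(gtv, ctv, c("GTV", "CTV"))
  if (!is.null(barrier)) stopIfIncompatible(gtv, barrier, c("GTV", "barrier"))
  d <- direction@vector
  # index-space direction per mm of physical arclength
  e <- as.numeric(crossprod(gtv@axisDirections, d)) / gtv@spacing
  u0 <- rbind(indices) - 1
  storage.mode(u0) <- "double"
  step <- control$stepFraction * min(gtv@spacing)
  cap <- gridDiagonalMm(gtv)
  res <- cpp_cast_rays(as.double(gtv@occupancy), as.double(ctv@occupancy),
                       if (is.null(barrier)) NULL else as.double(barrier@occupancy),
                       dim(gtv@occupancy), u0, e, step, cap,
                       control$graceMm, control$bisectIterations)
  res
}

#' Cast a single expansion vector
#'
#' Casts one ray parallel to \code{direction} from a GTV surface point: the
#' ray is marched in steps of \code{stepFraction * min(spacing)}; the GTV
#' exit crossing (occupancy falling below 0.5) is refined by bisection and
#' becomes the vector start; marching continues to the CTV exit crossing,
#' the vector end. The ray is rejected if any sample strictly beyond
#' \code{start + graceMm} re-enters the GTV before the end (interior
#' crossing), or lies inside the barrier mask. If the start already lies
#' outside the CTV the vector is clamped to length 0. Marching is capped at
#' the grid's physical diagonal.
#'
#' @param surfacePoint numeric(3), physical mm coordinates of a GTV surface
#'   voxel center (see [extractSurface()]).
#' @param direction a [DirectionSpec-class], label, or numeric(3).
#' @param gtv,ctv grid-compatible [BinaryVolume-class] masks.
#' @param barrier optional grid-compatible [BinaryVolume-class]; rays
#'   crossing it between start and end are rejected.
#' @param control see [castControl()].
#' @return a list with elements \code{status} (one of \code{"accepted"},
#'   \code{"clamped"}, \code{"rejected_interior"},
#'   \code{"rejected_barrier"}), \code{start}, \code{end} (numeric(3), mm)
#'   and \code{lengthMm}; rejected rays carry \code{NA} endpoints.
#' @seealso [directionalMargin()] to cast from every surface point.
#' @export
castExpansionVector <- function(surfacePoint, direction, gtv, ctv,
                                barrier = NULL, control = castControl()) {
  direction <- asDirectionSpec(direction)
  idx <- physicalToIndex(gtv, surfacePoint)
  res <- castRays(gtv, ctv, direction, idx, barrier, control)
  st <- res$status[1]
  if (st == 4L)
    ctvStop("ctv_cast_error",
            "ray never exits the GTV within the grid diagonal (grazing or pathological mask)")
  codes <- c(`0` = "accepted", `1` = "clamped", `2` = "rejected_interior",
             `3` = "rejected_barrier")
  d <- direction@vector
  p <- as.numeric(rbind(surfacePoint))
  if (st %in% c(0L, 1L)) {
    lengthMm <- if (st == 1L) 0 else res$tEnd[1] - res$tStart[1]
    start <- p + res$tStart[1] * d
    end <- start + lengthMm * d
  } else {
    start <- end <- rep(NA_real_, 3)
    lengthMm <- NA_real_
  }
  list(status = unname(codes[as.character(st)]), start = start, end = end,
       lengthMm = lengthMm)
}

#' Directional margin between a GTV and a CTV
#'
#' Computes the directional margin M(d): expansion vectors parallel to
#' \code{direction} are cast from every GTV surface voxel (see
#' [castExpansionVector()] for the per-ray rules) and the margin is the
#' median of the retained vector lengths, clamped zero-length vectors
#' included. Rays crossing the GTV interior (or a barrier mask) are rejected
#' and counted in the diagnostics.
#'
#' @param gtv non-empty [BinaryVolume-class] gross tumor volume mask.
#' @param ctv grid-compatible [BinaryVolume-class] clinical target volume.
#' @param direction a [DirectionSpec-class], label string (e.g. "SA"), or
#'   numeric(3) LPS vector.
#' @param barrier optional grid-compatible [BinaryVolume-class] barrier mask.
#' @param control see [castControl()].
#' @return a [DirectionalMarginResult-class]. A warning of class
#'   \code{ctv_few_vectors} is emitted when fewer than
#'   \code{control$minVectorsWarn} vectors enter the median; an error of
#'   class \code{ctv_no_vector} is raised when no vector is retained (the
#'   caller decides whether the direction is inapplicable for the case).
#' @examples
#' ph <- makePhantom("slab", size = list(axis = 1, lower = 0, upper = 10),
#'                   expansion = list(type = "signed",
#'                                    margins = c(2, 7, 0, 0, 0, 0)),
#'                   spacing = c(1, 1, 1))
#' marginMm(directionalMargin(gtvVolume(ph), ctvVolume(ph), c(1, 0, 0)))  # 7
#' marginMm(directionalMargin(gtvVolume(ph), ctvVolume(ph), c(-1, 0, 0))) # 2
#' @export
directionalMargin <- function(gtv, ctv, direction, barrier = NULL,
                              control = castControl()) {
  direction <- asDirectionSpec(direction)
  surf <- extractSurface(gtv)
  res <- castRays(gtv, ctv, direction, surf@indices, barrier, control)
  st <- res$status
  keep <- st == 0L | st == 1L
  nFailed <- sum(st == 4L)
  if (nFailed > 0)
    ctvWarn("ctv_cast_failures",
            sprintf("%d ray(s) never exited the GTV within the cap and were dropped (grazing rays)",
                    nFailed))
  if (!any(keep))
    ctvStop("ctv_no_vector",
            sprintf("no expansion vector retained in direction \"%s\"",
                    direction@label))
  d <- direction@vector
  tS <- res$tStart[keep]
  tE <- res$tEnd[keep]
  lengths <- ifelse(st[keep] == 1L, 0, tE - tS)
  pts <- surf@points[keep, , drop = FALSE]
  starts <- pts + tS %o% d
  ends <- starts + lengths %o% d
  vs <- new("ExpansionVectorSet", direction = direction, starts = starts,
            ends = ends, lengths = as.numeric(lengths),
            nCandidates = nrow(surf@indices),
            nRejectedInterior = sum(st == 2L),
            nRejectedBarrier = sum(st == 3L),
            nClamped = sum(st == 1L), nFailed = nFailed)
  if (length(lengths) < control$minVectorsWarn)
    ctvWarn("ctv_few_vectors",
            sprintf("only %d expansion vector(s) in direction \"%s\"; the median may be unstable",
                    length(lengths), direction@label))
  new("DirectionalMarginResult", direction = direction,
      marginMm = stats::median(lengths), vectorSet = vs,
      nUsed = length(lengths))
}

#' Interobserver margin deviation
#'
#' Computes the directional margin from the GTV to each expert CTV
#' independently, then the margin deviation CV(d) = sample SD / mean of the
#' K per-expert margins (sample standard deviation, K - 1 denominator). If
#' every expert margin is 0 the CV is 0 by convention. Experts whose CTV
#' excludes part of the GTV surface contribute clamped zero-length vectors
#' there rather than being dropped, so each expert always yields a margin.
#'
#' @param gtv non-empty [BinaryVolume-class] GTV mask.
#' @param expertCtvs list of K >= 2 grid-compatible [BinaryVolume-class]
#'   expert CTV masks.
#' @param direction a [DirectionSpec-class], label, or numeric(3).
#' @param barrier optional [BinaryVolume-class] barrier mask.
#' @param control see [castControl()].
#' @return a [MarginDeviationResult-class].
#' @export
marginDeviation <- function(gtv, expertCtvs, direction, barrier = NULL,
                            control = castControl()) {
  direction <- asDirectionSpec(direction)
  K <- length(expertCtvs)
  if (K < 2L)
    ctvStop("ctv_insufficient_experts",
            "at least 2 expert CTVs are required for the margin deviation")
  margins <- vapply(seq_len(K), function(j) {
    tryCatch(
      marginMm(directionalMargin(gtv, expertCtvs[[j]], direction, barrier,
                                 control)),
      ctv_no_vector = function(e)
        ctvStop("ctv_no_vector",
                sprintf("expert %d: %s", j, conditionMessage(e)))
    )
  }, numeric(1))
  mu <- mean(margins)
  cv <- if (mu > 0) stats::sd(margins) / mu else 0
  new("MarginDeviationResult", direction = direction,
      perExpertMarginsMm = margins, cv = cv)
}

#' @rdname ctvMargins-accessors
#' @export
setMethod("marginMm", "DirectionalMarginResult", function(object) object@marginMm)

#' @rdname ctvMargins-accessors
#' @export
setMethod("expansionVectors", "DirectionalMarginResult",
          function(object) object@vectorSet)

#' @rdname ctvMargins-accessors
#' @export
setMethod("vectorLengths", "ExpansionVectorSet", function(object) object@lengths)

#' @rdname ctvMargins-accessors
#' @export
setMethod("vectorLengths", "DirectionalMarginResult",
          function(object) object@vectorSet@lengths)

#' @rdname ctvMargins-accessors
#' @export
setMethod("marginCV", "MarginDeviationResult", function(object) object@cv)

#' @rdname ctvMargins-accessors
#' @export
setMethod("perExpertMargins", "MarginDeviationResult",
          function(object) object@perExpertMarginsMm)

setMethod("show", "ExpansionVectorSet", function(object) {
  cat(sprintf("ExpansionVectorSet along \"%s\": %d vectors from %d surface points\n",
              object@direction@label, length(object@lengths),
              object@nCandidates))
  cat(sprintf("  rejected: %d interior, %d barrier; clamped: %d; failed: %d\n",
              object@nRejectedInterior, object@nRejectedBarrier,
              object@nClamped, object@nFailed))
  if (length(object@lengths))
    cat(sprintf("  lengths (mm): min %.2f, median %.2f, max %.2f\n",
                min(object@lengths), stats::median(object@lengths),
                max(object@lengths)))
})

setMethod("show", "DirectionalMarginResult", function(object) {
  cat(sprintf("Directional margin \"%s\": %.1f mm (median of %d vectors)\n",
              object@direction@label, object@marginMm, object@nUsed))
})

setMethod("show", "MarginDeviationResult", function(object) {
  cat(sprintf("Margin deviation \"%s\": CV = %.2f over %d experts\n",
              object@direction@label, object@cv,
              length(object@perExpertMarginsMm)))
  cat(sprintf("  per-expert margins (mm): %s\n",
              paste(sprintf("%.1f", object@perExpertMarginsMm),
                    collapse = ", ")))
})
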