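#' STAPLE consensus segmentation
#'
#' Estimates a consensus segmentation from K expert masks with the STAPLE
#' (simultaneous truth and performance level estimation) EM algorithm. The
#' E-step computes each voxel's posterior probability of foreground from the
#' current per-rater sensitivity/specificity and a global scalar foreground
#' prior (the mean foreground fraction across raters, fixed across
#' iterations); the M-step re-estimates every rater's sensitivity and
#' specificity from the posteriors. Both performance parameters are
#' initialized to 0.99999 (near-perfect raters, avoiding the label-swapped
#' fixed point), and iteration stops when the mean absolute posterior change
#' drops below \code{tol}.
#'
#' Computation is restricted to the bounding box of the union of the masks
#' dilated by one voxel; outside it the posterior is 0 by construction.
#' Without this restriction the unbounded background would dominate the
#' specificity estimates.
#'
#' @param expertMasks list of K >= 1 grid-compatible [BinaryVolume-class]
#'   masks with at least one foreground voxel overall.
#' @param threshold posterior cut in (0, 1) for the consensus mask
#'   (foreground iff posterior >= threshold).
#' @param maxIter maximum EM iterations.
#' @param tol convergence tolerance on the mean absolute posterior change.
#' @return a [StapleResult-class].
#' @examples
#' occ <- array(FALSE, c(12, 12, 12)); occ[4:8, 4:8, 4:8] <- TRUE
#' masks <- list(BinaryVolume(occ), BinaryVolume(occ), BinaryVolume(occ))
#' res <- stapleConsensus(masks)
#' identical(occupancy(consensusMask(res)), occ) # unanimous raters
#' @export
stapleConsensus <- function(expertMasks, threshold = 0.5, maxIter = 100L,
                            tol = 1e-6) {
  K <- length(expertMasks)
  if (K < 1L)
    ctvStop("ctv_no_raters", "at least one expert mask is required")
  stopifnot(threshold > 0, threshold < 1)
  ref <- expertMasks[[1]]
  for (j in seq_len(K))
    stopIfIncompatible(ref, expertMasks[[j]],
                       c("expert 1", sprintf("expert %d", j)))
  n <- dim(ref@occupancy)
  un <- Reduce(`|`, lapply(expertMasks, function(v) v@occupancy))
  if (!any(un))
    ctvStop("ctv_degenerate_input", "all expert masks are empty")

  # bounding box of the union, dilated by one voxel, clipped to the grid
  idx <- which(un, arr.ind = TRUE)
  lo <- pmax(apply(idx, 2L, min) - 1L, 1L)
  hi <- pmin(apply(idx, 2L, max) + 1L, n)
  box <- lapply(1:3, function(a) lo[a]:hi[a])
  D <- vapply(expertMasks, function(v)
    as.numeric(v@occupancy[box[[1]], box[[2]], box[[3]]]),
    numeric(prod(hi - lo + 1)))
  D <- matrix(D, ncol = K)

  prior <- mean(colMeans(D))
  p <- rep(0.99999, K) # sensitivities
  q <- rep(0.99999, K) # specificities
  W <- rep(prior, nrow(D))
  converged <- FALSE
  iter <- 0L
  eps <- 1e-12
  while (iter < maxIter) {
    iter <- iter + 1L
    pc <- pmin(pmax(p, eps), 1 - eps)
    qc <- pmin(pmax(q, eps), 1 - eps)
    # E-step: voxel posteriors under conditional independence of raters
    logA <- log(prior) + D %*% log(pc) + (1 - D) %*% log1p(-pc)
    logB <- log1p(-prior) + (1 - D) %*% log(qc) + D %*% log1p(-qc)
    A <- exp(logA); B <- exp(logB)
    Wnew <- as.numeric(A / (A + B))
    Wnew[!is.finite(Wnew)] <- prior
    delta <- mean(abs(Wnew - W))
    W <- Wnew
    # M-step: per-rater performance from the posteriors
    sw <- sum(W); swc <- sum(1 - W)
    if (sw > 0) p <- as.numeric(crossprod(D, W)) / sw
    if (swc > 0) q <- as.numeric(crossprod(1 - D, 1 - W)) / swc
    if (delta < tol) { converged <- TRUE; break }
  }

  prob <- array(0, n)
  prob[box[[1]], box[[2]], box[[3]]] <- W
  consensus <- BinaryVolume(array(prob >= threshold, n), ref@spacing,
                            ref@origin, ref@axisDirections)
  new("StapleResult", probabilityMap = prob, sensitivities = as.numeric(p),
      specificities = as.numeric(q), consensusMask = consensus,
      threshold = threshold, nIterations = iter, converged = converged)
}

#' @rdname ctvMargins-accessors
#' @export
setMethod("probabilityMap", "StapleResult", function(object) object@probabilityMap)

#' @rdname ctvMargins-accessors
#' @export
setMethod("consensusMask", "StapleResult", function(object) object@consensusMask)

#' @rdname ctvMargins-accessors
#' @export
setMethod("sensitivities", "StapleResult", function(object) object@sensitivities)

#' @rdname ctvMargins-accessors
#' @export
setMethod("specificities", "StapleResult", function(object) object@specificities)

setMethod("show", "StapleResult", function(object) {
  K <- length(object@sensitivities)
  cat(sprintf("STAPLE consensus over %d rater(s): %s after %d iteration(s)\n",
              K, if (object@converged) "converged" else "NOT converged",
              object@nIterations))
  cat(sprintf("  threshold %.2f -> %d consensus voxels\n", object@threshold,
              sum(object@consensusMask@occupancy)))
  cat(sprintf("  sensitivity: %s\n",
              paste(sprintf("%.3f", object@sensitivities), collapse = ", ")))
  cat(sprintf("  specificity: %s\n",
              paste(sprintf("%.3f", object@specificities), collapse = ", ")))
})
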