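slabPhantom <- function(spacing = c(1, 1, 1))
  makePhantom("slab", size = list(axis = 1, lower = 0, upper = 10),
              expansion = list(type = "signed",
                               margins = c(2, 7, 0, 0, 0, 0)),
              spacing = spacing)

test_that("the asymmetric slab yields exact opposing margins 7 and 2 mm", {
  ph <- slabPhantom()
  gtv <- gtvVolume(ph); ctv <- ctvVolume(ph)
  mR <- directionalMargin(gtv, ctv, c(1, 0, 0))
  mL <- directionalMargin(gtv, ctv, c(-1, 0, 0))
  expect_equal(marginMm(mR), 7, tolerance = 1e-9)
  expect_equal(marginMm(mL), 2, tolerance = 1e-9)
  # every vector identical by construction: median = common value
  expect_lt(diff(range(vectorLengths(mR))), 1e-9)
  vs <- expansionVectors(mR)
  expect_identical(vs@nCandidates, nrow(extractSurface(gtv)@points))
  expect_gte(vs@nCandidates,
             length(vectorLengths(vs)) + vs@nRejectedInterior +
               vs@nRejectedBarrier)
})

test_that("a single cast re-anchors at the GTV exit and measures 7 mm", {
  ph <- slabPhantom()
  gtv <- gtvVolume(ph); ctv <- ctvVolume(ph)
  # a +x face surface point: start is the boundary crossing at x = 10
  front <- castExpansionVector(c(9.5, 0.5, 0.5), c(1, 0, 0), gtv, ctv)
  expect_identical(front$status, "accepted")
  expect_equal(front$start[1], 10, tolerance = 1e-6)
  expect_equal(front$end[1], 17, tolerance = 1e-6)
  expect_equal(front$lengthMm, 7, tolerance = 1e-6)
  # a -x face point cast in +x traverses the interior and exits at x = 10
  back <- castExpansionVector(c(0.5, 0.5, 0.5), c(1, 0, 0), gtv, ctv)
  expect_equal(back$lengthMm, 7, tolerance = 1e-6)
})

test_that("ctv == gtv gives zero margin in every direction", {
  gtv <- cubeVolume(7, pad = 3)
  set.seed(41)
  for (i in 1:5) {
    d <- rnorm(3); d <- d / sqrt(sum(d^2))
    m <- directionalMargin(gtv, gtv, d)
    expect_equal(marginMm(m), 0, tolerance = 1e-6)
  }
})

test_that("experts tighter than the GTV clamp to zero margin, not failure", {
  gtv <- cubeVolume(5, pad = 3)
  tight <- cubeVolume(3, pad = 4) # strictly inside the GTV
  expect_true(gridCompatible(gtv, tight))
  m <- directionalMargin(gtv, tight, c(1, 0, 0))
  expect_equal(marginMm(m), 0)
  expect_gt(expansionVectors(m)@nClamped, 0L)
})

test_that("rays crossing the U-shape concavity are interior-rejected", {
  ph <- phantomGallery("ushape")
  gtv <- gtvVolume(ph); ctv <- ctvVolume(ph)
  # inner face of the left prong, above the base, cast across the gap
  pt <- indexToPhysical(gtv, physicalToIndex(gtv, c(5.8, 5, 14)))
  stopifnot(occupancyAt(gtv, pt) >= 0.5)
  res <- castExpansionVector(as.numeric(pt), c(1, 0, 0), gtv, ctv)
  expect_identical(res$status, "rejected_interior")
  # over the whole surface the accepted vectors are all 4 mm (planar faces)
  m <- directionalMargin(gtv, ctv, c(1, 0, 0))
  expect_equal(marginMm(m), 4, tolerance = 1e-6)
  expect_gt(expansionVectors(m)@nRejectedInterior, 0L)
})

test_that("the bisection caster agrees with a dense fixed-step marcher", {
  set.seed(47)
  # finite phantoms with strictly positive margins everywhere: where GTV and
  # CTV boundaries coincide, accepted-vs-clamped is a tie at occupancy 0.5
  phantoms <- list(makePhantom("box",
                               size = list(lower = c(0, 0, 0),
                                           upper = c(10, 8, 6)),
                               expansion = list(type = "signed",
                                                margins = c(2, 7, 1, 3,
                                                            2, 1)),
                               spacing = c(1, 1, 1)),
                   phantomGallery("ushape", spacing = c(1, 1, 1)),
                   makePhantom("sphere",
                               size = list(radius = 6, center = c(0, 0, 0)),
                               expansion = list(type = "isotropic",
                                                margins = 3),
                               spacing = c(1, 1, 1)))
  nPer <- c(60, 80, 60)
  for (k in seq_along(phantoms)) {
    gtv <- gtvVolume(phantoms[[k]]); ctv <- ctvVolume(phantoms[[k]])
    surf <- extractSurface(gtv)
    pick <- sample(nrow(surf@points), nPer[k], replace = TRUE)
    for (i in pick) {
      d <- rnorm(3); d <- d / sqrt(sum(d^2))
      pt <- surf@points[i, ]
      got <- tryCatch(castExpansionVector(pt, d, gtv, ctv),
                      ctv_cast_error = function(e) list(status = "failed"))
      ref <- oracleCastRay(gtv, ctv, pt, d)
      expect_identical(got$status, ref$status)
      if (identical(got$status, "accepted")) {
        expect_lt(abs(got$lengthMm - ref$lengthMm), 0.05)
      }
    }
  }
})

test_that("margin deviation reproduces hand-computed CVs", {
  n <- c(40, 6, 6)
  origin <- c(-10.5, 0.5, 0.5)
  big <- c(99, 99, 99)
  gtv <- boxVolume(c(0, -99, -99), c(10, 99, 99), n, origin = origin)
  expert <- function(m) boxVolume(c(0, -99, -99), c(10 + m, 99, 99), n,
                                  origin = origin)
  d <- c(1, 0, 0)
  dev3 <- marginDeviation(gtv, lapply(c(1, 2, 3), expert), d)
  expect_equal(perExpertMargins(dev3), c(1, 2, 3), tolerance = 1e-6)
  expect_equal(marginCV(dev3), 0.5, tolerance = 1e-6)
  dev2 <- marginDeviation(gtv, lapply(c(4, 6), expert), d)
  expect_equal(marginCV(dev2), sqrt(2) / 5, tolerance = 1e-6)
  same <- marginDeviation(gtv, lapply(c(5, 5, 5), expert), d)
  expect_equal(marginCV(same), 0)
  # all-zero margins: CV is 0 by convention
  zero <- marginDeviation(gtv, list(gtv, gtv), d)
  expect_equal(marginCV(zero), 0)
  expect_error(marginDeviation(gtv, list(expert(1)), d),
               class = "ctv_insufficient_experts")
})

test_that("margins are medians bounded by the length extremes", {
  ph <- makePhantom("sphere", size = list(radius = 8, center = c(0, 0, 0)),
                    expansion = list(type = "isotropic", margins = 3),
                    spacing = c(1, 1, 1))
  set.seed(53)
  for (i in 1:5) {
    d <- rnorm(3); d <- d / sqrt(sum(d^2))
    m <- directionalMargin(gtvVolume(ph), ctvVolume(ph), d)
    ls <- vectorLengths(m)
    expect_gte(min(ls), 0)
    expect_gte(marginMm(m), min(ls))
    expect_lte(marginMm(m), max(ls))
    expect_equal(marginMm(m), median(ls))
  }
})

test_that("adding a barrier never increases the accepted vector count", {
  ph <- phantomGallery("sphere_barrier", spacing = c(1, 1, 1))
  gtv <- gtvVolume(ph); ctv <- ctvVolume(ph); bar <- ph@barrier
  set.seed(59)
  for (i in 1:6) {
    d <- rnorm(3); d <- d / sqrt(sum(d^2))
    free <- directionalMargin(gtv, ctv, d)
    walled <- directionalMargin(gtv, ctv, d, barrier = bar)
    expect_lte(length(vectorLengths(walled)), length(vectorLengths(free)))
  }
  up <- directionalMargin(gtv, ctv, c(0, 0, 1), barrier = bar)
  expect_gt(expansionVectors(up)@nRejectedBarrier, 0L)
})

test_that("zero retained vectors raise a no-vector error", {
  ph <- makePhantom("sphere", size = list(radius = 5, center = c(0, 0, 0)),
                    expansion = list(type = "isotropic", margins = 3),
                    spacing = c(1, 1, 1))
  gtv <- gtvVolume(ph); ctv <- ctvVolume(ph)
  # a barrier covering everything outside the GTV blocks every ray
  wall <- BinaryVolume(!occupancy(gtv), voxelSpacing(gtv), gridOrigin(gtv))
  expect_error(directionalMargin(gtv, ctv, c(1, 0, 0), barrier = wall),
               class = "ctv_no_vector")
})

test_that("few retained vectors trigger an instability warning", {
  occ <- array(FALSE, c(9, 9, 9)); occ[5, 5, 5] <- TRUE
  gtv <- BinaryVolume(occ)
  ctv <- cubeVolume(3, pad = 3)
  expect_true(gridCompatible(gtv, ctv))
  expect_warning(directionalMargin(gtv, ctv, c(1, 0, 0)),
                 class = "ctv_few_vectors")
})

test_that("incompatible grids are a geometry error, not a warp", {
  a <- cubeVolume(3, pad = 2)
  b <- cubeVolume(3, pad = 2, spacing = c(1, 1, 2))
  expect_error(directionalMargin(a, b, c(1, 0, 0)),
               class = "ctv_geometry_mismatch")
})

test_that("whole-voxel translation leaves margins bitwise identical", {
  ph <- slabPhantom()
  gtv <- gtvVolume(ph); ctv <- ctvVolume(ph)
  shift <- c(3, -2, 5) * voxelSpacing(gtv)
  move <- function(v) BinaryVolume(occupancy(v), voxelSpacing(v),
                                   gridOrigin(v) + shift)
  d <- c(0.4, -0.3, 0.87); d <- d / sqrt(sum(d^2))
  m1 <- directionalMargin(gtv, ctv, d)
  m2 <- directionalMargin(move(gtv), move(ctv), d)
  expect_identical(marginMm(m2), marginMm(m1))
  expect_identical(vectorLengths(m2), vectorLengths(m1))
})

test_that("90-degree rotation about a grid axis preserves margins", {
  ph <- makePhantom("box", size = list(lower = c(0, 0, 0),
                                       upper = c(8, 12, 6)),
                    expansion = list(type = "signed",
                                     margins = c(1, 5, 2, 3, 1, 2)),
                    spacing = c(1, 1, 1))
  gtv <- gtvVolume(ph); ctv <- ctvVolume(ph)
  set.seed(61)
  for (i in 1:4) {
    d <- rnorm(3); d <- d / sqrt(sum(d^2))
    m1 <- directionalMargin(gtv, ctv, d)
    m2 <- directionalMargin(rotateVolumeZ(gtv), rotateVolumeZ(ctv),
                            rotateDirectionZ(d))
    expect_equal(marginMm(m2), marginMm(m1), tolerance = 1e-9)
  }
})

test_that("doubling the spacing exactly doubles every margin", {
  ph <- slabPhantom()
  gtv <- gtvVolume(ph); ctv <- ctvVolume(ph)
  scale2 <- function(v) BinaryVolume(occupancy(v), 2 * voxelSpacing(v),
                                     2 * gridOrigin(v))
  set.seed(67)
  for (i in 1:4) {
    d <- rnorm(3); d <- d / sqrt(sum(d^2))
    m1 <- directionalMargin(gtv, ctv, d)
    m2 <- directionalMargin(scale2(gtv), scale2(ctv), d)
    expect_equal(marginMm(m2), 2 * marginMm(m1), tolerance = 1e-12)
  }
})
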