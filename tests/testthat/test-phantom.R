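test_that("phantom ground truth is exact for flat-faced shapes", {
  slab <- makePhantom("slab", size = list(axis = 1, lower = 0, upper = 10),
                      expansion = list(type = "signed",
                                       margins = c(2, 7, 0, 0, 0, 0)),
                      spacing = c(1, 1, 1),
                      directions = list(DirectionSpec("x+", c(1, 0, 0)),
                                        DirectionSpec("x-", c(-1, 0, 0))))
  tr <- phantomTruth(slab)
  expect_equal(tr$true_margin_mm, c(7, 2))
  for (i in seq_len(nrow(tr))) {
    m <- directionalMargin(gtvVolume(slab), ctvVolume(slab),
                           c(tr$vx[i], tr$vy[i], tr$vz[i]))
    expect_equal(marginMm(m), tr$true_margin_mm[i], tolerance = 1e-9)
  }
  box <- makePhantom("box", size = list(lower = c(0, 0, 0),
                                        upper = c(10, 8, 6)),
                     expansion = list(type = "peraxis", margins = c(3, 2, 5)),
                     spacing = c(1, 1, 1),
                     directions = list("L", "R", "P", "A", "S", "I"))
  tb <- phantomTruth(box)
  expect_equal(tb$true_margin_mm, c(3, 3, 2, 2, 5, 5))
  for (i in seq_len(nrow(tb))) {
    m <- directionalMargin(gtvVolume(box), ctvVolume(box),
                           c(tb$vx[i], tb$vy[i], tb$vz[i]))
    # round-trip within one voxel diagonal
    expect_lt(abs(marginMm(m) - tb$true_margin_mm[i]), sqrt(3))
  }
})

test_that("sphere truth tabulates the analytic pole gap of the ellipsoid", {
  ph <- makePhantom("sphere", size = list(radius = 10, center = c(0, 0, 0)),
                    expansion = list(type = "peraxis", margins = c(2, 4, 6)),
                    spacing = c(1, 1, 1),
                    directions = list("L", "P", "S",
                                      DirectionSpec("d", c(1, 1, 1))))
  tr <- phantomTruth(ph)
  expect_equal(tr$true_margin_mm[1:3], c(2, 4, 6))
  # oblique pole gap: 1 / sqrt(sum(d_i^2 / (r + m_i)^2)) - r
  d <- rep(1, 3) / sqrt(3)
  expect_equal(tr$true_margin_mm[4],
               1 / sqrt(sum(d^2 / (10 + c(2, 4, 6))^2)) - 10)
})

test_that("the barrier phantom clips the expansion and flags directions", {
  ph <- phantomGallery("sphere_barrier", spacing = c(1, 1, 1))
  tr <- phantomTruth(ph)
  expect_identical(tr$barrier_excluded, c(TRUE, FALSE))
  # voxel centers in the barrier half-space are never CTV-only territory
  occC <- occupancy(ctvVolume(ph)) & !occupancy(gtvVolume(ph))
  expect_false(any(occC & occupancy(ph@barrier)))
  # brute-force clipping check at sampled points
  set.seed(83)
  P <- cbind(runif(200, -16, 16), runif(200, -16, 16), runif(200, -16, 16))
  inside <- sqrt(rowSums(P^2)) <= 15 & !(P[, 3] >= 12) |
    sqrt(rowSums(P^2)) <= 10
  away <- abs(sqrt(rowSums(P^2)) - 15) > 1 & abs(sqrt(rowSums(P^2)) - 10) > 1 &
    abs(P[, 3] - 12) > 1
  got <- occupancyAt(ctvVolume(ph), P[away, ]) >= 0.5
  expect_identical(unname(got), unname(inside[away]))
})

test_that("phantom construction validates its inputs", {
  expect_error(makePhantom("sphere", size = list(radius = 5),
                           expansion = list(type = "signed",
                                            margins = rep(1, 6))),
               class = "ctv_label_parse")
  small <- BinaryVolume(array(FALSE, c(10, 10, 10)))
  expect_error(makePhantom("sphere", size = list(radius = 8),
                           expansion = list(type = "isotropic", margins = 5),
                           grid = small),
               class = "ctv_clearance_error")
})

test_that("expert ensembles are seed-deterministic and truncated at zero", {
  ph <- makePhantom("slab", size = list(axis = 1, lower = 0, upper = 10),
                    expansion = list(type = "isotropic", margins = 7),
                    spacing = c(1, 1, 1), padMm = 22)
  a <- makeExpertEnsemble(ph, 7, 2, K = 5, seed = 99)
  b <- makeExpertEnsemble(ph, 7, 2, K = 5, seed = 99)
  expect_identical(attr(a, "marginsMm"), attr(b, "marginsMm"))
  expect_identical(lapply(a, occupancy), lapply(b, occupancy))
  c2 <- makeExpertEnsemble(ph, 7, 2, K = 5, seed = 100)
  expect_false(identical(attr(a, "marginsMm"), attr(c2, "marginsMm")))
  expect_true(all(attr(a, "marginsMm") >= 0))
  expect_error(makeExpertEnsemble(ph, 7, 2, K = 1, seed = 1),
               class = "ctv_insufficient_experts")
})

test_that("zero expert noise collapses the margin deviation to zero", {
  ph <- makePhantom("slab", size = list(axis = 1, lower = 0, upper = 10),
                    expansion = list(type = "isotropic", margins = 7),
                    spacing = c(1, 1, 1), padMm = 12)
  ens <- makeExpertEnsemble(ph, 7, 0, K = 3, seed = 5)
  expect_identical(occupancy(ens[[1]]), occupancy(ens[[2]]))
  dev <- marginDeviation(gtvVolume(ph), ens, c(1, 0, 0))
  expect_equal(marginCV(dev), 0)
})

test_that("strong truncation raises the realized mean above the target", {
  ph <- makePhantom("slab", size = list(axis = 1, lower = 0, upper = 10),
                    expansion = list(type = "isotropic", margins = 7),
                    spacing = c(2, 2, 2), padMm = 45)
  draws <- unlist(lapply(1:12, function(s)
    attr(makeExpertEnsemble(ph, 7, 7, K = 9, seed = s), "marginsMm")))
  # brute-force truncated-normal oracle for the mean
  set.seed(1234)
  ref <- rnorm(2e5, 7, 7)
  ref <- ref[ref >= 0]
  expect_gt(mean(draws), 7)
  expect_equal(mean(draws), mean(ref), tolerance = 0.15)
})

test_that("expert order is exchangeable for the margin deviation", {
  ph <- makePhantom("slab", size = list(axis = 1, lower = 0, upper = 10),
                    expansion = list(type = "isotropic", margins = 7),
                    spacing = c(1, 1, 1), padMm = 22)
  ens <- makeExpertEnsemble(ph, 7, 2, K = 5, seed = 7)
  d <- c(1, 0, 0)
  cv1 <- marginCV(marginDeviation(gtvVolume(ph), ens, d))
  cv2 <- marginCV(marginDeviation(gtvVolume(ph), ens[c(4, 2, 5, 1, 3)], d))
  expect_identical(cv1, cv2)
})

test_that("the gallery ships the documented phantom suite", {
  expect_setequal(phantomGallery(),
                  c("sphere_iso", "sphere_ellipsoid", "slab_asym", "ushape",
                    "sphere_barrier"))
  ph <- phantomGallery("slab_asym", spacing = c(1, 1, 1))
  expect_s4_class(ph, "Phantom")
  expect_equal(phantomTruth(ph)$true_margin_mm, c(7, 2))
})
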