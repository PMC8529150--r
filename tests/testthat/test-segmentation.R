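# Stages 1, 3, 4 and the composed four-stage segmentation.

test_that("coarse segmentation recovers the aerated lung on a phantom", {
  ph <- cachedPhantom(smallSpec(seed = 1L))
  coarse <- coarseSegment(ph$volume)
  airTruth <- ph$truth@lungMaskTrue@data & !ph$truth@vesselMaskTrue@data
  expect_gte(diceCoefficient(coarse@data, airTruth), 0.98)
})

test_that("nothing below threshold yields an empty mask with a diagnostic", {
  vol <- ctVolume(array(50, c(5, 20, 20)))
  m <- coarseSegment(vol)
  expect_equal(voxelCount(m), 0L)
  expect_match(m@metadata$diagnostics, "no interior air")
})

test_that("border-connected exterior air is excluded from the coarse mask", {
  ph <- cachedPhantom(smallSpec(seed = 1L))
  coarse <- coarseSegment(ph$volume)
  exteriorAir <- ph$volume@data < -900 & !ph$truth@lungMaskTrue@data &
    !ph$truth@tracheaMask@data
  expect_equal(sum(coarse@data & exteriorAir), 0L)
})

test_that("the tracheal air column is removed iff excludeAirways is set", {
  ph <- cachedPhantom(phantomSpec(shape = c(24L, 80L, 80L),
                                  vessel = list(nBranches = 10L),
                                  trachea = list(on = TRUE, radiusMM = 4),
                                  seed = 5L))
  pLow <- segmentationParams(minLungComponentMM3 = 300)
  pLowKeep <- segmentationParams(minLungComponentMM3 = 300,
                                 excludeAirways = FALSE)
  tm <- ph$truth@tracheaMask@data
  expect_gt(sum(tm), 0)
  expect_equal(sum(coarseSegment(ph$volume, pLow)@data & tm), 0L)
  expect_gt(sum(coarseSegment(ph$volume, pLowKeep)@data & tm), 0.5 * sum(tm))
  # the lungs themselves survive either way
  airTruth <- ph$truth@lungMaskTrue@data & !ph$truth@vesselMaskTrue@data
  expect_gt(sum(coarseSegment(ph$volume, pLow)@data & airTruth),
            0.9 * sum(airTruth))
})

test_that("hole elimination removes organ indentations but keeps vessels", {
  ph <- cachedPhantom(smallSpec(seed = 2L, indentation = TRUE))
  p <- segmentationParams()
  coarse <- coarseSegment(ph$volume, p)
  cf <- detectContours(coarse, p, ph$volume@spacing)
  filled <- fillContours(cf, p)
  eh <- eliminateHoles(filled, coarse, p, ph$volume@spacing)
  ind <- ph$truth@indentationMask@data
  expect_gt(sum(ind), 0)
  expect_gt(sum(eh$hole@data & ind) / sum(ind), 0.5)
  expect_equal(sum(eh$quasiLung@data & eh$hole@data), 0L)
  expect_gte(diceCoefficient(eh$quasiLung@data, ph$truth@lungMaskTrue@data),
             0.95)
  # vessels (small dense components) are preserved inside the quasi lung
  vess <- ph$truth@vesselMaskTrue@data
  expect_gt(sum(eh$quasiLung@data & vess) / sum(vess), 0.95)
})

test_that("hole elimination is the identity when filled equals coarse", {
  m <- cachedPhantom(smallSpec(seed = 1L))$truth@lungMaskTrue
  eh <- eliminateHoles(m, m, segmentationParams(), c(1, 1, 1))
  expect_equal(voxelCount(eh$hole), 0L)
  expect_identical(eh$quasiLung@data, m@data)
})

test_that("small dense components below the hole volume threshold stay", {
  # synthetic: aerated slab with tubular dense inclusions < 500 mm^3 each
  d <- c(12L, 60L, 60L)
  air <- array(TRUE, d); air[, c(1:5, 56:60), ] <- FALSE
  air[, , c(1:5, 56:60)] <- FALSE
  vessels <- array(FALSE, d)
  vessels[4:9, 20, 20] <- TRUE; vessels[4:9, 40, 40] <- TRUE
  coarse <- binaryMask(air & !vessels)
  filled <- binaryMask(air)
  eh <- eliminateHoles(filled, coarse, segmentationParams(), c(1, 1, 1))
  expect_equal(voxelCount(eh$hole), 0L)
  expect_identical(eh$quasiLung@data, filled@data)
})

test_that("contour shrinkage is a fixed point on an already-accurate mask", {
  d <- c(3L, 40L, 40L)
  disk <- array(FALSE, d)
  for (r in 1:40) for (c in 1:40)
    if ((r - 20.5)^2 + (c - 20.5)^2 <= 144) disk[2, r, c] <- TRUE
  ring <- disk & !elvarkit:::erodeInPlane4(disk)
  cf <- new("ContourField", smoothed = array(as.numeric(disk), d),
            laplacian = array(0, d), zeroCrossings = binaryMask(ring),
            innerBoundary = binaryMask(ring),
            outerBoundary = binaryMask(array(FALSE, d)))
  out <- shrinkContour(binaryMask(disk), cf, segmentationParams())
  expect_identical(out@data, disk)
  expect_equal(out@metadata$iterations, 0L)
  expect_true(out@metadata$converged)
})

test_that("a mask dilated beyond its ring contracts back within 4 iterations", {
  d <- c(3L, 40L, 40L)
  disk <- array(FALSE, d)
  for (r in 1:40) for (c in 1:40)
    if ((r - 20.5)^2 + (c - 20.5)^2 <= 100) disk[2, r, c] <- TRUE
  ring <- disk & !elvarkit:::erodeInPlane4(disk)
  dil <- disk
  for (i in 1:3) dil <- elvarkit:::dilateInPlane(dil, 4L)
  cf <- new("ContourField", smoothed = array(as.numeric(disk), d),
            laplacian = array(0, d), zeroCrossings = binaryMask(ring),
            innerBoundary = binaryMask(ring),
            outerBoundary = binaryMask(array(FALSE, d)))
  out <- shrinkContour(binaryMask(dil), cf, segmentationParams())
  expect_lte(out@metadata$iterations, 4L)
  expect_equal(sum(out@data != disk), 0)
  # contraction never grows the mask
  expect_equal(sum(out@data & !dil), 0)
})

test_that("an empty stopping set leaves the mask unchanged with a flag", {
  d <- c(3L, 20L, 20L)
  m <- array(FALSE, d); m[2, 5:15, 5:15] <- TRUE
  cf <- new("ContourField", smoothed = array(0, d), laplacian = array(0, d),
            zeroCrossings = binaryMask(array(FALSE, d)),
            innerBoundary = binaryMask(array(FALSE, d)),
            outerBoundary = binaryMask(array(FALSE, d)))
  out <- shrinkContour(binaryMask(m), cf, segmentationParams())
  expect_identical(out@data, m)
  expect_false(out@metadata$converged)
})

test_that("the composed segmentation recovers phantom lungs accurately", {
  ph <- cachedPhantom(smallSpec(seed = 1L))
  seg <- cachedSegmentation(smallSpec(seed = 1L))
  expect_gte(diceCoefficient(lungMask(seg), ph$truth@lungMaskTrue), 0.95)
  expect_equal(seg@L, sum(lungMask(seg)@data))
})

test_that("segmentation does not carve out dense disease", {
  spec <- smallSpec(seed = 3L, targetFraction = 0.25)
  spec@disease$mix <- c(septal_sheet = 0, ggo = 0, consolidation = 1)
  ph <- cachedPhantom(spec)
  # the compact test phantom has small lungs; scale the minimum lung
  # component volume accordingly
  seg <- segmentLungs(ph$volume, segmentationParams(minLungComponentMM3 = 3000))
  expect_gte(diceCoefficient(lungMask(seg), ph$truth@lungMaskTrue), 0.90)
  dis <- ph$truth@diseaseMaskTrue@data
  expect_gt(sum(lungMask(seg)@data & dis) / sum(dis), 0.9)
})

test_that("segmentation is deterministic and respects the containment chain", {
  ph <- cachedPhantom(smallSpec(seed = 1L, targetFraction = 0.15))
  s1 <- segmentLungs(ph$volume)
  s2 <- segmentLungs(ph$volume)
  expect_identical(lungMask(s1)@data, lungMask(s2)@data)
  expect_identical(s1@L, s2@L)
  st <- segmentationStages(s1)
  allowed <- st$contour_filled@data & !st$hole@data
  expect_equal(sum(lungMask(s1)@data & !allowed), 0L)
  expect_equal(sum(st$coarse_air@data & !st$contour_filled@data), 0L)
  # shrink output is contained in its input
  expect_equal(sum(lungMask(s1)@data & !st$pre_shrink@data), 0L)
})

test_that("L is invariant under in-plane 90-degree rotation", {
  ph <- cachedPhantom(smallSpec(seed = 4L, targetFraction = 0.1))
  seg <- segmentLungs(ph$volume)
  rot <- function(a) aperm(a, c(1, 3, 2))[, , dim(a)[2]:1, drop = FALSE]
  segR <- segmentLungs(ctVolume(rot(ph$volume@data)))
  expect_identical(segR@L, seg@L)
})
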