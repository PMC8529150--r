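# Curvature-based interstitial enhancement: analytic geometry responses,
# phantom recovery, and the threshold/containment properties.

test_that("a one-voxel sheet scores high and flat background scores low", {
  d <- c(24L, 48L, 48L)
  arr <- array(-850, d); arr[12, , ] <- -200
  vol <- ctVolume(arr)
  lung <- binaryMask(array(TRUE, d))
  sc <- curvatureFeatures(vol, lung, enhancementParams())
  expect_gt(mean(sc[12, 5:44, 5:44]), 0.8)
  expect_lt(mean(sc[c(4:8, 16:20), 5:44, 5:44]), 0.1)
})

test_that("a thin cylinder (vessel) scores above threshold when enabled", {
  d <- c(24L, 48L, 48L)
  arr <- array(-850, d)
  co <- elvarkit:::.coordArrays(d)
  cyl <- (co$r - 23.5)^2 + (co$c - 23.5)^2 <= 1.5^2
  arr[cyl] <- 50
  vol <- ctVolume(arr)
  lung <- binaryMask(array(TRUE, d))
  p <- enhancementParams()
  sc <- curvatureFeatures(vol, lung, p)
  expect_gt(mean(sc[5:20, , ][cyl[5:20, , ]]), p@sheetnessThreshold)
  # with the tubular branch disabled the tube response collapses
  scNo <- curvatureFeatures(vol, lung, enhancementParams(includeVesselsInI = FALSE))
  expect_lt(mean(scNo[5:20, , ][cyl[5:20, , ]]), mean(sc[5:20, , ][cyl[5:20, , ]]))
})

test_that("a uniform lung interior has an identically zero score field", {
  d <- c(16L, 32L, 32L)
  vol <- ctVolume(array(-850, d))
  lung <- binaryMask(array(TRUE, d))
  expect_equal(max(curvatureFeatures(vol, lung, enhancementParams())), 0)
})

test_that("an empty lung mask gives a zero score field and I = 0", {
  d <- c(8L, 16L, 16L)
  vol <- ctVolume(array(-850, d))
  seg <- new("LungSegmentation", lungMask = binaryMask(array(FALSE, d)),
             L = 0, stages = list(),
             contours = new("ContourField", smoothed = array(0, d),
                            laplacian = array(0, d),
                            zeroCrossings = binaryMask(array(FALSE, d)),
                            innerBoundary = binaryMask(array(FALSE, d)),
                            outerBoundary = binaryMask(array(FALSE, d))),
             paramsUsed = segmentationParams(), diagnostics = character())
  imap <- enhanceInterstitium(vol, seg, enhancementParams())
  expect_equal(interstitialVoxels(imap), 0)
  expect_equal(max(scoreField(imap)), 0)
})

test_that("a healthy phantom has a low interstitial fraction", {
  out <- cachedPipeline(smallSpec(seed = 1L))
  expect_lte(out$result@I / out$result@L, 0.10)
})

test_that("interstitial burden is recovered against the healthy baseline", {
  healthy <- cachedPipeline(smallSpec(seed = 6L))
  diseased <- cachedPipeline(smallSpec(seed = 6L, targetFraction = 0.20))
  base <- healthy$result@I / healthy$result@L
  frac <- diseased$result@I / diseased$result@L
  expect_lte(abs(frac - (0.20 + base)), 0.05)
})

test_that("the interstitium is contained in the lung and I is monotone in the threshold", {
  ph <- cachedPhantom(smallSpec(seed = 6L, targetFraction = 0.20))
  seg <- cachedSegmentation(smallSpec(seed = 6L, targetFraction = 0.20))
  prev <- Inf
  for (th in c(0.2, 0.35, 0.6, 0.9)) {
    imap <- enhanceInterstitium(ph$volume, seg, enhancementParams(sheetnessThreshold = th))
    expect_equal(sum(imap@interstitiumMask@data & !lungMask(seg)@data), 0L)
    expect_lte(imap@I, prev)
    prev <- imap@I
  }
})

test_that("enhancement is deterministic for fixed inputs", {
  ph <- cachedPhantom(smallSpec(seed = 6L, targetFraction = 0.20))
  seg <- cachedSegmentation(smallSpec(seed = 6L, targetFraction = 0.20))
  i1 <- enhanceInterstitium(ph$volume, seg)
  i2 <- enhanceInterstitium(ph$volume, seg)
  expect_identical(i1@interstitiumMask@data, i2@interstitiumMask@data)
  expect_identical(i1@scoreField, i2@scoreField)
})

test_that("overlays tint exactly the marked voxels", {
  d <- c(4L, 20L, 20L)
  vol <- ctVolume(array(-850, d))
  lung <- binaryMask(array(TRUE, d))
  seg <- new("LungSegmentation", lungMask = lung, L = sum(lung@data),
             stages = list(),
             contours = new("ContourField", smoothed = array(0, d),
                            laplacian = array(0, d),
                            zeroCrossings = binaryMask(array(FALSE, d)),
                            innerBoundary = binaryMask(array(FALSE, d)),
                            outerBoundary = binaryMask(array(FALSE, d))),
             paramsUsed = segmentationParams(), diagnostics = character())

  mkImap <- function(mask) new("InterstitialMap",
                               interstitiumMask = mask, I = sum(mask@data),
                               scoreField = array(0, d),
                               paramsUsed = enhancementParams())
  tdEmpty <- withr::local_tempdir()
  renderEnhancement(vol, mkImap(binaryMask(array(FALSE, d))), 1L, tdEmpty)
  one <- array(FALSE, d); one[2, 7, 13] <- TRUE
  tdOne <- withr::local_tempdir()
  renderEnhancement(vol, mkImap(binaryMask(one)), 1L, tdOne)

  # empty interstitium: overlay equals the plain lung-window render
  a <- png::readPNG(file.path(tdEmpty, "overlay_0002.png"))
  b <- png::readPNG(file.path(tdOne, "overlay_0002.png"))
  diffs <- which(apply(abs(a - b) > 1e-6, c(1, 2), any))
  expect_equal(length(diffs), 1L)
  ad <- which(apply(abs(a - b) > 1e-6, c(1, 2), any), arr.ind = TRUE)
  expect_equal(unname(ad[1, ]), c(7L, 13L))
  # untouched slices are byte-identical
  expect_identical(readBin(file.path(tdEmpty, "overlay_0001.png"), "raw", 1e6),
                   readBin(file.path(tdOne, "overlay_0001.png"), "raw", 1e6))
})

test_that("peripherally confined disease stays peripheral in the map", {
  spec <- smallSpec(seed = 9L, targetFraction = 0.12)
  spec@disease$minRho <- 2 / 3
  spec@vessel$nBranches <- 0L
  ph <- cachedPhantom(spec)
  out <- elvarPipeline(ph$volume)
  # normalized lung radius of every marked voxel that is true disease
  dis <- ph$truth@diseaseMaskTrue@data
  marked <- out$interstitialMap@interstitiumMask@data & dis
  expect_gt(sum(marked), 0)
  d <- dim(dis)
  co <- elvarkit:::.coordArrays(d)
  ctrS <- (d[1] - 1) / 2; ctrR <- (d[2] - 1) / 2; ctrC <- (d[3] - 1) / 2
  off <- 0.235 * d[3]
  rho <- pmin(
    sqrt(((co$s - ctrS) / (0.42 * d[1]))^2 + ((co$r - ctrR) / (0.30 * d[2]))^2 +
           ((co$c - (ctrC - off)) / (0.17 * d[3]))^2),
    sqrt(((co$s - ctrS) / (0.42 * d[1]))^2 + ((co$r - ctrR) / (0.30 * d[2]))^2 +
           ((co$c - (ctrC + off)) / (0.17 * d[3]))^2))
  expect_gte(min(rho[marked]), 2 / 3 - 1e-9)
})
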