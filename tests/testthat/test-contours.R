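# Stage-2 contour detection: zero-crossing definition, boundary splitting,
# and contour filling.

diskMask <- function(radius, side = 64L, nslice = 3L, centre = NULL) {
  if (is.null(centre)) centre <- c((side + 1) / 2, (side + 1) / 2)
  m <- array(FALSE, c(nslice, side, side))
  for (r in seq_len(side)) for (c in seq_len(side))
    if ((r - centre[1])^2 + (c - centre[2])^2 <= radius^2)
      m[2, r, c] <- TRUE
  m
}

test_that("zero crossings match the brute-force neighbor sign-scan oracle", {
  masks <- randomMaskSlices(10L, side = 64L, seed = 42L)
  cf <- detectContours(binaryMask(masks), segmentationParams(), c(1, 1, 1))
  for (s in seq_len(dim(masks)[1])) {
    oracle <- zeroCrossingOracle(cf@laplacian[s, , ])
    expect_identical(cf@zeroCrossings@data[s, , ], oracle)
  }
})

test_that("a filled disk yields a single closed zero-crossing ring", {
  m <- diskMask(20)
  cf <- detectContours(binaryMask(m), segmentationParams(), c(1, 1, 1))
  zc <- cf@zeroCrossings@data
  expect_false(any(zc[c(1, 3), , ]))
  ring <- zc[2, , ]
  lab <- elvarkit:::labelComponents(array(ring, c(1, dim(ring))), 8L)
  expect_equal(max(lab), 1)  # one connected ring
  # the ring encloses the disk centre: filling it recovers a disk
  filled <- fillContours(cf, segmentationParams())
  expect_true(filled@data[2, 32, 32])
  oracle <- zeroCrossingOracle(cf@laplacian[2, , ])
  expect_identical(ring, oracle)
})

test_that("two disjoint disks give two disjoint rings", {
  m <- diskMask(9, centre = c(18, 18)) | diskMask(9, centre = c(46, 46))
  cf <- detectContours(binaryMask(m), segmentationParams(), c(1, 1, 1))
  lab <- elvarkit:::labelComponents(cf@zeroCrossings@data, 8L)
  expect_equal(max(lab), 2)
})

test_that("uniform slices have no interior zero crossings", {
  allTrue <- binaryMask(array(TRUE, c(3, 32, 32)))
  cf <- detectContours(allTrue, segmentationParams(), c(1, 1, 1))
  expect_equal(voxelCount(cf@zeroCrossings), 0L)
  allFalse <- binaryMask(array(FALSE, c(3, 32, 32)))
  cf0 <- detectContours(allFalse, segmentationParams(), c(1, 1, 1))
  expect_equal(voxelCount(cf0@zeroCrossings), 0L)
})

test_that("inner and outer boundaries are disjoint subsets of the crossings", {
  masks <- randomMaskSlices(5L, side = 48L, seed = 12L)
  cf <- detectContours(binaryMask(masks), segmentationParams(), c(1, 1, 1))
  expect_false(any(cf@innerBoundary@data & cf@outerBoundary@data))
  expect_true(all(cf@zeroCrossings@data ==
                    (cf@innerBoundary@data | cf@outerBoundary@data)))
})

test_that("filling a closed ring recovers the discrete disk within 3 percent", {
  # a one-voxel-thick circle of radius 20 as the contour itself
  d <- c(3L, 64L, 64L)
  ring <- array(FALSE, d)
  for (th in seq(0, 2 * pi, length.out = 720)) {
    r <- round(32.5 + 20 * cos(th)); c <- round(32.5 + 20 * sin(th))
    ring[2, r, c] <- TRUE
  }
  cf <- new("ContourField", smoothed = array(0, d), laplacian = array(0, d),
            zeroCrossings = binaryMask(ring),
            innerBoundary = binaryMask(array(FALSE, d)),
            outerBoundary = binaryMask(ring))
  filled <- fillContours(cf, segmentationParams())
  # everything enclosed by the ring is filled ...
  expect_equal(sum(diskMask(20)[2, , ] & !filled@data[2, , ]), 0L)
  # ... and the result matches the discrete disk spanned through the
  # one-voxel contour (radius 20.5) to within 3 percent, pi r^2 in the limit
  inclusive <- outer((1:64) - 32.5, (1:64) - 32.5,
                     function(a, b) a^2 + b^2) <= 20.5^2
  expect_lt(sum(filled@data[2, , ] != inclusive) / sum(inclusive), 0.03)
})

test_that("an open C-shaped contour is retained but encloses nothing", {
  d <- c(3L, 40L, 40L)
  zc <- array(FALSE, d)
  for (r in 1:40) for (c in 1:40) {
    rad <- sqrt((r - 20.5)^2 + (c - 20.5)^2)
    ang <- atan2(c - 20.5, r - 20.5)
    if (abs(rad - 12) < 0.8 && abs(ang) > 0.6) zc[2, r, c] <- TRUE  # gap
  }
  cf <- new("ContourField", smoothed = array(0, d), laplacian = array(0, d),
            zeroCrossings = binaryMask(zc),
            innerBoundary = binaryMask(array(FALSE, d)),
            outerBoundary = binaryMask(zc))
  filled <- fillContours(cf, segmentationParams())
  expect_identical(filled@data, zc)

  empty <- new("ContourField", smoothed = array(0, d),
               laplacian = array(0, d),
               zeroCrossings = binaryMask(array(FALSE, d)),
               innerBoundary = binaryMask(array(FALSE, d)),
               outerBoundary = binaryMask(array(FALSE, d)))
  expect_equal(voxelCount(fillContours(empty, segmentationParams())), 0L)
})
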