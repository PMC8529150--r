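# Shared fixtures: all test data are generated in code. Phantoms and
# pipeline runs are cached per session because several tests interrogate
# the same objects.

.fixtureCache <- new.env(parent = emptyenv())

# A compact thorax phantom for unit tests (fast: ~0.5 s to generate).
smallSpec <- function(seed = 1L, targetFraction = 0, indentation = FALSE,
                      ...) {
  phantomSpec(shape = c(24L, 80L, 80L), vessel = list(nBranches = 30L),
              disease = list(targetFraction = targetFraction),
              organIndentation = list(on = indentation, volumeMM3 = 1200),
              seed = seed, ...)
}

cachedPhantom <- function(spec) {
  key <- paste0("ph-", paramsFingerprint(spec))
  if (is.null(.fixtureCache[[key]]))
    .fixtureCache[[key]] <- generatePhantom(spec)
  .fixtureCache[[key]]
}

cachedSegmentation <- function(spec, p = segmentationParams()) {
  key <- paste0("seg-", paramsFingerprint(spec, p))
  if (is.null(.fixtureCache[[key]]))
    .fixtureCache[[key]] <- segmentLungs(cachedPhantom(spec)$volume, p)
  .fixtureCache[[key]]
}

cachedPipeline <- function(spec, segP = segmentationParams(),
                           enhP = enhancementParams()) {
  key <- paste0("pipe-", paramsFingerprint(spec, segP, enhP))
  if (is.null(.fixtureCache[[key]])) {
    ph <- cachedPhantom(spec)
    seg <- cachedSegmentation(spec, segP)
    imap <- enhanceInterstitium(ph$volume, seg, enhP)
    .fixtureCache[[key]] <- list(phantom = ph, segmentation = seg,
                                 interstitialMap = imap,
                                 result = computeElvar(seg, imap))
  }
  .fixtureCache[[key]]
}

# Independent brute-force oracle for the zero-crossing definition: a pixel
# is marked when its Laplacian differs in sign from an in-plane
# face-neighbor with magnitude not below its own (ties mark both), or is
# exactly zero with both signs among its neighbors. Pure loops over pixels;
# replicate boundary.
zeroCrossingOracle <- function(lapSlice) {
  nr <- nrow(lapSlice); nc <- ncol(lapSlice)
  out <- matrix(FALSE, nr, nc)
  for (r in seq_len(nr)) {
    for (c in seq_len(nc)) {
      v <- lapSlice[r, c]
      nb <- c(lapSlice[max(r - 1, 1), c], lapSlice[min(r + 1, nr), c],
              lapSlice[r, max(c - 1, 1)], lapSlice[r, min(c + 1, nc)])
      if (any(v * nb < 0 & abs(v) <= abs(nb))) out[r, c] <- TRUE
      else if (v == 0 && any(nb > 0) && any(nb < 0)) out[r, c] <- TRUE
    }
  }
  out
}

# Independent brute-force Youden scan: evaluates J at every midpoint
# between consecutive distinct scores and applies the documented
# tie-breaks (higher specificity, then lower cutoff).
youdenOracle <- function(scores, labels, lowPositive = TRUE) {
  u <- sort(unique(scores))
  gap <- if (length(u) > 1) min(diff(u)) / 2 else 0.5
  cuts <- c(u[1] - gap,
            if (length(u) > 1) (u[-length(u)] + u[-1]) / 2 else NULL,
            u[length(u)] + gap)
  best <- NULL
  for (ct in cuts) {
    pred <- if (lowPositive) scores < ct else scores > ct
    sens <- sum(pred & labels) / sum(labels)
    spec <- sum(!pred & !labels) / sum(!labels)
    J <- sens + spec - 1
    if (is.null(best) || J > best$J + 1e-12 ||
        (abs(J - best$J) <= 1e-12 &&
           (spec > best$spec + 1e-12 ||
              (abs(spec - best$spec) <= 1e-12 && ct < best$cut))))
      best <- list(cut = ct, J = J, spec = spec)
  }
  best
}

# Random smooth binary slices for contour tests: thresholded smoothed noise.
randomMaskSlices <- function(n, side = 64L, seed = 99L) {
  elvarkit:::.withSeed(seed, {
    arr <- array(stats::runif(n * side * side), c(n, side, side))
    sm <- elvarkit:::gaussianSmooth3d(arr, 4, c(1, 1, 1), axes = 2:3)
    sm > stats::quantile(sm, 0.6)
  })
}
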