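test_that("planted-line generator honours the requested composition and determinism", {
  gen <- planted(0.8, seed = 51L)
  expect_identical(nPoints(gen$points), 1500L)
  expect_identical(length(gen$inlierIdx), 300L)   # round(0.2 * 1500)
  gen2 <- planted(0.8, seed = 51L)
  expect_identical(coords(gen$points), coords(gen2$points))
  expect_identical(gen$truth@direction, gen2$truth@direction)
  # different seed, different cloud
  gen3 <- planted(0.8, seed = 52L)
  expect_false(identical(coords(gen$points), coords(gen3$points)))
})

test_that("outlier-free datasets hug the planted line like Gaussian jitter should", {
  for (s in 1:5) {
    gen <- planted(0, seed = 60L + s)
    d <- pointLineDistance(gen$points, gen$truth)
    # 3-sigma band: a few exceedances out of 1500 are expected, not many
    expect_gte(mean(d <= 3 * 0.5), 0.99)
    expect_lt(max(d), 6 * 0.5)
  }
})

test_that("gating at the true line and scale recovers the generated inliers at the binomial rate", {
  for (s in 1:10) {
    gen <- planted(0.5, seed = 70L + s)
    got <- gateInliers(gen$points, gen$truth, sigma = 0.5, z = 1.96)
    frac <- length(intersect(got, gen$inlierIdx)) / length(gen$inlierIdx)
    # capture probability is exactly 2*pnorm(1.96) - 1 = 0.95; allow the
    # 3-sigma binomial band around it
    band <- 3 * sqrt(0.95 * 0.05 / length(gen$inlierIdx))
    expect_gte(frac, 0.95 - band)
  }
})

test_that("phantom rendering matches its own ground truth geometry", {
  # noiseless slice: thresholded pixels sit within the stroke half-width
  spec <- PhantomSliceSpec(theta = 25, depth = 60, noiseSigma = 0, seed = 81L)
  ph <- generatePhantomSlice(spec)
  cand <- thresholdCandidates(ph$image, 0.5)
  expect_gt(nPoints(cand), 30)
  d <- pointLineDistance(cand, ph$truth[[1L]]$axis)
  expect_lte(max(d), 1.3 / 2 + 0.36)  # half-width plus an AA pixel fringe
  # noiseless mask PCA fit reproduces the spec axis almost exactly
  fit <- fitLinePCA(cand)
  expect_lte(angularDeviation(fit, ph$truth[[1L]]$axis), 0.1)
})

test_that("candidate count scales with insertion depth", {
  n40 <- nPoints(thresholdCandidates(
    generatePhantomSlice(PhantomSliceSpec(theta = 10, depth = 40,
                                          noiseSigma = 0, seed = 82L))$image, 0.5))
  n100 <- nPoints(thresholdCandidates(
    generatePhantomSlice(PhantomSliceSpec(theta = 10, depth = 100,
                                          noiseSigma = 0, seed = 82L))$image, 0.5))
  expect_equal(n100 / n40, 100 / 40, tolerance = 0.15)
})

test_that("a 20-needle grid at 5 mm pitch renders without overlap, crossing needles do not", {
  ph <- generatePhantomSlice(PhantomSliceSpec(
    nNeedles = 20L, theta = 15, depth = c(40, 60, 80, 100), pitchMm = 5,
    seed = 83L))
  expect_length(ph$truth, 20L)
  # a steep needle left of a vertical one crosses its path
  expect_error(generatePhantomSlice(PhantomSliceSpec(
    nNeedles = 2L, theta = c(60, 0), depth = 100, pitchMm = 5, seed = 83L)),
    "overlap")
})

test_that("deeper insertion gives more accurate axes on phantom slices", {
  b40 <- b100 <- numeric(10)
  for (s in 1:10) {
    for (h in c(40, 100)) {
      ph <- generatePhantomSlice(PhantomSliceSpec(theta = 15, depth = h,
                                                  seed = 200L + s))
      dets <- detectNeedles(ph$image, RansacConfig(seed = s),
                            MultiNeedleConfig(nNeedles = 1L), alpha = 0.5)
      ev <- evaluateDetections(dets, ph$truth)
      if (h == 40) b40[s] <- ev$meanBeta else b100[s] <- ev$meanBeta
    }
  }
  expect_gt(mean(b40), mean(b100))
})

test_that("the simulation sweep tabulates every ratio with sane columns", {
  sw <- simulationSweep(epsGrid = c(0.2, 0.5), reps = 3L, seed = 5L,
                        spec = PlantedLineSpec(nPoints = 400L))
  expect_identical(nrow(sw), 2L)
  expect_true(all(c("eps", "meanBetaBaseline", "sdBetaBaseline",
                    "meanBetaImproved", "sdBetaImproved",
                    "meanVerifBaseline", "meanVerifImproved",
                    "meanPretestRejections") %in% names(sw)))
  expect_true(all(is.finite(sw$meanBetaBaseline)))
  # single repetition: no spread to report
  sw1 <- simulationSweep(epsGrid = 0.3, reps = 1L, seed = 5L,
                         spec = PlantedLineSpec(nPoints = 400L))
  expect_true(is.na(sw1$sdBetaBaseline))
  expect_true(is.na(sw1$sdBetaImproved))
  # same seed reproduces the table
  sw2 <- simulationSweep(epsGrid = c(0.2, 0.5), reps = 3L, seed = 5L,
                         spec = PlantedLineSpec(nPoints = 400L))
  expect_identical(sw, sw2)
})
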