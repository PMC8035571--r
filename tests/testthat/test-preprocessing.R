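test_that("ROI from contour expands the bounding box by the margin and clips at edges", {
  img <- SliceImage(matrix(0.5, 40, 40), 1)
  sq <- rbind(c(10, 10), c(10, 20), c(20, 20), c(20, 10))
  expect_identical(unname(roiBounds(roiFromContour(img, 3, contour = sq))),
                   c(7L, 7L, 23L, 23L))
  expect_identical(unname(roiBounds(roiFromContour(img, 0, contour = sq))),
                   c(10L, 10L, 20L, 20L))
  # anisotropic spacing: 3 mm margin rounds outward per axis
  img2 <- SliceImage(matrix(0.5, 40, 40), c(2, 0.7))
  expect_identical(unname(roiBounds(roiFromContour(img2, 3, contour = sq))),
                   c(8L, 5L, 22L, 25L))
  # contour touching the image edge: clipped, no error
  edge <- rbind(c(0, 0), c(0, 10), c(10, 10))
  expect_identical(unname(roiBounds(roiFromContour(img, 3, contour = edge))),
                   c(0L, 0L, 13L, 13L))
  expect_error(roiFromContour(img, 3, contour = rbind(c(-5, 0), c(0, 10), c(10, 10))),
               "outside")
  expect_error(roiFromContour(img, 3, contour = rbind(c(1, 1), c(2, 2))),
               "3 vertices")
})

test_that("ROI construction is translation-equivariant with the contour", {
  img <- SliceImage(matrix(0.5, 80, 80), 1)
  sq <- rbind(c(10, 10), c(10, 20), c(20, 20), c(20, 10))
  b0 <- roiBounds(roiFromContour(img, 3, contour = sq))
  for (shift in list(c(5, 0), c(0, 7), c(11, 13))) {
    b1 <- roiBounds(roiFromContour(img, 3, contour = sweep(sq, 2, shift, "+")))
    expect_equal(unname(b1), unname(b0) + c(shift, shift))
  }
})

test_that("ROI grows stepwise until stray candidates are inside", {
  img <- SliceImage(matrix(0.5, 40, 40), 1)
  roi <- Roi(10L, 10L, 20L, 20L)
  inside <- PointSet(rbind(c(15, 15), c(20, 12)))
  expect_identical(roiBounds(expandRoiIfNeeded(roi, inside, 3, img)),
                   roiBounds(roi))
  # one point 2 mm beyond the box: a single 3 mm step suffices
  out1 <- PointSet(rbind(c(22, 15)))
  expect_identical(unname(roiBounds(expandRoiIfNeeded(roi, out1, 3, img))),
                   c(7L, 7L, 23L, 23L))
  # point beyond the image: box clips at the border, point is reported
  out2 <- PointSet(rbind(c(100, 15)))
  grown <- expandRoiIfNeeded(roi, out2, 3, img)
  expect_identical(attr(grown, "outside"), 1L)
})

test_that("contrast enhancement follows the saturating power curve", {
  img <- function(v) SliceImage(matrix(v, 1), 1)
  p <- ContrastParams(lowIn = 0.15, highIn = 1, gamma = 2)
  val <- function(v, pp = p) raster(enhanceContrast(img(v), pp))[1, 1]
  expect_equal(val(0.15), 0)
  expect_equal(val(1), 1)
  expect_equal(val(0.05), 0)   # below-range saturation
  expect_equal(val(0.575), ((0.575 - 0.15) / 0.85)^2)
  expect_equal(val(0.575), 0.25)
  # identity map: full ranges, gamma 1
  ident <- ContrastParams(lowIn = 0, highIn = 1, gamma = 1)
  for (v in c(0, 0.2, 0.77, 1)) expect_equal(val(v, ident), v)
})

test_that("contrast enhancement is monotone in the input intensity", {
  set.seed(31)
  p <- ContrastParams(lowIn = 0.1, highIn = 0.9, gamma = 2.5)
  v <- sort(runif(100))
  out <- raster(enhanceContrast(SliceImage(matrix(v, 1), 1), p))[1, ]
  expect_true(all(diff(out) >= -1e-12))
  expect_true(all(out >= 0 & out <= 1))
})

test_that("thresholding returns exactly the supra-threshold pixels in mm", {
  fx <- needle_mask_slice()
  cand <- thresholdCandidates(fx$image, 0.5)
  expect_identical(nPoints(cand), nrow(fx$mask_mm))
  expect_equal(coords(cand)[order(coords(cand)[, 2]), ],
               fx$mask_mm[order(fx$mask_mm[, 2]), ], ignore_attr = TRUE)
  expect_true(all(intensities(cand) == 0.9))
  # alpha = 0 keeps every ROI pixel, alpha above the range keeps none
  expect_identical(nPoints(thresholdCandidates(fx$image, 0)),
                   length(raster(fx$image)))
  expect_identical(nPoints(thresholdCandidates(fx$image, 1 + 1e-9)), 0L)
})

test_that("candidate count is nonincreasing in the threshold", {
  set.seed(32)
  img <- SliceImage(matrix(runif(900), 30), 1)
  counts <- vapply(seq(0, 1, by = 0.1),
                   function(a) nPoints(thresholdCandidates(img, a)), 1L)
  expect_true(all(diff(counts) <= 0))
})

test_that("thresholding respects the ROI and pixel spacing", {
  fx <- needle_mask_slice(spacing = 1)
  roi <- Roi(0L, 0L, 10L, 29L)  # rows 0..10 only
  cand <- thresholdCandidates(fx$image, 0.5, roi)
  expect_true(all(coords(cand)[, 2] <= 10))
  expect_identical(nPoints(cand), sum(fx$mask_mm[, 2] <= 10))
  # anisotropic spacing scales the mm coordinates
  m <- matrix(0.2, 10, 10); m[4, 7] <- 0.9
  img <- SliceImage(m, c(2, 0.5))
  cand2 <- thresholdCandidates(img, 0.5)
  expect_equal(unname(coords(cand2)[1, ]), c(6 * 0.5, 3 * 2))
})
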