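step_profile <- function(t_step = 0.5, drop_at = 10, len = 20,
                         hi = 1, lo = 0.1) {
  t <- seq(0, len, by = t_step)
  new("IntensityProfile", t = t, intensity = ifelse(t < drop_at, hi, lo),
      origin = c(0, 0), direction = c(1, 0))
}

test_that("tip threshold training finds the class-density crossing", {
  # identical spreads: crossing is the midpoint of the (sample) means
  set.seed(41)
  base <- rnorm(500, sd = 0.03)
  expect_equal(trainTipThreshold(0.8 + base, 0.2 + base),
               0.5 + mean(base), tolerance = 1e-9)
  # unequal variances: compare with the analytic crossing of the true
  # densities (root between the means)
  ne <- rnorm(1000, 0.9, 0.05); bg <- rnorm(1000, 0.2, 0.1)
  T_hat <- trainTipThreshold(ne, bg)
  T_true <- uniroot(function(x) dnorm(x, 0.9, 0.05) - dnorm(x, 0.2, 0.1),
                    c(0.25, 0.85), tol = 1e-12)$root
  expect_lt(abs(T_hat - T_true), 0.02)
  expect_gt(T_hat, 0.2); expect_lt(T_hat, 0.9)
  # degenerate zero-variance samples: midpoint fallback
  expect_equal(trainTipThreshold(rep(0.9, 5), rep(0.1, 5)), 0.5)
  # inverted classes signal bad training data
  expect_error(trainTipThreshold(rep(0.1, 5), rep(0.9, 5)), "exceed")
})

test_that("profile extraction reproduces constant and single-peak images", {
  img <- SliceImage(matrix(0.42, 30, 30), 1)
  roi <- Roi(0L, 0L, 29L, 29L)
  axis <- LineModel(c(0, 14), c(1, 0))
  pr <- extractProfile(img, axis, roi, insertionEdge = "left")
  expect_true(all(abs(pr@intensity - 0.42) < 1e-12))
  expect_equal(max(pr@t), 29)
  # single bright column crossed by a horizontal axis: peak at known t
  m <- matrix(0.1, 30, 30); m[, 21] <- 0.95
  img2 <- SliceImage(m, 1)
  pr2 <- extractProfile(img2, axis, roi, insertionEdge = "left")
  expect_equal(pr2@t[which.max(pr2@intensity)], 20)
  expect_error(extractProfile(img, LineModel(c(-50, -50), c(0, 1)), roi),
               "intersect")
})

test_that("profile extraction runs from the requested entry side", {
  m <- matrix(0.1, 20, 20); m[1:11, 11] <- 0.9  # vertical shaft, top half
  img <- SliceImage(m, 1)
  roi <- Roi(0L, 0L, 19L, 19L)
  axis <- LineModel(c(10, 0), c(0, 1))
  pr_top <- extractProfile(img, axis, roi, insertionEdge = "top")
  expect_equal(unname(pr_top@origin), c(10, 0))
  expect_gt(pr_top@intensity[1], 0.5)
  pr_bot <- extractProfile(img, axis, roi, insertionEdge = "bottom")
  expect_equal(unname(pr_bot@origin), c(10, 19))
  expect_lt(pr_bot@intensity[1], 0.5)
  # auto: geometric tie broken towards the bright (shaft) end
  pr_auto <- extractProfile(img, axis, roi, insertionEdge = "auto")
  expect_equal(unname(pr_auto@origin), c(10, 0))
})

test_that("tip localisation finds the plateau drop within one sample step", {
  pr <- step_profile()
  t_tip <- localizeTip(pr, 0.5)
  expect_lt(abs(as.numeric(t_tip) - 10), 0.5)
  expect_identical(attr(t_tip, "flag"), character(0))
  # entry side of the plateau is reported for the caller
  expect_equal(attr(t_tip, "entry_t"), 0)
})

test_that("tip localisation ignores short noise spikes beyond the plateau", {
  pr <- step_profile()
  spiked <- pr@intensity
  spiked[35] <- 0.95  # single bright sample at t = 17
  pr2 <- new("IntensityProfile", t = pr@t, intensity = spiked,
             origin = pr@origin, direction = pr@direction)
  expect_lt(abs(as.numeric(localizeTip(pr2, 0.5, minRun = 3L)) - 10), 0.5)
  # with minRun = 1 the spike would win instead
  expect_gt(as.numeric(localizeTip(pr2, 0.5, minRun = 1L)), 16)
})

test_that("tip localisation flags a needle running off the ROI and rejects absent needles", {
  t <- seq(0, 20, by = 0.5)
  all_hi <- new("IntensityProfile", t = t, intensity = rep(0.9, length(t)),
                origin = c(0, 0), direction = c(1, 0))
  t_tip <- localizeTip(all_hi, 0.5)
  expect_equal(as.numeric(t_tip), 20)
  expect_identical(attr(t_tip, "flag"), "tip_at_roi_edge")
  all_lo <- new("IntensityProfile", t = t, intensity = rep(0.1, length(t)),
                origin = c(0, 0), direction = c(1, 0))
  expect_error(localizeTip(all_lo, 0.5), "not present")
})

test_that("tip estimate is stable under 2x profile resampling", {
  coarse <- step_profile(t_step = 0.7, drop_at = 9.3)
  fine <- step_profile(t_step = 0.35, drop_at = 9.3)
  expect_lt(abs(as.numeric(localizeTip(coarse, 0.5)) -
                as.numeric(localizeTip(fine, 0.5))), 0.7)
})
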