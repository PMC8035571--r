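test_that("baseline estimator nails a clean collinear set and is deterministic", {
  pts <- collinear_points(10)
  r <- ransacBaseline(pts, test_cfg(0, seed = 3L))
  expect_identical(support(r), 10L)
  expect_lt(max(pointLineDistance(pts, modelOf(r))), 1e-9)

  gen <- planted(0.3, seed = 5L, n = 400L)
  cfg <- test_cfg(0.3, seed = 9L)
  r1 <- ransacBaseline(gen$points, cfg)
  r2 <- ransacBaseline(gen$points, cfg)
  expect_identical(r1@inlierIndices, r2@inlierIndices)
  expect_identical(modelOf(r1)@direction, modelOf(r2)@direction)
  expect_identical(r1@sigma, r2@sigma)
})

test_that("baseline estimator keeps most planted inliers at 20% contamination", {
  gen <- planted(0.2, seed = 4L)
  r <- ransacBaseline(gen$points, test_cfg(0.2, seed = 4L))
  n_true <- length(gen$inlierIdx)
  expect_gte(length(intersect(r@inlierIndices, gen$inlierIdx)), 0.9 * n_true)
})

test_that("pretest estimator degenerates to the baseline on outlier-free data", {
  pts <- collinear_points(40)
  r <- ransacPretest(pts, test_cfg(0, seed = 6L))
  expect_identical(r@pretestRejections, 0L)
  expect_identical(r@fullVerifications, r@iterationsRun)
  expect_identical(support(r), 40L)
})

test_that("pretest screening verifies far fewer models than the baseline at high contamination", {
  gen <- planted(0.8, seed = 2L)
  rb <- ransacBaseline(gen$points, test_cfg(0.8, seed = 2L))
  rp <- ransacPretest(gen$points, test_cfg(0.8, seed = 2L))
  expect_lt(rp@fullVerifications, rb@fullVerifications)
  # screened fraction: under half of the candidates reach full verification
  expect_lt(rp@fullVerifications / rp@iterationsRun, 0.5)
  # and the line is still recovered
  expect_lt(angularDeviation(modelOf(rp), gen$truth), 1)
})

test_that("pretest estimator's support holds up against the baseline across seeds", {
  supp_p <- supp_b <- numeric(8)
  for (s in 1:8) {
    gen <- planted(0.5, seed = 100L + s, n = 800L)
    supp_b[s] <- support(ransacBaseline(gen$points, test_cfg(0.5, seed = s)))
    supp_p[s] <- support(ransacPretest(gen$points, test_cfg(0.5, seed = s)))
  }
  expect_gte(mean(supp_p), 0.9 * mean(supp_b))
})

test_that("local optimisation leaves a perfect seed solution intact", {
  pts <- collinear_points(30)
  cfg <- test_cfg(0, seed = 8L)
  seed_res <- ransacPretest(pts, cfg)
  lo <- localOptimize(pts, seed_res, test_cfg(0))
  expect_identical(sort(lo@inlierIndices), sort(seed_res@inlierIndices))
  expect_lt(angularDeviation(modelOf(lo), modelOf(seed_res)), 1e-9)
})

test_that("local optimisation improves the axis in nearly all paired trials", {
  improved <- 0L
  for (s in 1:100) {
    gen <- planted(0.4, seed = s, n = 300L)
    pre <- ransacPretest(gen$points, test_cfg(0.4, seed = s))
    post <- localOptimize(gen$points, pre, test_cfg(0.4))
    b_pre <- angularDeviation(modelOf(pre), gen$truth)
    b_post <- angularDeviation(modelOf(post), gen$truth)
    if (b_post <= b_pre + 1e-12) improved <- improved + 1L
    expect_gte(support(post), support(pre))
  }
  expect_gte(improved, 90L)
})

test_that("the final PCA fit never has larger consensus SSE than the two-point seed model", {
  for (s in 1:10) {
    gen <- planted(0.3, seed = 50L + s, n = 400L)
    pre <- ransacPretest(gen$points, test_cfg(0.3, seed = s))
    post <- localOptimize(gen$points, pre, test_cfg(0.3))
    cons <- coords(gen$points)[post@inlierIndices, , drop = FALSE]
    expect_lte(sum(pointLineDistance(cons, modelOf(post))^2),
               sum(pointLineDistance(cons, modelOf(pre))^2) + 1e-9)
  }
})

test_that("single-needle detection equals its composed stages under one seed", {
  gen <- planted(0.5, seed = 31L, n = 600L)
  cfg <- test_cfg(0.5, seed = 31L)
  combined <- detectSingleNeedle(gen$points, cfg)
  set.seed(31L)
  cfg2 <- test_cfg(0.5)
  staged <- localOptimize(gen$points, ransacPretest(gen$points, cfg2), cfg2)
  expect_identical(combined@inlierIndices, staged@inlierIndices)
  expect_identical(modelOf(combined)@direction, modelOf(staged)@direction)
})

test_that("single-needle detection recovers the planted line across contamination levels and seeds", {
  for (eps in c(0.1, 0.5, 0.8)) {
    for (s in 1:4) {
      gen <- planted(eps, seed = 10L * s + round(10 * eps))
      r <- detectSingleNeedle(gen$points, test_cfg(eps, seed = s))
      expect_lt(angularDeviation(modelOf(r), gen$truth), 1)
    }
  }
})

test_that("estimators validate their inputs", {
  expect_error(ransacBaseline(PointSet(rbind(c(0, 0))), test_cfg(0.1)))
  expect_error(ransacBaseline(collinear_points(10), RansacConfig()),
               "outlierRatio")
  expect_error(ransacPretest(collinear_points(10), test_cfg(0.1)),
               "pretest subset")
})
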