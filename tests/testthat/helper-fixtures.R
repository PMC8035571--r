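# Shared fixtures, all built in code at test time.

# n exactly collinear points on y = x/2
collinear_points <- function(n = 10) {
  x <- seq(0, 45, length.out = n)
  PointSet(cbind(x, x / 2))
}

# planted-line dataset at the package's standard simulation conditions
planted <- function(eps, seed, n = 1500L, ...) {
  generatePlantedPoints(PlantedLineSpec(nPoints = n, outlierRatio = eps,
                                        seed = seed, ...))
}

test_cfg <- function(eps, seed = NA_integer_, ...) {
  RansacConfig(outlierRatio = eps, seed = as.integer(seed), ...)
}

# Jaccard similarity of two index sets
jaccard <- function(a, b) length(intersect(a, b)) / length(union(a, b))

# slice with a uniform background and one bright axis-aligned needle mask;
# returns image plus the exact mask pixel coordinates in mm
needle_mask_slice <- function(nr = 40, nc = 30, rows = 5:25, col = 10,
                              spacing = 1, needle = 0.9, bg = 0.2) {
  m <- matrix(bg, nr, nc)
  m[rows + 1L, col + 1L] <- needle
  list(image = SliceImage(m, spacing),
       mask_mm = cbind(x = rep(col * spacing, length(rows)),
                       y = rows * spacing))
}

# a small rotation matrix
rot2 <- function(deg) {
  a <- deg * pi / 180
  matrix(c(cos(a), sin(a), -sin(a), cos(a)), 2L, 2L)
}
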