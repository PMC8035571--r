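# Pure 2D geometry: distances, total-least-squares line fits and the two
# accuracy metrics used throughout (angular deviation of undirected axes,
# Euclidean tip deviation).

.coord_matrix <- function(points) {
  if (is(points, "PointSet")) return(points@coords)
  if (is.matrix(points)) return(points)
  if (is.numeric(points) && length(points) == 2L)
    return(matrix(points, ncol = 2L))
  stop("points must be a PointSet, an N x 2 matrix or a length-2 vector")
}

#' Perpendicular distance from points to a line
#'
#' @param points a [PointSet-class], N x 2 matrix, or a single (x, y)
#'   point; coordinates in mm.
#' @param line a [LineModel-class].
#' @return numeric vector of orthogonal distances (mm), one per point.
#' @examples
#' pointLineDistance(c(0, 1), LineModel(c(0, 0), c(1, 0)))
#' @export
pointLineDistance <- function(points, line) {
  stopifnot(is(line, "LineModel"))
  xy <- .coord_matrix(points)
  dx <- xy[, 1L] - line@anchor[1L]
  dy <- xy[, 2L] - line@anchor[2L]
  abs(dx * line@direction[2L] - dy * line@direction[1L])
}

#' Total-least-squares (PCA) line fit
#'
#' Fits the line minimising the sum of squared orthogonal distances: the
#' anchor is the centroid and the direction is the first principal axis of
#' the point cloud.  When the two principal variances are (numerically)
#' equal the axis is not unique; the fit then deterministically prefers the
#' axis closer to the x-axis, falling back to (1, 0) for an exactly
#' isotropic cloud.
#'
#' @param points a [PointSet-class] or N x 2 matrix with at least 2
#'   non-coincident points.
#' @return A [LineModel-class].
#' @examples
#' fitLinePCA(rbind(c(0, 0), c(2, 1)))
#' @export
fitLinePCA <- function(points) {
  xy <- .coord_matrix(points)
  if (nrow(xy) < 2L) stop("need at least 2 points for a line fit")
  ctr <- colMeans(xy)
  cc <- sweep(xy, 2L, ctr)
  if (max(abs(cc)) < 1e-12) stop("all points coincide; line fit is degenerate")
  cv <- crossprod(cc) / nrow(xy)
  e <- eigen(cv, symmetric = TRUE)
  v <- e$vectors
  gap <- e$values[1L] - e$values[2L]
  if (gap <= 1e-12 * max(e$values[1L], 1e-300)) {
    # isotropic cloud: no unique principal axis; deterministic tie-break
    if (abs(cv[1L, 2L]) < 1e-15 && abs(cv[1L, 1L] - cv[2L, 2L]) < 1e-15)
      return(LineModel(ctr, c(1, 0)))
    v1 <- if (abs(v[1L, 1L]) >= abs(v[1L, 2L])) v[, 1L] else v[, 2L]
    return(LineModel(ctr, v1))
  }
  LineModel(ctr, v[, 1L])
}

#' Angular deviation between two needle axes
#'
#' The angle between two undirected lines, folded into [0, 90] degrees via
#' the absolute dot product of the unit directions.  A needle axis has no
#' intrinsic orientation (directedness is restored at tip localisation),
#' so opposite direction vectors describe the same axis and give 0.
#'
#' @param a,b [LineModel-class] objects.
#' @return angle in degrees, in [0, 90]; symmetric in its arguments.
#' @examples
#' angularDeviation(LineModel(c(0, 0), c(1, 0)), LineModel(c(5, 5), c(1, 1)))
#' @export
angularDeviation <- function(a, b) {
  stopifnot(is(a, "LineModel"), is(b, "LineModel"))
  d <- abs(sum(a@direction * b@direction))
  acos(min(1, d)) * 180 / pi
}

#' Euclidean tip position deviation
#'
#' @param p1,p2 (x, y) positions in mm (length-2 numerics).
#' @return distance in mm.
#' @examples
#' tipDeviation(c(0, 0), c(3, 4))
#' @export
tipDeviation <- function(p1, p2) {
  p1 <- as.numeric(p1); p2 <- as.numeric(p2)
  stopifnot(length(p1) == 2L, length(p2) == 2L)
  sqrt(sum((p1 - p2)^2))
}

# point on `line` at signed arc length t from the anchor
.point_at <- function(line, t) line@anchor + t * line@direction

# orthogonal sum of squared distances of points to a line
.orthogonal_sse <- function(points, line) sum(pointLineDistance(points, line)^2)
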