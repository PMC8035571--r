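#' @import methods
NULL

.sign_normalize <- function(v) {
  nz <- which(abs(v) > 0)
  if (length(nz) && v[nz[1L]] < 0) v <- -v
  v
}

#' Undirected 2D line model
#'
#' A needle axis is represented as an anchor point plus a unit direction
#' vector, both in millimetres.  The direction is sign-normalised (first
#' non-zero component positive) so that two representations of the same
#' undirected line compare equal.
#'
#' @slot anchor numeric(2), a point on the line (x, y) in mm.
#' @slot direction numeric(2), unit vector along the line.
#' @export
setClass("LineModel",
  slots = c(anchor = "numeric", direction = "numeric"))

setValidity("LineModel", function(object) {
  if (length(object@anchor) != 2L || !all(is.finite(object@anchor)))
    return("anchor must be 2 finite coordinates (mm)")
  if (length(object@direction) != 2L || !all(is.finite(object@direction)))
    return("direction must be 2 finite components")
  if (abs(sqrt(sum(object@direction^2)) - 1) > 1e-9)
    return("direction must be a unit vector")
  nz <- which(abs(object@direction) > 0)
  if (length(nz) && object@direction[nz[1L]] < 0)
    return("direction must be sign-normalised (first nonzero component positive)")
  TRUE
})

#' Construct a LineModel
#'
#' @param anchor numeric(2) point on the line, mm.
#' @param direction numeric(2) direction; normalised internally, the zero
#'   vector is an error.
#' @return A [LineModel-class] object.
#' @examples
#' LineModel(c(0, 0), c(2, 0))
#' @export
LineModel <- function(anchor, direction) {
  anchor <- as.numeric(anchor)
  direction <- as.numeric(direction)
  nrm <- sqrt(sum(direction^2))
  if (!is.finite(nrm) || nrm < .Machine$double.eps)
    stop("direction must be a nonzero finite vector")
  new("LineModel", anchor = anchor,
      direction = .sign_normalize(direction / nrm))
}

setMethod("show", "LineModel", function(object) {
  cat(sprintf("LineModel: anchor (%.3f, %.3f) mm, direction (%.6f, %.6f)\n",
              object@anchor[1L], object@anchor[2L],
              object@direction[1L], object@direction[2L]))
})

#' Set of candidate needle points
#'
#' Candidate needle pixels in millimetre coordinates with optional
#' normalised intensities.  Point order (and hence point indices) is stable
#' across all operations in the package.
#'
#' @slot coords numeric matrix, N x 2, columns x and y in mm.
#' @slot intensity numeric, length 0 or N, normalised to [0, 1].
#' @export
setClass("PointSet",
  slots = c(coords = "matrix", intensity = "numeric"))

setValidity("PointSet", function(object) {
  if (ncol(object@coords) != 2L) return("coords must have 2 columns (x, y)")
  if (nrow(object@coords) && !all(is.finite(object@coords)))
    return("coords must be finite")
  if (length(object@intensity) &&
      length(object@intensity) != nrow(object@coords))
    return("intensity must be empty or one value per point")
  TRUE
})

#' Construct a PointSet
#'
#' @param coords N x 2 numeric matrix of (x, y) positions in mm.
#' @param intensity optional numeric vector of per-point intensities in
#'   [0, 1].
#' @return A [PointSet-class] object.
#' @export
PointSet <- function(coords, intensity = numeric(0)) {
  coords <- as.matrix(coords)
  if (nrow(coords) && !is.numeric(coords)) storage.mode(coords) <- "double"
  if (ncol(coords) != 2L) stop("coords must be an N x 2 matrix")
  colnames(coords) <- c("x", "y")
  new("PointSet", coords = coords, intensity = as.numeric(intensity))
}

#' Number of points in a PointSet
#' @param x a [PointSet-class].
#' @return integer count.
#' @export
nPoints <- function(x) nrow(x@coords)

#' Coordinates of a PointSet
#' @param x a [PointSet-class].
#' @return N x 2 numeric matrix (mm).
#' @export
coords <- function(x) x@coords

#' Intensities of a PointSet
#' @param x a [PointSet-class].
#' @return numeric vector (possibly length 0).
#' @export
intensities <- function(x) x@intensity

#' Subset a PointSet by point indices
#' @param x a [PointSet-class].
#' @param i integer or logical index.
#' @param j,...,drop ignored.
#' @export
setMethod("[", "PointSet", function(x, i, j, ..., drop = FALSE) {
  PointSet(x@coords[i, , drop = FALSE],
           if (length(x@intensity)) x@intensity[i] else numeric(0))
})

setMethod("show", "PointSet", function(object) {
  cat(sprintf("PointSet: %d points%s\n", nPoints(object),
              if (length(object@intensity)) " (with intensities)" else ""))
})

#' Grayscale CT slice
#'
#' A 2D raster of normalised intensities with its pixel spacing and an
#' optional closed target contour.  Pixel indices are 0-based with the
#' pixel-centre convention: the centre of pixel (row r, col c) is at
#' x = c * spacing_col, y = r * spacing_row (mm).
#'
#' @slot raster numeric matrix of intensities in [0, 1]; rows are image
#'   rows (y), columns are image columns (x).
#' @slot pixelSpacing numeric(2): mm per pixel along (row, col).
#' @slot contour numeric matrix, M x 2 of (row, col) vertices (0-based), or
#'   a 0-row matrix when absent.
#' @export
setClass("SliceImage",
  slots = c(raster = "matrix", pixelSpacing = "numeric", contour = "matrix"))

setValidity("SliceImage", function(object) {
  if (!is.numeric(object@raster)) return("raster must be numeric")
  if (any(object@raster < -1e-9 | object@raster > 1 + 1e-9))
    return("raster intensities must lie in [0, 1]")
  if (length(object@pixelSpacing) != 2L || any(object@pixelSpacing <= 0))
    return("pixelSpacing must be 2 positive values (mm/px row, mm/px col)")
  if (ncol(object@contour) != 2L) return("contour must have 2 columns (row, col)")
  TRUE
})

#' Construct a SliceImage
#'
#' @param raster numeric matrix of intensities; values are clipped to
#'   [0, 1].
#' @param pixelSpacing numeric(2) or numeric(1): mm per pixel along
#'   (row, col); a scalar is used for both axes.
#' @param contour optional M x 2 matrix of (row, col) contour vertices,
#'   0-based pixel coordinates.
#' @return A [SliceImage-class] object.
#' @export
SliceImage <- function(raster, pixelSpacing, contour = NULL) {
  raster <- as.matrix(raster)
  storage.mode(raster) <- "double"
  raster <- pmin(pmax(raster, 0), 1)
  if (length(pixelSpacing) == 1L) pixelSpacing <- rep(pixelSpacing, 2L)
  if (is.null(contour)) contour <- matrix(numeric(0), ncol = 2L)
  contour <- as.matrix(contour)
  new("SliceImage", raster = raster, pixelSpacing = as.numeric(pixelSpacing),
      contour = contour)
}

#' Raster of a SliceImage
#' @param x a [SliceImage-class].
#' @export
raster <- function(x) x@raster

#' Pixel spacing of a SliceImage
#' @param x a [SliceImage-class].
#' @return numeric(2): mm per pixel along (row, col).
#' @export
pixelSpacing <- function(x) x@pixelSpacing

#' Target contour of a SliceImage
#' @param x a [SliceImage-class].
#' @return M x 2 matrix of (row, col) vertices (0 rows when absent).
#' @export
contour <- function(x) x@contour

setMethod("show", "SliceImage", function(object) {
  cat(sprintf("SliceImage: %d x %d px, spacing %.3f x %.3f mm/px%s\n",
              nrow(object@raster), ncol(object@raster),
              object@pixelSpacing[1L], object@pixelSpacing[2L],
              if (nrow(object@contour)) sprintf(", contour (%d vertices)",
                                                nrow(object@contour)) else ""))
})

#' Rectangular region of interest
#'
#' Axis-aligned pixel rectangle with inclusive 0-based bounds
#' (rowMin, colMin, rowMax, colMax).
#'
#' @slot bounds integer(4): rowMin, colMin, rowMax, colMax (inclusive).
#' @export
setClass("Roi", slots = c(bounds = "integer"))

setValidity("Roi", function(object) {
  b <- object@bounds
  if (length(b) != 4L) return("bounds must be length 4")
  if (any(b < 0L)) return("bounds must be >= 0")
  if (b[3L] < b[1L] || b[4L] < b[2L]) return("Roi must be nonempty")
  TRUE
})

#' Construct a Roi
#' @param rowMin,colMin,rowMax,colMax inclusive 0-based pixel bounds.
#' @return A [Roi-class] object.
#' @export
Roi <- function(rowMin, colMin, rowMax, colMax) {
  new("Roi", bounds = as.integer(c(rowMin, colMin, rowMax, colMax)))
}

#' Bounds of a Roi
#' @param x a [Roi-class].
#' @return named integer(4): rowMin, colMin, rowMax, colMax (inclusive).
#' @export
roiBounds <- function(x) {
  b <- x@bounds
  names(b) <- c("rowMin", "colMin", "rowMax", "colMax")
  b
}

setMethod("show", "Roi", function(object) {
  b <- object@bounds
  cat(sprintf("Roi: rows %d..%d, cols %d..%d (inclusive, 0-based)\n",
              b[1L], b[3L], b[2L], b[4L]))
})

#' RANSAC estimator configuration
#'
#' All tunables of the robust line estimator in one validated record.
#'
#' @slot confidence probability P that at least one uncontaminated minimal
#'   sample is drawn (default 0.99).
#' @slot pretestSize size n of the random pretest subset (default 15).
#' @slot pretestConfidence minimal pretest pass probability Pt for a
#'   correct model (default 0.80).
#' @slot minimalSample minimal sample size m (2 for a 2D line).
#' @slot localIters number kL of local resampling rounds (default 15,
#'   conventional range 10 to 20).
#' @slot outlierRatio assumed outlier ratio epsilon; NA until supplied
#'   (the multi-needle pipeline recomputes it every round).
#' @slot gateZ z multiplier of the inlier gate d <= z * sigma (1.96).
#' @slot minSampleSep minimal separation (mm) of a 2-point sample; closer
#'   pairs are treated as degenerate and redrawn.
#' @slot minSigma floor (mm) on the residual scale used for gating; on
#'   raster-derived point sets a floor of half the pixel spacing stops the
#'   gate from collapsing onto a single exactly collinear pixel column
#'   (0 = no floor, appropriate for continuous point clouds).
#' @slot seed integer RNG seed, NA to continue the current RNG stream.
#' @export
setClass("RansacConfig",
  slots = c(confidence = "numeric", pretestSize = "integer",
            pretestConfidence = "numeric", minimalSample = "integer",
            localIters = "integer", outlierRatio = "numeric",
            gateZ = "numeric", minSampleSep = "numeric",
            minSigma = "numeric", seed = "integer"))

setValidity("RansacConfig", function(object) {
  if (object@confidence <= 0 || object@confidence >= 1)
    return("confidence must be in (0, 1)")
  if (object@pretestConfidence <= 0 || object@pretestConfidence > 1)
    return("pretestConfidence must be in (0, 1]")
  if (object@minimalSample < 2L) return("minimalSample must be >= 2")
  if (object@pretestSize < 2L * object@minimalSample)
    return("pretestSize must be >= 2 * minimalSample (robust scale validity)")
  if (object@localIters < 1L) return("localIters must be >= 1")
  if (!is.na(object@outlierRatio) &&
      (object@outlierRatio < 0 || object@outlierRatio >= 1))
    return("outlierRatio must be in [0, 1)")
  if (object@gateZ <= 0) return("gateZ must be positive")
  if (object@minSampleSep < 0) return("minSampleSep must be >= 0")
  if (object@minSigma < 0) return("minSigma must be >= 0")
  TRUE
})

#' Construct a RansacConfig
#'
#' Defaults follow the method's standard operating point: P = 0.99,
#' pretest size n = 15, minimal pretest confidence Pt = 0.80, kL = 15
#' local rounds, inlier gate 1.96 sigma.
#'
#' @param confidence,pretestSize,pretestConfidence,minimalSample,localIters
#'   see [RansacConfig-class].
#' @param outlierRatio,gateZ,minSampleSep,minSigma,seed see
#'   [RansacConfig-class].
#' @return A [RansacConfig-class] object.
#' @examples
#' RansacConfig(outlierRatio = 0.5, seed = 1L)
#' @export
RansacConfig <- function(confidence = 0.99, pretestSize = 15L,
                         pretestConfidence = 0.80, minimalSample = 2L,
                         localIters = 15L, outlierRatio = NA_real_,
                         gateZ = 1.96, minSampleSep = 1e-6, minSigma = 0,
                         seed = NA_integer_) {
  new("RansacConfig", confidence = confidence,
      pretestSize = as.integer(pretestSize),
      pretestConfidence = pretestConfidence,
      minimalSample = as.integer(minimalSample),
      localIters = as.integer(localIters),
      outlierRatio = as.numeric(outlierRatio), gateZ = gateZ,
      minSampleSep = minSampleSep, minSigma = minSigma,
      seed = as.integer(seed))
}

setMethod("show", "RansacConfig", function(object) {
  cat(sprintf(paste0("RansacConfig: P=%.2f, n=%d, Pt>=%.2f, m=%d, kL=%d, ",
                     "eps=%s, z=%.2f\n"),
              object@confidence, object@pretestSize,
              object@pretestConfidence, object@minimalSample,
              object@localIters,
              ifelse(is.na(object@outlierRatio), "NA",
                     sprintf("%.3f", object@outlierRatio)),
              object@gateZ))
})

#' Result of a robust line fit
#'
#' @slot model the fitted [LineModel-class].
#' @slot inlierIndices integer indices of the consensus set.
#' @slot sigma robust residual scale (mm) of the winning model.
#' @slot iterationsRun number of candidate minimal samples drawn.
#' @slot pretestRejections candidates discarded by the pretest without full
#'   verification (0 for the baseline estimator).
#' @slot fullVerifications candidates scored against the full dataset.
#' @slot flags character vector of diagnostic flags.
#' @export
setClass("RansacResult",
  slots = c(model = "LineModel", inlierIndices = "integer", sigma = "numeric",
            iterationsRun = "integer", pretestRejections = "integer",
            fullVerifications = "integer", flags = "character"))

#' Support (consensus size) of a RansacResult
#' @param x a [RansacResult-class].
#' @export
support <- function(x) length(x@inlierIndices)

#' Fitted model of a RansacResult
#' @param x a [RansacResult-class] (or a NeedleDetection).
#' @export
modelOf <- function(x) if (is(x, "NeedleDetection")) x@axis else x@model

#' Inlier indices of a result
#' @param x a [RansacResult-class] or [NeedleDetection-class].
#' @export
inlierIndices <- function(x) x@inlierIndices

setMethod("show", "RansacResult", function(object) {
  cat(sprintf(paste0("RansacResult: support %d, sigma %.4f mm, %d iterations ",
                     "(%d verified, %d pretest-rejected)%s\n"),
              support(object), object@sigma, object@iterationsRun,
              object@fullVerifications, object@pretestRejections,
              if (length(object@flags))
                paste0(" [", paste(object@flags, collapse = ","), "]")
              else ""))
})

#' One detected needle
#'
#' @slot axis fitted needle axis ([LineModel-class]).
#' @slot tip distal needle endpoint (x, y) in mm.
#' @slot entry proximal end of the detected shaft segment (x, y) in mm.
#' @slot inlierIndices indices into the slice's candidate [PointSet-class].
#' @slot order detection rank (1 = first extracted).
#' @slot sigma robust residual scale (mm).
#' @slot flags diagnostic flags (e.g. "tip_at_roi_edge").
#' @export
setClass("NeedleDetection",
  slots = c(axis = "LineModel", tip = "numeric", entry = "numeric",
            inlierIndices = "integer", order = "integer", sigma = "numeric",
            flags = "character"))

setValidity("NeedleDetection", function(object) {
  if (length(object@tip) != 2L || length(object@entry) != 2L)
    return("tip and entry must be (x, y) in mm")
  if (sqrt(sum((object@tip - object@entry)^2)) <= 0)
    return("tip must differ from entry")
  TRUE
})

#' Tip position of a detection
#' @param x a [NeedleDetection-class].
#' @return numeric(2) (x, y) in mm.
#' @export
tipOf <- function(x) x@tip

setMethod("show", "NeedleDetection", function(object) {
  cat(sprintf(paste0("NeedleDetection #%d: tip (%.2f, %.2f) mm, ",
                     "%d inliers, sigma %.3f mm%s\n"),
              object@order, object@tip[1L], object@tip[2L],
              length(object@inlierIndices), object@sigma,
              if (length(object@flags))
                paste0(" [", paste(object@flags, collapse = ","), "]")
              else ""))
})

#' Multi-needle extraction configuration
#'
#' @slot nNeedles known number of needles on the slice.
#' @slot epsNoise residual noise fraction of the candidate set after
#'   preprocessing (default 0.15).
#' @slot tipThreshold fixed intensity threshold T for tip localisation, or
#'   NA to train it from the slice (needle inliers vs background).
#' @slot acceptFrac a round's model is accepted only if its support is at
#'   least acceptFrac * nen (default 0.5).
#' @slot minRun minimal run length (profile samples) of the supra-threshold
#'   plateau (default 3).
#' @slot insertionEdge which image edge the needles enter from: "top",
#'   "bottom", "left", "right" or "auto" (nearest image edge).
#' @export
setClass("MultiNeedleConfig",
  slots = c(nNeedles = "integer", epsNoise = "numeric",
            tipThreshold = "numeric", acceptFrac = "numeric",
            minRun = "integer", insertionEdge = "character"))

setValidity("MultiNeedleConfig", function(object) {
  if (object@nNeedles < 1L) return("nNeedles must be >= 1")
  if (object@epsNoise < 0 || object@epsNoise >= 1)
    return("epsNoise must be in [0, 1)")
  if (!is.na(object@tipThreshold) &&
      (object@tipThreshold < 0 || object@tipThreshold > 1))
    return("tipThreshold must be in [0, 1] or NA (trained)")
  if (object@acceptFrac <= 0 || object@acceptFrac > 1)
    return("acceptFrac must be in (0, 1]")
  if (object@minRun < 1L) return("minRun must be >= 1")
  if (!object@insertionEdge %in% c("auto", "top", "bottom", "left", "right"))
    return("insertionEdge must be auto/top/bottom/left/right")
  TRUE
})

#' Construct a MultiNeedleConfig
#' @param nNeedles,epsNoise,tipThreshold,acceptFrac,minRun,insertionEdge
#'   see [MultiNeedleConfig-class].
#' @return A [MultiNeedleConfig-class] object.
#' @export
MultiNeedleConfig <- function(nNeedles = 1L, epsNoise = 0.15,
                              tipThreshold = NA_real_, acceptFrac = 0.5,
                              minRun = 3L, insertionEdge = "auto") {
  new("MultiNeedleConfig", nNeedles = as.integer(nNeedles),
      epsNoise = epsNoise, tipThreshold = as.numeric(tipThreshold),
      acceptFrac = acceptFrac, minRun = as.integer(minRun),
      insertionEdge = insertionEdge)
}

#' Intensity profile along a needle axis
#'
#' @slot t arc-length samples (mm), strictly increasing, measured from the
#'   entry-side origin.
#' @slot intensity normalised image intensity at each t.
#' @slot origin (x, y) mm of the t = 0 point.
#' @slot direction unit vector of increasing t (signed: points from entry
#'   towards the distal end).
#' @export
setClass("IntensityProfile",
  slots = c(t = "numeric", intensity = "numeric", origin = "numeric",
            direction = "numeric"))

setValidity("IntensityProfile", function(object) {
  if (length(object@t) != length(object@intensity))
    return("t and intensity must have equal length")
  if (length(object@t) > 1L && any(diff(object@t) <= 0))
    return("t must be strictly increasing")
  TRUE
})

setMethod("show", "IntensityProfile", function(object) {
  cat(sprintf("IntensityProfile: %d samples over %.2f mm\n",
              length(object@t),
              if (length(object@t)) diff(range(object@t)) else 0))
})
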