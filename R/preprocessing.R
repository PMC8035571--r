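# Slice preprocessing: contour-driven ROI extraction, gamma contrast
# stretching and intensity thresholding into a candidate point set.

#' Contrast mapping parameters
#'
#' Parameters of the saturating power-law intensity map: inputs in
#' [lowIn, highIn] are rescaled to [lowOut, highOut] through a gamma
#' curve; inputs below/above the input range saturate at the output
#' bounds.  gamma > 1 compresses low intensities and expands high ones,
#' which is what separates bright needle pixels from soft-tissue
#' background.
#'
#' @slot lowIn,highIn input saturation thresholds (normalised intensity).
#' @slot lowOut,highOut output range (normalised intensity).
#' @slot gamma positive exponent of the mapping curve.
#' @export
setClass("ContrastParams",
  slots = c(lowIn = "numeric", highIn = "numeric", lowOut = "numeric",
            highOut = "numeric", gamma = "numeric"))

setValidity("ContrastParams", function(object) {
  v <- c(object@lowIn, object@highIn, object@lowOut, object@highOut)
  if (any(v < 0 | v > 1)) return("intensity bounds must lie in [0, 1]")
  if (object@lowIn >= object@highIn) return("lowIn must be < highIn")
  if (object@lowOut >= object@highOut) return("lowOut must be < highOut")
  if (object@gamma <= 0) return("gamma must be positive")
  TRUE
})

#' Construct ContrastParams
#'
#' Defaults: input saturation at 15\% and 100\% of the intensity range,
#' output spanning [0, 1], gamma = 2.  The input thresholds follow the
#' standard operating point of the method; gamma and the downstream
#' threshold alpha are empirical and exposed in every configuration
#' surface.
#'
#' @param lowIn,highIn,lowOut,highOut,gamma see [ContrastParams-class].
#' @return A [ContrastParams-class] object.
#' @export
ContrastParams <- function(lowIn = 0.15, highIn = 1, lowOut = 0,
                           highOut = 1, gamma = 2) {
  new("ContrastParams", lowIn = lowIn, highIn = highIn, lowOut = lowOut,
      highOut = highOut, gamma = gamma)
}

#' ROI from the target contour
#'
#' Axis-aligned bounding box of the contour vertices, expanded by a safety
#' margin (mm, converted per axis to whole pixels, rounding outward) and
#' clipped to the image.  The margin guarantees that needle pixels just
#' outside the clinical target contour stay inside the search region.
#'
#' @param image a [SliceImage-class] whose contour slot is set, or one
#'   passed alongside an explicit `contour`.
#' @param marginMm expansion margin in mm (default 3).
#' @param contour optional M x 2 (row, col) vertex matrix overriding the
#'   image's contour.
#' @return A [Roi-class].
#' @export
roiFromContour <- function(image, marginMm = 3, contour = NULL) {
  stopifnot(is(image, "SliceImage"), marginMm >= 0)
  if (is.null(contour)) contour <- image@contour
  if (nrow(contour) < 3L) stop("contour must have at least 3 vertices")
  nr <- nrow(image@raster); nc <- ncol(image@raster)
  if (any(contour[, 1L] < 0) || any(contour[, 1L] > nr - 1L) ||
      any(contour[, 2L] < 0) || any(contour[, 2L] > nc - 1L))
    stop("contour lies (partly) outside the image")
  mrow <- ceiling(marginMm / image@pixelSpacing[1L])
  mcol <- ceiling(marginMm / image@pixelSpacing[2L])
  Roi(max(0, floor(min(contour[, 1L])) - mrow),
      max(0, floor(min(contour[, 2L])) - mcol),
      min(nr - 1L, ceiling(max(contour[, 1L])) + mrow),
      min(nc - 1L, ceiling(max(contour[, 2L])) + mcol))
}

# mm (x, y) -> 0-based pixel (row, col)
.mm_to_px <- function(xy, spacing) {
  cbind(row = xy[, 2L] / spacing[1L], col = xy[, 1L] / spacing[2L])
}

#' Grow a ROI until it contains all candidate points
#'
#' If any candidate needle points fall outside the ROI, the box is grown
#' in steps of `stepMm` (per axis, rounded outward to pixels) until all of
#' them are inside or the image boundary is reached.  Points outside the
#' image itself are reported via the `"outside"` attribute.
#'
#' @param roi a [Roi-class].
#' @param candidates a [PointSet-class] in mm coordinates.
#' @param stepMm growth step in mm (default 3).
#' @param image the [SliceImage-class] providing bounds and spacing.
#' @return A [Roi-class] (possibly unchanged), with attribute `outside`
#'   giving indices of candidates beyond the image bounds.
#' @export
expandRoiIfNeeded <- function(roi, candidates, stepMm = 3, image) {
  stopifnot(is(roi, "Roi"), is(candidates, "PointSet"),
            is(image, "SliceImage"), stepMm > 0)
  nr <- nrow(image@raster); nc <- ncol(image@raster)
  if (nPoints(candidates) == 0L) return(roi)
  px <- .mm_to_px(candidates@coords, image@pixelSpacing)
  outside_img <- which(px[, 1L] < 0 | px[, 1L] > nr - 1L |
                       px[, 2L] < 0 | px[, 2L] > nc - 1L)
  srow <- ceiling(stepMm / image@pixelSpacing[1L])
  scol <- ceiling(stepMm / image@pixelSpacing[2L])
  b <- roi@bounds
  inside <- function(b) {
    all(px[, 1L] >= b[1L] & px[, 1L] <= b[3L] &
        px[, 2L] >= b[2L] & px[, 2L] <= b[4L])
  }
  keep <- setdiff(seq_len(nrow(px)), outside_img)
  px_all <- px
  px <- px[keep, , drop = FALSE]
  while (nrow(px) && !inside(b) &&
         !(b[1L] == 0L && b[2L] == 0L && b[3L] == nr - 1L && b[4L] == nc - 1L)) {
    b <- c(max(0L, b[1L] - srow), max(0L, b[2L] - scol),
           min(nr - 1L, b[3L] + srow), min(nc - 1L, b[4L] + scol))
  }
  out <- Roi(b[1L], b[2L], b[3L], b[4L])
  attr(out, "outside") <- as.integer(outside_img)
  out
}

#' Saturating power-law contrast enhancement
#'
#' Per-pixel intensity map: values below `lowIn` saturate at `lowOut`,
#' values above `highIn` at `highOut`, and in-range values follow
#' `lowOut + (highOut - lowOut) * ((i - lowIn)/(highIn - lowIn))^gamma`.
#' The map is monotone nondecreasing in the input intensity.
#'
#' @param image a [SliceImage-class].
#' @param params a [ContrastParams-class].
#' @return A new [SliceImage-class] with the transformed raster.
#' @export
enhanceContrast <- function(image, params = ContrastParams()) {
  stopifnot(is(image, "SliceImage"), is(params, "ContrastParams"))
  i <- image@raster
  u <- (i - params@lowIn) / (params@highIn - params@lowIn)
  u <- pmin(pmax(u, 0), 1)
  out <- params@lowOut + (params@highOut - params@lowOut) * u^params@gamma
  SliceImage(matrix(out, nrow = nrow(i)), image@pixelSpacing,
             if (nrow(image@contour)) image@contour else NULL)
}

#' Threshold a slice into candidate needle points
#'
#' All pixels inside the ROI with intensity >= alpha become candidate
#' needle points, returned as pixel-centre coordinates converted to mm,
#' with their intensities.  The complementary background set is implied,
#' not materialised.
#'
#' @param image a [SliceImage-class].
#' @param alpha intensity threshold in [0, 1] (empirical; applied after
#'   contrast enhancement).
#' @param roi optional [Roi-class]; default is the whole image.
#' @return A [PointSet-class] (possibly empty).
#' @export
thresholdCandidates <- function(image, alpha, roi = NULL) {
  stopifnot(is(image, "SliceImage"))
  nr <- nrow(image@raster); nc <- ncol(image@raster)
  if (is.null(roi)) roi <- Roi(0L, 0L, nr - 1L, nc - 1L)
  b <- roi@bounds
  sub <- image@raster[(b[1L] + 1L):(b[3L] + 1L), (b[2L] + 1L):(b[4L] + 1L),
                      drop = FALSE]
  hit <- which(sub >= alpha, arr.ind = TRUE)
  if (nrow(hit) == 0L)
    return(PointSet(matrix(numeric(0), ncol = 2L)))
  row0 <- hit[, 1L] - 1L + b[1L]
  col0 <- hit[, 2L] - 1L + b[2L]
  PointSet(cbind(x = col0 * image@pixelSpacing[2L],
                 y = row0 * image@pixelSpacing[1L]),
           sub[hit])
}
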