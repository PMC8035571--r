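# Needle-tip localisation: intensity profile extraction along a fitted
# axis, threshold training from class samples, and the drop-point search.

#' Train the tip intensity threshold
#'
#' Estimates the intensity T at which the class-conditional densities of
#' needle and background pixels cross, i.e. where an intensity is equally
#' likely under both classes.  Both densities are modelled as Gaussians
#' fitted by moments; the crossing between the two class means is
#' returned.  With (near-)equal variances, or degenerate zero-variance
#' samples, the crossing is the midpoint of the means.
#'
#' @param needleSamples intensities sampled from known needle pixels.
#' @param backgroundSamples intensities sampled from background pixels.
#' @return threshold T (normalised intensity), strictly between the two
#'   class means.
#' @export
trainTipThreshold <- function(needleSamples, backgroundSamples) {
  stopifnot(length(needleSamples) > 0, length(backgroundSamples) > 0)
  mn <- mean(needleSamples); mb <- mean(backgroundSamples)
  if (mn <= mb)
    stop("needle mean intensity must exceed background mean; bad training data")
  sn <- stats::sd(needleSamples); sb <- stats::sd(backgroundSamples)
  if (is.na(sn)) sn <- 0
  if (is.na(sb)) sb <- 0
  midpoint <- (mn + mb) / 2
  if (sn < 1e-12 || sb < 1e-12 || abs(sn - sb) < 1e-9) return(midpoint)
  # equal-density crossing of two Gaussians: a*t^2 + b*t + cc = 0 from
  # equating the log densities
  a <- 1 / (2 * sb^2) - 1 / (2 * sn^2)
  b <- mn / sn^2 - mb / sb^2
  cc <- mb^2 / (2 * sb^2) - mn^2 / (2 * sn^2) + log(sb / sn)
  disc <- b^2 - 4 * a * cc
  if (disc < 0) return(midpoint)
  roots <- (-b + c(1, -1) * sqrt(disc)) / (2 * a)
  inside <- roots[roots > mb & roots < mn]
  if (length(inside) == 0L) return(midpoint)
  inside[which.min(abs(inside - midpoint))]
}

# Liang-Barsky clip of the parametric line anchor + t * dir against an
# axis-aligned mm rectangle; returns c(t0, t1) or NULL
.clip_line_rect <- function(anchor, dir, xlim, ylim) {
  t0 <- -Inf; t1 <- Inf
  for (ax in 1:2) {
    lo <- c(xlim[1L], ylim[1L])[ax]; hi <- c(xlim[2L], ylim[2L])[ax]
    p <- dir[ax]; q0 <- anchor[ax]
    if (abs(p) < 1e-12) {
      if (q0 < lo || q0 > hi) return(NULL)
    } else {
      ta <- (lo - q0) / p; tb <- (hi - q0) / p
      t0 <- max(t0, min(ta, tb)); t1 <- min(t1, max(ta, tb))
    }
  }
  if (t0 > t1) return(NULL)
  c(t0, t1)
}

# bilinear interpolation of the raster at mm positions (pixel-centre
# convention, clamped at the borders)
.bilinear <- function(image, xy) {
  r <- xy[, 2L] / image@pixelSpacing[1L]
  c_ <- xy[, 1L] / image@pixelSpacing[2L]
  nr <- nrow(image@raster); nc <- ncol(image@raster)
  r <- pmin(pmax(r, 0), nr - 1L); c_ <- pmin(pmax(c_, 0), nc - 1L)
  r0 <- pmin(floor(r), nr - 2L); c0 <- pmin(floor(c_), nc - 2L)
  if (nr == 1L) r0 <- rep(0, length(r))
  if (nc == 1L) c0 <- rep(0, length(c_))
  fr <- r - r0; fc <- c_ - c0
  idx <- function(rr, cc) image@raster[cbind(rr + 1L, cc + 1L)]
  (1 - fr) * (1 - fc) * idx(r0, c0) +
    (1 - fr) * fc * idx(r0, pmin(c0 + 1L, nc - 1L)) +
    fr * (1 - fc) * idx(pmin(r0 + 1L, nr - 1L), c0) +
    fr * fc * idx(pmin(r0 + 1L, nr - 1L), pmin(c0 + 1L, nc - 1L))
}

#' Intensity profile along a needle axis
#'
#' Samples the image by bilinear interpolation along the axis, restricted
#' to the ROI, at sub-pixel steps (half the finer pixel spacing).  The
#' profile runs from the entry side: either the endpoint nearest a named
#' image edge, or (`insertionEdge = "auto"`) the endpoint of the clipped
#' segment closest to any image edge.  In auto mode, when the geometric
#' rule is ambiguous (both clipped endpoints on an edge, as for an axis
#' crossing the whole ROI) the brighter end wins: the shaft hugs the
#' entry side of the profile while beyond the tip there is only
#' background.
#'
#' @param image a [SliceImage-class].
#' @param axis a [LineModel-class] in mm coordinates.
#' @param roi a [Roi-class]; the axis must intersect it.
#' @param insertionEdge `"auto"`, `"top"`, `"bottom"`, `"left"` or
#'   `"right"`.
#' @param step sample step in mm; default half the finer pixel spacing.
#' @return An [IntensityProfile-class].
#' @export
extractProfile <- function(image, axis, roi, insertionEdge = "auto",
                           step = NULL) {
  stopifnot(is(image, "SliceImage"), is(axis, "LineModel"), is(roi, "Roi"))
  sp <- image@pixelSpacing
  b <- roi@bounds
  xlim <- c(b[2L], b[4L]) * sp[2L]
  ylim <- c(b[1L], b[3L]) * sp[1L]
  tt <- .clip_line_rect(axis@anchor, axis@direction, xlim, ylim)
  if (is.null(tt) || diff(tt) < 1e-9)
    stop("axis does not intersect the ROI")
  ends <- rbind(.point_at(axis, tt[1L]), .point_at(axis, tt[2L]))
  nr <- nrow(image@raster); nc <- ncol(image@raster)
  w <- (nc - 1L) * sp[2L]; h <- (nr - 1L) * sp[1L]
  score <- switch(insertionEdge,
    top    = ends[, 2L],
    bottom = -ends[, 2L],
    left   = ends[, 1L],
    right  = -ends[, 1L],
    auto   = pmin(ends[, 1L], w - ends[, 1L], ends[, 2L], h - ends[, 2L]),
    stop("insertionEdge must be auto/top/bottom/left/right"))
  entry_end <- if (score[1L] <= score[2L]) 1L else 2L
  if (is.null(step)) step <- 0.5 * min(sp)
  len <- diff(range(tt))
  sample_from <- function(end) {
    t_entry <- tt[end]; t_far <- tt[c(2L, 1L)[end]]
    dir_signed <- axis@direction * sign(t_far - t_entry)
    origin <- .point_at(axis, t_entry)
    ts <- seq(0, len, by = step)
    if (ts[length(ts)] < len) ts <- c(ts, len)
    xy <- cbind(origin[1L] + ts * dir_signed[1L],
                origin[2L] + ts * dir_signed[2L])
    list(ts = ts, intensity = .bilinear(image, xy), origin = origin,
         direction = dir_signed)
  }
  pr <- sample_from(entry_end)
  if (insertionEdge == "auto" && abs(score[1L] - score[2L]) < 1e-6) {
    # geometric rule ambiguous: the shaft hugs the entry side, so the
    # brighter end of the profile is the entry
    q <- max(2L, ceiling(length(pr$ts) / 4))
    if (mean(utils::tail(pr$intensity, q)) >
        mean(utils::head(pr$intensity, q)) + 1e-9)
      pr <- sample_from(c(2L, 1L)[entry_end])
  }
  new("IntensityProfile", t = pr$ts, intensity = pr$intensity,
      origin = as.numeric(pr$origin), direction = as.numeric(pr$direction))
}

#' Localise the needle tip on an intensity profile
#'
#' The needle appears as a supra-threshold plateau starting at the entry
#' side; the tip is its distal drop point.  Runs of samples with
#' intensity >= T shorter than `minRun` are treated as isolated bright
#' noise and ignored.  The returned arc length is the linear
#' interpolation of the T-crossing just past the last sample of the last
#' qualifying run (the sample position itself when the profile ends while
#' still above T, flagged `"tip_at_roi_edge"`).
#'
#' @param profile an [IntensityProfile-class].
#' @param T intensity threshold (from [trainTipThreshold()] or fixed).
#' @param minRun minimal plateau length in samples (default 3).
#' @return arc length t_tip (mm) with attributes `index` (last plateau
#'   sample) and `flag` (character(0) or "tip_at_roi_edge").
#' @export
localizeTip <- function(profile, T, minRun = 3L) {
  stopifnot(is(profile, "IntensityProfile"), length(profile@t) > 0)
  above <- profile@intensity >= T
  if (!any(above)) stop("needle not present on axis: no sample reaches T")
  r <- rle(above)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  ok <- which(r$values & r$lengths >= minRun)
  if (length(ok) == 0L)
    stop("needle not present on axis: no supra-threshold run of length >= minRun")
  last <- ok[length(ok)]
  i <- ends[last]
  flag <- character(0)
  if (i == length(profile@t)) {
    t_tip <- profile@t[i]
    flag <- "tip_at_roi_edge"
  } else {
    i0 <- profile@intensity[i]; i1 <- profile@intensity[i + 1L]
    frac <- if (i0 - i1 > 1e-12) (i0 - T) / (i0 - i1) else 0
    t_tip <- profile@t[i] + frac * (profile@t[i + 1L] - profile@t[i])
  }
  structure(t_tip, index = i, flag = flag,
            entry_t = profile@t[starts[ok[1L]]])
}
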