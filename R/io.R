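# Format glue: slice readers (PNG/TIFF/CSV), contour JSON, detection
# JSON/CSV writers and the QC overlay image.

#' Read a CT slice image
#'
#' Reads a single-frame grayscale image from PNG, TIFF or a plain CSV
#' matrix.  Pixel spacing is not carried by these formats and must be
#' supplied (mm per pixel; scalar or per-axis).  Intensities outside
#' [0, 1] (e.g. raw CT stored values in a CSV) are min-max normalised per
#' slice; `normalize = "none"` requires values already in [0, 1].
#'
#' @param path image file (.png, .tif/.tiff or .csv).
#' @param pixelSpacing numeric(1) or numeric(2), mm per pixel (row, col).
#' @param contour optional M x 2 (row, col) matrix or path to a contour
#'   JSON file.
#' @param normalize "auto" (default), "minmax" or "none".
#' @return A [SliceImage-class].
#' @export
readSliceImage <- function(path, pixelSpacing, contour = NULL,
                           normalize = c("auto", "minmax", "none")) {
  normalize <- match.arg(normalize)
  ext <- tolower(tools::file_ext(path))
  m <- switch(ext,
    png = png::readPNG(path),
    tif = ,
    tiff = tiff::readTIFF(path),
    csv = as.matrix(utils::read.csv(path, header = FALSE)),
    stop("unsupported slice format: .", ext,
         " (use PNG, TIFF or CSV; convert DICOM upstream)"))
  if (length(dim(m)) == 3L) m <- (m[, , 1L] + m[, , 2L] + m[, , 3L]) / 3
  storage.mode(m) <- "double"
  rng <- range(m)
  if (normalize == "minmax" ||
      (normalize == "auto" && (rng[1L] < 0 || rng[2L] > 1))) {
    m <- if (diff(rng) > 0) (m - rng[1L]) / diff(rng) else m * 0
  }
  if (is.character(contour)) contour <- readContourJSON(contour)
  SliceImage(m, pixelSpacing, contour)
}

#' Read a contour JSON file
#'
#' Expects `{"vertices": [[row, col], ...]}` with 0-based pixel
#' coordinates.
#'
#' @param path JSON file path.
#' @return M x 2 numeric matrix of (row, col) vertices.
#' @export
readContourJSON <- function(path) {
  obj <- jsonlite::fromJSON(path)
  if (is.null(obj$vertices)) stop("contour JSON must contain 'vertices'")
  v <- as.matrix(obj$vertices)
  if (ncol(v) != 2L) stop("contour vertices must be [row, col] pairs")
  storage.mode(v) <- "double"
  v
}

#' Write candidate points as CSV
#'
#' Columns: x_mm, y_mm, intensity.
#'
#' @param points a [PointSet-class].
#' @param path output CSV path.
#' @return the path, invisibly.
#' @export
writeCandidatesCSV <- function(points, path) {
  stopifnot(is(points, "PointSet"))
  df <- data.frame(x_mm = points@coords[, 1L], y_mm = points@coords[, 2L],
                   intensity = if (length(points@intensity))
                     points@intensity else NA_real_)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

.det_to_list <- function(d) {
  list(needle_id = d@order,
       anchor_x_mm = d@axis@anchor[1L], anchor_y_mm = d@axis@anchor[2L],
       dir_x = d@axis@direction[1L], dir_y = d@axis@direction[2L],
       tip_x_mm = d@tip[1L], tip_y_mm = d@tip[2L],
       entry_x_mm = d@entry[1L], entry_y_mm = d@entry[2L],
       n_inliers = length(d@inlierIndices), sigma_mm = d@sigma,
       inlier_indices = d@inlierIndices,
       flags = as.list(d@flags))
}

#' Write detections to JSON
#'
#' Full per-needle record (axis, tip, entry, inliers, scale, flags);
#' [readDetectionsJSON()] restores the objects field by field.
#'
#' @param detections list of [NeedleDetection-class].
#' @param path output JSON path.
#' @return the path, invisibly.
#' @export
writeDetectionsJSON <- function(detections, path) {
  jsonlite::write_json(
    list(needles = lapply(detections, .det_to_list),
         missed = attr(detections, "missed") %||% 0L,
         n_candidates = attr(detections, "nCandidates") %||% NA_integer_),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Read detections from JSON
#'
#' @param path a JSON file written by [writeDetectionsJSON()].
#' @return list of [NeedleDetection-class] with attribute `missed`.
#' @export
readDetectionsJSON <- function(path) {
  obj <- jsonlite::fromJSON(path, simplifyDataFrame = FALSE)
  dets <- lapply(obj$needles, function(nd) {
    new("NeedleDetection",
        axis = LineModel(c(nd$anchor_x_mm, nd$anchor_y_mm),
                         c(nd$dir_x, nd$dir_y)),
        tip = c(nd$tip_x_mm, nd$tip_y_mm),
        entry = c(nd$entry_x_mm, nd$entry_y_mm),
        inlierIndices = as.integer(unlist(nd$inlier_indices)),
        order = as.integer(nd$needle_id), sigma = as.numeric(nd$sigma_mm),
        flags = as.character(unlist(nd$flags)))
  })
  structure(dets, missed = obj$missed %||% 0L,
            nCandidates = obj$n_candidates %||% NA_integer_)
}

#' Write detections as CSV
#'
#' One row per needle with the documented columns needle_id,
#' anchor_x_mm, anchor_y_mm, dir_x, dir_y, tip_x_mm, tip_y_mm,
#' n_inliers, sigma_mm.
#'
#' @param detections list of [NeedleDetection-class].
#' @param path output CSV path.
#' @return the path, invisibly.
#' @export
writeDetectionsCSV <- function(detections, path) {
  rows <- lapply(detections, function(d) {
    l <- .det_to_list(d)
    data.frame(l[c("needle_id", "anchor_x_mm", "anchor_y_mm", "dir_x",
                   "dir_y", "tip_x_mm", "tip_y_mm", "n_inliers",
                   "sigma_mm")])
  })
  df <- if (length(rows)) do.call(rbind, rows)
        else data.frame(needle_id = integer(0))
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

# draw a straight stroke into an RGB array (0-based mm geometry)
.draw_segment <- function(rgb, image, p0, p1, col) {
  sp <- image@pixelSpacing
  len <- sqrt(sum((p1 - p0)^2))
  if (len <= 0) return(rgb)
  ts <- seq(0, len, by = min(sp) / 2)
  xs <- p0[1L] + ts / len * (p1[1L] - p0[1L])
  ys <- p0[2L] + ts / len * (p1[2L] - p0[2L])
  rr <- round(ys / sp[1L]) + 1L; cc <- round(xs / sp[2L]) + 1L
  keep <- rr >= 1L & rr <= dim(rgb)[1L] & cc >= 1L & cc <= dim(rgb)[2L]
  for (ch in 1:3) rgb[cbind(rr[keep], cc[keep], ch)] <- col[ch]
  rgb
}

#' Write a QC overlay image
#'
#' Writes the slice as PNG with detected needle axes drawn in red and
#' tips as green dots.
#'
#' @param image the [SliceImage-class] that was analysed.
#' @param detections list of [NeedleDetection-class].
#' @param path output PNG path.
#' @return the path, invisibly.
#' @export
writeOverlayPNG <- function(image, detections, path) {
  stopifnot(is(image, "SliceImage"))
  g <- image@raster
  rgb <- array(rep(g, 3L), dim = c(nrow(g), ncol(g), 3L))
  sp <- image@pixelSpacing
  for (d in detections) {
    rgb <- .draw_segment(rgb, image, d@entry, d@tip, c(1, 0, 0))
    rr <- round(d@tip[2L] / sp[1L]) + 1L
    cc <- round(d@tip[1L] / sp[2L]) + 1L
    for (dr in -1:1) for (dc in -1:1) {
      r <- rr + dr; c_ <- cc + dc
      if (r >= 1L && r <= nrow(g) && c_ >= 1L && c_ <= ncol(g)) {
        rgb[r, c_, ] <- c(0, 1, 0)
      }
    }
  }
  png::writePNG(rgb, path)
  invisible(path)
}
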