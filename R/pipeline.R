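# Per-slice orchestration: successive multi-needle extraction with
# round-wise outlier-ratio bookkeeping, tip localisation, matching of
# detections against ground truth.

#' Expected inliers per needle
#'
#' nen = floor(N0 * (1 - epsNoise) / nNeedles): of the N0 initial
#' candidate points, a fraction epsNoise is residual noise and the rest is
#' assumed to split evenly over the known number of needles.
#'
#' @param N0 initial candidate count.
#' @param epsNoise residual noise fraction after preprocessing.
#' @param nNeedles number of needles on the slice.
#' @return integer nen >= 0.
#' @examples
#' expectedInliersPerNeedle(1500, 0.15, 3)   # 425
#' @export
expectedInliersPerNeedle <- function(N0, epsNoise, nNeedles) {
  stopifnot(N0 >= 0, epsNoise >= 0, epsNoise < 1, nNeedles >= 1)
  as.integer(floor(N0 * (1 - epsNoise) / nNeedles))
}

#' Outlier ratio for the current extraction round
#'
#' eps = (Nj - nen) / Nj: with Nj candidate points remaining and nen
#' expected to belong to the needle extracted next, everything else
#' (noise plus the other needles) counts as outliers.
#'
#' @param Nj number of candidate points remaining after j deletions.
#' @param nen expected inliers of one needle ([expectedInliersPerNeedle()]).
#' @return eps in [0, 1); when nen exceeds Nj (late-stage depletion) the
#'   ratio is clamped to 0 with a warning.
#' @examples
#' currentOutlierRatio(1500, 425)
#' @export
currentOutlierRatio <- function(Nj, nen) {
  stopifnot(Nj > 0, nen >= 0)
  if (nen > Nj) {
    warning("expected inliers exceed remaining candidates; clamping eps to 0")
    return(0)
  }
  (Nj - nen) / Nj
}

# deterministic background sample for threshold training: ROI pixels below
# alpha whose 8-neighbourhood is also below alpha (partial-volume pixels on
# the needle boundary belong to neither class cleanly and would inflate the
# background variance), thinned by a fixed stride
.background_sample <- function(image, roi, alpha, max_n = 5000L) {
  b <- roi@bounds
  sub <- image@raster[(b[1L] + 1L):(b[3L] + 1L), (b[2L] + 1L):(b[4L] + 1L),
                      drop = FALSE]
  nr <- nrow(sub); nc <- ncol(sub)
  near <- sub >= alpha
  if (nr > 2L && nc > 2L) {
    grown <- near
    for (dr in -1:1) for (dc in -1:1) {
      if (dr == 0L && dc == 0L) next
      rs <- pmin(pmax(seq_len(nr) + dr, 1L), nr)
      cs <- pmin(pmax(seq_len(nc) + dc, 1L), nc)
      grown <- grown | near[rs, cs, drop = FALSE]
    }
    near <- grown
  }
  bg <- sub[!near]
  if (length(bg) > max_n) bg <- bg[seq(1L, length(bg), length.out = max_n)]
  bg
}

#' Detect all needles on a slice
#'
#' Runs the full per-slice pipeline: contrast enhancement and
#' thresholding inside the contour-derived ROI, then up to `nNeedles`
#' rounds of single-needle estimation with successive inlier deletion.
#' Before each round the outlier ratio is recomputed from the remaining
#' candidate count and the expected per-needle inlier count; after an
#' accepted needle its inliers are removed.  A round's model is accepted
#' only if its support reaches `acceptFrac * nen`; otherwise extraction
#' stops and the remaining needles are reported as missed.  Tips are
#' localised on the enhanced image along each fitted axis.
#'
#' @param image a [SliceImage-class] (raw, un-enhanced intensities).
#' @param cfg a [RansacConfig-class]; its `outlierRatio` is overwritten
#'   round by round; its `seed` (if not NA) seeds the whole extraction.
#' @param mcfg a [MultiNeedleConfig-class].
#' @param marginMm ROI expansion margin in mm (default 3).
#' @param contrast a [ContrastParams-class].
#' @param alpha candidate threshold on the enhanced image (default 0.85).
#' @return list of [NeedleDetection-class] objects (possibly shorter than
#'   `nNeedles`), with attributes `missed` (count), `nCandidates` (N0),
#'   `roi`, and `candidates` (the thresholded [PointSet-class]).
#' @export
detectNeedles <- function(image, cfg, mcfg, marginMm = 3,
                          contrast = ContrastParams(), alpha = 0.85) {
  stopifnot(is(image, "SliceImage"), is(cfg, "RansacConfig"),
            is(mcfg, "MultiNeedleConfig"))
  .maybe_seed(cfg@seed)
  cfg@seed <- NA_integer_
  if (cfg@minSampleSep <= 1e-6)
    cfg@minSampleSep <- 0.5 * min(image@pixelSpacing)
  # raster candidates are quantised to pixel centres: the inlier gate must
  # bridge at least one pixel pitch in any orientation, or an exactly
  # collinear pixel column can never aggregate its neighbours
  if (cfg@minSigma <= 0)
    cfg@minSigma <- 1.2 * min(image@pixelSpacing) / cfg@gateZ
  roi <- if (nrow(image@contour) >= 3L) roiFromContour(image, marginMm)
         else Roi(0L, 0L, nrow(image@raster) - 1L, ncol(image@raster) - 1L)
  enhanced <- enhanceContrast(image, contrast)
  candidates <- thresholdCandidates(enhanced, alpha, roi)
  N0 <- nPoints(candidates)
  empty <- structure(list(), missed = mcfg@nNeedles, nCandidates = N0,
                     roi = roi, candidates = candidates)
  if (N0 < 2L * cfg@minimalSample) return(empty)
  nen <- expectedInliersPerNeedle(N0, mcfg@epsNoise, mcfg@nNeedles)
  if (nen < cfg@minimalSample) return(empty)

  detections <- list()
  remaining <- seq_len(N0)  # indices into the original candidate set
  for (ord in seq_len(mcfg@nNeedles)) {
    Nj <- length(remaining)
    if (Nj < max(2L * cfg@minimalSample, cfg@pretestSize)) break
    cfg@outlierRatio <- suppressWarnings(currentOutlierRatio(Nj, nen))
    pts_j <- candidates[remaining]
    res <- tryCatch(detectSingleNeedle(pts_j, cfg), error = function(e) NULL)
    if (is.null(res) || support(res) < mcfg@acceptFrac * nen) break
    inl_orig <- remaining[res@inlierIndices]

    # tip localisation on the enhanced image
    T_use <- mcfg@tipThreshold
    if (is.na(T_use)) {
      T_use <- tryCatch(
        trainTipThreshold(candidates@intensity[inl_orig],
                          .background_sample(enhanced, roi, alpha)),
        error = function(e) alpha)
    }
    det <- tryCatch({
      prof <- extractProfile(enhanced, res@model, roi, mcfg@insertionEdge)
      t_tip <- localizeTip(prof, T_use, mcfg@minRun)
      tip <- prof@origin + as.numeric(t_tip) * prof@direction
      entry <- prof@origin + attr(t_tip, "entry_t") * prof@direction
      new("NeedleDetection", axis = res@model, tip = tip, entry = entry,
          inlierIndices = as.integer(inl_orig), order = as.integer(ord),
          sigma = res@sigma, flags = attr(t_tip, "flag"))
    }, error = function(e) NULL)
    if (is.null(det)) {
      # axis found but no usable profile: keep the axis, flag the tip
      seg <- range(pointLineDistance(pts_j[res@inlierIndices], res@model))
      proj <- as.numeric((coords(pts_j[res@inlierIndices]) -
                          matrix(res@model@anchor, support(res), 2L,
                                 byrow = TRUE)) %*% res@model@direction)
      det <- new("NeedleDetection", axis = res@model,
                 tip = .point_at(res@model, max(proj)),
                 entry = .point_at(res@model, min(proj)),
                 inlierIndices = as.integer(inl_orig),
                 order = as.integer(ord), sigma = res@sigma,
                 flags = "tip_from_inlier_extent")
    }
    detections[[ord]] <- det
    remaining <- setdiff(remaining, inl_orig)
  }
  structure(detections, missed = mcfg@nNeedles - length(detections),
            nCandidates = N0, roi = roi, candidates = candidates)
}

#' Match detections to ground truth and score them
#'
#' Greedy bipartite matching by smallest angular deviation (ties broken by
#' tip deviation), then per-needle beta (degrees) and xi (mm) plus summary
#' statistics.  Cardinality mismatches are reported as missed or spurious
#' needles, not errors.
#'
#' @param detections list of [NeedleDetection-class] (or of lists with
#'   elements `axis` and `tip`).
#' @param truth list of lists with elements `axis` ([LineModel-class]) and
#'   `tip` (numeric(2), mm).
#' @return list with `perNeedle` (data.frame: truthId, detId, beta, xi),
#'   `meanBeta`, `sdBeta`, `meanXi`, `sdXi`, `detectionRate`, `missed`,
#'   `spurious`.
#' @export
evaluateDetections <- function(detections, truth) {
  getAxis <- function(d) if (is(d, "NeedleDetection")) d@axis else d$axis
  getTip <- function(d) if (is(d, "NeedleDetection")) d@tip else d$tip
  nd <- length(detections); nt <- length(truth)
  if (nt == 0L) stop("ground truth must contain at least one needle")
  beta <- matrix(Inf, nt, max(nd, 1L)); xi <- beta
  for (i in seq_len(nt)) for (j in seq_len(nd)) {
    beta[i, j] <- angularDeviation(truth[[i]]$axis, getAxis(detections[[j]]))
    xi[i, j] <- tipDeviation(truth[[i]]$tip, getTip(detections[[j]]))
  }
  rows <- list()
  used_t <- logical(nt); used_d <- logical(max(nd, 1L))
  for (k in seq_len(min(nt, nd))) {
    bb <- beta; bb[used_t, ] <- Inf; bb[, used_d] <- Inf
    cand <- which(bb == min(bb), arr.ind = TRUE)
    if (!is.finite(min(bb))) break
    if (nrow(cand) > 1L)
      cand <- cand[order(xi[cand]), , drop = FALSE]
    i <- cand[1L, 1L]; j <- cand[1L, 2L]
    used_t[i] <- TRUE; used_d[j] <- TRUE
    rows[[k]] <- data.frame(truthId = i, detId = j,
                            beta = beta[i, j], xi = xi[i, j])
  }
  per <- if (length(rows)) do.call(rbind, rows)
         else data.frame(truthId = integer(0), detId = integer(0),
                         beta = numeric(0), xi = numeric(0))
  list(perNeedle = per,
       meanBeta = if (nrow(per)) mean(per$beta) else NA_real_,
       sdBeta = if (nrow(per) > 1L) stats::sd(per$beta) else NA_real_,
       meanXi = if (nrow(per)) mean(per$xi) else NA_real_,
       sdXi = if (nrow(per) > 1L) stats::sd(per$xi) else NA_real_,
       detectionRate = 100 * nrow(per) / nt,
       missed = nt - nrow(per),
       spurious = nd - nrow(per))
}
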