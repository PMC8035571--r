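# Robust line estimation: sample-count bounds, the binomial pretest, the
# robust residual scale and inlier gate, the baseline estimator and the
# pretest-accelerated, locally optimised estimator.

#' Minimal number of RANSAC samples
#'
#' Smallest integer k such that, with per-sample success probability
#' (1 - eps)^m * Pt, at least one uncontaminated minimal sample that also
#' survives the pretest is drawn with confidence P:
#' k >= log(1 - P) / log(1 - (1 - eps)^m * Pt).  With Pt = 1 this is the
#' classical RANSAC bound.
#'
#' @param P required confidence, in (0, 1).
#' @param eps assumed outlier ratio, in [0, 1).
#' @param m minimal sample size (2 for a 2D line).
#' @param Pt pretest pass probability for a correct model, in (0, 1];
#'   1 when no pretest is used.
#' @return integer k >= 1.
#' @examples
#' minSamples(0.99, 0.5, 2)        # 17
#' minSamples(0.99, 0.5, 2, 0.8)   # 21
#' @export
minSamples <- function(P, eps, m, Pt = 1) {
  stopifnot(P > 0, P < 1, eps >= 0, eps < 1, m >= 1, Pt > 0, Pt <= 1)
  q <- (1 - eps)^m * Pt
  if (q >= 1) return(1L)
  max(1L, as.integer(ceiling(log(1 - P) / log(1 - q))))
}

#' Probability that a correct model passes the pretest
#'
#' A candidate model is scored on a random subset of n points and kept only
#' if at least nf of them are inliers.  For a correct model each subset
#' point is an inlier with probability 1 - eps, so the pass probability is
#' the upper binomial tail
#' Pt = 1 - sum_{i=0}^{nf-1} C(n, i) eps^(n-i) (1-eps)^i.
#'
#' @param n pretest subset size.
#' @param nf minimal number of subset inliers required.
#' @param eps outlier ratio, in [0, 1].
#' @return probability in [0, 1]; nf = 0 gives 1 (empty criterion).
#' @examples
#' pretestPassProbability(2, 1, 0.5)   # 0.75
#' @export
pretestPassProbability <- function(n, nf, eps) {
  stopifnot(n >= 1, nf >= 0, nf <= n, eps >= 0, eps <= 1)
  if (nf == 0L) return(1)
  i <- 0:(nf - 1L)
  pt <- 1 - sum(choose(n, i) * eps^(n - i) * (1 - eps)^i)
  min(max(pt, 0), 1)
}

#' Strictest feasible pretest criterion
#'
#' Scans nf = n, n-1, ..., 0 and returns the largest nf whose pass
#' probability for a correct model still meets the minimal confidence
#' PtMin, together with that probability.  nf = 0 (pass everything) is
#' always feasible.
#'
#' @param n pretest subset size.
#' @param eps outlier ratio, in [0, 1).
#' @param PtMin minimal acceptable pass probability, in (0, 1].
#' @return list with elements `nf` (integer) and `Pt` (its pass
#'   probability).
#' @examples
#' selectNf(15, 0.3, 0.8)   # nf = 9
#' @export
selectNf <- function(n, eps, PtMin) {
  stopifnot(n >= 1, eps >= 0, eps < 1, PtMin > 0, PtMin <= 1)
  for (nf in seq.int(n, 0L)) {
    pt <- pretestPassProbability(n, nf, eps)
    if (pt >= PtMin) return(list(nf = as.integer(nf), Pt = pt))
  }
  list(nf = 0L, Pt = 1)  # unreachable; nf = 0 always satisfies
}

#' Robust residual scale
#'
#' Median-based robust estimate of the residual standard deviation,
#' sigma = 1.4826 * (1 + 5 / (n - m)) * median(|d|), valid for n >= 2m.
#' The 1.4826 factor makes the median of absolute residuals consistent for
#' Gaussian noise; the (1 + 5/(n-m)) term is a small-sample correction.
#'
#' @param residuals numeric vector of residuals (mm); absolute values are
#'   taken internally.
#' @param m number of model parameters absorbed by the fit (minimal sample
#'   size, 2 for a 2D line).
#' @return sigma >= 0 (mm).
#' @examples
#' robustSigma(c(rep(1, 6), rep(-1, 6)), 2)   # 1.4826 * 1.5
#' @export
robustSigma <- function(residuals, m) {
  n <- length(residuals)
  if (n < 2L * m)
    stop("robustSigma requires n >= 2m residuals (formula validity)")
  1.4826 * (1 + 5 / (n - m)) * stats::median(abs(residuals))
}

# Robust scale under a known contamination fraction eps: the (1-eps)/2
# quantile of |d| estimates the inlier median, so the same 1.4826 *
# (1 + 5/(n-m)) factor yields a noise-scale estimate that stays consistent
# beyond 50% contamination.  Reduces to robustSigma() at eps = 0.
.robust_scale <- function(absd, m, eps = 0) {
  n <- length(absd)
  if (n < 2L * m) stop("robust scale requires n >= 2m residuals")
  q <- (1 - eps) / 2
  1.4826 * (1 + 5 / (n - m)) * stats::quantile(absd, q, names = FALSE)
}

# numeric tolerance used when sigma is exactly 0 (points "on" the line)
.ZERO_GATE <- 1e-9

#' Gate points into inliers of a line
#'
#' A point is an inlier when its perpendicular distance satisfies
#' d <= z * sigma.  With sigma = 0 only points within 1e-9 mm of the line
#' qualify.
#'
#' @param points a [PointSet-class] or N x 2 matrix.
#' @param model a [LineModel-class].
#' @param sigma residual scale (mm), >= 0.
#' @param z gate multiplier (default 1.96).
#' @return integer vector of inlier indices.
#' @export
gateInliers <- function(points, model, sigma, z = 1.96) {
  stopifnot(sigma >= 0)
  d <- pointLineDistance(points, model)
  thr <- if (sigma > 0) z * sigma else .ZERO_GATE
  which(d <= thr)
}

# --- internal machinery --------------------------------------------------

# probability that a true inlier falls inside the z-sigma gate; used to
# convert the nominal outlier ratio into the effective per-point success
# probability of the pretest binomial model
.gate_capture <- function(z) 2 * stats::pnorm(z) - 1

.effective_eps <- function(eps, z) min(1 - (1 - eps) * .gate_capture(z), 1 - 1e-12)

# exact line through two points; NULL when degenerate
.two_point_line <- function(p1, p2, min_sep) {
  d <- p2 - p1
  if (sqrt(sum(d^2)) <= max(min_sep, .Machine$double.eps)) return(NULL)
  LineModel(p1, d)
}

# draw a non-degenerate 2-point sample; degenerate draws are redrawn and
# not counted against the iteration budget
.sample_model <- function(xy, min_sep, max_tries = 100L) {
  n <- nrow(xy)
  for (i in seq_len(max_tries)) {
    idx <- sample.int(n, 2L)
    ln <- .two_point_line(xy[idx[1L], ], xy[idx[2L], ], min_sep)
    if (!is.null(ln)) return(ln)
  }
  NULL
}

# score a candidate on the full dataset: robust scale at the known
# contamination level (floored at cfg minSigma), then the z-sigma gate
.score_model <- function(xy, model, m, eps, z, min_sigma = 0) {
  absd <- pointLineDistance(xy, model)
  sigma <- max(.robust_scale(absd, m, eps), min_sigma)
  thr <- if (sigma > 0) z * sigma else .ZERO_GATE
  list(sigma = as.numeric(sigma), inliers = which(absd <= thr))
}

# candidate ranking: minimal robust scale, then larger support, then the
# earlier iteration (strict improvement required)
.better <- function(sigma, supp, best_sigma, best_supp) {
  if (sigma < best_sigma - 1e-12) return(TRUE)
  if (sigma <= best_sigma + 1e-12 && supp > best_supp) return(TRUE)
  FALSE
}

.check_points <- function(points, cfg) {
  stopifnot(is(points, "PointSet"), is(cfg, "RansacConfig"))
  if (is.na(cfg@outlierRatio))
    stop("cfg@outlierRatio must be set before running the estimator")
  if (nPoints(points) < cfg@minimalSample)
    stop("fewer points than the minimal sample size")
  if (nPoints(points) < 2L * cfg@minimalSample)
    stop("need at least 2m points for the robust residual scale")
  invisible(TRUE)
}

.maybe_seed <- function(seed) if (!is.na(seed)) set.seed(seed)

# --- estimators ----------------------------------------------------------

#' Baseline RANSAC line estimator
#'
#' Classical minimal-sample consensus without pretest or local
#' optimisation: k = minSamples(P, eps, m) candidate lines are drawn, each
#' an exact fit through 2 random points, and each is scored on all N
#' points (robust residual scale at the assumed contamination level, then
#' the z-sigma inlier gate).  Candidates are ranked by minimal robust
#' scale, with consensus size and iteration order as tie-breaks; the
#' returned model is the raw winning two-point line.
#'
#' @param points a [PointSet-class] with at least 2m points.
#' @param cfg a [RansacConfig-class]; `outlierRatio` must be set.
#' @return A [RansacResult-class].
#' @examples
#' set.seed(1)
#' xy <- cbind(seq(0, 50, length.out = 60), seq(0, 25, length.out = 60))
#' r <- ransacBaseline(PointSet(xy), RansacConfig(outlierRatio = 0, seed = 7L))
#' support(r)
#' @export
ransacBaseline <- function(points, cfg) {
  .check_points(points, cfg)
  .maybe_seed(cfg@seed)
  xy <- points@coords
  m <- cfg@minimalSample
  eps <- cfg@outlierRatio
  k <- minSamples(cfg@confidence, eps, m)
  best <- NULL; best_sigma <- Inf; best_supp <- -1L
  for (it in seq_len(k)) {
    model <- .sample_model(xy, cfg@minSampleSep)
    if (is.null(model)) next
    sc <- .score_model(xy, model, m, eps, cfg@gateZ, cfg@minSigma)
    if (.better(sc$sigma, length(sc$inliers), best_sigma, best_supp)) {
      best <- list(model = model, sc = sc)
      best_sigma <- sc$sigma; best_supp <- length(sc$inliers)
    }
  }
  if (is.null(best))
    stop("all candidate samples were degenerate; cannot fit a line")
  new("RansacResult", model = best$model,
      inlierIndices = as.integer(best$sc$inliers), sigma = best_sigma,
      iterationsRun = as.integer(k), pretestRejections = 0L,
      fullVerifications = as.integer(k), flags = character(0))
}

#' Pretest-accelerated RANSAC line estimator
#'
#' Each candidate line is first scored on a fresh random subset of n
#' points; candidates with fewer than nf subset inliers are rejected
#' without touching the remaining data.  nf and the associated pass
#' probability Pt come from [selectNf()] at the effective contamination
#' ratio (the nominal ratio inflated by the 5\% of true inliers that fall
#' outside the 1.96 sigma gate), and the iteration budget is the
#' pretest-adjusted bound [minSamples()] with that Pt.  The pretest gate
#' uses the smaller of the subset's own robust scale and the best
#' full-data scale seen so far, so that once a clean model has been
#' verified the screening operates at the true noise scale.  Surviving
#' candidates are verified on all N points exactly as in
#' [ransacBaseline()].
#'
#' @param points a [PointSet-class]; must have at least `cfg@pretestSize`
#'   points.
#' @param cfg a [RansacConfig-class]; `outlierRatio` must be set.
#' @return A [RansacResult-class]; `pretestRejections` counts candidates
#'   discarded before full verification.
#' @export
ransacPretest <- function(points, cfg) {
  .check_points(points, cfg)
  N <- nPoints(points)
  n <- cfg@pretestSize
  if (n > N) stop("pretest subset size exceeds the number of points")
  .maybe_seed(cfg@seed)
  xy <- points@coords
  m <- cfg@minimalSample
  eps <- cfg@outlierRatio
  eff <- .effective_eps(eps, cfg@gateZ)
  sel <- selectNf(n, eff, cfg@pretestConfidence)
  k <- minSamples(cfg@confidence, eps, m, sel$Pt)
  best <- NULL; best_sigma <- Inf; best_supp <- -1L
  rejections <- 0L
  for (it in seq_len(k)) {
    model <- .sample_model(xy, cfg@minSampleSep)
    if (is.null(model)) next
    sub <- sample.int(N, n)
    absd <- pointLineDistance(xy[sub, , drop = FALSE], model)
    sig_pre <- max(min(.robust_scale(absd, m, eps), best_sigma), cfg@minSigma)
    thr <- if (sig_pre > 0) cfg@gateZ * sig_pre else .ZERO_GATE
    if (sum(absd <= thr) < sel$nf) {
      rejections <- rejections + 1L
      next
    }
    sc <- .score_model(xy, model, m, eps, cfg@gateZ, cfg@minSigma)
    if (.better(sc$sigma, length(sc$inliers), best_sigma, best_supp)) {
      best <- list(model = model, sc = sc)
      best_sigma <- sc$sigma; best_supp <- length(sc$inliers)
    }
  }
  if (is.null(best))
    stop("no candidate model passed the pretest; check the assumed outlier ratio")
  new("RansacResult", model = best$model,
      inlierIndices = as.integer(best$sc$inliers), sigma = best_sigma,
      iterationsRun = as.integer(k), pretestRejections = rejections,
      fullVerifications = as.integer(k - rejections), flags = character(0))
}

#' Local optimisation of a consensus set
#'
#' Refines a seed solution by kL rounds of resampling restricted to the
#' seed's inlier set: each round draws a (larger than minimal) subset,
#' fits it by total least squares and re-scores it on the inlier set; the
#' round with the largest support (then smallest scale) wins.  The final
#' model is the PCA (total-least-squares) fit of the winning consensus
#' set, re-gated against all points.  The returned support never falls
#' below the seed's.
#'
#' @param points the full [PointSet-class] the seed was estimated from.
#' @param seedResult a [RansacResult-class] with at least m inliers.
#' @param cfg a [RansacConfig-class].
#' @return A [RansacResult-class] whose counters carry over from the seed.
#' @export
localOptimize <- function(points, seedResult, cfg) {
  stopifnot(is(points, "PointSet"), is(seedResult, "RansacResult"),
            is(cfg, "RansacConfig"))
  .maybe_seed(cfg@seed)
  xy <- points@coords
  m <- cfg@minimalSample
  S0 <- seedResult@inlierIndices
  if (length(S0) < m)
    stop("seed result must have at least m inliers")
  degenerate <- function(res, flag) {
    res@flags <- unique(c(res@flags, flag))
    res
  }
  if (length(S0) < 2L * m || max(abs(sweep(xy[S0, , drop = FALSE], 2L,
                                           colMeans(xy[S0, , drop = FALSE])))) < 1e-12)
    return(degenerate(seedResult, "lo_degenerate_inliers"))

  sub_xy <- xy[S0, , drop = FALSE]
  s_lo <- max(m, min(14L, length(S0) %/% 2L))
  best_cons <- S0
  best_supp <- length(S0); best_sigma <- seedResult@sigma
  best_model <- seedResult@model
  for (it in seq_len(cfg@localIters)) {
    idx <- sample.int(length(S0), s_lo)
    model <- tryCatch(fitLinePCA(sub_xy[idx, , drop = FALSE]),
                      error = function(e) NULL)
    if (is.null(model)) next
    absd <- pointLineDistance(sub_xy, model)
    sigma <- max(robustSigma(absd, m), cfg@minSigma)
    thr <- if (sigma > 0) cfg@gateZ * sigma else .ZERO_GATE
    inl <- which(absd <= thr)
    if (length(inl) > best_supp ||
        (length(inl) == best_supp && sigma < best_sigma - 1e-12)) {
      best_supp <- length(inl); best_sigma <- sigma
      best_model <- model; best_cons <- S0[inl]
    }
  }
  if (length(best_cons) < 2L)
    return(degenerate(seedResult, "lo_degenerate_consensus"))
  final_model <- tryCatch(fitLinePCA(xy[best_cons, , drop = FALSE]),
                          error = function(e) NULL)
  if (is.null(final_model))
    return(degenerate(seedResult, "lo_degenerate_consensus"))
  sig_f <- max(robustSigma(pointLineDistance(xy[best_cons, , drop = FALSE],
                                             final_model), m), cfg@minSigma)
  inl_f <- gateInliers(points, final_model, sig_f, cfg@gateZ)
  if (length(inl_f) < length(S0)) {
    # widen to the seed's scale before giving up on the refined model
    inl_f <- gateInliers(points, final_model, max(sig_f, seedResult@sigma),
                         cfg@gateZ)
    if (length(inl_f) < length(S0))
      return(degenerate(seedResult, "lo_no_gain"))
  }
  new("RansacResult", model = final_model, inlierIndices = as.integer(inl_f),
      sigma = as.numeric(sig_f), iterationsRun = seedResult@iterationsRun,
      pretestRejections = seedResult@pretestRejections,
      fullVerifications = seedResult@fullVerifications,
      flags = character(0))
}

#' Detect a single needle axis
#'
#' The full single-needle estimator: pretest-accelerated consensus
#' ([ransacPretest()]) followed by local optimisation and the final
#' total-least-squares fit ([localOptimize()]).
#'
#' @param points a [PointSet-class].
#' @param cfg a [RansacConfig-class]; `outlierRatio` must be set.
#' @return A [RansacResult-class].
#' @export
detectSingleNeedle <- function(points, cfg) {
  .maybe_seed(cfg@seed)
  cfg@seed <- NA_integer_  # continue the stream through both stages
  seed_res <- ransacPretest(points, cfg)
  localOptimize(points, seed_res, cfg)
}
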