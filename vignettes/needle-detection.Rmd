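---
title: "Robust needle detection in transverse CT slices"
author: "needleCT"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Robust needle detection in transverse CT slices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(needleCT)
```

## The problem

In CT image-guided lung interstitial brachytherapy, hollow needles are
inserted through a coplanar template into the tumour and radioactive seeds
are implanted through them. Verifying where the needles actually ended up —
quickly, on the intraoperative CT — is what makes dose correction possible
before the seeds go in. On a transverse slice a needle appears as a short,
bright, straight streak, surrounded by soft tissue, ribs, metal artifacts
and noise. The task is therefore robust estimation: find one or several
straight lines in a heavily contaminated 2D point cloud, then find each
needle's distal endpoint (tip) along its line.

needleCT implements the full per-slice pipeline: region-of-interest (ROI)
extraction from the clinical target contour, contrast enhancement,
thresholding into candidate points, robust line estimation, tip
localisation, and multi-needle extraction by successive deletion of each
accepted needle's inliers. A synthetic-data module generates planted-line
point clouds and rendered needle-phantom slices with exact ground truth, so
everything can be exercised and benchmarked without clinical data.

## Preprocessing

A slice enters as a raster of normalised intensities in $[0,1]$ (raw
stored values are min–max normalised per slice) with its pixel spacing in
mm. All geometry downstream is metric: pixel $(r,c)$ has its centre at
$(x, y) = (c\,s_c,\; r\,s_r)$, 0-based, and anisotropic spacing is
supported.

1. **ROI.** The axis-aligned bounding box of the target contour, expanded
   by a safety margin (default 3 mm, converted outward-rounded to whole
   pixels per axis) and clipped to the image. If candidate points are later
   found outside, `expandRoiIfNeeded()` grows the box stepwise.
2. **Contrast.** A saturating power-law map: inputs below `lowIn` (default
   0.15) saturate at `lowOut`, inputs above `highIn` (default 1) at
   `highOut`, and in between
   $i_f = \mathrm{lowOut} + (\mathrm{highOut}-\mathrm{lowOut})
   \left(\frac{i-\mathrm{lowIn}}{\mathrm{highIn}-\mathrm{lowIn}}\right)^{\gamma}.$
   With $\gamma > 1$ (default 2) low intensities are compressed and high
   ones expanded, which separates the bright metal shaft from soft-tissue
   background.
3. **Thresholding.** Pixels with enhanced intensity $\ge \alpha$ inside the
   ROI become the candidate set $X_n$; everything else is background. Both
   $\gamma$ and $\alpha$ are empirical, case-dependent quantities and are
   exposed in every configuration surface. The package default
   $\alpha = 0.85$ assumes min–max normalised clinical slices where the
   needle is the brightest structure; the rendered phantom (needle 0.9 on
   0.2 background, enhanced plateau $\approx 0.78$) is analysed with
   $\alpha = 0.5$ throughout the test suite — any cut in roughly
   $(0.1, 0.7)$ separates the classes there.

## The robust line estimator

A 2D line is parameterised by an anchor point and a unit direction,
sign-normalised because a needle axis is undirected (orientation is
restored at tip localisation; angles between axes are folded into
$[0°, 90°]$ via the absolute dot product).

### Candidate generation and the iteration budget

Classical consensus sampling: each candidate is the exact line through
$m = 2$ random points (pairs closer than `minSampleSep` are redrawn as
degenerate, not counted). With outlier ratio $\varepsilon$ and required
confidence $P$ (default 0.99), the budget is the smallest $k$ with
$k \ge \log(1-P)/\log\!\bigl(1-(1-\varepsilon)^m P_t\bigr)$, where $P_t$ is
the probability that a *correct* model survives the pretest
($P_t \equiv 1$ without pretest). $\varepsilon$ is an input, not a guess:
the multi-needle bookkeeping below supplies it analytically each round.

### Scoring: robust scale under known contamination

Each candidate is scored on all $N$ points through a robust residual
scale. For residuals $d_i$ and $n \ge 2m$ the package's
`robustSigma()` is the median-based estimate
$\hat\sigma = 1.4826\,\bigl(1+\tfrac{5}{n-m}\bigr)\,\mathrm{med}_i |d_i|,$
consistent for Gaussian noise. The plain median, however, breaks down
beyond 50% contamination, while the multi-needle rounds routinely run at
$\varepsilon \approx 0.7$–0.8. Because $\varepsilon$ is known, candidate
scoring replaces the median by the $(1-\varepsilon)/2$ quantile of
$|d_i|$ — an estimate of the *inlier* median — with the same constants;
at $\varepsilon = 0$ the two coincide. Inliers are then the points with
$d \le z\hat\sigma$ ($z = 1.96$, the 95% band of a Gaussian residual;
with $\hat\sigma = 0$ only points within $10^{-9}$ mm qualify).

**Model selection is by minimal robust scale** (support size, then
iteration order, as tie-breaks), not by raw inlier count. This is a
deliberate design decision. With a per-model scale, a grossly wrong model
far from any structure has a huge $\hat\sigma$, hence a huge gate, hence
near-total "support": ranking by support under per-model gates is not
robust, and collapses exactly in the high-contamination regime the method
is built for. Minimising the robust scale is the least-quantile-of-squares
criterion of the classical robust regression literature (the same one the
$1.4826\,(1+5/(n-m))$ scale formula comes from), it is what makes the
estimator work from $\varepsilon = 0$ to $0.8$, and the consensus count is
still computed, reported and used everywhere downstream.

### The binomial pretest

Scoring a candidate on all $N$ points is the expensive step. Before full
verification, each candidate is scored on a fresh random subset of
$n = 15$ points and discarded if fewer than $n_f$ of them pass the gate.
For a correct model each subset point is an inlier with some probability
$p$, so the pass probability is the binomial tail
$P_t = P(\mathrm{Binom}(n, p) \ge n_f)$; `selectNf()` picks the largest
$n_f$ whose $P_t$ still meets the configured floor (default 0.80), and that
$P_t$ enters the iteration budget above, which grows slightly — the cost of
occasionally discarding a good model — while the far more numerous
contaminated models are rejected after 15 distance evaluations instead of
$N$.

Two calibration details make the binomial model coherent in practice:

* A true inlier only falls inside the $1.96\hat\sigma$ gate with
  probability $2\Phi(1.96)-1 \approx 0.95$, so the estimator evaluates
  $n_f$ at the effective ratio
  $\varepsilon' = 1-(1-\varepsilon)\cdot 0.95$. (The exported
  `pretestPassProbability()`/`selectNf()` operations keep their exact
  nominal contracts.)
* The pretest gate uses the *smaller* of the subset's own robust scale and
  the best full-data scale seen so far. Early on, nothing is known and the
  subset scale rules; once any good model has been verified, screening
  operates at the true noise scale, which is what actually gives the
  pretest its rejection power at high contamination.

### Local optimisation and the final fit

The winning candidate is still an exact fit through 2 points. Local
optimisation draws `localIters` (default 15, sensible range 10–20)
subsets — larger than minimal, up to 14 points — from the current inlier
set, fits each by total least squares, re-scores on the inlier set, and
keeps the best. The final model is the PCA (total-least-squares) fit of
the winning consensus: anchor at the centroid, direction along the first
principal axis, which minimises the orthogonal squared error. The final
consensus is re-gated against all points; the returned support never falls
below the seed's. Isotropic point clouds have no unique principal axis;
the fit then deterministically prefers the axis closer to the x-axis.

### Gate floor on raster data

Candidates that come from a pixel raster are quantised to pixel centres. A
perfectly vertical needle yields exactly collinear columns whose robust
scale is 0 — the gate collapses and one needle fragments into per-column
detections. `detectNeedles()` therefore floors the gating scale so that
$z\,\sigma_{\min} = 1.2\times$ the pixel pitch, the smallest gate that can
bridge adjacent pixel columns in any orientation. The floor is 0 (off) for
continuous point clouds.

## Tip localisation

The image is sampled by bilinear interpolation along the fitted axis
inside the ROI at half-pixel steps. The profile is traversed from the
entry side: a named image edge if configured, otherwise the clipped
endpoint nearest an image edge, with geometric ties broken toward the
brighter end (the shaft hugs the entry; beyond the tip there is only
background).

The threshold $T$ separating "needle" from "background" intensities is
either fixed or trained: Gaussian class-conditional densities are fitted
by moments to needle and background samples and $T$ is their crossing
between the two class means (closed-form quadratic; midpoint of the means
for equal or degenerate variances; training data with inverted means is an
error). In the pipeline the needle sample is the detection's own inlier
intensities and the background sample is drawn from sub-threshold ROI
pixels whose 8-neighbourhood is also sub-threshold — boundary pixels are
partial-volume mixtures that belong to neither class and would otherwise
inflate the background variance.

The tip is the distal end of the last run of $\ge$ `minRun` (default 3)
consecutive supra-threshold samples; shorter runs are isolated bright
noise. The returned arc length linearly interpolates the $T$-crossing
between the last supra-threshold sample and its successor, making the
estimate resolution-independent; a profile that ends while still above $T$
is flagged `tip_at_roi_edge` (needle leaves the ROI). The entry point is
the start of the first qualifying run.

## Multi-needle extraction

The needle count $n_{\mathrm{needles}}$ per slice is a clinical input (the
template geometry is known), not inferred. With $N_0$ initial candidates
and a residual noise fraction $\varepsilon_{\mathrm{noise}}$ (default
0.15), the expected per-needle support is
$n_{en} = \lfloor N_0 (1-\varepsilon_{\mathrm{noise}})/n_{\mathrm{needles}} \rfloor$,
and before each round the outlier ratio is recomputed from the current
candidate count $N_j$ as $\varepsilon = (N_j - n_{en})/N_j$ (clamped to 0
with a warning if depletion leaves fewer than $n_{en}$). Each accepted
needle's inliers are deleted; rejected rounds delete nothing and stop the
extraction. A round is accepted only if its support reaches
`acceptFrac` $\times\, n_{en}$ (default 0.5) — the stop rule is otherwise
unquantified, and half the expected support separates "a real needle with
losses" from "leftover noise" cleanly in practice. Fewer detections than
needles is a valid outcome, reported as missed.

## The synthetic-data module

Two generators make every stage testable with exact ground truth:

* **Planted-line point clouds** (`generatePlantedPoints()`): $n = 1500$
  points in a 100 mm × 100 mm field; a fraction $1-\varepsilon$ are
  inliers placed uniformly along a random chord through the central region
  with perpendicular Gaussian jitter ($\sigma = 0.5$ mm); outliers are
  Gaussian-scattered (2 mm) around uniform random centres. The field is
  the ROI scale of a lung target; the chord length (80–140 mm) brackets
  clinical insertion depths. The exact outlier geometry and jitter of the
  reference simulation conditions are not recoverable, so these values are
  declared defaults — estimator accuracies that depend on the
  jitter-to-length ratio (notably the *baseline* two-point error) move
  directly with them.
* **Phantom slices** (`generatePhantomSlice()`): needles rendered as
  bright anti-aliased strokes (18-gauge width 1.3 mm, intensity 0.9 on
  0.2) entering from the top edge at angles 0–60° and depths 40–100 mm at
  0.7 mm pixel spacing, with Gaussian pixel noise ($\sigma = 0.02$) and
  optional streak artifacts. The stroke has a *flat* end cap — lateral and
  longitudinal coverage ramps are separated — so the rendered 50% edge
  coincides with the ground-truth tip; a rounded (distance-to-segment) cap
  would displace the apparent endpoint by half the needle width.
  Overlapping needle specifications are an error (exact segment–segment
  distance test).

What the phantom does *not* emulate: CT physics (beam hardening, realistic
metal-artifact structure, partial-volume in Z across 5 mm slices), ribs
and anatomy, patient-specific intensity distributions. Passing phantom
tests therefore demonstrates the geometry and the estimator logic, not
clinical-grade robustness; the pipeline's empirical knobs ($\alpha$,
$\gamma$, $T$) exist precisely because real slices differ.

`simulationSweep()` reproduces the benchmarking design: for each outlier
ratio in 0.1–0.8 it generates fresh 1500-point datasets, runs the baseline
estimator (no pretest, no local optimisation, raw two-point winner) and
the improved estimator 15 times each, and tabulates mean/sd angular
deviation against the planted line plus the full-verification counters —
the hardware-independent cost measure (wall-clock time is
hardware-specific; the number of full-dataset verifications is not).

## Reproducibility and numerical choices

* Every stochastic operation is a pure function of (data, configuration,
  seed); a seed of `NA` continues the ambient RNG stream, which is how
  composed stages (`detectSingleNeedle()`, `detectNeedles()`) share one
  seeded stream. Per-run seeds in `simulationSweep()` are
  `seed + 1009 * ratio_index + rep`.
* Tie-breaks are deterministic everywhere: model ranking (scale, then
  support, then iteration order), PCA axis for isotropic clouds, entry-end
  selection.
* Degenerate inputs error early with messages naming the violated
  precondition (coincident points, empty contours, inverted training
  classes, axes missing the ROI); empty candidate sets and missed needles
  are valid results, not errors.
* Problem sizes in the shipped test-suite: 1500-point clouds for the
  estimator benchmarks (15 repetitions per ratio), 300–800-point clouds
  for paired and property tests, single- and multi-needle phantoms up to
  20 needles, and a 200-slice angle × depth × seed grid for the phantom
  accuracy trends.

## Known limitations

* 2D only: needle deformation along Z and 3D stacking of per-slice
  detections are out of scope.
* Straight needles only (consistent with 18-gauge brachytherapy needles,
  which do not bend appreciably in-plane during insertion).
* The tip estimate carries a small distal bias (a fraction of the
  anti-aliasing/PSF ramp) that depends on where the trained $T$ sits on
  the intensity drop; it stays well inside the 1 mm clinical gate on the
  phantom but is the dominant term of the tip error there, which also
  makes the phantom tip error nearly independent of insertion depth.
* The baseline estimator's absolute accuracy is a function of the
  synthetic geometry (jitter-to-length ratio); only the improved
  estimator's accuracy is stable across contamination levels.
* DICOM is not read directly; slices arrive as PNG/TIFF/CSV with pixel
  spacing supplied by configuration, conversion happening upstream.
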