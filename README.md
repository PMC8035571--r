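# needleCT

Robust detection of brachytherapy needles in transverse CT slices.

In CT image-guided lung interstitial brachytherapy, hollow needles are
inserted through a template into the tumour and radioactive seeds are
implanted through them. Intraoperative dose correction needs to know where
the needles actually are, which means segmenting short bright straight
streaks out of slices contaminated by ribs, metal artifacts and noise —
for the physicist who wants an automatic measurement tool, and for anyone
building a replanning step on top of it.

## The method

A slice is reduced to a candidate point set by contour-driven ROI
extraction, a saturating power-law contrast stretch
(*i<sub>f</sub> = lowOut + (highOut − lowOut)·((i − lowIn)/(highIn −
lowIn))<sup>γ</sup>*, γ > 1) and thresholding at α. Needle axes are then
estimated by a consensus line fit built for heavy contamination:

* **Sampling.** Candidate lines through random point pairs; the budget is
  the classical bound *k ≥ log(1 − P)/log(1 − (1 − ε)<sup>m</sup>
  P<sub>t</sub>)* with confidence P = 0.99 and minimal sample m = 2.
* **Binomial pretest.** Each candidate is first scored on a random subset
  of n = 15 points and discarded unless at least n<sub>f</sub> of them fall
  inside the inlier gate; n<sub>f</sub> is the largest value whose
  pass probability for a correct model, the binomial tail
  *P<sub>t</sub> = P(Binom(n, 1 − ε) ≥ n<sub>f</sub>)*, still exceeds 0.80.
  Contaminated models die after 15 distance evaluations instead of N.
* **Robust scale and gate.** Residuals are summarised by
  *σ̂ = 1.4826·(1 + 5/(n − m))·med|d|*, generalised to the
  (1 − ε)/2 residual quantile since ε is known; inliers satisfy
  *d ≤ 1.96 σ̂*. Candidates are ranked by minimal robust scale
  (least quantile of squares) with support as tie-break.
* **Local optimisation.** Resampling restricted to the winning consensus
  set, finished by a PCA (total-least-squares) fit.
* **Multi-needle extraction.** With the needle count known per slice,
  *n<sub>en</sub> = ⌊N<sub>0</sub>(1 − ε<sub>noise</sub>)/n<sub>needles</sub>⌋*
  expected inliers per needle and round-wise ε = (N<sub>j</sub> −
  n<sub>en</sub>)/N<sub>j</sub>; each accepted needle's inliers are deleted
  before the next round.
* **Tip localisation.** The intensity profile along the fitted axis is
  thresholded at the crossing T of Gaussian class-conditional densities
  (needle vs background); the tip is the interpolated distal end of the
  last supra-threshold plateau.

Accuracy is reported as the angular deviation β between detected and true
axes (folded into [0°, 90°]) and the Euclidean tip deviation ξ in mm.

A synthetic-data module generates the benchmarking inputs: 1500-point
planted-line clouds at outlier ratios 0.1–0.8, and rendered needle-phantom
slices (18-gauge strokes, 0.7 mm pixels, angles 0–60°, depths 40–100 mm)
with exact ground truth.

## Worked example

Render a 3-needle phantom slice, detect the needles, and score them
against the generator's ground truth:

```r
library(needleCT)

ph <- generatePhantomSlice(PhantomSliceSpec(nNeedles = 3L, theta = c(0, 15, 30),
                                            depth = c(60, 80, 100), seed = 42L))
dets <- detectNeedles(ph$image, RansacConfig(seed = 42L),
                      MultiNeedleConfig(nNeedles = 3L), alpha = 0.5)
for (d in dets) show(d)
#> NeedleDetection #1: tip (76.20, 88.33) mm, 182 inliers, sigma 0.429 mm
#> NeedleDetection #2: tip (5.95, 62.04) mm, 170 inliers, sigma 0.534 mm
#> NeedleDetection #3: tip (36.80, 79.08) mm, 145 inliers, sigma 0.429 mm

ev <- evaluateDetections(dets, ph$truth)
ev$perNeedle
#>      truthId detId  beta    xi
#> row        1     2 0.000 0.644
#> row1       2     3 0.006 0.415
#> row2       3     1 0.008 0.382
```

All three needles are found (detection rate 100%); the deepest needle is
extracted first because it carries the most candidate pixels. Axis errors
β are millidegrees; tip errors ξ are about half a pixel (0.4–0.6 mm),
dominated by the intensity drop-off at the rendered tip. `writeOverlayPNG()`
draws the detected axes and tips onto the slice for QC, and
`cmdDetect()`/`inst/cli/needlect.R` wrap the same pipeline for files on
disk.

The simulation benchmark compares the improved estimator against the
baseline on planted lines:

```r
sw <- simulationSweep(epsGrid = c(0.2, 0.5, 0.8), reps = 15L, seed = 1L)
sw[, c("eps", "meanBetaBaseline", "meanBetaImproved",
       "meanVerifBaseline", "meanVerifImproved")]
#>   eps meanBetaBaseline meanBetaImproved meanVerifBaseline meanVerifImproved
#> 1 0.2           0.3817           0.0446                 5            3.2000
#> 2 0.5           0.4094           0.0676                17            6.1333
#> 3 0.8           0.5834           0.1370               113           29.9333
```

The improved estimator keeps the axis error an order of magnitude below
the raw two-point baseline at every contamination level, and at ε = 0.8
the pretest cuts the expensive full-dataset verifications from 113 to
about 30 per run.

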