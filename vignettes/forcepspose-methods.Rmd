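---
title: "Part-based CRF pose estimation of surgical forceps: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Part-based CRF pose estimation of surgical forceps: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(forcepspose)
```

## The problem

Microsurgical forceps are articulated instruments: a rigid shaft whose distal
end (the *center* joint) splits into two gripper arms ending in the *left* and
*right* tips. Steering intraoperative imaging (for example positioning OCT
scan lines at the tips and along the shaft) requires, per video frame, the 2D
positions of both tips, the center joint, and the shaft orientation — under
rapid motion, illumination changes, vessel clutter and occasional
disappearance of the instrument from the field of view. A plain
tracking-by-appearance approach fails in exactly the interesting moments and
then needs manual reinitialization; `forcepspose` instead detects the parts
independently in every frame and fuses them with an articulated prior, so
losing the instrument is an observable, recoverable state.

## The model

The instrument pose is a configuration $y = (y_L, y_C, y_R, y_S)$ of four 2D
part positions (left tip, center, right tip, a point on the shaft
centerline), each taken from a discrete hypothesis set produced by a part
detector. Given image evidence $x$ and the previous pose $P$, the pose is
scored by an unnormalized posterior over a conditional random field whose
factors encode the instrument's kinematics:

$$p(y \mid x, P) \propto \prod_i \Phi^{Conf}(y_i, x)\,\Phi^{Temp}(y_i, P_i)
  \cdot \!\!\prod_{(i,j)} \Psi^{Conn}(y_i, y_j)
  \cdot \Psi^{RLen} \cdot \Psi^{Cons} \cdot \Psi^{Rot}.$$

* **Unary confidence** $\Phi^{Conf}$: a probability random forest (50 trees,
  depth 25) over HOG descriptors of 50×50 patches, with five classes (four
  parts plus background). The confidence is the mean over trees of the
  per-tree class probabilities.
* **Temporal prior** $\Phi^{Temp} = \exp(-\lVert y_i - P_i\rVert^2 / 2\sigma_t^2)$.
  The literal unit-variance kernel decays within ~3 px, which is useless at
  video resolution, so the scale is a parameter (default $\sigma_t = 20$ px;
  $\sigma_t = 1$ recovers the literal kernel). On the first frame, or before
  any confident pose exists, the factor is 1.
* **Connectivity** $\Psi^{Conn}$: tips must be connected to the center along
  the gripper arm edges. Candidate quadratic Bézier curves between the two
  hypotheses (control point offset along the chord orthogonal, seven offsets
  spanning ±0.35 of the chord length by default) are rasterized onto a binary
  Sobel edge map; each curve scores $\sum_j |s_j|^2 / k^2$ where the $s_j$ are
  maximal runs of edge pixels along the curve and $k$ is the curve's pixel
  count. The normalization by $k$ (the "normalization factor" left open in the
  factor's definition) makes the score scale-free with 1 = fully connected,
  and squaring favors long unbroken segments over fragmented ones. A 1-px
  dilation of the edge map absorbs rasterization slack. The potential is the
  maximum over the curve family; a curve touching no edge scores the floor
  $\varepsilon = 10^{-6}$.
* **Relative length** $\Psi^{RLen}$: a peak-normalized isotropic bivariate
  Gaussian over the pair of gripper lengths
  $(\lVert y_C - y_L\rVert, \lVert y_C - y_R\rVert)$, fitted from annotations
  (sample means; pooled SD floored at 1 px). Peak normalization keeps the
  factor on the same $(\,\varepsilon, 1]$ scale as the other potentials so no
  single family dominates the product.
* **Consistency** $\Psi^{Cons} \in \{1, \varepsilon\}$: both gripper lengths
  must be *strictly* less than half the ROI side.
* **Rotation** $\Psi^{Rot}$: each configuration defines an angle triple
  $\theta = (\theta_1, \theta_2, \theta_3)$ — the unsigned angles between
  (left−center, shaft−center), (right−center, shaft−center) and
  (left−center, right−center); the third is the gripper opening. The
  potential is the *unweighted sum* of two trivariate Gaussian densities, one
  fitted on closed-state annotations, one on open-state ones (sample mean and
  covariance per state, ridged by $10^{-4} I$). The sum is left unnormalized;
  everything downstream that needs a scale uses the density relative to the
  component modes. Which three angles constitute $\theta$ is a documented
  package convention (unsigned, in $[0, \pi]$, via `acos` of normalized dot
  products).

## Inference

MAP inference maximizes the log posterior (the partition function is constant
in $y$ and products of many factors underflow, hence the log domain). The
search space is the product of the per-part hypothesis sets; a genetic
algorithm searches it: 1000 random configurations as the initial population,
single-cut crossover over the gene order (left, center, right, shaft),
mutation that replaces a gene by a same-label hypothesis within 20 px
(fallback: any same-label hypothesis), tournament selection (size 4), 5%
elitism, and an elitist memory that always keeps the best configuration ever
evaluated. Termination: 50 generations, or earlier when the best fitness is
unchanged (to $10^{-12}$) across two successive generations. Ties are broken
lexicographically on the coordinate vector for reproducibility; the whole
optimizer is a pure function of (context, seed). Crossover pairs are formed by
random (tournament-selected) pairing; a fitness-ranked pairing would also be
defensible, but random pairing keeps selection pressure in one place.

`exhaustive_infer()` enumerates small spaces exactly and is the test oracle:
on 200 random contexts with 256 configurations each, the GA attains the
enumerated optimum in ≈97% of runs and by construction can never exceed it.

## Tracking and automatic recovery

Detection runs inside a square ROI. The first frame uses the full image; a
confident pose recenters the ROI at the inferred center and resets its side to
the base size (4× the fitted mean gripper length — "a region comfortably
containing the gripper" made concrete); any failure multiplies the side by
1.5, capped at the full frame. A pose is *not* confident when the consistency
potential returned $\varepsilon$ or when the rotation density at its angle
triple is below 1% of the larger component-mode density — a relative
threshold, so the check is independent of the fitted covariance scale. When a
part has no hypothesis at all, detection is retried with an expanded ROI up to
3 times within the same frame (cheap, and short occlusions then do not cost a
whole frame); frames that stay incomplete are reported *missing* — data, not
an error — and the ROI keeps growing geometrically until the instrument
reappears. No manual reinitialization exists anywhere in the loop.

## The synthetic scene generator

All training and testing runs on rendered scenes with exact ground truth. The
generator draws a bright shaft (a thick stroke) whose distal end splits into
two gripper arms rendered as quadratic Bézier strokes — the same curve family
the connectivity potential searches, so connectivity is exercised by
construction. Backgrounds are flat, smoothly textured, or textured plus
random dark curvilinear strokes that imitate retinal vessels and provoke
plausible false detections; illumination gain, Gaussian blur and additive
noise complete the scene. Rendering is bit-deterministic in
(geometry, scene, seed).

Default study conditions (chosen once, as what a practitioner would call a
plausible desk-scale stand-in for microsurgical video): 240×320 px frames,
arm length 52–58 px, shaft length ≈90 px, shaft angles spanning a ±0.6 rad
arc (instruments enter through a fixed port, so their orientation varies
moderately — and a detector on orientation-variant HOG features genuinely
cannot distinguish "left tip" from "right tip" under full 360° rotation),
opening angles from a two-regime mixture (35% closed, uniform on [0, 0.08]
rad; the rest open, uniform on [0.25, 0.9] rad) so both components of the
rotation prior are populated; state labels follow the generating angle with a
0.1 rad closed threshold. The annotated shaft point sits 60 px from the
center along the centerline; the annotation protocol does not pin this
distance down, so it is an explicit parameter. Training uses 200 images;
patch mining takes the annotated joint plus 4 jittered replicas within 5 px
as positives and 16 background patches at least 10 px from every joint as
negatives.

What the generator does **not** emulate: photorealistic retina texture,
specular highlights, shadows, motion blur, fluid/instrument interaction,
stereo, or multiple instruments. Green tests on synthetic scenes therefore
demonstrate the correctness and internal consistency of the method — not
clinical performance on real surgical video.

## Numerical choices and degenerate inputs

* Coordinates are (x, y), 0-based, origin at the top-left pixel center, x
  rightward, y downward — one convention shared by every module.
* $\varepsilon = 10^{-6}$ floors every factor, so log posteriors are finite
  and a single hostile factor cannot veto a configuration to $-\infty$.
* The Sobel threshold defaults to Otsu's method on the gradient magnitude.
* A configuration that collapses a tip or shaft point onto the center has no
  defined angle triple; the batch scorer gives it the rotation floor instead
  of raising, so the GA can wade through such candidates.
* Closed forceps (coincident tips) are legal everywhere: the opening angle is
  0 and the rotation prior's closed component covers them.
* HOG descriptors are L2-normalized; constant patches give the all-zero
  descriptor rather than dividing by zero. Patches are reflect-padded at
  image borders so hypotheses near ROI edges are not discarded.
* Duplicate-aware caching: connectivity values are memoized per hypothesis
  pair and configuration fitnesses per configuration, so GA generations and
  the exhaustive oracle never recompute a factor.

## Problem sizes used in the test suite

The suite trains on 80–200 rendered frames, tracks sequences of 8–100 frames,
and compares GA inference against exhaustive enumeration on 200 contexts of
256 configurations; these sizes make the full suite run in a few minutes on
one CPU while still exercising every code path at the defaults. The
`scripts/acceptance.R` report recomputes the same quantities at the 200-image
/ 100-frame scale.

## Known limitations

* The detector is orientation-variant by design (HOG); instruments rotating
  far outside the training arc need retraining or rotation augmentation.
* The shaft point is localized only *across* the shaft, not along it — any
  point on the centerline is an equally good hypothesis. Orientation (the
  quantity that matters downstream) is unaffected; the raw shaft-point
  Euclidean error is not a meaningful accuracy measure.
* One instrument per frame; multi-instrument scenes would need per-instrument
  hypothesis partitioning.
* The GA is an approximate maximizer: on enumerable spaces it misses the
  global optimum in a few percent of runs (always from below).
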