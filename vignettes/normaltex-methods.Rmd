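---
title: "Normal-field surface texture analysis: models, parameters and design choices"
author: "normaltex"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Normal-field surface texture analysis: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(normaltex)
```

# The problem

Skin conditions such as wrinkles, enlarged pores and acne are
three-dimensional phenomena: what a rater perceives depends on the relief
of the skin surface at the scale of individual pores, not on the albedo
image alone. Photometric-stereo systems (light stages) deliver this relief
as a *dense normal map*: an H x W field of outward unit vectors
n = (nx, ny, nz), z > 0. `normaltex` analyses such fields directly and
turns them into fixed-length texture descriptors for condition-severity
classification.

The obstacle is that unit normals live on the sphere S², not in a vector
space, so convolution, averaging and interpolation cannot be applied to
the components naively. The package therefore builds every operation on
two Riemannian primitives:

* the **logarithmic map** `logMap(n, mu)`, the azimuthal-equidistant chart
  that unfolds a normal about a reference normal mu into 2-D tangent
  coordinates while preserving radial geodesic distances (scale factor
  k = c/sin c, c the geodesic angle), and its inverse `expMap`;
* the **geodesic (Karcher) mean** `geodesicMean`, the normal minimising
  the weighted sum of squared geodesic distances, computed by the standard
  fixed-point iteration mu <- Exp_mu(sum w Log_mu(n) / sum w).

All linear operations on whole maps (smoothing, down-/up-sampling,
off-grid sampling) are performed in a tangent chart and folded back, so
results are unit vectors by construction.

# The three descriptors

**Rotation-fields pyramid** (`rotationPyramid`, `rfDescriptor`). Smoothing
a map with radius r and recording, per pixel, the axis-angle rotation that
carries the original normal onto the smoothed one separates the
high-frequency relief (the rotation field) from the low-frequency shape.
Iterating smooth / extract / down-sample-by-2 yields an l-level pyramid;
the three components of the rotation vector (axis x angle) act as the
sub-bands of each level. Per pixel we take the parallel-axis SO(3)
distances to the N x M - 1 neighbours plus the central rotation vector
(N*M + 2 values), quantise with a k-means dictionary and concatenate the
level histograms: an l x k descriptor (300 or 600 for 3 levels with
k = 100 / 200).

Two metric conventions deserve a note. The SO(3) distance composes the
two rotations rather than their relative rotation, so the distance of a
rotation to itself equals its angle: the quantity measures *accumulated
deviation*, which is what the descriptor needs, and `so3Distance` exposes
both the full quaternion-product form and the parallel-axis simplification
(they coincide on shared axes; the tests assert this to 1e-9). We keep the
printed convention deliberately rather than "correcting" it to a true
metric.

**Local orientation patterns** (`lopImage`, `lopDescriptor`). A
generalised texture-spectrum descriptor: each pixel's texture unit encodes
the comparison patterns between its normal and N normals on a circle of
radius r, in base-n positional code, histogrammed over the map. Pattern
function 1 thresholds the dot product (2^N bins, 256 for N = 8); pattern
function 2 compares azimuth and polar angles directly (4^N bins, 65536).
Off-grid circle points are sampled by bilinear interpolation in the fixed
tangent chart. The dot-product threshold is a corpus statistic: the
pipeline fits it on training folds (mean of the training patches' global
mean dot products) so that a patch's absolute roughness remains
informative; per-patch thresholds would normalise exactly that signal
away.

**Multi-scale azimuthal projection distance** (`apdiImage`,
`apdiPyramid`, `apdiFeatures`). Each normal is projected onto the tangent
plane of a reference mean normal; the scalar image is either the distance
from the projection centre (original variant, blind to azimuth) or the
arc value atan2(x, y) * sqrt(x^2 + y^2) (modified variant, sensitive to
azimuth as well). Using per-pixel *local* mean normals instead of the
fixed vertical removes the low-frequency shape bias — on a sphere-cap test
map the local-mean APDI variance is ~0.3% of the fixed-mean variance. A
pyramid of APDIs at halving resolutions (geodesic down-sampling) captures
pore-scale detail at the native level and acne-scale spots at deeper
levels; per-level histograms concatenate to bins x depth features (512 for
128 bins, 4 levels).

The source formulation of the projection scale factor prints a
relation for c that is dimensionally inconsistent with k = c/sin c and
with its own fixed-mean specialisation c = sin(theta). We expose both
readings: `cMode = "literal"` (default) transcribes the printed formulas,
`cMode = "standard"` uses the great-circle cos c, which makes the
projection the exact azimuthal-equidistant chart (and is what the
package's own log map uses). The two differ only in radial scaling; the
tests pin each documented property to the mode in which it holds.

# Geodesic resampling

Down-sampling (factor S, window u x v) unfolds the whole map into one
fixed chart at its global geodesic mean, block-averages the chart
coordinates over windows anchored at rows/columns i*S - floor(u/2), and
folds back; up-sampling interpolates bilinearly in the same chart. The
printed index arithmetic of the source's down-sampling algorithm omits the
factor S (it would read only the top-left corner of the input); we anchor
at i*S - floor(u/2), which reduces exactly to the printed arithmetic at
S = 1. Against the classical per-channel route (point decimation +
bilinear up-sampling + renormalisation) the geodesic route has strictly
lower mean angular error on every synthetic patch the acceptance script
generates (typically ~0.07 vs ~0.10 rad on 32 px patches at S = 2).

# The synthetic generator

No public light-stage corpus exists at pore resolution, so the package
generates its own study material (`makePatch`, `makeDataset`): a height
field (units: pixels) composed of a smooth random base surface (amplitude
2 px), condition structures, and pixel noise (sd 0.02 px), converted to
normals as the normalised (-dh/dx, -dh/dy, 1). Condition structures and
their severity-5 parameters:

* *wrinkles*: oriented quasi-parallel valleys, wavelength 12 px, Gaussian
  cross-profile width 2.5 px, depth 2 px, smooth orientation jitter;
* *pores*: dense Gaussian pits, sigma 1.2 px, depth 0.9 px, density
  0.05/px²;
* *acne*: sparse Gaussian bumps, sigma 4 px, height 2.5 px, density
  0.004/px², with slight albedo darkening.

Severity s in 1..5 scales amplitude and density by (s - 1)/4, so severity
1 is clear skin and every descriptor energy grows monotonically with
severity (asserted over 20 seeds per condition). Patch sizes follow the
20/50/80 px sampling grids typical for facial regions. Because the normals
derive from a single-valued height field they are exactly integrable
(curl-free gradient field), which real photometric-stereo normals are only
approximately; the generator also has no subsurface scattering, no
specular residue, no spatially varying noise, and its albedo is greyscale.
Passing tests on this generator therefore demonstrate correctness of the
descriptors and the pipeline's discriminative machinery, not clinical
performance on captured faces.

Rater simulation: faithful raters score
clamp(round(severity + bias + N(0, 1)), 1, 5) with per-rater bias
N(0, 0.3); the noise sd of 1 point is calibrated so that faithful pairwise
Spearman correlations sit near 0.6, the agreement level reported for the
best-behaved facial region in the study this package models. Adversarial
raters score uniformly at random. The consensus procedure
(`raterConsensus`) excludes raters in ascending order of correlation with
the rest and keeps the largest subset whose mean pairwise correlation
reaches 0.5. At that threshold the procedure is intentionally permissive:
with few rated items a random rater can survive by chance correlation
(the acceptance script reports the removal fraction it actually achieves);
a stricter threshold removes them reliably.

# Classification pipeline

`evaluateDescriptor` runs stratified 10-fold cross-validation with every
data-dependent quantity fitted inside the training fold: k-means
dictionaries (rotation fields, BTF textons; `stats::kmeans` with 10
restarts under a fixed seed, subsampled to at most 10000 vectors), LOP
thresholds, SVM-weight feature ranking to 64 features (one-vs-rest linear
SVMs, summed |w|), per-feature standardisation, and a single-hidden-layer
perceptron (`nnet`) whose hidden size is the mean of the class count and
the post-selection attribute count, weight decay 0.1. Reports are
`EvalReport` objects with per-class precision/recall/F and the
support-weighted and macro means.

Problem sizes used by the tests and the acceptance script are chosen to
exercise every code path at desk scale: 50 px patches, 10 per class,
severity 1 vs 5, one corpus per descriptor — rotation fields and LOP on
pores (their high-frequency strength; LOP uses pattern function 2, the
variant suited to fine relief), modified APDI on wrinkles. All three reach
weighted F = 1.0 there. LOP on coarse acne structures is weaker
(0.85-0.95 across corpus seeds with fold-fitted thresholds) — consistent
with the source study, where the texture-spectrum descriptor trails the
pyramid methods on acne — and we report rather than hide that.

# Numerical choices

* Dot products are clamped to [-1, 1] before acos; chart scale factors
  use the limit k = 1 as c -> 0.
* Karcher iterations: tolerance 1e-9 rad on the update angle, at most 100
  iterations, initialised at the normalised Euclidean mean; smoothing
  runs the iteration at all pixels simultaneously.
* Coincident normals get the canonical rotation axis (0, 0, 1) with angle
  0; antipodal pairs raise errors (undefined chart/axis).
* Gaussian smoothing weights: sigma = r/2, truncated at radius r; border
  windows are truncated and renormalised.
* Min-max response normalisation treats numerically constant images
  (range below 1e-12 relative to magnitude) as constant, mapping to 0.
* Histogram bin edges are right-closed at the top edge; APDI pipeline
  features use a fixed binning range (arc values in [-pi/2, pi/2]) for
  cross-patch comparability.
* Self-fitted k-means dictionaries reduce k to the number of distinct
  vectors and zero-pad the histogram, preserving the l x k length
  contract.
* The Euclidean (renormalised arithmetic) mean is the pipeline's
  smoothing default — it agrees with the geodesic mean to O(spread³) and
  is separable, hence fast; the geodesic mean is the low-level default
  and the reference in tests.

# Known limitations

* Synthetic-only validation; see the generator caveats above.
* The BTF "viewpoints" are small in-plane re-projections, not true
  perspective changes; the texton baseline is exercised for its
  representational properties (response dimensionality, illumination
  robustness), not benchmarked against the proposed descriptors.
* The 65536-bin LOP pattern-function-2 histogram is kept full and sparse;
  feature selection reduces it in the pipeline.
* The rotation-field dictionary uses random-restart k-means, so exact
  histogram values depend on the seed (fixed throughout).
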