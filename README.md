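# normaltex

3D surface-texture descriptors for dense facial normal fields, applied to
skin-condition assessment (wrinkles, enlarged pores, acne).

Photometric-stereo and light-stage systems capture skin relief at pore
resolution as *normal maps*: per-pixel fields of outward unit vectors
n = (nx, ny, nz). Conditions such as wrinkles and acne are geometric, so
descriptors computed directly on the surface orientation field outperform
descriptors of the albedo image — but normals live on the unit sphere, and
averaging, filtering or resampling their components channel-wise is
geometrically wrong. `normaltex` provides the Riemannian machinery and
three normal-field texture descriptors built on it, for researchers in
skin image analysis and 3D surface texture.

## What is inside

* **Manifold primitives** — azimuthal-equidistant log/exp maps on S²
  (`logMap`, `expMap`), weighted geodesic (Karcher) and Euclidean means,
  axis-angle rotations between normals, and SO(3) distances via unit
  quaternions (`so3Distance`, full and parallel-axis forms).
* **Normal-map operations** — PNG/plain-text I/O (`readNormalMap`),
  slant-tilt and tangent maps, per-pixel geodesic smoothing
  (`smoothNormalMap`), and geodesic down-/up-sampling in a fixed tangent
  chart (`downsampleNormalMap`, `upsampleNormalMap`), with
  `meanAngularError` for comparisons.
* **Descriptors** —
  * *Rotation-fields pyramid* (`rfDescriptor`): per-level rotation fields
    (high-frequency residual of smoothing, Eq. R(i,j) = rotation from
    N(i,j) to the smoothed normal), SO(3) neighbourhood distance vectors,
    k-means texton histograms, concatenated over levels (l x k features).
  * *Local orientation patterns* (`lopDescriptor`): texture units
    f(p0) = sum_i f_i n^(i-1) over N circle normals, with a thresholded
    dot-product pattern function (2^N bins) or a four-way azimuth/polar
    comparison (4^N bins).
  * *Multi-scale azimuthal projection distance* (`apdiPyramid`,
    `apdiFeatures`): normals projected onto local tangent planes; original
    L2 and azimuth-sensitive arc variants, histogrammed over a pyramid of
    geodesically down-sampled maps.
* **Baselines** — multi-scale Gabor and rotation-invariant LBP descriptors
  on albedo, slant-tilt and tangent channels; a BTF-texton gold standard
  (14-filter bank at 3 scales, 42 responses/pixel, k-means textons over
  multi-view/multi-light stacks).
* **Synthetic data** — height-field skin patches with graded wrinkle /
  pore / acne severity (`makePatch`, `makeDataset`), Lambertian relighting
  and BTF stacks (`renderPatch`, `makeBTFStack`), and a multi-rater score
  simulator.
* **Pipeline** — rater-exclusion consensus labels (`raterConsensus`),
  SVM-weight feature ranking (`svmRankSelect`), stratified 10-fold MLP
  classification (`classifyCV`, `evaluateDescriptor`) with all fitting
  confined to training folds, reporting per-class and weighted F-measures.

## Worked example

```r
library(normaltex)

patch <- makePatch("pores", severity = 5L, size = 50L, seed = 7)
patch
#> LabeledPatch: pores, severity 5, 50 x 50 px, 0 rating(s)
N <- patchNormalMap(patch)
N
#> NormalMap: 50 x 50 pixels, mean slant 21.70 deg

# small smoothing radii capture pore-scale relief, large radii coarser
# structure; the mean rotation angle is the "texture energy" at that scale
fine   <- rotationField(N, r = 2, method = "euclidean")
coarse <- rotationField(N, r = 7, method = "euclidean")
mean(rotationAngles(fine))    #> 0.0980  rad
mean(rotationAngles(coarse))  #> 0.2396  rad

# modified APDI about local means keeps only high-frequency relief
apdi <- apdiImage(N, variant = "modified_arc", meanMode = "local",
                  window = 15L)
var(as.vector(apdi))          #> 0.5615

# clear (severity 1) vs severe (severity 5) pores, cross-validated
patches <- c(lapply(1:6, function(i) makePatch("pores", 1L, 50L, seed = i)),
             lapply(1:6, function(i) makePatch("pores", 5L, 50L,
                                               seed = 100 + i)))
severity <- rep(c(1L, 5L), each = 6)
report <- evaluateDescriptor(patches, severity, "rotation_fields",
                             folds = 3L, seed = 1)
report
#> EvalReport: weighted F = 1.000, macro F = 1.000 (3 folds)
#>  class precision recall f support
#>      1         1      1 1       6
#>      5         1      1 1       6
```

The rotation-field energies say the patch carries substantial orientation
texture at both scales (pits affect both radii); the APDI variance is the
descriptor's severity signal; the report shows the descriptor separating
clear from severe skin perfectly on this small corpus.

## Vignette

`vignettes/normaltex-methods.Rmd` documents the models and their
assumptions, the tangent-chart conventions, the synthetic generator's
parameters and what it does and does not emulate, the pipeline's
no-leakage protocol, numerical edge cases, and known limitations.
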