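---
title: "Methods: from ROI images to spatial mixing scores and ligand-target pairs"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: from ROI images to spatial mixing scores and ligand-target pairs}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# The problem

Digital spatial profiling (DSP) platforms such as GeoMx capture transcript
counts from pathologist-selected regions of interest (ROIs) on slides stained
with multiplex immunofluorescence (mIF): typically a DNA dye (blue), an
epithelial/tumour marker such as PanCK (green), and an immune marker such as
CD45 (red). The expression readout is one number per gene per ROI; everything
about *where* cells sit inside the ROI is discarded unless the exported ROI
images are analysed separately. `spatroi` closes that gap: it turns each
exported ROI image into per-cell features and marker-based classifications,
summarizes the spatial arrangement of marker-positive versus negative cells
with a single mixing score, and carries the resulting ROI groups into
standard DSP expression preprocessing and a correlation-based ligand-target
screen.

The package operates on three inputs: RGB TIFF exports (one circular ROI on a
white margin, roughly 300 um in diameter within a ~600 um field), probe- or
gene-level count tables, and a ligand-target regulatory-potential table in a
NicheNet-like schema. Because study data of this kind are rarely
redistributable, the package also ships seeded generators that emulate all
three inputs with known ground truth; every claim the test suite makes is
made against those generators.

# Image preprocessing

**ROI detection.** The exported images surround the circular ROI with a
near-white margin. The detector thresholds "background" as all three channels
at or above `255 - background_tol` (default `background_tol = 10`), takes the
largest connected non-background component, and fits an area-equivalent
circle: centre at the component centroid, radius `sqrt(area / pi)`. This is
robust to anti-aliased ROI edges and needs no vendor metadata. The image is
cropped to the circle's tight bounding square; pixels outside the circular
mask are set to white (255, 255, 255) and excluded from every downstream
statistic through the mask. White rather than zero is deliberate: a zero
sentinel would silently contaminate blue-channel (DNA) statistics for any
routine that forgot the mask, and white is exactly what those pixels were in
the export.

If the non-background region touches all four image borders the image is
assumed to be pre-cropped; the crop is skipped (with a warning) and only the
mask is fitted. The detector does not assume the ROI is centred.

**Physical scale.** The exports carry no pixel-size metadata. When the user
asserts the vendor-default ROI diameter (about 300 um), `set_roi_scale()`
derives `um_per_px = diameter_um / (2 * radius_px)`; otherwise the scale
stays unknown and all spatial quantities are reported in pixels.

# Segmentation

The segmenter is a pluggable backend behind a registry, because production
deployments of this kind of pipeline use pretrained neural models whose
weights cannot be bundled. The package ships a deterministic classical
reference backend with the same contract, so the full pipeline is testable
without any trained weights:

1. smooth the nuclear (blue) channel with a Gaussian, `sigma = diameter_px / 8`;
2. threshold with Otsu's method computed over in-mask pixels only (the
   rectangular raster is mostly margin, which would otherwise dominate the
   histogram);
3. take the Euclidean distance transform of the foreground, smooth it mildly
   (same sigma) to suppress spurious maxima from ragged anti-aliased
   boundaries, and find local maxima with minimum separation
   `diameter_px / 2` (greedy deduplication by decreasing peak height);
4. grow the peaks through a marker-controlled watershed over the foreground;
5. remove components smaller than `(diameter_px / 4)^2` pixels.

`segment_cells()` then enforces the label-mask contract for *any* backend:
labels are clipped to the ROI mask, cells whose centroid falls outside the
mask are dropped, and labels are recompacted to `1..n_cells`. Dropping
boundary-straddling centroids mirrors the margin false-positives that
image-analysis tools are known to produce near ROI edges. The reference
backend additionally erodes the working mask by a few pixels before
thresholding: the fitted circle inevitably brushes the bright white-margin
transition, which would otherwise surface as a ring of false cells.

Two parameters matter. `diameter_px` (default 23, the pipeline default for
DSP exports at native resolution) sets the smoothing scale, the peak
separation and the minimum area; it should match the apparent cell diameter
in pixels, and the synthetic-fixture tests use 11 because the rendered cells
are ~10 px across. `flow_threshold` (default 0.4) is a quality knob passed
through to neural backends; the classical backend has no use for it.
Channels are named explicitly (`nuclear_channel = "B"`, `cyto_channel = "G"`)
rather than by index, avoiding the off-by-one ambiguity of 1-based
channel-index conventions in upstream tools.

# Per-cell features

For each label the package reports the centroid (unweighted mean of member
pixel coordinates; x = column, y = row, 0-based, origin top-left), mean R/G/B
intensities over the cell's pixels, pixel count, area (equal to the pixel
count, in pixel^2), perimeter and circularity `4 * pi * area / perimeter^2`.

The perimeter uses the 4-direction Crofton approximation (a bit-quad lookup
table): counting boundary pixels is known to overestimate perimeters of
small, round objects, which would push circularity systematically above 1.
With the Crofton estimator, a rasterized disc of radius 20 scores within
[0.95, 1.05], and circularity is scale-invariant to within 5% under size
doubling; the test suite asserts both. Values slightly above 1 (up to ~1.1)
still occur for very small cells as pure rasterization noise, and the
feature-table contract allows them.

Intensities are measured on the original pixel values; the white sentinel
outside the mask can never contribute because labels are confined to the
mask.

# Cell typing

The green (PanCK) channel of these images is strongly bimodal: a dim
negative mode and a bright marker-positive mode. Three classifiers are
provided and, on separated mixtures, agree:

* **Cutoff**: positive iff mean green intensity is *strictly* greater than
  the cutoff; ties are negative by documented convention. The default cutoff
  is 20 (on the 0-255 scale); a value of 10 has also been reported for data
  of the same kind, and because the appropriate value is data-dependent the
  cutoff is always an explicit parameter, never auto-selected.
* **GMM**: a k-component Gaussian mixture (default k = 2, fitted with
  `mclust`). The component with the higher mean on the positive channel is
  "positive" - mapping by component index would be fit-order-dependent. In
  1-D the reported `threshold_used` is the intensity where the posterior
  responsibilities of the two extreme components cross 0.5.
* **K-means**: centroid-based assignment, positive cluster by higher centre.

Degeneracy handling for the GMM is decided by model evidence, not by
eyeballing variances: if BIC prefers fewer than k components (or the fitted
component means sit closer than half the summed component SDs, or the fit
fails outright), the classifier falls back to a cutoff at the midpoint of
the component means and warns. Both clustering methods take a seed (default
0) and are invariant to record order.

The typing report formats the positive percentage to two decimals (e.g. 258
of 535 cells prints as "48.22%"), matching the annotation convention of the
snapshot images, which show the original ROI next to an overlay with
positive cells outlined in orange and negative in cyan.

# The cross-K mixing score

The spatial summary is the bivariate Ripley cross-K function between
positive and negative cells,

$$\hat K_{+-}(r) = \frac{|W|}{n_+ n_-} \sum_{i \in +} \sum_{j \in -}
  w_{ij}\, \mathbf{1}[d_{ij} \le r],$$

evaluated on `n_r = 100` equally spaced radii up to `r_max` (default: a
quarter of the window radius, the customary default radius range for
K-functions), against the analytic Poisson reference `pi r^2`. The mixing
score is the signed, normalized area between the curves:

$$\mathrm{AUC} = \frac{1}{r_{max}^2} \int_0^{r_{max}}
  \left(\hat K_{+-}(r) - \pi r^2\right) dr$$

by the trapezoid rule over the radius grid. Under independence of the two
populations the expectation is zero; attraction gives positive scores,
segregation negative ones. The score is signed rather than clipped at zero
because "more mixed" is an ordering: segregated ROIs must rank below
complete spatial randomness. Normalizing by `r_max^2` makes scores
comparable across ROIs of different sizes.

Edge corrections: `translation` (default) weights each pair by
`|W| / |W intersect W_shifted|`, which for the circular window has the
closed-form lens-area denominator and is unbiased under the null;
`border` is the reduced-sample estimator (only reference points at least
`r` from the boundary count at radius `r`), which coincides exactly with
the uncorrected estimator when all points are far from the edge; `none` is
the raw estimator, and a brute-force O(n^2) double loop of the same
estimator is kept as an independent test oracle. Because the translation
weight depends only on the pair distance, the score is exactly symmetric
under swapping the marks.

ROI grouping into `Mixture` versus `Separative` requires an explicit rule -
either `top_n` (ties broken lexicographically by ROI id) or a score
`threshold` - because no principled universal cutoff exists; ranking is the
primary use and is robust to the estimator details above.

# Expression preprocessing

The expression module follows the standard DSP preprocessing chain, in a
fixed order: probe-to-gene aggregation (arithmetic mean of a gene's probes
per segment), a segment detection filter, a gene detection filter, then
upper-quartile normalization.

* **Detection** is taken as input: an explicit detected matrix, or the
  simple default "value > limit of detection" with LOD 0. Vendor
  negative-probe detection models are out of scope by design; reimplementing
  them poorly would be worse than accepting a caller-supplied definition.
* **Segment filter**: a segment is dropped when its detected genes are
  strictly fewer than 5% (default) of the genes detected *anywhere in the
  matrix*. "Total detected genes" could also be read as the panel size; the
  detected-anywhere reading is implemented because it is the one that adapts
  to the data actually present.
* **Gene filter**: genes detected in at least 10% (default, inclusive) of
  the remaining segments are kept.
* **Q3 normalization**: per segment, the factor is that segment's 75th
  percentile over retained genes divided by the geometric mean of the 75th
  percentiles across segments; values are divided by the factor. Referencing
  to the geometric mean keeps the matrix on its original scale. The
  percentile uses linear interpolation between order statistics
  (`stats::quantile` type 7) as the fixed, documented definition.

Both filters are idempotent, and Q3 normalization preserves within-segment
gene ranks. Upper-quartile normalization presumes a transcriptome-scale
panel: with only tens of genes the 75th percentile is a noisy scale
estimate, so the package's calibration checks use panels of several hundred
genes, at which size the recovered factors correlate with planted
per-segment scales at r >= 0.99.

# Ligand-target pair prediction

For each ROI group with at least three segments, the package computes the
Pearson correlation of every ligand-target pair listed in a curated table
(NicheNet-like schema: ligand, target, provenance), after removing rows
whose provenance is PPI prediction, and retains pairs with `r > 0.75`
(strict, the documented convention). Correlation is computed only for
table-listed pairs; the all-pairs-then-intersect route gives the identical
result and is retained as a test oracle. Pairs involving a
constant-expression gene are skipped with a warning (their correlation is
undefined), and pairs whose genes are absent from the matrix are counted in
a skip report. No multiple-testing correction is applied: the procedure is
a pure correlation screen, and p-values would be descriptive only at these
group sizes. Duplicate (ligand, target) rows documented by both curated and
PPI sources collapse to curated, since the non-PPI evidence is what the
filter is designed to keep.

# Synthetic generators

The generators define the study conditions under which the package is
tested; they are deliberately simple and fully seeded.

* **Images** (`make_roi_image`): anti-aliased elliptical cells inside a
  circular ROI on a white margin; per-cell channel intensities drawn from
  class-specific normal distributions (defaults: green 60 +/- 8 for
  positives vs 8 +/- 2 for negatives, blue nuclei 200 +/- 20, red 15 +/- 5);
  additive painting over a dark tissue background clipped at 255; a 1 px
  Gaussian blur emulating optical blur. The default geometry mirrors the
  export format: 600 x 600 px, ROI radius 150 px. Non-overlap placement uses
  random sequential adsorption with a minimum-separation rule.
* **Point patterns** (`make_pattern`): complete spatial randomness (two
  independent uniform populations in the disc), attraction (negatives placed
  uniformly within a stated distance of random positives), and segregation
  (marks confined to opposite half-discs).
* **Expression** (`make_expression`): log-normal gene baselines, per-segment
  multiplicative scale factors, 2-4 probes per gene with multiplicative
  probe noise, planted pair correlations through shared latent factors, and
  constructed detection failures for exercising the filters exactly at
  their boundaries.

What the generators do *not* emulate - tissue texture, autofluorescence,
channel spillover, scanner noise, irregular ROI shapes, cell-density
gradients - bounds what passing tests show: they demonstrate that the
estimators and rules are implemented correctly and calibrated under their
stated models, not that the classical reference segmenter matches a trained
neural model on real tissue. On real data the segmentation backend and the
intensity cutoff are the two components a user should expect to tune.

# Numerical choices and problem sizes

* Background tolerance 10 intensity units; crop-detection accuracy on clean
  discs is ~1 px on the centre and within 2% on the radius for radii
  50-250 px (blur biases the detected radius upward by about 1 px, which is
  immaterial downstream).
* Classifier seeds default to 0; every generator takes an explicit seed and
  identical seeds give byte-identical outputs.
* Cross-K calibration in the tests uses 100 CSR replicates of 200 + 200
  points in a radius-150 window (the null mean sits within two standard
  errors of zero), 50 replicates each for the attraction/segregation sign
  checks, and a 7 + 19 cohort for group recovery - sizes chosen to mirror
  the scale of a single-study ROI cohort while keeping the whole suite fast
  on one CPU.
* Segmentation recovery is tested at 20, 100 and 500 planted cells (the
  500-cell image uses a proportionally larger ROI so that non-touching
  placement stays feasible).
* Q3 calibration uses 500 genes x 16 segments with log-normal scale factors
  (sd 0.4 on the log scale).

# Known limitations

* The reference segmenter is a classical pipeline: it under-splits genuinely
  overlapping nuclei and has no concept of cell shape beyond the distance
  transform. It is a correctness baseline and a plumbing test double for
  neural backends, not a competitor to them.
* The cross-K estimator assumes a circular window; arbitrary polygonal
  windows are not supported.
* Only two-class typing is implemented (marker-positive vs negative); the
  red channel in these images is not reliably bimodal and is not used for
  classification.
* Expression detection is binary and caller-defined; no negative-probe
  background model, batch correction, differential expression or enrichment
  analysis is included - those belong to the established downstream tools.
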