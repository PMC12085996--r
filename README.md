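# spatroi

Cell-level image analysis and spatial mixing scores for digital spatial
profiling (DSP) ROI images.

GeoMx-style DSP platforms report one expression vector per region of interest
(ROI), discarding everything about where cells sit inside the ROI. `spatroi`
recovers that information from the multiplex-immunofluorescence TIFFs the
platform exports alongside the counts. It is aimed at computational biologists
analysing DSP studies who want per-ROI tumour content, per-cell morphology,
and a quantitative tumour-stroma mixing score to carry into their expression
analysis.

The pipeline:

1. **Crop** — detect the circular ROI on its white margin and mask the rest.
2. **Segment** — per-cell label masks via a pluggable backend; a
   deterministic classical reference backend (Otsu + distance-transform
   peaks + marker-controlled watershed) ships with the package so nothing
   depends on trained weights.
3. **Features** — per-cell centroid, mean R/G/B intensities, pixel count,
   area, Crofton perimeter, circularity (4πA/P²).
4. **Typing** — marker-positive vs negative cells by fixed intensity cutoff,
   2-component Gaussian mixture, or K-means on the marker (green/PanCK)
   channel; annotated snapshot images with counts.
5. **Mixing score** — the bivariate Ripley cross-K function between positive
   and negative cells against the Poisson reference πr², summarized as a
   signed AUC:

   K̂₊₋(r) = |W|/(n₊n₋) · Σᵢⱼ wᵢⱼ 1[dᵢⱼ ≤ r],  AUC = ∫(K̂₊₋ − πr²)dr / r²ₘₐₓ

   AUC ≈ 0 under independence, > 0 for mixed (attracted) populations, < 0
   for segregated ones; ROIs are ranked and grouped into Mixture vs
   Separative.
6. **Expression** — GeoMx-style preprocessing: probe averaging, segment
   filter (< 5% detected genes dropped), gene filter (≥ 10% of segments),
   upper-quartile (Q3) normalization referenced to the geometric mean.
7. **Ligand–target screen** — Pearson correlation across each ROI group's
   segments for pairs in a curated (NicheNet-schema) table, keeping
   non-PPI-derived pairs with r > 0.75.

Seeded synthetic generators (`make_roi_image`, `make_pattern`,
`make_expression`) emulate all three input kinds with machine-readable ground
truth and drive the entire test suite.

## Worked example

```r
library(spatroi)

# a synthetic ROI: 50 marker-positive + 50 negative cells, known truth
fx   <- make_roi_image(image_fixture_spec(seed = 1))
img  <- crop_roi(fx$image)
mask <- segment_cells(img, seg_params(diameter_px = 11))
cells  <- extract_features(img, mask, roi_id = "demo")
typing <- classify_gmm(cells, seed = 0)
cells  <- apply_typing(cells, typing)
ck <- cross_k(cells_to_pattern(cells, img))
print(img); print(mask); print(typing); print(ck)
```

```
RoiImage: 306 x 306 px, cropped
  ROI centre (x, y) = (152.5, 152.5), radius = 151.8 px
LabelMask: 306 x 306 px, 100 cells
TypingResult (gmm on G): 50 / 100 positive (50.00%)
  effective intensity boundary: 16.572
CrossKResult: 100 radii up to 38.0, edge = translation, AUC mixing score = -9.0743
```

All 100 rendered cells are recovered and classified correctly (the planted
split is 50/50). The GMM places the decision boundary at green intensity
16.6, between the dim (8 ± 2) and bright (60 ± 8) class modes. The mixing
score is negative because non-overlapping cell placement makes the two
populations mildly repel each other; planted attraction/segregation regimes
score positive/negative respectively (see `make_pattern`).

`annotate_snapshot()` writes the side-by-side original/overlay PNG headed
by the counts, e.g. `Total cells: 100  Positive: 50 (50.00%)` — with 535
cells of which 258 positive it prints `48.22%`.

For batch runs, a declarative YAML config drives the whole pipeline:

```r
run_pipeline(read_run_config("run.yaml"))
```

and `inst/cli/spatroi.R` exposes the same stages as a command-line tool
(`crop`, `segment`, `classify`, `crossk`, `expr`, `rl`, `synth`, `run`).

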