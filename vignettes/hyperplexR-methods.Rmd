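---
title: "Methods: alignment, phenotyping and spatial statistics for cyclic immunofluorescence"
author: "hyperplexR"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: alignment, phenotyping and spatial statistics for cyclic immunofluorescence}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# Scope and data model

Cyclic immunofluorescence images one tissue section repeatedly: each round
stains a handful of markers, is scanned as a multi-channel whole-slide
image, and is then eluted before the next round. Because the slide is
remounted between rounds, the rounds are related by small unknown planar
motions (typically a few degrees of rotation at most and tens of pixels of
shift), and every channel carries the same endogenous tissue
autofluorescence on top of its marker signal. hyperplexR covers the
computational chain from raw per-round images to spatial statistics:

1. background subtraction and rigid/affine registration of all rounds to
   the round-1 DAPI reference, with pixel-wise autofluorescence removal
   and assembly into a single multi-channel stack;
2. region masks and derived tissue niches;
3. single-cell measurement over four intensity zones;
4. semi-supervised phenotyping with a self-organizing map (SOM);
5. spatial analytics: composition, nearest-neighbor distance networks with
   Shannon diversity, cellular neighborhoods and permutation interaction
   tests.

Images are stored as matrices with rows = y and columns = x, pixel-center
physical coordinates `(index - 1) * pixelSize` in micrometres, isotropic
pixels only (anisotropic inputs are rejected at read time, matching
slide-scanner output). Pixels are 16-bit intensities kept in whatever
numeric storage they arrive in; all operations clamp results into
[0, 65535].

## Image files

The `tiff` package used for I/O cannot write OME-XML or resolution tags,
so files written by hyperplexR are plain multi-page TIFFs (lossless
deflate/LZW, one channel per page, pyramid levels appended level-major)
accompanied by a JSON sidecar holding the channel names, pixel size and
pyramid layout. On read, metadata is resolved in this order: explicit
override, sidecar, OME-XML found in the ImageDescription tag of foreign
OME-TIFFs, TIFF resolution tags. `streamChannel()` decodes only the
requested page, so the peak working set is one full-resolution channel
plus constant overhead regardless of the stack size; the test suite
instruments this with `gc()` accounting. Vendor formats (CZI) are out of
scope; convert with standard tools (bioformats2raw/bfconvert) first.

# Registration

`estimateTransform()` minimizes the mean squared intensity difference
between the reference DAPI and the warped moving DAPI. Choices:

* **Parametrization.** Rigid = (rotation about the image center, row
  shift, col shift); affine = the six matrix entries, refined from the
  rigid solution. A `PlanarTransform` maps moving coordinates into the
  reference frame; warping samples through its inverse.
* **Pyramid.** Images are halved by 2x2 block means until the shorter
  edge is about 64 px. Initialisation is a grid search over rotation
  (-3 to 3 degrees in 0.5-degree steps) and integer shifts (+-6) at the
  *second*-coarsest level — at the coarsest level nuclei can fall below
  one pixel and the rotation signal vanishes. Each level then refines the
  three (or six) parameters by Nelder-Mead on a strided subgrid of at
  most ~256^2 sample points; translations double when moving a level up.
* **Interpolation.** Bilinear everywhere, including the synthetic-data
  generator, so forward-simulated fixtures and the estimator share one
  interpolator and integer shifts are exact.
* **Convergence.** Relative SSD tolerance 1e-10 with an iteration cap per
  level (default 200 at the coarsest, a third of that elsewhere). The
  full-resolution mean squared difference is reported as the residual.
* **Reference.** Always round-1 DAPI. Chaining round k to round k-1 is
  rejected because registration errors would accumulate across many
  rounds.

The registration search range is sized for slide-scanner repositioning
error (|shift| <= ~25 px, |rotation| <= ~3 degrees at full resolution).
Larger motions would need a wider initial grid.

Background subtraction uses the flat-disc variant of rolling-ball
estimation: grayscale morphological opening with a disc of 75 um diameter
(converted to pixels round-half-up, padded to the next odd size). Flat and
slowly varying backgrounds vanish; structures smaller than the disc
survive. Near the image border the opening uses replicated padding, so a
band of about one ball radius is less reliable — the tests therefore
assert gradient removal on the interior.

Autofluorescence removal is literal pixel-wise subtraction
`max(channel - scale * af, 0)` with the pre-antibody autofluorescence
round registered to the reference like any other round (its DAPI channel
carries true signal, so DAPI is always exempt). Channels with endogenous
fluorophores (e.g. GFP reporters) are exempted by name via
`skipAfChannels`. By default channels match their autofluorescence
counterpart by name, falling back to position, which corresponds to the
excitation/emission filter slot on the scanner.

`alignExperiment()` operates on in-memory rounds; `alignExperimentDir()`
is the disk-to-disk variant that holds only the reference DAPI plus one
streamed channel at a time and writes one single-channel TIFF per aligned
channel with a JSON manifest. Re-assembling those channels into a single
pyramidal file necessarily loads the full stack once.

The spec-level open question of whether rolling-ball precedes alignment is
resolved as *before* (it is part of raw-tile post-processing);
`rollingBallSubtract()` is exposed separately so the order can be changed.

# Regions

Binary masks for lesion, tumor, brain, vessel, ECM and excluded artifacts
come either from an external tool (imported) or from a small baseline
pixel classifier (single-hidden-layer `nnet` on per-channel raw +
Gaussian-smoothed intensities at sigma 2 and 4 px, trained on user
scribbles, seeded). This baseline stands in for interactively trained
pixel classifiers; it is not a reimplementation of any specific tool.

Mask clean-up removes connected fragments and fills enclosed holes below
per-region pixel thresholds, taken verbatim in pixels: lesion 20000,
vessel 20, tumor/brain 4000, ECM holes 50 / fragments 300. The operation
is idempotent. Derived niches use exact Euclidean dilation via distance
transforms (cheap at any radius): lesion context = lesion + 750 um,
perivascular = vessel + 15 um minus the vessel core, tumor border = the
tumor-brain interface (pixels of either mask 8-adjacent to the other —
classifier masks rarely overlap, so adjacency is the robust reading of
"intersection") dilated by 70 um. The excluded mask is always imported;
artifact removal is manual QC by nature.

# Single cells

Detections arrive as per-object masks (overlaps resolved by the strict
interior-distance rule: a contested pixel goes to the object whose
internal Euclidean distance map is strictly greatest, ties to background)
or as label maps with per-object probabilities from an external deep
segmenter. Objects below probability 0.5 are dropped (boundary kept:
filter is "< 0.5"); a size filter (`minAreaUm2`, default 4 um^2) removes
fragments. The threshold/watershed baseline (`baselineWatershedSegment`)
exists for data without an external segmenter and as the classical
comparator.

`expandCells()` grows each nucleus by 2.5 um (round-half-up to pixels)
with exact nearest-nucleus assignment, so neighboring cells meet at the
equidistant line and never overlap, and caps each cell at 1.5x its
nucleus area (`floor(1.5 * areaN)` pixels), dropping the farthest
candidate pixels first with deterministic tie-breaks. Four zones follow:
nucleus, cytoplasm (cell minus nucleus), whole cell, and membrane — the
1-px-wide boundary ring *inside* the cell mask (width configurable); the
membrane is never defined outside the cell so zones stay within the cell
partition. Empty zones yield missing values, not zeros.

Morphometrics: areas are pixel counts scaled to um^2; perimeters use
chain-code tracing with Vossepoel-Smeulders corner-corrected weights
(about 1% accurate on smooth digital shapes); circularity
4*pi*A/P^2 is capped at 1, as digital morphometry tools conventionally do,
because corrected chain perimeters can dip below the isoperimetric bound
on near-circular rasterized shapes. Region distances are measured from the
nucleus centroid to the nearest region boundary pixel (the image frame
does not count as a boundary). Cells whose centroid falls in `excluded`
are dropped.

# Phenotyping

Per marker, the classifying MFI (nuclear or whole-cell, per the marker's
biology) is clipped at the 99.7th percentile (type-7, linear-interpolation
quantiles — the convention matters at this extreme percentile) and min-max
scaled to [0, 1]; clipping means value truncation, not cell removal.
Scaling parameters are returned so new data can be projected into the same
space.

The SOM is a 10 x 10 rectangular grid (100 nodes) trained in *batch*
mode: each sweep assigns all cells to their best-matching unit and
replaces every codebook vector by the Gaussian-neighborhood-weighted data
mean, with the neighborhood radius decaying geometrically from 5 to 0.5
grid units. Batch training is deterministic given the seed (codebook
initialised from sampled data rows), fully vectorized, and converges in
few tens of sweeps; the default is 30 sweeps, a conservative setting for
the batch variant (an online SOM would instead take a few passes with
per-sample updates). Nodes are metaclustered by average-linkage
hierarchical clustering of the codebook, cut at a user-chosen k;
annotation is a user-supplied total mapping from nodes (or metaclusters)
to cell-type labels — automated naming is out of scope by design.
Batches are clustered independently (one model per batch) and merged at
annotation, which avoids batch effects entering the clustering space.

# Spatial statistics

All spatial inputs are per-cell tables (image id, group, centroid in um,
cell type, region flags). Defaults follow the workflow's constants:

* **Neighborhoods.** Neighbors are cells within 30 um (centroid
  distance, self excluded); each cell's profile is the cell-type fraction
  vector of its neighbors. Profiles pooled across images are k-means
  clustered (default k = 15, seeded, 10 restarts) into cellular
  neighborhoods; isolated cells are flagged and left unassigned. A
  passage describing the same radius as a "30 um diameter" is resolved in
  favor of the 30 um radius; pass `radiusUm = 15` for the diameter
  reading.
* **Interaction test.** The classical label-permutation test: statistic =
  mean count of B-type neighbors per A-type cell on the fixed 30 um
  graph; the null permutes cell-type labels within the image (1000
  permutations), and add-one estimators give one-tailed p values for
  attraction and avoidance. `sigval` is +1/-1/0 at alpha = 0.01 and is
  summed across a group's images (`sum_sigval`); the per-pair sum of the
  two one-tailed p values is exported alongside, since published usage is
  ambiguous between the two summaries, and neither is asserted as a
  reference value. Per-image permutation seeds derive from the master
  seed and the image id, so results are reproducible under any execution
  order. On sparse point patterns the discrete statistic makes the test
  conservative (attained levels below alpha), never anticonservative.
* **Distance networks.** For each ordered type pair, the mean over
  A-cells of the distance to the nearest B-cell, averaged per image, then
  mean/SD across a group's images. Undirected edges average the two
  directed means and SDs (the directed values remain available). Edge
  width = 100/SD. The published threshold rule "median SD x 0.8" is
  scale-dependent if applied to widths literally and contradicts its own
  worked examples; the scale-invariant reading implemented here drops an
  edge iff its SD exceeds median(SD)/0.8, i.e. the width threshold is the
  width at the median SD times the 0.8 heterogeneity cofactor. Node sizes
  bin pooled percent-total composition linearly between 1% (size 3) and
  25% (size 70) in 8 steps; endpoints saturate. Louvain clustering at
  resolution 1.5 (edge widths as weights, seeded) groups nodes; a seeded
  Fruchterman-Reingold layout with target edge lengths proportional to
  mean distance is attached for plotting only.
* **Shannon diversity.** H' = -sum p_i ln p_i per image over type
  proportions (natural log, matching reported magnitudes of ~2 over ~20
  types; the base is configurable), with the group mean reported as
  mu-H'.

# Synthetic data

The generator exists to make every contract falsifiable, not to render
realistic tissue:

* **Cyclic rounds** — Gaussian-blob nuclei (the landmark ground truth),
  per-channel marker blobs, a shared smooth autofluorescence field
  (blurred uniform noise), rendered per round through the declared true
  transform with the same bilinear interpolator as the pipeline, plus
  Poisson photon noise and Gaussian read noise (sd 2). Default
  perturbations are uniform over +-2 degrees and +-25 px, the motion
  range the registration is designed for.
* **Nuclei images** — radially perturbed blobs with non-uniform internal
  texture (emulating uneven DAPI labeling), density-controlled spacing
  (high density plants touching pairs for watershed stress tests), exact
  label-map ground truth.
* **Marker tables** — Gaussian mixtures around phenotype centroids,
  clamped non-negative. The phenotype-recovery conditions used in the
  tests are 10,000 cells, five phenotypes, centroid separation >= 5x the
  within-phenotype SD.
* **Point patterns** — CSR, Neyman-Scott clustered (shared parents across
  types plant attraction; a CSR background type is added when testing
  detection, because with *all* types sharing parents the labels are
  exchangeable and there is genuinely no interaction signal), and
  segregated bands with a declared gap (planting avoidance and spatial
  niches). Calibration tests use 200 CSR images of 150 cells in a 1 mm^2
  window with three types.

What the fixtures do **not** emulate: optical blur and chromatic shifts,
tile-stitching seams, uneven illumination, cell-shape anisotropy, marker
spillover between channels, and the sheer size and artifact diversity of
real slides. Passing tests therefore demonstrate correctness of the
algorithms under their stated assumptions, not performance on real
tissue.

# Problem sizes and determinism

The test and acceptance workloads are sized to run on one CPU in minutes:
registration recovery on 20 synthetic 2048^2 round-pairs, phenotype
recovery on 10,000 cells, interaction calibration on 200 simulated images
with 1000 permutations each, brute-force cross-checks on fixtures up to
2000 cells and 128^2 masks. Every stochastic component takes an explicit
seed; sub-seeds are derived by hashing the master seed with a component
key, so adding a component never shifts another's stream.

# Known limitations

* Only planar rigid/affine motion; no deformable registration, no tile
  stitching or flat-field correction (vendor-side in the intended
  workflow).
* OME-XML is read but not written; metadata written by this package lives
  in JSON sidecars.
* The pixel classifier is a deliberate baseline; segmentation is expected
  to come from an external deep-learning tool via label maps.
* Percentile clipping at 99.7% is sensitive to the quantile convention at
  small n; the convention is fixed (type 7) and documented.
* The interaction test's attained level is below nominal on sparse
  patterns (discrete statistic); interpret `sigval` sums accordingly.
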