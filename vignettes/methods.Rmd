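---
title: "Methods: label-free differential cell counts from quantitative phase imaging"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: label-free differential cell counts from quantitative phase imaging}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(holodcc)
```

`holodcc` turns multi-frame quantitative phase recordings of blood and milk
leukocytes into per-sample differential cell counts. This vignette explains
the model behind each stage, the parameters that matter, the numerical
choices, and what the synthetic-data tests do and do not establish about
instrument data.

## The measurement model

A digital holographic microscope with a microfluidic channel produces
frames in which each pixel holds the optical phase shift (radians) induced
by whatever lies in the light path — a function of object height and
refractive-index difference. Cells in the channel appear as smooth phase
bumps of a few radians on a quasi-static background (the channel itself,
fractions of a radian) plus sensor noise. Because sheath flows keep cells
in one focal plane, cell-on-cell occlusion is rare, and the pipeline
deliberately does not attempt to split touching objects (no watershed); an
overlapping pair is counted as one object. This is a documented limitation,
acceptable at the cell densities the pipeline targets (about 5 cells per
512 × 384 frame).

## Preprocessing

* **Background**: per-pixel median over the first `background_frames`
  (default 1000) frames of the recording. The median is robust to cells
  transiting a pixel as long as the pixel is cell-free in most frames;
  with ~5 cells/frame on a full-size frame the occupancy per pixel is well
  below 1 %. Short recordings break this assumption: with only a handful
  of frames the median absorbs part of the cell signal and segmentation
  degrades. The pipeline warns when an entire class vanishes this way.
* **Segmentation**: foreground is `(frame − background) > phase_threshold`
  with a strictly-greater comparison at 0.8 rad — applied after background
  subtraction, so the threshold has a fixed physical meaning regardless of
  channel artifacts. Connected components use 8-connectivity by default
  (4 is available); labeling is a two-pass union-find in C++ and is tested
  against an exhaustive flood-fill oracle under both connectivities.
* **Area filter**: components under `min_area_px = 30` pixels are dropped.
  The pixel count is the normative criterion; the equivalent area in µm²
  (`min_area_px * pixel_area_um2`, default 357 µm²) is reported only as
  metadata, because the pixel pitch of a given instrument is configuration,
  not algorithm. Sub-filter objects are typically debris from the cell
  isolation process, which is why the milk scene generator plants such
  objects deliberately.
* **Patches**: each cell is extracted as a `patch_size` (96 × 96) window of
  the background-subtracted frame, centered on the rounded centroid.
  Cells whose window would leave the frame are discarded by default
  (`edge_policy = "discard"`) so truncated morphology cannot bias
  features; `"zero_pad"` keeps them, which is preferable when estimating
  compositions, because discarding scales with cell size and would bias
  class proportions. Components are returned in raster order of their
  bounding boxes so every downstream artifact is reproducible.

## The 24-feature catalog

`feature_catalog()` lists the names, units and definitions. Choices a
reimplementation needs to know:

* All features are computed on the patch's stored mask and phase values —
  the mask is *not* re-derived from the patch, so segmentation and
  description cannot disagree.
* Perimeter counts exposed pixel edges (digitization-exact, easy to verify
  by hand) rather than smoothed contour length; circularity 4πA/P² with
  this perimeter peaks at π/4 ≈ 0.785 for a square.
* Ellipse features derive from the population second moments of pixel
  centers; major/minor axis are 4√λ (the uniform-ellipse convention).
* Solidity divides the pixel count by the number of pixel centers inside
  the convex hull of the mask's pixel centers (boundary inclusive,
  tolerance 1e-9); collinear masks define solidity 1.
* Phase SD, skewness and kurtosis are population moments; kurtosis is
  excess; both are defined as 0 for zero-variance patches. Entropy uses a
  32-bin histogram spanning the patch's own [min, max] with natural logs,
  and is 0 for constant patches.
* The optical volume is Σ φ · pixel_area (rad·µm²), the standard dry-mass
  proxy.
* Texture features operate on a local crop (mask bounding box plus a 4 px
  margin): gradient magnitude uses central differences (one-sided at crop
  borders), and the lobation proxy counts strict local maxima after a
  σ = 1 px Gaussian (radius 3, zero-padded). "Strict" is enforced with an
  epsilon of 1e-9 so that symmetric plateaus — where two floating-point
  evaluation orders can disagree in the 17th digit — never count as maxima.
  The 4 px margin exceeds the kernel radius, so the count is independent of
  the crop and therefore translation-invariant.

Feature tables carry a fingerprint of the ordered (name, unit) schema;
models refuse tables whose fingerprint differs from their training schema,
so a swapped or re-ordered catalog fails loudly instead of silently.

## Class balancing and training

Sorted-cell recordings are naturally imbalanced (granulocytes dominate),
so training data are balanced with SMOTE: each minority class is raised to
the majority count by sampling a base row, picking one of its
`k_neighbors = 5` same-class nearest neighbors (Euclidean distance on
z-standardized features), and interpolating with λ ~ U(0, 1). Because
standardization is affine, interpolating in original units is equivalent.
Synthetic rows are flagged, and the splitters refuse flagged tables: the
supported protocol is *split first, balance the training side only*,
including inside every cross-validation fold. Balancing before splitting —
which leaks interpolated copies of test rows into training — can be
reproduced explicitly via `allow_synthetic = TRUE` for comparison studies,
but is not the default.

Three classifier families are supported, each deterministic given its
seed:

* **kNN** — features z-standardized with training statistics; prediction is
  implemented in-package so vote ties break deterministically (smallest
  mean neighbor distance, then class order) rather than at random.
* **Random forest** — `randomForest` with grid over `ntree` {100, 300} and
  `mtry` {4, 8, 12}; raw features (forests are scale-invariant).
* **SVM** — RBF kernel via `e1071`, grid over cost {0.1, 1, 10} and γ
  {1/p heuristic, 0.01, 0.1}, standardized features.

`grid_search_cv()` scores every grid point by stratified 5-fold CV on the
training split, selecting by mean accuracy with ties broken by mean macro
sensitivity and then grid order; the winner is conventionally refitted on
the full (balanced) training data.

## Evaluation

Multi-class sensitivity and specificity are one-vs-rest per class and
aggregated as unweighted macro means; classes with zero support are
excluded from the macro with a warning. Leave-one-subject-out validation
holds out all cells of one animal per fold — the only split that measures
transfer to unseen individuals — and reports per-fold metrics with their
mean and SD.

Compositions are proportions in [0, 1] (exports may render percentages).
`compare_series()` aligns two composition series on (subject, matrix, day,
class) and reports MAE, RMSE and MRE. MRE pools all aligned pairs whose
reference value is positive; reference-zero pairs are skipped and counted,
since relative error is undefined there. MAE ≤ RMSE holds by the
quadratic-mean inequality and is asserted in tests. Whether MRE should
instead average per class before pooling is genuinely ambiguous; pooled
pairs were chosen and documented so the number has one meaning.

The vaccination-style question — did cell morphology change after an
intervention — is handled descriptively, matching how such checks are
typically assessed visually: `feature_shift_report()` computes per-feature
standardized mean differences (Cohen's d) between samples before and after
a split day, with KDE overlays via `autoplot()`. No hypothesis test is
bundled, deliberately: per-cell n is huge and would declare trivial shifts
"significant".

## The synthetic-data generator

The generator exists so that every stage has ground truth. A cell phantom
is a raised-cosine phase bump φ(ρ) = peak · cos(πρ/2) on an elliptical
digital mask (area-preserving elongation, so eccentricity does not change
expected size), with optional angular lobes (up to 25 % depression between
`lobe_count` ridges — a nuclear-lobation stand-in that feeds the
local-maxima feature) and truncated multiplicative speckle. Radius and
peak are drawn from truncated normals (±2.5 σ), which both avoids
non-physical negative draws and guarantees the default phenotypes stay
above the 0.8 rad / 30 px detection floor. Frames add a deterministic
smooth channel-artifact pattern, i.i.d. Gaussian phase noise, and phantoms
placed by rejection sampling with overlap forbidden by default. Debris
phantoms (small, below the area filter) emulate milk isolation remnants.

Default phenotypes make lymphocytes small/round/optically tall,
granulocytes medium and lobed with strong texture, and
monocytes/macrophages large, flatter and eccentric. They are stand-ins
chosen for plausibility and class overlap, *not* calibrated to bovine
cells — no quantitative per-class morphology was available to calibrate
against. Consequently, classifier accuracies on synthetic data (≈0.95–1.0)
are upper bounds: real cells vary more within class, so passing tests
demonstrate the pipeline's correctness and determinism, not clinical
accuracy. Subject-to-subject variation is emulated by jittering phenotype
size and height per subject (relative SD 0.04 by default), which is what
makes leave-one-subject-out measurably harder than pooled splits in the
test suite (jitter 0.15 there, to make the gap robust rather than
marginal).

The longitudinal design defaults to five subjects sampled on days
1, 3, 5, 8, 9, 10, 11, 12, 15, 17, 19, 22, 24, 26 — fourteen time points
across a 26-day window, four before and ten after a day-8 intervention.
Ground-truth compositions are logistic-normal perturbations of
matrix-typical base compositions (blood 55/35/10
granulocyte/lymphocyte/monocyte, milk 40/45/15 with macrophages); the
reference-method series adds truncated Gaussian noise (SD 0.02, a
realistic flow-cytometry repeatability) to the realized proportions and
renormalizes.

What the generator does **not** emulate: optical wavefront propagation or
hologram reconstruction (generation starts at reconstructed phase), focus
drift, cell-cell adhesion/doublets, debris above the area filter,
intra-class morphology shifts over time, and staining/gating errors in the
reference method beyond additive noise.

## Problem sizes and storage

Scales were chosen so the whole validation suite runs on one CPU in
minutes while keeping estimates statistically meaningful: the end-to-end
composition study uses 5 subjects × 14 days with ≥2000 cells per sample on
128 × 192 px scenes at 10 cells/frame (multinomial SE per proportion
≈0.01, far below the 0.05 acceptance band), the sorted-cell training sets
use three subjects with the default 5:3:1 class imbalance, and
segmentation recovery is checked on 200 full-size (384 × 512) frames at
noise SD 0.05 rad. Recordings are stored as multi-page 32-bit TIFF after
an affine map to [0, 1] ((φ + 4)/16, recorded in the JSON sidecar along
with scene parameters and truth records), accurate to ~4 × 10⁻⁹ rad —
the `tiff` writer normalizes samples, so raw radians cannot be stored
directly. Large studies are not kept in memory: `dhm_study` objects store
the design plus derived seeds, and `realize_sample()` regenerates any
recording bit-identically on demand.

## Reproducibility

Every stochastic function takes a seed; multi-stage drivers derive
per-stage seeds by hashing (seed, stage name), so inserting a stage never
shifts another stage's stream. The full pipeline writes a manifest with a
config hash and MD5 of every output; two runs with the same configuration
and seed are byte-identical, and a re-run over an existing directory skips
stages whose configuration hash and outputs are unchanged.
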