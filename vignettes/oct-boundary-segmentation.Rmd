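---
title: "Retinal boundary segmentation in OCT: model, phantom and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Retinal boundary segmentation in OCT: model, phantom and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

Total retinal thickness — the axial distance from the internal limiting
membrane (ILM) to the base of the retinal pigment epithelium (RPE), or to
Bruch's membrane where the RPE has atrophied — and its integral over the
central 6 mm macular zone (macular volume) are the clinical quantities used
to track degenerative retinal disease in OCT volume scans.  Instrument
software segments healthy retinas well but fails where the RPE is lost,
flecks disrupt the outer retina, or choroidal atrophy breaks the Bruch's
membrane contour, as in Stargardt disease.  `octseg` implements a fully
automatic alternative: per-pixel semantic segmentation by a convolutional
encoder–decoder, followed by graph-search extraction of each boundary.

## The segmentation model

The network is a U-Net-topology encoder–decoder over three classes
(vitreous + padding, retina, choroid + sclera).  Architecture, in the
package's `net_config()` vocabulary:

* `n_pool` (4, optionally 5) encoder levels, each of `convs_per_level = 3`
  blocks of 3×3 convolution → batch normalisation → ReLU, with a residual
  connection adding the outputs of the first and last blocks of the level.
  "Same" padding keeps the spatial size, so the output map matches the
  padded input pixel for pixel.
* `base_filters = 8` filters at the first level, doubled after every 2×2
  stride-2 max pooling: 8/16/32/64/128 for the 4-pool variant.
* A mirrored decoder: 2×2 transposed-convolution upsampling (nearest
  neighbour + 3×3 convolution available via `upsample = "nearest"`),
  concatenation with the encoder skip at the same resolution, then the same
  three-block residual level.
* 50 % dropout at the bottleneck output; a final 1×1 convolution and
  per-pixel softmax.
* Optionally a squeeze-and-excitation block at every level output.  The
  channel path (cSE) pools each feature map globally, passes the channel
  vector through a reduction-`r` bottleneck (default `r = 2`, falling back
  to 1 when a level has fewer channels) and gates each channel with a
  sigmoid; the spatial path (sSE) gates each location with a sigmoid of a
  1×1 convolution.  The concurrent variant (scSE) combines the two
  recalibrated maps elementwise.

The effective receptive field at the bottleneck, by the standard recursion
`r <- r + (k − 1) · j` with `j` the cumulative stride, is 202 px for the
4-pool variant and 410 px for the 5-pool variant — context on the order of
the whole retinal depth, which is what lets the network label atrophic
regions where local texture is uninformative.

Training minimises the soft Dice loss (`dice_loss()`), `1 − mean_c D_c`
with `D_c = (2 Σ p t + ε)/(Σ p + Σ t + ε)`, ε = 1e-6 in numerator and
denominator, with Adam at its default parameters (learning rate 1e-3,
β₁ = 0.9, β₂ = 0.999), batch size 3, samples reshuffled every epoch, and
the checkpoint with the highest validation hard-Dice (mean over the three
classes of the argmax-label overlap) selected afterwards.

### Preprocessing and augmentation

* **Contrast enhancement** (`enhance_contrast()`): per A-scan attenuation
  compensation, `E(i,j) = I(i,j)^n / (2 Σ_{k≥i} I(k,j)^n + ε)`, rescaled to
  [0, 255].  The exponent `n` (default 2) is exposed because the original
  attenuation filter's constants are not fixed by this package; the
  operation is deterministic and strictly column-local, which the tests
  exploit (it commutes with horizontal flips).
* **Padding** (`pad_top()`): 16 zero rows at the top of every image, so a
  128-row desk image (or a 496-row clinical scan) is divisible by `2^4`
  through the pooling pyramid; padding rows belong to class 0.
* **Augmentation** (`augment()`): at each presentation exactly one of
  unchanged / flipped / noisy / flipped+noisy, probability ¼ each; the
  noise is i.i.d. Gaussian with variance drawn uniformly from [250, 1000]
  per presentation, clipped to [0, 255].  Flips mirror both the image and
  the boundary arrays; noise never moves boundaries.  Enhancement is
  treated as a dataset-level preprocess and noise is added to the enhanced
  intensities; `noise_on = "raw"` re-enhances after corrupting the raw
  image instead, since the alternative ordering is equally defensible.

## Graph-search delineation

From a probability map (or a voted hard label map, one-hot encoded), each
boundary gets an edge map: the ILM is the positive row-wise rise of
`1 − p(vitreous)` and the RPE base the rise of `p(choroid)`.  The ILM
definition deliberately uses the vitreous exit rather than the retina-class
rise: the two coincide on well-formed maps, but only the former remains
meaningful where the retina class is empty (coincident boundaries over
full-thickness atrophy), and row 0 carries no edge because there is nothing
above it to transition from.

The boundary graph connects every pixel to its three rightmost neighbours
(horizontal, diagonal up, diagonal down) with weight
`w(s, d) = 2 − (p_s + p_d)`.  The weight is read as the sum form: it is
non-negative (so Dijkstra applies), vanishes exactly along fully confident
boundaries, and decreases in the destination probability — a form in which
the minimal path is the most probable boundary.  The literal reading
`2 − p_s + p_d` would penalise confident destinations and contradict the
premise that the shortest path is the predicted boundary; it is retained
behind `formula = "printed"` for auditability.  One dummy column on each
side, acting as probability-1 pixels connected vertically at zero cost,
lets the fixed top-left → bottom-right path enter and leave the map at any
row.  Ties are broken deterministically: the queue orders by (cost,
column, row) and equal-cost relaxations prefer dummy-vertical, then
horizontal, then diagonal-up, then diagonal-down moves, so an all-zero map
yields the topmost horizontal path.  The graph's ±1-row step constrains
recoverable boundaries to slopes ≤ 1 px/column — which the phantom
generator honours by construction.

Rows and columns are 0-based from the image top/left throughout the
package's data structures and its CSV dialect; `floor(row)` is the first
row of the region below a boundary when rasterising to label maps, and the
inverse mapping recovers `floor` of the original fractional rows exactly.

## Cohorting, folds and ensembling

Participants are labelled "low"/"high" macular volume by the median of the
baseline ground-truth volume (stable ordering with participant-id
tie-break, so equal volumes still split deterministically).  `make_folds()`
rotates a one-low + one-high validation pair over the group-sorted ids —
with one fold per participant pair, everyone validates exactly once — and
all remaining participants train; no participant's volumes ever straddle
the train/validation divide.  `run_experiment()` repeats training
`n_runs` times with per-cell seeds `base + 1000·run + fold`, logged in the
report.

Fold models are combined two ways.  The *average* path lets each fold model
delineate its own probability map and averages the per-fold error tables.
The *ensemble* path votes the fold label maps per pixel (modal argmax
class; ties resolved by the highest mean class probability, or the lowest
class index when no probabilities are supplied) and delineates the single
voted map.  Voting happens on hard label maps because continuous
probability maps have no natural mode; as a consequence the two paths
coincide exactly only where hard-map and soft-map delineation agree — true
for confident predictions, and tested both ways (voting identical maps
reduces to single-map delineation; naturally agreeing scans are checked in
the end-to-end test).

## The synthetic phantom

Clinical OCT volumes cannot ship with the package, so every stage is
exercised on a seeded generator (`generate_cohort()`) that emulates the
geometry of a macular raster and the gross Stargardt phenotype:

* Smooth surfaces: the RPE base is a sum of low-frequency cosines
  (amplitude decaying as 1/f) around a constant level; the ILM sits above
  it by baseline thickness (default 320 µm) minus a Gaussian foveal pit
  (default 120 µm deep, 1.2 mm FWHM) minus raised-cosine atrophy lesions
  scaled by a severity in [0, 1].  Slopes are validated against the
  1 px/column graph constraint and configurations violating it are
  rejected rather than silently clipped.
* Rendering: piecewise-constant region intensities (vitreous 15, retina
  110, a 3-row RPE band at 200, choroid 75, sclera 45), the RPE band
  suppressed by `1 − severity·w` and the sub-boundary choroid brightened
  (hypertransmission) inside lesions, Gaussian-profile hyperreflective
  flecks above the RPE, columnar vessel shadows, then multiplicative
  Gamma speckle (shape = "looks", mean 1 — the standard multiplicative
  OCT speckle model) and clipping to [0, 255].
* Cohorts: half of the participants draw mild severities (0.05–0.25), half
  severe (0.55–0.85), plus a ±15 µm thickness jitter, so baseline volumes
  straddle the cohort median and the low/high split is meaningful.

Default desk-scale geometry is 256 × 128 px with 25 slices at
34.4 / 15.1 / 260 µm — the same ~8.8 × 1.9 mm footprint as a clinical scan
with slice coverage 6.5 mm.  Twenty-five slices rather than a smaller
count is a deliberate choice: with cell-centre ETDRS membership, the 6 mm
disc area is quantised to about 0.3 % at 260 µm spacing, keeping the
constant-thickness phantom volume within the 1 % analytic tolerance that
the evaluation layer promises; at ~440 µm spacing (15 slices) the
quantisation error alone exceeds 1 %.  Clinical geometry
(1536 × 496 × 61 at 5.7 / 3.9 / 119 µm) is available by overriding the
config.

What the phantom does *not* model: physical reflectivity and attenuation,
intra-retinal sublayers, realistic lesion morphology (the free parameters
are not calibrated against any clinical cohort), eye motion, or vendor
post-processing.  Passing phantom tests therefore demonstrates that the
pipeline is correct and trainable, not that clinical-level accuracy
transfers to real scans.

## Evaluation layer

* `boundary_errors()`: MAE and signed ME in pixels over the truth's valid
  column range; positive ME means the prediction sits lower on the image.
  SDs are reported over columns per scan; aggregation across scans averages
  the per-scan tables (both conventions are printed because the field's
  summary tables rarely state which SD they use).
* `dice_overlap()`: hard per-class Dice × 100, mean over classes; a class
  empty in both maps counts as perfect agreement.
* `thickness_map()` / `etdrs_stats()`: thickness is `(rpe − ilm) ×
  axial_res`; ETDRS subfields (central 1 mm disc; inner 3 mm and outer 6 mm
  rings split into quadrants along the ±45° diagonals) are assigned by
  cell-centre membership without inter-scan interpolation — scan spacing
  dominates the discretisation, and the cell-centre rule makes the
  9-subfield volumes sum *exactly* to the direct disc integral (a tested
  partition property).  Superior is toward the first B-scans (negative y);
  nasal/temporal follow an eye-laterality flag, `OD` mapping nasal to
  positive x.  The fovea centre defaults to the volume centre (where the
  phantom pit sits); for real data it is a required input, not estimated.
* `bland_altman()`: mean paired difference with limits of agreement at
  ±1.96 sample SD.

For thickness maps built from raw *predictions*, crossing boundary pairs
(possible early in training) can be clamped to zero thickness
(`clamp = TRUE`, used by the evaluation command) instead of rejected.

## Numerical choices

* Dice ε = 1e-6; batch-norm ε = 1e-5, momentum 0.9 for running statistics
  (batch statistics in training, running statistics at inference).
* He-normal weight initialisation; all randomness (weights, shuffling,
  augmentation, dropout, phantom draws) flows from explicit seeds through a
  save/restore RNG helper, so every artifact is reproducible from its
  recorded seed.
* The convolution, batch-norm and pooling kernels run in compiled code with
  single-precision GEMMs (parameters and the R interface stay double);
  float rounding is ~1e-6 relative per pass, far below the Dice changes
  that drive training, and the test suite checks the kernels against plain
  double-precision reference implementations and finite differences.
* scSE with the elementwise-max combination has subgradient kinks where the
  two paths tie (e.g. at zeroed activations); the backward pass routes ties
  to the channel path, which is the usual subgradient convention for max.
* Batch-norm ordering is conv → BN → ReLU; the residual addition uses the
  post-activation outputs of the first and last blocks and is taken before
  the level's scSE block, so the recalibration sees the level's final
  features.  The scSE combination operator (max, with sum via config) and
  the reduction ratio follow the block's original formulation, since the
  architecture family does not pin them down.

## Problem sizes used by the tests

The bundled checks run at sizes chosen to make their properties exact or
statistically stable: Dijkstra is compared with exhaustive enumeration on
maps up to 5 × 6 (≤ 3^5 paths); boundary recovery is exact on 20 seeded
desk-scale phantoms; ETDRS closed-form checks use the clinical 61 × 1536
grid where quantisation is negligible; augmentation frequencies use
n = 10 000 draws against the binomial band; the learning sanity check
trains on 64 × 64 phantoms; and the end-to-end experiment uses 12 training
participants (3 scans each, 128 × 256) for 2 folds × 20 epochs with 4
held-out test participants — small enough to train on a single CPU, large
enough that the network reaches validation Dice > 0.95 and the ensemble
path localises both boundaries to nearly a pixel.

## Known limitations

* Only the two outer boundaries are segmented; no intra-retinal sublayers.
* The graph search is per-boundary and unconstrained across boundaries, so
  a pathological probability map can order ILM below RPE; downstream
  consumers validate or clamp.
* Boundaries are integer-row (no sub-pixel refinement after the argmax-like
  edge construction).
* The phantom's appearance model is geometric, not physical; transfer
  claims to clinical data are out of scope.
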