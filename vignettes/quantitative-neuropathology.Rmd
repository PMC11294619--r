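---
title: "Methods: synthetic validation of a post-mortem neuropathology pipeline"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: synthetic validation of a post-mortem neuropathology pipeline}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nigraquant)
```

# Scope and rationale

`nigraquant` implements the quantitative desk-side half of a post-mortem
study of nigral dopaminergic neurons: subcellular quantification of
lysosomal-related puncta in labelled cells, optical-fractionator
stereology, DAB densitometry and elemental-map summarisation, and
two-group estimation statistics. The tissue itself (macaque midbrain) is
not available at desk scale, so every procedure is validated against a
synthetic-data generator whose ground truth is known by construction.
This vignette records the models, the parameters that matter, and the
design decisions taken where the field's conventions leave room.

# The synthetic-data generator

The generator is first-class, tested code — it defines the conditions
under which the pipeline is validated.

**Single-cell images** (`generate_cell_image()`). One neuron per image:
soma and nucleus are (optionally rotated) ellipses; the default geometry
is a 30 × 30 µm field at 0.1 µm/px (a typical confocal sampling density),
a 12 × 10 µm-semi-axis soma and a 5 × 4 µm nucleus. Puncta are rendered as
isotropic Gaussian spots truncated at 3σ with σ = radius/2, which mimics a
diffraction-limited vesicle while keeping an unambiguous true area (πr²);
the default radius is 0.5 µm, in the range reported for
lysosome-associated vesicles. Placement is rejection sampling (≤ 1000
retries per punctum, an explicit placement-failure error otherwise) under
three constraints: centres at least one radius inside the soma border,
centres clearly on the intended side of the perinuclear band (a two-pixel
class margin, so that sub-pixel centroid error can never flip a
ground-truth compartment label), and centre-to-centre separation of at
least 2.5 radii so that noiseless detection is unambiguous. The camera
model is optional Poisson shot noise on the signal followed by additive
Gaussian read noise — the standard fluorescence-camera cascade. All
randomness flows from one integer seed; identical parameters and seed
give bit-identical images.

The defaults (10 perinuclear + 5 cytosolic puncta, peak intensity 100
over background 10) are free choices, not claims about real intensity
statistics, which the source imaging does not constrain. What the
generator deliberately does *not* emulate: point-spread anisotropy and
z-blur (the analysis is strictly 2-D on one chosen z-plane), tissue
autofluorescence texture, multi-cell crowding, and segmentation error
(masks are inputs, drawn manually in the emulated workflow). Passing
tests therefore demonstrate correctness of the measurement chain given
masks, not robustness to segmentation failure.

**Neuron fields** (`generate_neuron_field()`). Reference points
(nucleolus proxies) uniform in a cuboid (default study geometry
6000 × 4000 × 3000 µm, about the extent of a macaque SNpc block), cut
into 50 µm sections; each neuron belongs to exactly one section, which is
what counting "the nucleus included in the probe" enforces. A 1-in-12
series is sampled with a random phase (systematic uniform random
sampling).

**DAB images** (`generate_dab_image()`). A Gaussian-smoothed random field
thresholded at its k-th largest value, k = round(fraction × n): blob-like
stain with an *exactly* known stained-pixel count, so surface-ratio
recovery can be asserted to one-pixel quantisation. Intensities use an
inverted-brightfield convention (stain bright).

**Elemental maps** (`generate_elemental_map()`). I.i.d. normal
concentrations truncated at zero around a mean ppm; the default map is
100 × 100 pixels at a 5 µm step — a 500 × 500 µm field matching the
synchrotron raster geometry it emulates. Spatial correlation of real
elemental maps is not modelled; only ROI means are consumed downstream.

**Group tables** (`generate_group_table()`). Two normal samples in the
long per-hemisphere layout. The study-scale conditions used throughout
the tests are n = 6 control vs 4 test hemispheres, SD 8, effect −30.

# Puncta quantification

The measurement chain per cell is: QC filter → soma masking → detection →
compartment partition → metrics.

* **QC.** Cells are analysed only when cytoplasm:nucleus area ratio ≥ 2
  (the "2:1" criterion, read as a minimum and configurable); excluded
  cells are logged with their ratio, never silently dropped.
* **Detection.** Gaussian pre-smoothing (σ = 1 px by default; standard
  spot-calling practice, and measurably harmless on noiseless input),
  then Otsu's threshold computed on *within-soma* pixels only — per cell,
  so that the dominant extracellular background cannot drive the
  threshold, and so that per-cell staining variation is absorbed. A
  degenerate (single-valued) histogram raises an error that points to the
  fixed-threshold mode rather than guessing. Binarised components are
  8-connected; components below 2 px are discarded as single-pixel noise.
  Areas and centroids are reported in µm using the pixel-centre
  convention (physical position = (index − ½) × pixel size on 1-based
  matrix indices).
* **Compartments.** The perinuclear compartment is the cytoplasm within a
  Euclidean distance band of the nucleus region (default 2 µm — the
  boundary is not defined in the emulated workflow, so it is an exposed,
  resolution-independent parameter); the cytosolic compartment is the
  remaining cytoplasm, and the two tile the cytoplasm exactly. The
  distance threshold is floored at one pixel so a vanishing band degrades
  to the one-pixel shell rather than to an empty set. Puncta are assigned
  by centroid membership; a centroid overlying the nucleus (distance 0)
  is assigned to the perinuclear compartment, which makes whole-cell =
  perinuclear + cytosolic an identity rather than a fallible assertion.
* **Distances.** The nucleus is summarised by its moment-matching ellipse
  (semi-axes 2√eigenvalues of the pixel covariance, with a px²/12
  within-pixel correction; collinear regions are rejected before the
  correction can mask them). Border distance = centre distance − mean
  radius, with mean radius = (a + b)/2, and is negative over the nucleus.

Measured behaviour under the generator's conditions: noiseless recovery
is exact in count and compartment for 100/100 seeds, and at peak
signal-to-noise 5 the mean absolute relative count error is ~0.3%
(bound asserted: 5%).

# Stereology

The optical fractionator estimates total neuron number as
N̂ = ΣQ⁻ / (ssf · asf · tsf). The default design — 100 × 80 µm frames on a
600 × 400 µm grid (asf = 1/30), a 1-in-12 section series (ssf = 1/12),
tsf = 1 — gives the multiplier 360. tsf defaults to 1 (planar counting)
because the emulated procedure states no dissector height or guard zones;
it is exposed as a parameter rather than invented.

Counting frames use the Gundersen convention: inclusion on the top and
right edges, exclusion on the left and bottom with their extensions;
abutting frames therefore count every point exactly once (asserted on
10 000 random points). Grid placement draws one uniform-random offset per
section within a grid cell; a frame belongs to the layout when its origin
falls inside the region bounds — the only rule consistent with "one grid
cell ⇒ one frame". This rule leaves a thin under-sampled strip at two
region edges worth ≲ 0.5% of the estimate at the study geometry; the
Monte-Carlo bias over 200 simulated fields measures 1–2%, inside the 5%
acceptance band and dominated by sampling noise (estimator CV ≈ 18% per
field at this design — which is also why per-hemisphere contrasts on 6 vs
4 fields are noisy, as the analysis scripts show).

# Densitometry

`mean_grey()` is the plain ROI mean. `surface_fraction()` is the fraction
of ROI pixels at or above a stored threshold — the operative quantity
behind colour-thresholded "surface" measurements; the RGB colour
deconvolution of the original toolchain is deliberately reduced to
single-channel thresholding on an inverted-brightfield convention, since
only the ratio semantics are reproduced. Thresholds are configuration
values applied unchanged across all images of a stain.
`percent_of_control()` rescales by the control mean (the control sample
then averages exactly 100%). `roi_mean_concentration()` averages
elemental maps over an ROI.

# Estimation statistics

`unpaired_t()` is the pooled-variance two-tailed Student t
(df = n₁ + n₂ − 2), matching the reported convention; Welch is behind a
flag. The degenerate zero-variance case is defined as t = 0, p = 1 for
equal means and an explicit error otherwise. Calibration is asserted by
simulation: type-I error 0.05 ± 0.01 over 10 000 null experiments at
n = 6 vs 4.

`bootstrap_mean_diff()` resamples within groups and returns the resample
distribution of mean(test) − mean(control) with a percentile (default),
BCa, or studentized (bootstrap-t) interval, all seed-deterministic,
default 5000 resamples (a warning below 1000). A design point worth
stating plainly: at the tiny group sizes this field works with (n = 4–6
per group), percentile and BCa intervals *undercover* — we measured ~0.87
empirical coverage at nominal 0.95 under the study conditions. This is a
known small-sample property of those intervals, not an implementation
artefact. The studentized interval, which pivots each resample by its own
standard error, restores ~0.95 coverage and is the method the coverage
validation exercises; percentile remains the default because its
resample distribution is what Gardner–Altman estimation graphics display.

`zscore_profile()` standardises each variable against the control group
((x − mean_ctrl)/sd_ctrl, sample SD), with controls optionally collapsed
to their all-zero mean row as in heat-map summaries; zero-SD variables
are dropped with a warning rather than producing infinities.
`export_gardner_altman()` packs raw values, group mean ± SD, the effect
size with CI, the resample curve, and the difference-axis origin (the
control mean, so the effect marker aligns with the test-group mean).

Observational units are hemispheres, taken as independent — mirroring
the emulated study design; this ignores the nesting of hemispheres
within animals and is a deliberate, documented statistical caveat, not
an endorsement.

# Problem sizes and determinism

The validation suite uses: 100 cells (300 × 300 px) per puncta criterion,
200 simulated fields of 12 000 neurons for stereology, 10 000 points for
the edge rule, 10 000 null t-tests, and 2000 bootstrap-coverage
experiments at 1000 resamples — sizes chosen so the whole suite validates
the estimators' asymptotic claims in minutes on one CPU. Every stochastic
step takes an explicit integer seed and derives any sub-streams
deterministically, so all results here are exactly reproducible.

# Known limitations

* Masks are inputs: nothing here measures segmentation quality.
* Strictly 2-D; no optical-dissector stepping in z, no 3-D PSF.
* Elemental maps are consumed, not fitted: no X-ray spectrum modelling.
* No multiple-testing correction across endpoints (none is applied in
  the emulated workflow); no hierarchical modelling of hemisphere
  nesting.
* The stereology estimator's per-field CV at the default design is
  ~18%; group contrasts on a handful of hemispheres inherit that noise.
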