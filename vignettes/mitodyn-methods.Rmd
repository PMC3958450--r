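---
title: "Methods: how mitodyn measures organelle dynamics, FRAP and puncta"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: how mitodyn measures organelle dynamics, FRAP and puncta}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

mitodyn quantifies three things from time-lapse confocal imaging of
cultured cells: how much mitochondria remodel their length over minutes,
how mobile a fluorescent cargo is between compartments (FRAP), and how many
bright autophagy-associated puncta each cell carries. This vignette is the
package's own account of the models, the parameters that matter, the
numerical choices, and what the synthetic-data validation does and does not
demonstrate.

## Imaging model and calibration

A movie is a list of grayscale intensity frames plus two calibration
numbers: `pixel_size_um` (default 0.09 µm/px) and `time_step_s` (default
109 s), matching a 63×/1.4 NA confocal acquisition of MitoTracker-stained
fibroblasts at 8-bit depth. All geometry below is computed in pixels and
converted once at the end; all defaults assume bright objects on a dark
background. The analysis is planar: when a z-stack is present one
best-in-focus plane is selected per series (variance-of-Laplacian score,
first-index tie-break) rather than per frame, because refocusing between
frames would couple focus drift into the length signal. An explicit plane
index can override the automatic choice.

## Segmentation: two morphologies, two methods

No single segmentation handles both a bright interconnected tubular
network and a field of dim short fragments well, so the pipeline has two
modes selected by `segmentation.mode`:

* **`midgrey`** (fragmented morphology). A pixel is foreground iff its
  intensity strictly exceeds `(local_min + local_max)/2 − offset`, extrema
  taken over a disk of `radius` 15 px with reflect padding at borders. Ties
  go to background, so constant regions produce nothing. Two guards make
  the textbook rule practical: `min_contrast` (default 25, ~10 % of the
  8-bit range) forces pixels whose local contrast is below it to
  background — in object-free regions the mid-grey sits in the middle of
  the noise and would otherwise mark ~half of the background as foreground
  — and `min_area_px` (default 9, a 3×3 block, below the optical resolution
  at 0.09 µm/px) removes speck components.
* **`ridge`** (tubular morphology). The frame is min-max normalized,
  Gaussian-smoothed at `tubule_sigma_px` (default 2, matched to the tubule
  half-width), and the smaller eigenvalue of the Hessian is computed per
  pixel; bright tubules give a strongly negative value across the tube.
  The scale-normalized ridge strength is thresholded at
  `response_threshold` (default 0.04) and cleaned with the same area
  filter.

### Centerlines and length

Each connected component (8-connectivity throughout) is reduced to an
ordered single-pixel-wide path. The default extractor is a **geodesic
medial axis**: the weighted shortest path between the component's two most
geodesically distant pixels, with edge costs inflated away from the ridge
of the Euclidean distance transform (centering weight β = 2) so the path
runs along the tube axis and spans the object tip to tip. Classic
iterative thinning (Zhang–Suen, with spur pruning and longest-path
decomposition) is also available, but thinning retracts the rounded ends
of a tubule by roughly its own width — on a 2 µm fragment that is a 30 %
error — so it is kept for topology and QC, not measurement.

Path length is the sum of axial (1) and diagonal (√2) steps times the
pixel size. Because the geodesic path runs tip to tip, it overshoots the
true filament length by one end-cap radius per end; `segment_movie()`
therefore subtracts `2 · r_mean` pixels, where `r_mean` is the mean
distance-transform value along the path (the tube half-width). In ridge
mode the mask additionally extends longitudinally past the tip (the
curvature response decays slower than the intensity), so the path is first
trimmed to its intensity full-width-half-maximum endpoints before the cap
subtraction; the mid-grey mask needs no trim because its boundary is
already an adaptive half-maximum surface. On noise-free synthetic movies
these conventions keep per-object length errors within ±10 % for both
presets (mean bias ≈ +1–2 %), which is the accuracy the dynamics
statistics below require.

## Tracking

Per frame, each centerline contributes one record: the unweighted centroid
of its path pixels plus its length. Frame-to-frame linking minimizes total
squared centroid displacement by the Hungarian algorithm with the
Crocker–Grier opt-out: candidate pairs farther than `max_disp_px` (default
20 px ≈ 1.8 µm/frame) are forbidden, and any object may instead remain
unmatched at cost `max_disp_px²`. The pure "minimize displacement among
feasible assignments" objective is degenerate (the empty assignment is
always optimal); the birth/death-cost formulation is the standard
non-degenerate reading and is what the exhaustive-enumeration oracle in
the test suite implements as well. Unmatched objects stay claimable for
`memory_frames` (default 2) before their track closes. Equal-cost optima
are resolved toward low previous-object indices by an infinitesimal
lexicographic perturbation of the cost matrix, making linking fully
deterministic. Tracks shorter than 3 records are excluded from dynamics
summaries (and counted), not deleted. Neither parameter is measured from
data — both are config keys with declared defaults.

## Dynamics statistics

Per track with ≥ `min_track_len` records:

* **dynamic range** `100 · (max − min)/mean` of the length series (%), the
  single-number measure of length remodelling. A network whose filaments
  swing between half and 1.5× their mean length scores 100 %; a static
  fragment scores 0. The statistic is scale-invariant, so calibration and
  any residual proportional length bias cancel.
* **net displacement** (µm), first-to-last centroid distance;
  **path length** (µm), summed step distances; **directionality**, their
  ratio (confinement ratio, in [0, 1]). The confinement ratio was chosen
  as the most widely used single-number directionality for organelle
  motion.

Condition-level summaries report medians and interquartile ranges rather
than means, because per-track statistics are skewed and track lengths are
heterogeneous.

## FRAP

The recovery model is a single exponential
`F(t) = F0 + (F_inf − F0)(1 − e^{−(t−t0)/τ})` fitted by Levenberg–Marquardt
least squares over the post-bleach samples only. `F0` is fixed at the
bleach-index sample rather than fitted: the bleach empties the compartment
by design, and freeing `F0` makes shallow-slow and deep-fast fits nearly
degenerate at 2-min sampling. Initialization is deterministic (`F_inf`
from the last sample, nudged off the floor for barely-recovering series;
τ from a fixed ladder starting at half the post-bleach span, because the
nonlinear-model construction occasionally rejects a single unlucky start).
An exactly flat post-bleach series short-circuits to mobile fraction 0
with τ undefined. The mobile fraction `(F_inf − F0)/(F_pre − F0)` is
reported clipped to [0, 1] with the raw value retained. The bleach index
is the largest single-step drop, accepted only if it exceeds 50 % of the
running prebleach mean. Recovery percent at an arbitrary time (e.g.
15 min, which is not a 2-min sample time) uses linear interpolation
between the bracketing samples. No acquisition-photobleaching or
reference-ROI correction is applied by default, matching low-illumination
acquisition; the normalization `(F − F0)/(F_pre − F0)` is used identically
for measurement and simulation truth, since no alternative convention is
dictated by the data.

## Puncta

Spots are detected as local maxima of scale-normalized
negative-Laplacian-of-Gaussian responses over a geometric ladder of 4
scales in `[sigma_min_px, sigma_max_px]` (default 1–3 px), followed by
cross-scale non-maximum suppression (strongest first, exclusion radius
√2 σ). Two gates remove noise: a candidate's response must exceed both 5 %
of the strongest response in the field and 6× the robust (MAD) spread of
the response map — the latter makes blank or noise-only fields yield
exactly zero spots — and its image intensity must exceed
`median + k_background · MAD` of the frame (default k = 3), the robust
automatic analog of "larger and brighter than background". Cells are a
provided label image (cell segmentation is out of scope); each spot is
assigned to the cell containing its center, spots on background are
discarded but counted. A cell is positive iff it has **more than 5**
puncta (5 is negative, 6 positive), the fraction positive and the mean
count per cell (autophagy index) are reported, and two conditions are
compared as an index ratio.

## The synthetic-data generators

The generators define the study conditions; their defaults are the
conditions the analyses are validated against and are not tuning knobs.

* `control_mito`: 6 smooth random curves of 5–10 µm in a 512² px field
  (~46 µm), tubule width 0.36 µm, length oscillation amplitude 1.0;
  `mutant_mito`: 12 curves of 1–3 µm in a 288² px field, amplitude 0.15.
  Both: PSF σ 0.15 µm, additive Gaussian noise σ 2 (8-bit counts),
  background 12, peak 200, centroid jitter 0.15/0.05 µm per frame, zero
  fission/fusion rate. Per object the length scale follows a sinusoid with
  random phase, affinely normalized so that `(max − min)/mean` over the
  series equals the amplitude *exactly* — only that statistic is
  contractual, the waveform is not. Field sizes are ROI-scale crops of the
  1024² px acquisition geometry; they keep a full test run in tens of
  seconds while leaving every object tens of pixels long. Object placement
  rejects overlap at the maximal oscillation scale and fails loudly after
  bounded retries. Fission (`event_rate` > 0) splits a curve permanently,
  the larger fragment keeping the identity; fusion is not simulated, and
  both shipped presets use rate 0, since event counting is not an output
  of the analysis.
* `control_frap` (mobile fraction 0.92, τ 240 s) and `mutant_frap` (0.55,
  τ 375 s) encode ≈90 % and ≈50 % recovery 15 min post-bleach via the
  closed form `100 · Mf · (1 − e^{−900/τ})`, sampled every 2 min for
  30 min with 3 prebleach samples, 90 % bleach depth and 2 % multiplicative
  noise.
* Puncta fields: cells are disks (radius 24 px) on a grid; per-cell counts
  come from a user distribution; spots (Gaussian, σ 1.5 px, amplitude 150
  over background 20, noise σ 2) are placed with ≥ 4σ separation by
  dart-throwing with whole-cell restarts.

What passing these simulations shows — and what it does not. The movies
share the acquisition's geometry, PSF blur, quantization and noise floor,
so they exercise rasterization, thresholding, skeleton extraction, linking
and all downstream arithmetic at realistic scales. They do not contain
out-of-focus haze, uneven illumination, organelle crossings, true
fission/fusion topology changes, photobleaching over the series, or cell
movement; real data will degrade segmentation and tracking in ways these
tests cannot detect, and the two-mode segmentation in particular assumes
the user picks the mode matching the morphology.

## Numerical conventions and degenerate inputs

Pixel coordinates are 1-based `(row, column)` as in R matrices; ROIs are
inclusive rectangles. Mid-grey ties resolve to background; focus and
assignment ties resolve to the first/lowest index. A constant image
segments to nothing; an empty mask yields a zero-row centerline table; a
blank movie aborts the pipeline with a stage-tagged error rather than an
empty summary. Length of a single-pixel path is 0. `dynamic_range`
requires ≥ 2 finite positive values; tracks below the length filter are
counted, not silently dropped. TIFF I/O is bit-exact at 8 and 16 bit;
calibration travels in the run config, not the image file.

## Problem sizes used in validation

The shipped test suite and the acceptance script run, per condition, one
8-frame movie (6 or 12 objects), 20 FRAP series, and two 200-cell puncta
fields — sizes chosen to mirror the emulated study (≥ 8 time intervals,
200 cells scored per genotype, ~20 FRAP cells) while completing in about a
minute; the amplitude-recovery sweep additionally covers amplitudes
{0, 0.15, 0.5} on noise-free movies, with the static condition run without
centroid jitter so that a truly constant object tests for spurious
dynamics.

## Known limitations

* Planar analysis; 3-D structure is collapsed to the selected plane.
* Lengths assume tube-like objects; the longest-geodesic convention
  underreports strongly branched networks (a branched object contributes
  its longest limb).
* The tracker links objects one-to-one; fission/fusion appear as track
  births/deaths, not lineage.
* FRAP fitting assumes a single kinetic component and no acquisition
  bleaching.
* Puncta counting needs a cell label image from elsewhere, and the >5 rule
  is a fixed convention of the assay it reproduces.
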