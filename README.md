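# mitodyn

Quantitative image analysis of mitochondrial morphology dynamics,
fluorescence recovery after photobleaching (FRAP), and autophagic puncta
from time-lapse confocal microscopy — built for studies that compare a
tubular, highly dynamic mitochondrial network against a fragmented,
near-static one (e.g. wild-type versus lipid-trafficking-deficient
fibroblasts).

## What it computes

**Mitochondrial morphology dynamics.** Each frame of a calibrated movie
(`0.09 µm/px`, `109 s/frame` by default) is segmented into single-pixel-wide
centerlines, one per mitochondrion:

* fragmented morphologies: adaptive local *mid-grey* thresholding — a pixel
  is foreground iff its intensity exceeds `(local_min + local_max)/2` over a
  disk of radius 15 px — followed by medial-axis centerline extraction;
* tubular networks: Hessian ridge tracing — the principal-curvature map of
  the Gaussian-smoothed image is thresholded and reduced to centerline
  paths.

Objects are linked across frames by optimal bipartite assignment on squared
centroid displacement (Hungarian algorithm with a maximum displacement and
a gap-closing memory, in the Crocker–Grier formulation). Per track, the
package reports mean length, **dynamic range**
`100 · (max − min)/mean` of the length series (the statistic used to
quantify fission/fusion-driven length remodelling), net displacement, path
length and directionality (confinement ratio `net/path`).

**FRAP.** ROI intensity series are normalized as
`100 · (F(t) − F0)/(F_pre − F0)`; the bleach is auto-detected, recovery at
any time point is interpolated, and the exponential model
`F(t) = F0 + (F_inf − F0)(1 − e^{−t/τ})` is least-squares fitted with `F0`
fixed at the bleach-floor sample, yielding the mobile fraction
`(F_inf − F0)/(F_pre − F0)` and the recovery time constant τ.

**Autophagy scoring.** Bright puncta are detected by multi-scale
Laplacian-of-Gaussian filtering with a robust brightness gate
(`median + k·MAD`), counted per cell (cells are a provided label image), a
cell is *positive* iff it has more than 5 puncta, and the **autophagy
index** is the mean puncta count per cell; two conditions are compared by
the fold change of their indices.

**Synthetic data with ground truth.** Because every stage must be testable
without raw microscopy, the package ships generators that emulate the study
conditions: `control_mito` (6 filaments of 5–10 µm, length dynamic range
1.0), `mutant_mito` (12 fragments of 1–3 µm, dynamic range 0.15),
`control_frap`/`mutant_frap` (2-min sampling, 2 % noise, ≈90 % / ≈50 %
recovery at 15 min), and puncta fields with known per-cell counts. All
generators are bit-reproducible given a seed, and every analysis result in
this README and in the test suite is a *recovery* of those known truths
through the full pipeline.

## Worked example

```r
library(mitodyn)

gm <- generate_mito_movie("mutant_mito", n_frames = 8, seed = 2)
gm$movie
#> <mito_movie> 8 frame(s), 288 x 288 px, 0.09 um/px, 109 s/frame

objects <- segment_movie(gm$movie, mode = "midgrey")
tracks  <- link_tracks(objects, max_disp_px = 20, memory_frames = 2)
summarize_dynamics(tracks, pixel_size_um = gm$movie$pixel_size_um)
#> <dynamics_summary> 12 track(s), 0 excluded (< min length)
#>   median dynamic range: 17.3%  median length: 1.70 um
```

All 12 simulated fragments are recovered as tracks; the median measured
length (1.70 µm) falls in the preset's 1–3 µm range and the median dynamic
range (17.3 %) recovers the preset's 15 % truth — compare ≈100 % when the
same pipeline runs on `"control_mito"` in ridge mode.

```r
g   <- generate_frap_series(0.55, 375, seed = 10)  # mutant-like series
fit <- fit_recovery(g$curve)
fit
#> <frap_fit> mobile fraction 0.567, tau 395.9 s (F_pre 198.0, F0 19.8, F_inf 120.9)
recovery_percent(g$curve, 900)
#> 51.7
```

The fitted mobile fraction (0.567) and recovery at 15 min (51.7 %) recover
the generating truth (0.55, τ = 375 s). `autoplot(fit)` draws the curve
with its fit; `tidy()`/`glance()` return the parameters as tibbles.

The same pipelines run headless from a YAML config:

```sh
Rscript inst/scripts/odyn.R mito --config run.yaml --seed 2 --out results/
```

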