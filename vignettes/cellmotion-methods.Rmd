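---
title: "Measuring collective keratinocyte motion: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring collective keratinocyte motion: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cellmotion)
```

## The measurement problem

Cultured oral keratinocytes destined for tissue-engineered grafts must be
quality-controlled without staining, fixing or sacrificing the cells.
First-passage (p1) keratinocytes grow as discrete, loosely connected
colonies, and how fast this cell mass moves collectively turns out to be a
useful, non-invasive proxy for proliferative capacity: fast-moving
cultures double quickly (low population doubling time, PDT), and cultures
whose mean motion speed falls below a system-specific threshold — 40 μm/h
in the culture system this method was developed on — are flagged as
substandard before any graft is manufactured.

`cellmotion` implements that measurement from time-lapse phase-contrast
frames:

1. **Segmentation** of the cell-covered area per frame: 3×3 Gaussian
   smoothing → Sobel edge magnitude → Chan–Vese two-phase binarisation of
   the edge image. Cell area is edge-rich; background is flat.
2. **Dense optical flow** between consecutive frames (polynomial-expansion
   / Farnebäck-style, coarse-to-fine).
3. **Motion speed (MS)** per frame pair: the mean displacement magnitude
   over the cell mask of the pair's first frame, converted to μm/h.
   Sub-pixel vectors are included — there is no minimum-displacement
   cutoff.
4. **Mean motion speed (MMS)**: the time-average of MS over the capture;
   growth fraction, PD/PDT, threshold screening and the MMS–PDT Spearman
   correlation complete the quality-control picture.

The standard capture is 4 h at 8-min intervals (31 frames, both endpoints
imaged), started when the culture reaches ≈50% confluency;
`start_condition_check()` enforces that window because motion declines
under contact inhibition at ≥70% confluency and drifts upward at 30%.

## Calibration

Pixel size is not standardised across instruments, so
`calibration_profile(microns_per_pixel, minutes_per_frame)` is a mandatory
user input with no default scale. The conversion is exact:
`μm/h = px/frame × microns_per_pixel × 60 / minutes_per_frame`; at
0.5 μm/px and 8 min/frame, 1 px/frame = 3.75 μm/h. Every speed the
package reports scales linearly with `microns_per_pixel`.

## Chan–Vese segmentation: parameters and numerics

The two-phase energy is

$$ E(C) = \mu\,\mathrm{Length}(C) + \nu\,\mathrm{Area(inside)}
  + \lambda_1 \int_{in} (u_0 - c_1)^2 + \lambda_2 \int_{out} (u_0 - c_2)^2 $$

with `λ1 = 1.2, λ2 = 1.0, ν = 0.02, μ = 0.8` as defaults — the weights
tuned against manual segmentations of phase-contrast keratinocyte images.
Those weights presuppose a fixed intensity scale, so the edge image is
min–max rescaled to [0, 1] before evolution (`rescale = TRUE`); input
frames are likewise normalised to [0, 1] on load regardless of bit depth.

Numerical choices, all exposed in `chan_vese_params()`:

* **Evolution.** Explicit gradient descent on a level set with the
  smoothed Heaviside/delta pair (`epsilon = 1`), initial step
  `time_step = 0.5`. Whenever a step would *increase* the energy the step
  is halved and retried (backtracking), so the recorded energy trace is
  non-increasing by construction; if no decrease is possible the
  evolution stops at the local minimum.
* **Convergence.** Mean absolute level-set change below
  `tolerance = 1e-4`, or 500 iterations. The looser 1e-3 sometimes stops
  before interior holes have closed, because the mean is diluted by the
  large static far field; 1e-4 costs a few hundred extra vectorised
  iterations and closes them.
* **Initialisation.** The default seeds the level set with the image
  minus its Otsu threshold. The classical checkerboard seeding was
  evaluated and rejected as a default: on edge-magnitude images it
  reliably settles into a local minimum that traces individual texture
  ridges (IoU ≈ 0.3 against known colony masks) rather than whole cell
  regions, whereas the threshold seed converges to the cell/background
  split (IoU > 0.9). `init = "checkerboard"` remains available.
* **Phase labelling.** After convergence, the phase with the larger mean
  edge magnitude is "cell", removing the sign ambiguity of the level set.
* **Degenerate input.** A constant image admits no two-phase split: the
  fit is flagged `degenerate`, carries an empty mask, and warns.
* **Cleanup.** Hole filling and small-object removal (`clean_mask()`)
  exist but are **off** by default — the basic three-step procedure does
  not include a morphology pass.
* **Performance.** The evolution loop is compiled (Rcpp); a 256×256
  frame converges in roughly a second on one CPU core, and every frame
  of a sequence is segmented independently. No automatic downscaling is
  applied to large frames; `segment_sequence(decimate = k)` offers
  explicit decimation. A `warm_start` option can seed each frame from
  the previous frame's level set, but it is **off** by default: a
  warm-started contour adapts only slowly to content that moved or grew
  between frames — on sequences with the standard 4–16 px/frame motion
  it visibly erodes the masks — so it is safe only for near-static
  scenes.

## Optical flow

Each image patch is approximated by a local quadratic
`f(x) ≈ xᵀAx + bᵀx + c` under a Gaussian weight (`poly_expansion()`,
window 5 px, σ = 1.1); equating the expansions of two frames yields a
per-pixel linear system for the displacement, solved after Gaussian
window-averaging (15 px) of the normal-equation terms and refined 3 times
per pyramid level. Defaults follow the conventional settings of the
widely used implementation of this scheme, with one deviation: **4
pyramid levels** instead of 3. At the default calibration the relevant
speed range of 15–60 μm/h corresponds to 4–16 px/frame, and 3 levels fail
to lock onto ~16 px displacements while 4 levels recover 0.5–16 px
shifts to within a few percent at negligible extra cost.

Flow runs on the normalised grayscale frames (not the edge images), and
the mask paired with frames (t, t+1) is the mask of frame *t*, where the
vectors originate. Pairs with an empty mask yield `NA` (the statistic is
undefined, not zero), are excluded from the MMS, and warn.

## The MMS divisor

An n-frame capture has n − 1 consecutive pairs, yet the originally
described statistic divides the MS sum of a 31-frame capture by 31.
`mms()` and `motion_record()` default to the mean over the actual pair
count — the defensible estimator — and provide `paper_divisor = TRUE`,
which divides the pair sum by `n_frames` instead (ratio 30/31 ≈ 0.968 for
the standard schedule) for numeric comparability with the original
convention.

## Proliferation metrics and screening

PD and PDT use the standard closed forms `PD = log2(N/N0)` and
`PDT = I/PD` for `N0` cells plated, `N` harvested, `I` days in culture —
the forms consistent with how those variables are defined in the source
protocol (the original supplementary formula is not printed in the
available text; this identification is deliberate and worth knowing
about). A non-growing culture (PD ≤ 0) has undefined PDT, returned as
`NA` with a warning.

`classify_culture()` marks a culture SUBSTANDARD when MMS is *strictly*
below the threshold, 40 μm/h by default. That number is explicitly
culture-system-specific, so it is a plain argument, not a constant.

`spearman_correlation()` uses average ranks, the two-sided t
approximation for p, and a Fisher-z interval with standard error
`1.03/√(n−3)` — the mildly inflated variance conventional for rank
correlations and the style of interval printed by common biostatistics
software for cohorts of this size (n = 32).

## The synthetic generator: what it emulates, and what it does not

No imaging data ships with the package; `simulate_sequence()` builds
captures with exact ground truth instead. Colonies are star-convex blobs
(low-order harmonic radius modulation) on a near-uniform background,
filled with a colony-anchored texture that is evaluated *analytically* at
displaced coordinates, so brightness constancy holds exactly and
sub-pixel motion carries no interpolation error. Motion wraps toroidally;
coverage stays constant apart from an imposed growth ramp, mirroring the
near-flat growth of a compliant 4-h capture.

The texture has two bands, and the split is deliberate:

* a **fine band** — two orthogonal triangle waves (base wavelength
  `texture_scale = 5` px). Triangle waves have piecewise-constant slope,
  so the gradient magnitude inside a colony is bounded away from zero
  almost everywhere, emulating the dense granularity of phase-contrast
  cytoplasm. Pure sinusoid textures were evaluated and rejected: their
  broad gradient-magnitude distribution makes the *edge image*
  non-bimodal, and edge-based Chan–Vese then splits the texture rather
  than cell from background, at any parameter setting.
* a **coarse band** — random-phase sinusoids at 2.4–6.4× the base
  wavelength, giving the flow pyramid structure to track under large
  displacements.

Defaults describe the standard study condition: 256×256 px fields at 50%
confluency with 3 colonies, 0.5 μm/px, 8 min/frame, ±1 percentage point
growth per capture, Gaussian intensity noise σ = 0.01. All randomness
sits behind one seed; output is bit-reproducible.

What the generator does **not** emulate — hence what passing tests do not
show about real data: optical artifacts (halo, shade-off, vignetting,
debris), cell division and death, intra-colony deformation (colonies move
rigidly), colony collisions beyond simple overlap, and photon noise
statistics. Tests on generator data validate the *algorithmic* chain —
segmentation, flow, unit conversion, statistics — not robustness to every
optical property of a specific microscope.

`make_cohort()` layers a monotone decreasing speed→PDT link (default
`4 − v/30` days, spreading PDT over ≈2–3.5 days across 15–60 μm/h,
matching the scale on which real cohorts disperse) plus Gaussian noise
(σ = 0.15 d) on top of per-sample sequences, so pipeline-level rank
correlations can be compared against ground truth.

## Validation scales

The shipped tests and the acceptance script run entirely on generated
data at sizes chosen to exercise every code path at desk scale:
segmentation oracles at 256×256 across 30–90% confluency; flow oracles at
imposed shifts of 0.5–3 px plus a zero-motion control; end-to-end MMS
recovery on 10-frame 256×256 sequences at 15/30/45/60 μm/h; and a
32-sample cohort at 128×128 × 6 frames for the Spearman comparison.
Full-resolution 1920×1440 × 31-frame captures run through exactly the
same code, only slower (the original workflow used GPU acceleration for
this step; this package accepts CPU runtimes and offers `decimate`).

## Known limitations

* Chan–Vese is a two-phase piecewise-constant model: it measures covered
  area, not instances — no per-cell segmentation, counting or tracking.
* The flow statistic is a mean magnitude; directional structure
  (divergence, rotation, order parameters) is out of scope.
* Flow accuracy degrades within ~half a window (≈7 px) of colony
  boundaries, biasing MS slightly; at the default window this stays well
  inside the 15% envelope validated by the tests.
* The 40 μm/h threshold and the PD/PDT identification above inherit the
  caveats stated with them.

## File formats

Sequences: multi-page TIFF or a directory of numbered TIFF/PNG frames
(natural-sorted), normalised to [0, 1] grayscale on load. Masks: 0/255
single-channel PNG/TIFF. Flow fields: 2-page 32-bit float TIFF through a
fixed affine code `(d + 64)/128`, because TIFF float samples live on a
[0, 1] scale (round trip accurate to ~1e-5 px). Results: plain CSV, one
row per frame pair plus a summary row, written at full double precision
so a round trip reproduces the record exactly.
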