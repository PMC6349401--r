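---
title: "Object-based colocalization of cytoplasmic foci: methods and design"
author: "fociloc"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Object-based colocalization of cytoplasmic foci: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fociloc)
```

## Scope and model

`fociloc` answers one question per field of view: do the micron-scale foci
visible in two fluorescence channels of a confocal z-stack occupy the same
3D objects more often than chance placement would predict? The unit of
analysis is the *punctum* — a compact, locally bright 3D object — and the
statistic is a volume-based overlap fraction per punctum, judged against a
randomized-placement null computed in the same cell with the same punctum
shapes. The package also fits FRAP recovery traces, whose mobile fraction
is the standard readout for how dynamically a protein exchanges between a
focus and the surrounding cytoplasm.

Assumptions worth stating explicitly:

* one cell of interest per field, and it is the largest bright object in
  the segmentation channel;
* foci are bright relative to the local diffuse signal after median-filter
  background subtraction, and are roughly 1–3 µm across;
* the two channels are registered (no chromatic shift correction is
  attempted) and acquired with the same geometry;
* axial sampling is coarser than lateral sampling, so per-layer (2D)
  processing with 3D assembly at the end is the appropriate decomposition.

## Pipeline stages and their parameters

### Cell segmentation

Each z-layer of the segmentation channel (default green, configurable) is
thresholded with Otsu's method. The per-layer binary masks are summed into
a projection; disjoint islands of the projection are labeled with
**4-connectivity** (a deliberate, conservative choice — diagonal contact
does not join islands) and the island with the largest projected pixel sum
(a proxy of volume, not of footprint area) is taken as the cell. Layer
masks are then restricted to that island's footprint.

Otsu's threshold is computed by exhaustive maximization of the
between-class variance over a 256-bin histogram; for integer data whose
range fits the bin count, bins are the exact integer gray levels, so the
result is identical to a brute-force search over candidate thresholds (the
test suite checks this equivalence against an independently written
oracle). A layer whose pixels are all equal has no meaningful threshold
and yields an empty mask; similarly, a degenerate second-round (vacuole)
threshold removes nothing.

Per-layer clean-up applies morphological **closing then opening** with a
disc of radius `struct_radius` (default 3 px). A second round of Otsu
thresholding restricted to in-mask pixels then identifies intracellular
vacuoles and organelles with markedly lower fluorophore concentration.
Two robustness rules guard this step:

* *minority rule* — removal only fires when the below-threshold class is
  the minority of in-mask pixels. An in-mask histogram dominated by
  cytoplasm with a bright rim or bright foci would otherwise be split
  *above* the cytoplasm mode, and most of the cell would be deleted as
  "vacuole".
* *opening by reconstruction* — the below-threshold set is reduced to
  components containing a core at least as large as the structuring
  element, and those components are removed whole. Plain per-pixel removal
  would pepper the mask with noise holes, and every hole edge would later
  drag the edge-attenuation map to zero around it; plain opening would
  leave the eroded rim of each real vacuole inside the mask.

### Fluorescent foreground

Per layer and channel, the diffuse background is estimated by a median
filter of radius `median_radius` (default 15 px — larger than the largest
expected punctum radius, so foci survive subtraction) and subtracted; the
difference is clipped at zero. Out-of-mask pixels are filled with the
layer's in-mask median *before* filtering, so windows near the cell edge
are not contaminated by background zeros; this also makes the stage
exactly zero for a constant in-mask image and invariant under a constant
intensity offset. The median filter runs on a 16-bit quantized copy of the
layer (a constant-time algorithm); residues at or below the quantization
step are zeroed afterwards, as they are numerical noise that would
otherwise form large spurious connected regions of epsilon-level
"foreground".

The result is denoised by grayscale opening then closing with a disc of
radius `noise_radius`. The default is **2 px**: with radius 1 the
brightest 2–3 px of the cell rim survive subtraction as a thin connected
ring, and shot-noise speckles form filaments; watershed basins that touch
either structure balloon across the cell, which corrupts both the overlap
denominator and the feasibility of re-placing those shapes during
randomization. A 2 px radius erases structures up to ~4 px wide while
preserving foci of 1 µm (10 px at the default calibration) and above.

Bright cell edges are then attenuated: each in-mask pixel is multiplied by
`min(d / 40, 1)`, where `d` is its per-layer Euclidean distance from the
cell boundary, so the factor is 0 at the edge, 0.5 at 20 px and 1 from
40 px inward. Two conventions are fixed here. First, the distance is 2D
(per layer): with an axial step several times the pixel size, 3D pixel
distances would mix incommensurate units. Second, the *outermost in-mask
pixel* sits at `d = 0`: the distance transform assigns it distance 1 to
the nearest background pixel, so the package uses `distmap − 1`. This is
what makes the calibration constants exact — factor 0 at the edge pixel,
0.5 at a pixel 20 px inside, 1.0 at 40 px — as `scripts/acceptance.R`
recomputes.

### Puncta: detection, delineation, 3D assembly

Detection uses a scale-normalized, negated Laplacian-of-Gaussian filter at
`n_scales = 5` sigmas geometrically spaced over `sigma_min = 2` to
`sigma_max = 8` px, covering 1–3 µm foci at 0.05–0.15 µm/px. Local maxima
over the (y, x, scale) neighbourhood qualify as seeds if their response
exceeds `rel_threshold = 0.1` of the strongest response anywhere in the
cell (all layers, that channel); overlapping detections are resolved by
non-maximum suppression at the blob radius `sqrt(2)·sigma`, keeping the
stronger seed. A purely relative threshold cannot declare an image
"empty": in a field with no true foci the strongest noise responses are
detected. This is a known limitation, accepted to keep the detector free
of absolute intensity units.

The LoG marks *where* foci are but not their extent, so each seed becomes
a marker for a watershed-style flooding of the foreground landscape
(seeded region growing via `EBImage::propagate`), restricted to the
support `foreground > 0`. Basins are disjoint, contain only
positive-foreground pixels, and a lone seed claims its entire connected
support. Punctum intensity is the sum of foreground values over the basin.

2D basins are assembled into 3D puncta by the adjacency rule: basins in
layers z and z + 1 sharing at least one (y, x) pixel belong to the same
object, and the relation is closed transitively (connected components of
the adjacency graph) — a basin bridging two disjoint basins in the next
layer merges all three. Collation conserves voxels exactly; the suite
checks both properties against a brute-force graph search.

### Overlap metric and the randomization null

For each punctum, the overlapped volume is the count of its voxels lying
inside the union of the other channel's basins on the same layers, and the
overlap fraction divides by its total volume. Cell-level summaries report
the unweighted mean of per-punctum fractions (primary) and a
volume-weighted mean (secondary); no threshold declaring a punctum
"colocalized" is imposed.

The null model re-places each channel's puncta independently, one punctum
at a time in decreasing volume order (large shapes placed first keeps the
rejection rate low), at uniformly random integer (z, y, x) offsets. A
placement is rejected if any voxel leaves the mask or collides with an
already placed punctum *of the same channel* — cross-channel collisions
are precisely the signal being measured, so they are allowed. Offsets are
drawn uniformly over all in-image bounding-box positions and rejected
against the mask, which makes a single-voxel punctum's placement exactly
uniform over the mask (verified by a chi-square test in the suite). A
punctum that cannot be placed within `max_attempts = 1000` draws raises a
"placement limit reached" error naming it.

Ten replicates per cell (default) give the background overlap rate: the
per-replicate mean fraction per channel, its mean ± sd, and the number of
replicates reaching the observed mean (exceedance). With ten replicates
this count is a descriptive statistic, not a calibrated p-value, and it is
reported as such.

Derived seeds: replicate r of channel c uses a deterministic substream
seed computed from the global seed and the replicate index, so any single
replicate can be reproduced in isolation.

### FRAP

Double normalization divides the background-subtracted bleach ROI by the
background-subtracted reference ROI frame by frame — cancelling
acquisition photobleaching, which hits both alike — and rescales so the
pre-bleach mean is 1. The recovery model is a single exponential,
`F(t) = f0 + (f∞ − f0)(1 − exp(−(t − t_b)/τ))`, the standard
one-component model for this assay; the model name is recorded in every
result row so downstream interpretation is explicit. The bleach time
`t_b` is taken as the time of the first post-bleach frame. Initialization
is data-driven (`f0` from the first post-bleach value, `f∞` from the last
10% of frames, τ from the time to half-recovery), and fitting uses
Levenberg–Marquardt least squares. The mobile fraction
`100·(f∞ − f0)/(1 − f0)` is clamped to [0, 100] with a warning if the fit
exceeds bounds. A curve whose estimated recovery span is below 0.01 is
degenerate — τ is unidentifiable — and is reported directly from the
plateau estimates with `tau = NA` and model `flat_no_recovery`. Half-bleach
traces run through the same model; the mode flag only annotates output.
Groups are summarized as mean ± sd with N; sd rather than sem is reported,
with N alongside, so either can be derived.

## The synthetic-data generator

`generate_stack()` renders what the pipeline expects to meet: a single
bright, irregular cell (low-order Fourier modulation of a ~10 µm radius at
0.1 µm/px) spanning all 20 layers of a 256 × 256 stack, with a brighter
rim (×1.8 over 3 px), two dark ellipsoidal vacuoles, and eight puncta per
channel. Puncta are thresholded anisotropic Gaussians — the configured
diameter (1.2–2.8 µm, uniform) is the major axis, a random elongation up
to 1.6 shrinks the minor axis, orientation is uniform — placed in the
middle third of the axial range and toward the cell periphery, clear of
vacuoles and of each other. A fraction `coincident_fraction` of red puncta
copies a green punctum's exact position and shape (true overlap 1); the
rest are placed clear of the other channel (true overlap 0). Noise is
Poisson on the signal plus Gaussian read noise.

The cell spans every acquired layer by default because a confocal series
of a cell is acquired *inside* the cell: a layer containing no cell at all
would be pure detector noise, which a per-layer Otsu threshold necessarily
shreds into a meaningless mask. Scenes with empty outer layers are
therefore not part of the default conditions.

What the generator does **not** emulate: optics-accurate point-spread
functions (a Gaussian profile stands in), chromatic aberration and channel
misregistration, multiple cells per field, partial coincidence (planted
overlaps are 0 or 1; intermediate observed fractions arise from
segmentation differences), intensity heterogeneity within a punctum, and
time-lapse dynamics. Passing tests on these scenes therefore demonstrate
algorithmic correctness and calibration, not robustness to every
real-microscope artifact.

`generate_frap_trace()` samples a single-exponential recovery at 0.2 s
intervals for 300 frames (10 pre-bleach), with multiplicative per-frame
acquisition bleaching applied to bleach and reference ROIs alike, additive
constant background, and Gaussian noise; the bleach event coincides with
the first post-bleach sample, matching the fit's `t_b` convention.

## Numerical choices and degenerate inputs

* Coordinates are 0-based (z, y, x) in every exported table (each CSV
  carries a header comment saying so); internally R's 1-based `[y, x, z]`
  arrays are used.
* Calibration metadata travels in a JSON sidecar next to each TIFF (the
  reader also accepts JSON in an ImageDescription tag); physical units are
  carried as metadata but the algorithm operates in pixel units — the 20
  and 40 px attenuation distances are pixel quantities.
* Label masks are written as 16-bit TIFF with labels stored as k/65535,
  exact for up to 65535 objects.
* Otsu ties are broken toward the smallest maximizing threshold.
* Watershed seeds landing on zero foreground are dropped with a warning.
* All-empty layer masks produce a "no cell found" error; constant channels
  make the Pearson correlation undefined (`NA` with a warning).
* Randomization, generators and pipeline accept a single integer seed;
  every internal stream is derived deterministically from it.

## Benchmark problem sizes

The validation suite runs, per check: 100 random 8-bit layers against the
exhaustive Otsu oracle; 100 random punctum configurations against the
brute-force overlap oracle; 50 random scenes against the brute-force
collation oracle; 50 randomizations for the placement contracts plus a
200-replicate sparse-case comparison with the analytic uniform-placement
expectation; five full-size (256 × 256 × 20) scenes across coincident
fractions {0, 0.25, 0.5, 0.75, 1} for end-to-end recovery (≥ 90%
detection, ≤ 3 px centroid error, per-punctum overlap MAE ≤ 0.1 pooled
across the sweep, strictly monotone observed overlap in the coincident
fraction); and a 4 × 3 × 20 grid of FRAP simulations (mobile fraction
{20, 40, 60, 80}% × τ {1, 3, 10} s, 1–3% noise) with a ≤ 3 percentage
point median absolute error requirement.

## Known limitations

* Single-cell fields only; no multi-cell segmentation or tracking.
* The relative LoG threshold always reports the strongest structures in a
  field, even if none are real foci; pair the observed overlap with its
  randomized background before interpreting it.
* Ten randomization replicates bound the resolution of the exceedance
  count; raise `replicates` for finer nulls.
* The FRAP module consumes ROI-mean traces (CSV); it does not extract ROIs
  from movies, and it does not model reaction–diffusion kinetics or
  estimate diffusion coefficients.
* No support for proprietary microscope formats; convert to TIFF upstream.
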