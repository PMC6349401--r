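# fociloc

Object-based colocalization of cytoplasmic foci in two-channel confocal
z-stacks, with a randomized-placement null model, plus FRAP (fluorescence
recovery after photobleaching) mobile-fraction analysis.

## The problem

Many cytoplasmic proteins concentrate in micron-scale foci (puncta) —
phase-separated organelles, stress granules, assembly particles. Deciding
whether two fluorescently tagged proteins occupy the *same* foci is an
object-level question that pixel correlation alone answers poorly: diffuse
cytoplasmic signal, bright cell edges and chance juxtaposition all inflate
pixel-based readouts. `fociloc` implements a 3D object-based pipeline for a
single cell per field:

1. **Cell segmentation** — per-layer Otsu thresholding of the segmentation
   (green) channel; thresholded layers are summed into a projection, its
   4-connected islands scored by projected pixel sum, the largest island
   taken as the cell; per-layer masks are cleaned by morphological
   closing/opening, and a second, in-mask round of Otsu thresholding excises
   dark intracellular vacuoles.
2. **Fluorescent foreground** — per-layer median-filter background
   subtraction (clipped at zero, denoised by grayscale opening/closing),
   then linear attenuation of the bright cell edge: values at the edge are
   multiplied by 0, at 20 px from the edge by 0.5, and from 40 px inward
   by 1.
3. **Puncta** — multiscale Laplacian-of-Gaussian (LoG) detection provides
   seeds; a marker-seeded watershed on the foreground (restricted to its
   positive support) delineates each punctum's 2D body; basins overlapping
   in adjacent z-layers are collated into 3D puncta (connected components
   of the adjacency graph), with volume and summed intensity.
4. **Overlap metric** — for a punctum in one channel,
   `overlap = (voxels inside any punctum of the other channel) / (total voxels)`,
   accumulated across all z-layers: a volume-based overlap fraction in
   [0, 1]. A pixel-based Pearson correlation over in-cell voxels is also
   reported.
5. **Randomization null** — each channel's puncta are independently
   re-placed, one at a time, at uniformly random integer (z, y, x) offsets
   (rigid translations), rejecting placements that leave the cell mask or
   collide within the channel; ten such synthetic replicates per cell give
   the background overlap rate against which the observed overlap is judged
   (reported with an empirical exceedance count).

The FRAP module applies double normalization
`F(t) = [(B−bg)/(R−bg)] · [⟨R−bg⟩_pre / ⟨B−bg⟩_pre]` (bleach ROI B,
reference ROI R, background bg; pre-bleach mean scaled to 1), fits a
single-exponential recovery `F(t) = f0 + (f∞ − f0)(1 − e^{−(t−t_b)/τ})`
over the post-bleach frames, and reports the mobile fraction
`100·(f∞ − f0)/(1 − f0)` percent with group mean ± sd and N.

A synthetic-data generator renders two-channel stacks with known ground
truth — one bright irregular cell with dark vacuoles and a brighter rim,
1–3 µm anisotropic puncta with a controllable coincident fraction, Poisson
shot noise plus Gaussian read noise — and FRAP traces with known mobile
fraction, time constant and acquisition bleaching, so the whole pipeline is
testable end to end without any data download.

## Worked example

```r
library(fociloc)

sim <- generate_stack(scene_params(coincident_fraction = 0.5), seed = 1)
res <- coloc_pipeline(sim$stack, seed = 1)
print(res$summary, digits = 3)
#>           cell_id channel n_puncta observed_mean observed_mean_volume_weighted
#> 1 synthetic_seed1   green        8         0.397                         0.554
#> 2 synthetic_seed1     red        8         0.458                         0.635
#>   randomized_mean randomized_sd exceedance n_replicates seed
#> 1          0.0184        0.0285          0           10    1
#> 2          0.0133        0.0163          0           10    1
```

Half of the planted red puncta coincide with green puncta, so the mean
observed overlap fraction per channel is ≈ 0.4–0.46 (coincident puncta
score ≈ 0.9, independent ones 0), while random re-placement of the same
puncta inside the same cell yields only ≈ 0.02 ± 0.02; no randomized
replicate reaches the observed mean (exceedance 0). The pixel-based
Pearson correlation in the same cell is 0.766.

```r
fit <- fit_recovery(correct_and_normalize(
  generate_frap_trace(mobile_fraction = 60, tau = 3, seed = 1)$trace))
print(fit)
#> frap_result (full_bleach, single_exponential): mobile fraction 60.4% |
#>   tau 3.02 s (t1/2 2.09 s) | f0 0.303 -> plateau 0.724
```

A simulated trace with a true mobile fraction of 60% and τ = 3 s is
recovered as 60.4% and τ = 3.02 s after bleach correction.

## Command line

```sh
Rscript inst/cli/fociloc.R simulate --kind stack --out data --seed 1
Rscript inst/cli/fociloc.R coloc --in data --out results --seed 1 --replicates 10
Rscript inst/cli/fociloc.R frap --in traces/ --out frap_results
```

`coloc` writes per-punctum, per-overlap, per-replicate and per-cell CSV
tables (coordinates 0-based, (z, y, x)), 16-bit label-mask TIFFs and a JSON
manifest (all parameters, seed, package version, input hashes) that makes
every run reproducible.

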