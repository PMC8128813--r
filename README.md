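# cthabitat

CT radiomic tumour habitat mapping with CT/ultrasound fusion accuracy,
for precision tissue sampling in metastatic ovarian cancer and similar
settings where biopsies should target radiomically distinct tumour
subregions rather than arbitrary locations.

## What it does

Given a contrast-enhanced CT volume and a tumour volume of interest
(VOI), `cthabitat`:

1. restricts omental VOIs to solid tissue (fat at HU ≤ −30 is removed,
   followed by a 3×3×1 morphological opening and small-component
   removal);
2. computes per-voxel sliding-window texture maps: a symmetric grey-level
   co-occurrence matrix (5×5-voxel in-plane window, 32 grey levels, four
   in-plane directions) yielding nine Haralick features per voxel —
   energy, entropy, sum average, correlation, inverse difference moment
   normalised, contrast, cluster shade, cluster prominence, Haralick
   correlation;
3. reduces the standardised features by PCA, retaining the smallest
   number of components (≤ 6) explaining ≥ 90% of the variance;
4. clusters (PC scores, standardised HU) per voxel with a full-covariance
   Gaussian mixture fitted by seeded EM for k = 1…3 and selects the
   habitat count by minimum AIC, `AIC = 2q − 2 ln L̂` with
   `q = (k−1) + kd + kd(d+1)/2`, `d = m+1`; habitats smaller than 3 cm³
   are dissolved into the remaining components;
5. exports habitat maps as DICOM segmentation objects (plus NIfTI);
6. registers CT to an axially acquired ultrasound frame with 1–3 paired
   fiducials (translation → z-rotation → full Procrustes hierarchy),
   reslices the CT tumour silhouette into the US plane, and scores fusion
   accuracy with the Dice similarity coefficient
   `DSC = 2|A∩B| / (|A|+|B|)` on the largest-tumour-area slice.

A seeded phantom generator (`make_phantom()`, `make_us_frame()`) produces
CT-like ellipsoidal lesions with ground-truth habitats — distinct in mean
HU, noise amplitude and noise correlation length — and simulated US
frames under a known rigid transform, so the whole pipeline is testable
without any imaging data.

## Worked example

```r
library(cthabitat)

ph <- make_phantom(phantom_spec(true_k = 3, seed = 7))
stack <- texture_map_stack(ph$volume, ph$mask)
pca   <- fit_pca(stack)
pc    <- project_pca(stack, pca)
model <- fit_habitats(pc, stack$hu, pipeline_config(seed = 7))
print(model)
#> <habitat_model> k = 3 (AIC by k: 61422.0, 33920.1, 27417.0)

vm <- array(FALSE, stack$dim); vm[stack$idx] <- TRUE
map <- enforce_min_volume(
  label_habitats(model, pc, stack$hu, voi_mask(vm), ph$volume$spacing),
  model, 3)
print(map)
#> <habitat_map> k = 3 habitats over 72 x 72 x 14 grid
#>   habitat 1: 19.18 cm^3
#>   habitat 2: 28.09 cm^3
#>   habitat 3: 10.20 cm^3

us <- make_us_frame(ph, jitter_mm = 0)
tf <- fit_rigid(us$landmarks)
dice(reslice_mask(ph$mask, ph$volume, us$frame, tf), us$truth_mask)
#> [1] 1
```

The AIC curve decreases to its minimum at the selected k; the three
habitat volumes partition the ≈57 cm³ lesion and each exceeds the 3 cm³
targetability threshold; with noise-free landmarks the fusion loop closes
exactly (DSC 1.0). With jittered landmarks the DSC falls below 1 and
decreases, on average, with the jitter level.

The per-patient table of the six-patient development cohort ships with
the package:

```r
s <- summarize_values(study_patients()$dsc)
#> median 0.53, range 0.37–0.79 over the five defined values
```

A command-line front end is installed at
`system.file("cli", "habitat.R", package = "cthabitat")` with subcommands
`phantom`, `prep`, `textures`, `pca`, `cluster`, `fuse`, `report`, `run`,
and `run_pipeline()` performs the one-shot run with a JSON manifest of
configuration, stage list and output content hashes.

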