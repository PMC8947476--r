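# petseg

Semi-automatic tumor volume delineation for FDG-PET images in R.

PET is increasingly used to define the target volume for radiation-therapy
planning, but how to delineate a lesion on a noisy, low-resolution PET
image is an open question. `petseg` implements two families of
semi-automatic segmentation:

* the widely used **adaptive threshold** reference: keep the 26-connected
  component of voxels with intensity ≥ 40% of the lesion maximum (the
  lesion maximum is found by a fixed-point iteration from the seed, so no
  bounding box needs to be drawn);
* **texture-criterion region growing**: starting from a 27-voxel cube
  around a user-selected seed, the region grows by one-voxel steps in the
  six axis directions; a growth step is accepted only while a textural
  statistic of the grown region stays on the lesion side of a threshold.

The three supported stop statistics are

* kurtosis `KU = (1/N) Σ ((x_i − x̄)/σ)⁴` of the raw intensities (population
  σ, non-excess convention),
* local entropy `LE = −Σ_ij M1_ij log₂ M1_ij` of the 3D gray-level
  co-occurrence matrix `M1` (13 unique unit directions, symmetrized),
* long-zone emphasis `LZE = Σ_ij M4_ij j² / Σ_ij M4_ij` of the gray-level
  size-zone matrix `M4` (26-connected zones),

computed on the whole candidate region after every growth step. Thresholds
are scanner- and protocol-dependent; `calibrate_threshold()` derives them
from example tissue regions (midpoint rule) and `calibrate_boundary()` from
phantom ground truth.

Because no patient data can be shipped, the package includes a synthetic
**moving-sphere phantom** (3 / 12 / 26 ccm spheres at 1.2 MBq/ccm on a
128 × 128 grid with 5 mm slices, 5 mm Gaussian post-filter, sinusoidal
15 mm cranio-caudal motion at 12 cycles/min, signal-dependent noise) and
the **repeated-measurement statistics** used to compare methods: mean,
range, absolute and relative standard deviation over consecutive
segmentations, relative difference to the true volume, and the signed
difference between motion-uncorrected and corrected volumes.

## Worked example

```r
library(petseg)

ps  <- phantom_spec(seed = 1)          # default three-sphere phantom
img <- simulate_static(ps)             # one noisy acquisition
sv  <- sphere_center_voxel(ps, 3)      # seed at the 26 ccm sphere center

# reference method
m40 <- threshold_segment(img, sv)
mask_volume_ccm(m40, img$spacing)
#> [1] 23.68
max_diameter_mm(m40, img$spacing)
#> [1] 35.4542

# texture criterion: calibrate at the known object boundary, then grow
fs  <- feature_spec("long_zone_emphasis", n_levels = 64, binning = "per-region")
cal <- calibrate_boundary(img, truth_mask(ps, 3), fs)
res <- texture_region_grow(img, sv, cal$spec)
res
#> <region_grow_result> long_zone_emphasis: 83.36 ccm, max diameter 70.9 mm
#>   7 iterations, 1042 voxels
head(res$trace, 3)
#>   iteration direction  feature accepted volume_ccm
#> 1         1        +x 1.612903     TRUE       2.88
#> 2         1        -x 1.500000     TRUE       2.88
#> 3         1        +y 1.666667     TRUE       2.88

# consecutive-measurement stability study (20 repeats, jittered seeds)
st <- stability_experiment(ps, repeats = 20)
st[st$method == "threshold", c("sphere_ccm", "mean_ccm", "diff_pct", "rel_sd_pct")]
#>   sphere_ccm mean_ccm diff_pct rel_sd_pct
#> 1          3    3.016      0.5  3.3441467
#> 2         12   11.900      0.8  3.2268539
#> 3         26   24.272      6.6  0.9468488
```

The threshold method recovers the spheres within a few percent with
relative SDs of 1–3%; the texture criteria systematically overgrow on this
homogeneous cold-background phantom and are much more variable — the
expected qualitative behaviour of whole-region texture criteria, discussed
in the methods vignette (`vignettes/petseg-methods.Rmd`), which also
documents every model parameter, the calibration design, and the known
limitations.

A thin command-line front end is provided in `inst/scripts/petseg`
(`phantom`, `segment`, `evaluate stability`, `evaluate diff` subcommands)
for use outside R.

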