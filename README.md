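# musclequant

Quantitative muscle MRI metrics from Dixon and STIR imaging, for
studying fatty replacement and inflammation in muscular dystrophies
such as facioscapulohumeral muscular dystrophy (FSHD).

Muscle-by-muscle MRI biomarkers — volume, fat fraction, the spatial
distribution of fat along each muscle, and STIR-hyperintense (free
water / inflammation) content — are the standard quantitative readout
for tracking these diseases and evaluating therapies. Segmenting the
muscles is nowadays done upstream by AI models or human raters; this
package implements everything *downstream* of a label map: given
co-registered Dixon water/fat volumes, an integer-coded muscle label
map, and optionally a STIR volume, it computes the per-muscle metrics,
the reliability statistics used to validate them, and ships a synthetic
limb phantom generator with analytic ground truth so the whole pipeline
is testable without any patient data.

## The model

For each voxel *p* of a muscle with fat signal FSI and water signal
WSI, the fat fraction is the signal ratio, and the muscle-level FF is
its mean over the muscle's TP voxels with nonzero signal:

    FF_muscle = (1/TP) * sum_p FSI_p / (FSI_p + WSI_p) * 100   [%]

Boundary volume is the labelled voxel count times the voxel volume;
fat and lean volume split it:

    FatVolume  = BoundaryVolume * FF/100
    LeanVolume = BoundaryVolume * (1 - FF/100)

The same decomposition applied per axial slice gives boundary, lean
and fat cross-sectional areas and an area FF, which are normalized to
percent of muscle length (0% = inferior end, 100% = superior end) and
linearly interpolated at 1% steps. STIR content (%) is the fraction of
a muscle's voxels labelled STIR-positive by limb-local Otsu
thresholding after rigidly registering the Dixon frame to the STIR
frame. Agreement statistics include Dice/Jaccard overlap
(Dice = 2|A∩B|/(|A|+|B|), Jaccard = |A∩B|/|A∪B|), absolute volume
error 100|a−b|/((a+b)/2), Bland–Altman bias tests, and Spearman
correlation against ordinal clinical ratings (fat 1–6, STIR 0–4).

## Worked example

```r
library(musclequant)

## a small synthetic limb: two muscles, one homogeneous (20% FF), one
## with a distal-to-proximal fatty gradient (70% -> 10%)
ds <- generate_phantom(phantom_spec_minimal())
comp <- composition_table(ds$water, ds$fat, ds$labelmap)
comp[, c("name", "tp", "boundary_volume_mm3", "fat_fraction_pct",
         "fat_volume_mm3", "lean_volume_mm3")]
#>                name  tp boundary_volume_mm3 fat_fraction_pct fat_volume_mm3 lean_volume_mm3
#> 1 tibialis anterior 840              5670.0               20         1134.0          4536.0
#> 2            soleus 878              5926.5               40         2370.6          3555.9

prof <- trim_profile(normalize_profile(
  slice_metrics(ds$water, ds$fat, ds$labelmap, 2L)))
range(prof$area_ff_pct)    # fatty distally, spared proximally
#> [1] 10.4081 69.5919
```

The first muscle's FF is exactly its programmed 20%: the phantom's
noiseless water/fat channels satisfy the Dixon signal model, so the
ratio computation recovers the ground-truth field to machine
precision. The soleus row shows how a 40% mean FF muscle decomposes
into fat and lean volume; its trimmed length profile spans ~12–68%
area FF, the programmed distal-to-proximal gradient. With
`phantom_spec_stir()` the same phantom family adds a STIR acquisition
with a known rigid offset and programmed STIR+ volume fractions
(0/10/30/72%), and

```r
ds  <- generate_phantom(phantom_spec_stir())
tf  <- register_rigid(ds$water, ds$stir)           # recover the offset
lab <- resample_labels(ds$labelmap, tf, ds$stir, method = "vote")
ct  <- stir_content(segment_stir(ds$stir, limb_mask(ds$stir)), lab)
```

recovers each muscle's STIR content within a fraction of a percentage
point (the heavily affected muscle reads ~71–72%).

## Command line

A thin CLI over the same functions is installed at `exec/musclequant`
with subcommands `quantify`, `profile`, `erode`, `stir`, `reliability`,
`phantom`, `run` (full single-subject pipeline from a YAML config) and
`longitudinal`. Exit codes: 0 success, 2 validation error,
3 computation error.

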