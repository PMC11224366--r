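---
title: "Quantifying muscle composition and STIR hyperintensity: models and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying muscle composition and STIR hyperintensity: models and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(musclequant)
```

# Scope

`musclequant` quantifies segmented muscle MRI. Its inputs are the
products of an upstream segmentation step — co-registered Dixon water
and fat volumes, an integer-coded muscle label map, optionally a STIR
volume — and its outputs are per-muscle composition metrics, length
profiles, STIR content, and agreement statistics. Nothing in the
package trains or runs a segmentation model; label maps may come from
a network, a human rater, or the built-in phantom generator's ground
truth.

# Composition model

Two-point Dixon imaging yields, per voxel, a fat signal FSI and a
water signal WSI. The voxel fat fraction is
FF = FSI/(FSI + WSI) × 100, and a muscle's fat fraction is the *mean
of the voxelwise ratios* over its labelled voxels, not the ratio of
summed signals. The two differ in the presence of intensity
inhomogeneity; the voxel-mean form is the one used in quantitative
muscle MRI studies and is what `muscle_composition()` implements.

Voxels where FSI + WSI = 0 carry no compositional information. They
are excluded from the FF average (and counted separately) but kept in
the boundary volume, which is defined purely by the segmentation:
`boundary = (tp + excluded) × voxel volume`. Fat and lean volumes are
`boundary × FF/100` and `boundary × (1 − FF/100)`, so the closure
`fat + lean = boundary` holds by construction — the tests assert it to
1e−9 relative on every run. Setting `on_zero_signal = "error"` turns
an all-zero-signal muscle into an error instead of an `NA` row.

FF histograms use 1%-wide bins over [0, 100] by default (the last bin
closed); any width dividing 100 is accepted.

# Length profiles

Disease progression in FSHD is spatially heterogeneous within single
muscles, so muscle-level means hide information. `slice_metrics()`
decomposes each axial slice into boundary/lean/fat CSA and an area FF
(the FF mean restricted to the slice), and `normalize_profile()` maps
the occupied slices onto a 0–100% axis (0% at the inferior-most
occupied slice) with linear interpolation at 1% steps.

Design choices:

* **Linear interpolation.** Linearity preserves the per-slice closure
  `lean + fat = boundary` at every interpolated point; splines would
  not.
* **Physical positions.** Percent positions derive from slice
  positions in mm, not slice indices, so anisotropic or gapped stacks
  normalize correctly (for uniform spacing the two are identical).
* **Presence threshold.** A slice "contains" the muscle if it has at
  least one labelled voxel; no minimum-area filter is applied by
  default. End-slice noise is instead handled the way analyses of
  length profiles usually do, by trimming to the central 10–90% for
  visualization and end-insensitive summaries (`trim_profile()`, which
  keeps the untrimmed profile alongside).
* The ±5% (CSA) and ±2.5 point (FF) shaded bands in `plot()` are
  rendering aids reflecting typical repeat variability, not computed
  statistics.

# Label erosion

Chemical shift slightly displaces fat relative to water, which can
contaminate boundary voxels. `erode_labels()` erodes each label
slice-by-slice (never across slices) with a disc whose pixel radius is
`round(radius_mm / in-plane spacing)`; pixel-centre distance ≤ radius,
inclusive at the exact radius, so the footprint is deterministic. The
`one_layer` mode (radius-1 disc, the 4-connected cross) removes the
outermost pixel ring, as used after registration in the STIR pathway.
`erosion_sensitivity()` pairs each muscle's longitudinal FF change
computed from raw and eroded labels; on phantoms without rim
contamination the two agree, and their Spearman correlation is the
quantity a chemical-shift robustness check reads out. Radial mode
requires isotropic in-plane spacing, since the rounded pixel radius is
otherwise ill-defined.

# STIR pathway

STIR hyperintensity marks free water (inflammation). Quantification
needs four stages, each with explicit design decisions:

1. **Limb masking.** Per-slice Otsu on log intensity (log keeps
   air-vs-tissue the dominant bimodality even with very bright
   lesions), hole filling, retention of large connected components.
2. **Local thresholding.** The interactive workflow this emulates
   paints with an Otsu-driven tool on circular regions of up to 20% of
   the limb. Deterministically, windows of diameter 0.2 × the limb's
   equivalent diameter tile each slice with 50% overlap; a voxel is a
   candidate if any covering window marks it. Within a window the Otsu
   split is refined to the midpoint of the two class medians: for
   well-separated classes the raw argmax sits at the low edge of its
   plateau and would mark every partial-volume boundary voxel, while
   the median midpoint implements a ~50% occupancy rule. Pixels within
   `edge_margin_px` of the limb boundary are excluded (smooth edge
   artifacts).
3. **Degenerate guard and consolidation.** A window whose threshold
   does not exceed a brightness floor yields no detections. The floor
   is a Tukey fence (q75 + 1.5 IQR) over the limb interior of the
   *whole volume*: hyperintensity is treated as a brightness outlier
   against the pooled normal-tissue distribution. Per-slice floors
   fail in both directions — robust scale estimates collapse on
   homogeneous slices and are dragged upward on slices where lesions
   are a large area fraction — whereas even extensive lesions are a
   small fraction of the limb volume. A final consolidation pass
   removes candidates dimmer than the midpoint between the pooled
   normal-tissue and detected-lesion medians, which strips
   partial-volume rims at lesion margins. An optional veto removes
   candidates whose Dixon FF exceeds 50%, encoding the manual
   fat-vs-STIR check against the Dixon images.
4. **Registration and content.** Dixon water is registered to STIR
   rigidly (6 DOF): centre-of-mass initialization, matched Gaussian
   pre-smoothing of both volumes (0.6 voxel SD), a block-mean pyramid
   (4×, 2×, 1×), a coarse grid search over angles and axial offset,
   then Nelder–Mead refinement with restarts. The default similarity
   is the correlation ratio — Dixon water and STIR intensities are
   functionally related tissue by tissue, which correlation ratio
   exploits and which makes it smoother here than mutual information
   (also available, as is MSE for same-modality problems). Sampling is
   a deterministic stride over foreground voxels, half of the budget
   taken from the strongest axial-gradient voxels because axial
   structure is sparse relative to in-plane edges. Labels are then
   resampled onto the STIR grid (nearest-neighbour, or majority-vote
   sub-voxel sampling which suppresses half-voxel aliasing of the
   first/last occupied slices and is used by the pipeline), eroded one
   layer to absorb residual registration error, and STIR content is
   the percentage of each muscle's voxels inside the STIR+ mask.

Matched pre-smoothing deserves a note: intensity metrics computed by
interpolating one voxelized image against another are attracted to
poses where interpolation blur vanishes (grid-aligned offsets), an
artifact on the order of a quarter voxel. Smoothing both volumes
identically and rendering synthetic data with partial volume (below)
makes the attraction negligible relative to the information content.

# Ordinal rating scales

Volumetric FF maps to the 1–6 clinical fat rating through a monotone
step function anchored at the published 30% and 60% boundaries (rating
4 spans 30–60% inclusive). The sub-30% boundaries (5% and 15%) and
the 5/6 boundary (85%) have no published anchors; they are package
defaults, configurable in `fat_rating_from_ff()`. STIR content maps
to the modified 0–4 grade as 0 (no content), 2 (< 30%), 3 (30–60%),
4 (> 60%); grade 1 ("mild diffuse elevation") is categorical rather
than a content band and is assigned only from a mild-elevation flag.
A phantom programmed with a 15% whole-muscle intensity lift and no
discrete lesions is expected to score near 0% content while grading 1,
reproducing the known mismatch between the categorical and
quantitative readouts.

# Statistics

* `bland_altman()`: differences (b − a) against means; fixed bias by
  one-sample t (df = n − 1), proportional bias by the least-squares
  slope of difference on mean (df = n − 2). Both tests are always
  reported because published repeatability analyses describe
  proportional bias while printing one-sample degrees of freedom;
  limits of agreement are bias ± 1.96 SD. Zero-variance differences
  are flagged degenerate instead of producing a t.
* `spearman_cor()`: average-rank rho; exact two-sided permutation p by
  full enumeration for n ≤ 9, t approximation otherwise. The exact
  branch is cross-checked in the tests against an independent
  enumeration oracle.
* `overlap()`: both Dice and Jaccard are always reported. Overlap
  studies in this field sometimes print the intersection-over-union
  form under the name "Dice"; reporting both keeps results comparable
  with either convention, and the identity dice = 2j/(1 + j) is
  asserted in the tests.
* No multiple-testing correction is applied by default (matching
  common practice in the validation studies this supports); a Holm
  option exists in downstream summaries.

# The phantom generator

`generate_phantom()` rasterizes a continuous limb model: a cylindrical
limb with a subcutaneous fat shell, elliptical muscle tubes with
closed-form tapers (`none`, `cone`, spindle-shaped `cosine`), optional
bones (low-signal cortical ring around fatty marrow), and per-muscle
FF fields following the five canonical spatial patterns (homogeneous,
high-distal, high-proximal, high-ends, high-center) as logistic or
Gaussian functions of normalized length. Noiseless channels satisfy
water = S0(1 − FF/100), fat = S0·FF/100 exactly, so the composition
pipeline recovers the truth field to machine precision — the
generative-closure property the acceptance tests assert.

Deliberate modelling choices:

* **Noise** is additive Gaussian per channel with SD a fraction of S0
  (default 2% in the noisy fixtures), clipped at zero — the standard
  thermal-noise approximation at phantom SNR; a Rician model would
  differ only near zero signal.
* **Partial volume.** `supersample` renders each voxel as the average
  of a sub-voxel grid, emulating the scanner's point-spread function.
  Point sampling (the default for the fast fixtures) keeps closed-form
  oracles exact; the registration fixture uses 3×3×3 supersampling
  because aliased boundaries are exactly what makes intensity-based
  registration of piecewise-constant images artifact-prone.
* **STIR model.** Fat-suppressed: subcutaneous fat and marrow are
  dark, muscle intensity decreases mildly with FF, lesions are bright,
  and STIR+ (edematous) tissue also carries a mild water-signal boost
  in the Dixon channel — inflamed muscle is water-rich, and this
  cross-modality landmark is what makes axial registration of a limb
  well-posed, as bones and fascia do in real scans.
* **Truth conventions.** Truth labels and the truth STIR+ mask on the
  STIR grid use majority volume occupancy, the binarization an ideal
  mid-intensity thresholder implies; the truth STIR+ fraction is
  defined on the STIR grid because that is where content is measured
  (a Dixon-frame count of the same lesion differs by the relative
  half-slice quantization of the two grids, which at 3 mm slices is
  larger than the recovery error itself). Muscle ends in the STIR
  fixture sit midway between slice centres so the label voxelization
  is exact rather than maximally ambiguous.
* **Cohort severity** (`phantom_spec_cohort_subject()`) sweeps mean FF
  ~3–90% and STIR+ fractions 0–75% deterministically across subjects
  so that every rating bin is populated; its STIR protocol renders
  normal muscle isointense with background tissue (base intensity
  100), so only genuine lesions are brightness outliers.
* **Scan–rescan.** With ground-truth labels reused verbatim, volume
  error between rescans is identically zero and a repeatability test
  is vacuous. `label_jitter_p` drops a random subset of boundary-layer
  label voxels per realization, emulating segmentation variability;
  rescan simulations enable it (0.3), producing sub-percent volume
  errors and Dice ≈ 0.95 for large muscles.
* **Follow-up.** `make_followup()` adds FF preferentially where the
  within-muscle axial FF gradient is large (weight |∂FF/∂z|^2,
  renormalized to the programmed per-muscle mean increase; uniform
  fallback for homogeneous muscles), reflecting the observation that
  progression concentrates in transition zones between high and low
  FF. Gradients are computed within the muscle only — one-sided at the
  ends — because the field jump at the muscle boundary is not disease
  signal. FF is clipped at 100 with the clipped mass reported.

Problem sizes in the shipped fixtures (36³–64³ voxel grids, 2–5
muscles, 30-subject cohorts) are chosen so the full suite exercises
every pathway in a few minutes on one core; they are phantoms, not
anatomy. What passing tests show is that the *computational* pipeline
is exact and stable under the modelled conditions: clean labels,
piecewise-smooth signal, rigid misalignment, Gaussian noise. They do
not certify behaviour under bias fields, motion, chemical-shift
displacement, through-plane curvature of muscles, or segmentation
errors beyond boundary jitter — real-data properties the phantom
deliberately does not model.

# Numerical notes and limitations

* Spacing mismatches up to 1e−4 mm between label and image headers are
  absorbed; larger ones are alignment errors.
* All internal units are mm/mm²/mm³; percent for FF and STIR content.
* The registration optimizer is local after a coarse grid
  initialization (±6° about each axis, ±5 mm axially); initial offsets
  far outside that envelope need an explicit `init` transform.
* STIR content of thin lesions is quantized by slice thickness: a
  lesion spanning k slices carries a ±(1/k-ish) relative uncertainty
  no algorithm can remove. Likewise content depends on where labels
  end along the muscle; half-voxel conventions matter at clinical
  slice thickness, which is why the vote-based label resampling
  exists.
* `run_subject()` writes a resolved-config snapshot and a hashed
  manifest before/after computation; reruns with identical config and
  seed reproduce identical hashes for all computed artifacts.
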