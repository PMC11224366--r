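## Packaged phantom specifications: a minimal two-muscle phantom for
## fast tests, a five-pattern showcase, a STIR arm with a known rigid
## offset, a high-resolution pair of large muscles for fat-fraction
## recovery studies, and a parameterized cohort subject.

#' Packaged phantom specifications
#'
#' `phantom_spec_minimal()`: two spindle-shaped muscles (homogeneous 20%
#' and a distal-to-proximal gradient) in a small limb; generates in well
#' under a second and backs most unit tests.
#'
#' `phantom_spec_five_pattern()`: five muscles, one per canonical FF
#' distribution pattern.
#'
#' `phantom_spec_stir()`: four near-cylindrical muscles with programmed
#' STIR+ fractions (default 0, 10, 30, 72% of muscle volume) and a STIR
#' acquisition on its own grid related to the Dixon frame by a known
#' rigid transform.
#'
#' `phantom_spec_ff_recovery()`: two muscles of >= 10,000 voxels each at
#' finer resolution, for noise-recovery studies.
#'
#' `phantom_spec_cohort_subject(subject, seed)`: one synthetic subject
#' of a reproducible cohort; disease severity (mean FF level, pattern,
#' STIR+ fraction) varies deterministically across subjects so that
#' cohort-level ordinal ratings span the full scales.
#'
#' @param seed RNG seed stored in the spec.
#' @param noise_sd_frac channel noise SD as a fraction of S0.
#' @param label_jitter_p boundary label dropout probability.
#' @return a [phantom_spec].
#' @name phantom_fixtures
NULL

#' @rdname phantom_fixtures
#' @export
phantom_spec_minimal <- function(seed = 1L, noise_sd_frac = 0,
                                 label_jitter_p = 0) {
  ctr <- 26
  muscles <- data.frame(
    code = c(1L, 2L),
    name = c("tibialis anterior", "soleus"),
    side = c("left", "left"),
    cx_mm = ctr + c(-9, 9), cy_mm = c(ctr, ctr),
    a_mm = c(7, 7.5), b_mm = c(6.5, 7),
    z0_mm = c(9, 12), z1_mm = c(72, 69),
    taper = "cosine", taper_floor = 0.35, curve_amp_mm = 0)
  patterns <- list(
    "1" = list(type = "homogeneous", ff_hi = 20, ff_lo = 20),
    "2" = list(type = "high_distal", ff_hi = 70, ff_lo = 10,
               center = 0.5, width = 0.08))
  phantom_spec(shape = c(36, 36, 28), spacing = c(1.5, 1.5, 3),
               limb_center_mm = c(ctr, ctr), limb_radius_mm = 24,
               subcut_thickness_mm = 3.5, muscles = muscles,
               patterns = patterns, noise_sd_frac = noise_sd_frac,
               label_jitter_p = label_jitter_p, seed = seed)
}

#' @rdname phantom_fixtures
#' @export
phantom_spec_five_pattern <- function(seed = 1L, noise_sd_frac = 0) {
  ctr <- 36
  ang <- seq(0, 2 * pi, length.out = 6)[1:5]
  rad <- 19
  muscles <- data.frame(
    code = 1:5,
    name = c("homogeneous", "high distal", "high proximal",
             "high ends", "high center"),
    side = "left",
    cx_mm = ctr + rad * cos(ang), cy_mm = ctr + rad * sin(ang),
    a_mm = 7.5, b_mm = 7, z0_mm = 10, z1_mm = 110,
    taper = "cosine", taper_floor = 0.35, curve_amp_mm = 0)
  patterns <- list(
    "1" = list(type = "homogeneous", ff_hi = 35, ff_lo = 35),
    "2" = list(type = "high_distal", ff_hi = 70, ff_lo = 10,
               center = 0.5, width = 0.08),
    "3" = list(type = "high_proximal", ff_hi = 70, ff_lo = 10,
               center = 0.5, width = 0.08),
    "4" = list(type = "high_ends", ff_hi = 65, ff_lo = 15,
               center = 0.5, width = 0.18),
    "5" = list(type = "high_center", ff_hi = 65, ff_lo = 15,
               center = 0.5, width = 0.18))
  phantom_spec(shape = c(48, 48, 40), spacing = c(1.5, 1.5, 3),
               limb_center_mm = c(ctr, ctr), limb_radius_mm = 34,
               subcut_thickness_mm = 4, muscles = muscles,
               patterns = patterns, noise_sd_frac = noise_sd_frac,
               seed = seed)
}

#' @rdname phantom_fixtures
#' @param fractions programmed STIR+ volume fractions for the four
#'   muscles (0-1 scale).
#' @param angles_deg,translation_mm the known Dixon-to-STIR rigid offset.
#' @param stir_noise_sd absolute STIR noise SD.
#' @export
phantom_spec_stir <- function(seed = 1L, noise_sd_frac = 0.02,
                              fractions = c(0, 0.10, 0.30, 0.72),
                              angles_deg = c(0, 0, 3),
                              translation_mm = c(4, 2, -2.2),
                              stir_noise_sd = 8) {
  ctr <- 34
  muscles <- data.frame(
    code = 1:4,
    name = c("adductor magnus", "semimembranosus", "gracilis",
             "tibialis anterior"),
    side = "left",
    cx_mm = ctr + c(-15, 15, -15, 15), cy_mm = ctr + c(-14, -14, 14, 14),
    a_mm = 8.5, b_mm = 8,
    z0_mm = c(13.5, 22.5, 16.5, 28.5), z1_mm = c(133.5, 127.5, 139.5, 121.5),
    taper = "none", taper_floor = 0.65, curve_amp_mm = 0)
  patterns <- list(
    "1" = list(type = "high_proximal", ff_hi = 30, ff_lo = 20,
               center = 0.5, width = 0.2),
    "2" = list(type = "high_distal", ff_hi = 42, ff_lo = 28,
               center = 0.5, width = 0.2),
    "3" = list(type = "high_distal", ff_hi = 55, ff_lo = 28,
               center = 0.5, width = 0.1),
    "4" = list(type = "high_proximal", ff_hi = 52, ff_lo = 38,
               center = 0.5, width = 0.2))
  bones <- data.frame(cx_mm = c(ctr, ctr), cy_mm = c(ctr, ctr - 13.5),
                      radius_mm = c(5.5, 3), marrow_frac = 0.55)
  stir <- list(
    shape = c(60, 60, 52), spacing = c(1.6, 1.6, 3),
    transform = rigid_transform(angles_deg, translation_mm,
                                center_mm = c(ctr, ctr, 72)),
    noise_sd = stir_noise_sd,
    edema_water_boost = 1.25,
    lesions = data.frame(code = 1:4, fraction = fractions, mild = FALSE))
  phantom_spec(shape = c(64, 64, 52), spacing = c(1.5, 1.5, 3),
               limb_center_mm = c(ctr, ctr), limb_radius_mm = 31,
               subcut_thickness_mm = 4, muscles = muscles,
               patterns = patterns, noise_sd_frac = noise_sd_frac,
               seed = seed, stir = stir, bones = bones, supersample = c(3L, 3L, 3L))
}

#' @rdname phantom_fixtures
#' @export
phantom_spec_ff_recovery <- function(seed = 1L, noise_sd_frac = 0.02,
                                     label_jitter_p = 0) {
  ctr <- 40
  muscles <- data.frame(
    code = c(1L, 2L),
    name = c("vastus lateralis", "semimembranosus"),
    side = c("right", "right"),
    cx_mm = ctr + c(-14, 14), cy_mm = c(ctr, ctr),
    a_mm = 12.5, b_mm = 12,
    z0_mm = c(5, 7.5), z1_mm = c(115, 112.5),
    taper = "cosine", taper_floor = 0.75, curve_amp_mm = 0)
  patterns <- list(
    "1" = list(type = "homogeneous", ff_hi = 25, ff_lo = 25),
    "2" = list(type = "high_proximal", ff_hi = 60, ff_lo = 15,
               center = 0.5, width = 0.1))
  phantom_spec(shape = c(64, 64, 48), spacing = c(1.25, 1.25, 2.5),
               limb_center_mm = c(ctr, ctr), limb_radius_mm = 37,
               subcut_thickness_mm = 4, muscles = muscles,
               patterns = patterns, noise_sd_frac = noise_sd_frac,
               label_jitter_p = label_jitter_p, seed = seed)
}

#' @rdname phantom_fixtures
#' @param subject subject index (1-based); severity and lesion load vary
#'   deterministically with it.
#' @export
phantom_spec_cohort_subject <- function(subject, seed = 1L,
                                        noise_sd_frac = 0.02,
                                        label_jitter_p = 0) {
  ctr <- 27
  ## deterministic severity sweep: mean FF spans ~3-90% and STIR+
  ## fraction spans 0-75% across the cohort, covering every rating bin
  sev <- (subject - 1) %% 10 / 9               # 0..1 severity
  types <- c("homogeneous", "high_distal", "high_proximal",
             "high_ends", "high_center")
  t1 <- types[1L + (subject %% 5L)]
  t2 <- types[1L + ((subject + 2L) %% 5L)]
  ffmid <- 3 + 87 * sev
  spread <- pmin(ffmid - 1, 100 - ffmid - 1, 20)
  pat <- function(type, mid) {
    if (type == "homogeneous")
      list(type = type, ff_hi = mid, ff_lo = mid)
    else
      list(type = type, ff_hi = mid + spread, ff_lo = mid - spread,
           center = 0.5, width = 0.12)
  }
  f1 <- c(0, 0.05, 0.15, 0.34, 0.45, 0.55, 0.65, 0.75)[1L + (subject - 1L) %% 8L]
  f2 <- c(0.02, 0.25, 0, 0.5, 0.08, 0.7, 0.36, 0)[1L + (subject - 1L) %% 8L]
  muscles <- data.frame(
    code = c(1L, 2L),
    name = c("tibialis anterior", "gastrocnemius medial head"),
    side = c("left", "left"),
    cx_mm = ctr + c(-10, 10), cy_mm = c(ctr, ctr),
    a_mm = 8, b_mm = 7.5, z0_mm = 8, z1_mm = 92,
    taper = "none", taper_floor = 0.35, curve_amp_mm = 0)
  patterns <- list("1" = pat(t1, ffmid),
                   "2" = pat(t2, pmax(3, pmin(90, ffmid * 0.8 + 5))))
  ## base_intensity 100: normal muscle is isointense with background
  ## tissue on this protocol, so only genuine lesions are outliers
  stir <- list(shape = c(40, 40, 36), spacing = c(1.6, 1.6, 3),
               transform = rigid_transform(),
               noise_sd = 8, base_intensity = 100,
               lesions = data.frame(code = c(1L, 2L), fraction = c(f1, f2),
                                    mild = FALSE))
  phantom_spec(shape = c(40, 40, 36), spacing = c(1.6, 1.6, 3),
               limb_center_mm = c(ctr, ctr), limb_radius_mm = 25,
               subcut_thickness_mm = 3.5, muscles = muscles,
               patterns = patterns, noise_sd_frac = noise_sd_frac,
               label_jitter_p = label_jitter_p, stir = stir,
               seed = as.integer(seed + subject * 131L))
}
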