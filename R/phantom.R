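## Synthetic limb phantom: Dixon water/fat (and optionally STIR) volumes,
## a muscle label map, and voxelwise ground-truth fat-fraction fields
## following the five canonical spatial patterns of fatty infiltration
## seen in FSHD muscle (homogeneous, high-distal, high-proximal,
## high-ends, high-center). Geometry is analytic (elliptical tubes with
## closed-form taper), so cross-sectional areas and mean fat fractions
## have exact oracles.

#' Taper profile of a muscle tube
#'
#' Relative in-plane radius as a function of normalized length
#' u in [0, 1]: `"none"` (cylinder), `"cone"` (radius 1 - u), and
#' `"cosine"` (`floor + (1 - floor) * sin(pi u)`, spindle-shaped with
#' radius `floor` at both ends). CSA scales with the square.
#'
#' @param taper one of `"none"`, `"cone"`, `"cosine"`.
#' @param u normalized length in [0, 1].
#' @param taper_floor end radius of the cosine taper.
#' @return relative radius (same length as `u`).
#' @export
taper_value <- function(taper, u, taper_floor = 0.3) {
  switch(taper,
         none = rep(1, length(u)),
         cone = pmax(0, 1 - u),
         cosine = taper_floor + (1 - taper_floor) * sin(pi * u),
         mq_stop(sprintf("unknown taper '%s'", taper), "mq_spec_error"))
}

#' Ground-truth fat-fraction pattern along the muscle
#'
#' The five spatial patterns, as closed-form functions of normalized
#' length u (0 = inferior/distal end, 1 = superior/proximal end):
#' `homogeneous` (constant `ff_hi`); `high_distal` / `high_proximal`
#' (logistic transition of width `width` centred at `center` from
#' `ff_hi` at one end to `ff_lo` at the other); `high_center` /
#' `high_ends` (Gaussian bump/dip of scale `width` at `center`).
#'
#' @param pattern list with fields `type`, `ff_hi`, `ff_lo`, `center`,
#'   `width` (percent FF values; `center`, `width` in normalized length).
#' @param u normalized length in [0, 1].
#' @return FF in percent.
#' @export
ff_pattern_value <- function(pattern, u) {
  type <- pattern$type
  hi <- pattern$ff_hi; lo <- pattern$ff_lo
  ctr <- if (is.null(pattern$center)) 0.5 else pattern$center
  w <- if (is.null(pattern$width)) 0.1 else pattern$width
  switch(type,
         homogeneous = rep(hi, length(u)),
         high_distal = lo + (hi - lo) / (1 + exp((u - ctr) / w)),
         high_proximal = lo + (hi - lo) / (1 + exp((ctr - u) / w)),
         high_center = lo + (hi - lo) * exp(-(u - ctr)^2 / (2 * w^2)),
         high_ends = hi - (hi - lo) * exp(-(u - ctr)^2 / (2 * w^2)),
         mq_stop(sprintf("unknown FF pattern '%s'", type), "mq_spec_error"))
}

#' Build a phantom specification
#'
#' @param shape Dixon grid dimensions (x, y, z voxels).
#' @param spacing Dixon voxel spacing in mm.
#' @param limb_center_mm in-plane centre of the limb cylinder (mm).
#' @param limb_radius_mm limb radius (mm).
#' @param subcut_thickness_mm thickness of the subcutaneous fat shell.
#' @param muscles data.frame, one row per muscle: `code`, `name`,
#'   `side`, `cx_mm`, `cy_mm` (tube axis position), `a_mm`, `b_mm`
#'   (elliptical radii at full width), `z0_mm`, `z1_mm` (axial extent),
#'   `taper`, `taper_floor`, `curve_amp_mm` (in-plane axis bowing).
#' @param patterns named list (names = codes as character) of FF
#'   patterns, see [ff_pattern_value].
#' @param S0 base signal (arbitrary units); water + fat sum to S0 at a
#'   noiseless voxel.
#' @param noise_sd_frac additive Gaussian noise SD on each channel, as a
#'   fraction of `S0` (magnitude clipped at zero).
#' @param stir `NULL` or a list describing the STIR acquisition:
#'   `shape`, `spacing`, `transform` (a [rigid_transform] mapping
#'   STIR-frame points into the Dixon frame), `noise_sd` (absolute),
#'   `lesions` (data.frame `code`, `fraction` in [0,1], `mild` logical),
#'   and optional intensity overrides (`base_intensity`,
#'   `fat_intensity`, `lesion_intensity`, `other_intensity`,
#'   `ff_attenuation`, `mild_lift`).
#' @param label_jitter_p probability of dropping each boundary-layer
#'   label voxel, emulating segmentation variability between repeated
#'   runs (0 = exact ground-truth labels).
#' @param bones `NULL` or a data.frame (`cx_mm`, `cy_mm`, `radius_mm`,
#'   `marrow_frac`) of full-length bone cylinders: a low-signal
#'   cortical ring around fatty marrow. Bones anchor rigid registration
#'   the way the tibia/femur do in real limb MRI; they carry no FF
#'   metrics (they are never labelled as muscle).
#' @param supersample per-axis sub-voxel sampling factors for signal
#'   rendering. 1 = point sampling at voxel centres (crisp boundaries,
#'   exact closed-form oracles); higher values average the continuous
#'   object over each voxel, emulating the scanner's partial-volume
#'   effect (important for realistic boundary profiles, e.g. in
#'   registration studies). Labels and truth masks always use centre
#'   sampling; the truth FF field is defined as the FF the Dixon
#'   equations recover from the rendered signals, so generative closure
#'   holds exactly at any factor.
#' @param seed RNG seed; a fixed seed makes the dataset bit-reproducible.
#' @return object of class `phantom_spec`.
#' @export
phantom_spec <- function(shape, spacing, limb_center_mm, limb_radius_mm,
                         subcut_thickness_mm, muscles, patterns,
                         S0 = 500, noise_sd_frac = 0, stir = NULL,
                         label_jitter_p = 0, bones = NULL,
                         supersample = 1L, seed = 1L) {
  stopifnot(length(shape) == 3, length(spacing) == 3)
  muscles <- as.data.frame(muscles)
  need <- c("code", "name", "side", "cx_mm", "cy_mm", "a_mm", "b_mm",
            "z0_mm", "z1_mm")
  if (!all(need %in% names(muscles)))
    mq_stop("muscles needs columns code, name, side, cx_mm, cy_mm, a_mm, b_mm, z0_mm, z1_mm",
            "mq_spec_error")
  if (is.null(muscles$taper)) muscles$taper <- "cosine"
  if (is.null(muscles$taper_floor)) muscles$taper_floor <- 0.3
  if (is.null(muscles$curve_amp_mm)) muscles$curve_amp_mm <- 0
  for (code in muscles$code) {
    p <- patterns[[as.character(code)]]
    if (is.null(p))
      mq_stop(sprintf("no FF pattern for code %d", code), "mq_spec_error")
    vals <- ff_pattern_value(p, seq(0, 1, 0.05))
    if (any(vals < 0 | vals > 100))
      mq_stop(sprintf("FF pattern for code %d leaves [0, 100]", code),
              "mq_spec_error")
  }
  if (!is.null(stir)) {
    if (is.null(stir$transform)) stir$transform <- rigid_transform()
    if (is.null(stir$noise_sd)) stir$noise_sd <- 0
    if (is.null(stir$base_intensity)) stir$base_intensity <- 140
    if (is.null(stir$fat_intensity)) stir$fat_intensity <- 25
    if (is.null(stir$lesion_intensity)) stir$lesion_intensity <- 300
    if (is.null(stir$other_intensity)) stir$other_intensity <- 80
    if (is.null(stir$ff_attenuation)) stir$ff_attenuation <- 0.6
    if (is.null(stir$mild_lift)) stir$mild_lift <- 1.15
    if (is.null(stir$lesions))
      stir$lesions <- data.frame(code = integer(), fraction = numeric(),
                                 mild = logical())
    stir$lesions$mild <- if (is.null(stir$lesions$mild)) FALSE else stir$lesions$mild
  }
  if (!is.null(bones)) {
    bones <- as.data.frame(bones)
    if (is.null(bones$marrow_frac)) bones$marrow_frac <- 0.55
  }
  supersample <- as.integer(supersample)
  if (length(supersample) == 1L) supersample <- rep(supersample, 3L)
  if (any(supersample < 1L))
    mq_stop("supersample factors must be >= 1", "mq_spec_error")
  structure(list(shape = as.integer(shape), spacing = as.numeric(spacing),
                 limb_center_mm = as.numeric(limb_center_mm),
                 limb_radius_mm = limb_radius_mm,
                 subcut_thickness_mm = subcut_thickness_mm,
                 muscles = muscles, patterns = patterns, S0 = S0,
                 noise_sd_frac = noise_sd_frac, stir = stir,
                 label_jitter_p = label_jitter_p, bones = bones,
                 supersample = supersample, seed = as.integer(seed)),
            class = "phantom_spec")
}

## Evaluate the phantom geometry at arbitrary physical points (mm).
## Returns, per point: the muscle code (0 none), normalized length u,
## limb/subcut indicators. Shared by the Dixon- and STIR-frame
## rasterizers so both frames see the identical continuous object.
phantom_eval <- function(spec, pts) {
  n <- nrow(pts)
  code <- integer(n); u <- rep(NA_real_, n)
  r2 <- (pts[, 1] - spec$limb_center_mm[1])^2 +
        (pts[, 2] - spec$limb_center_mm[2])^2
  limb <- r2 <= spec$limb_radius_mm^2
  subcut <- limb & r2 > (spec$limb_radius_mm - spec$subcut_thickness_mm)^2
  overlap_codes <- integer(0)
  for (i in seq_len(nrow(spec$muscles))) {
    m <- spec$muscles[i, ]
    uu <- (pts[, 3] - m$z0_mm) / (m$z1_mm - m$z0_mm)
    inz <- uu >= 0 & uu <= 1
    tp <- taper_value(m$taper, pmin(1, pmax(0, uu)), m$taper_floor)
    cx <- m$cx_mm + m$curve_amp_mm * sin(pi * pmin(1, pmax(0, uu)))
    inside <- inz & tp > 0 &
      ((pts[, 1] - cx) / (m$a_mm * tp))^2 +
      ((pts[, 2] - m$cy_mm) / (m$b_mm * tp))^2 <= 1
    clash <- inside & code != 0L
    if (any(clash))
      overlap_codes <- union(overlap_codes, c(m$code, unique(code[clash])))
    code[inside] <- m$code
    u[inside] <- uu[inside]
  }
  if (length(overlap_codes))
    mq_stop(sprintf("overlapping muscle geometry for codes [%s]",
                    paste(sort(overlap_codes), collapse = ", ")), "mq_spec_error")
  bone <- integer(n)   # 0 none, 1 cortical, 2 marrow
  if (!is.null(spec$bones)) {
    for (i in seq_len(nrow(spec$bones))) {
      b <- spec$bones[i, ]
      br2 <- (pts[, 1] - b$cx_mm)^2 + (pts[, 2] - b$cy_mm)^2
      inb <- br2 <= b$radius_mm^2
      if (any(inb & code != 0L))
        mq_stop(sprintf("bone %d overlaps muscle geometry", i), "mq_spec_error")
      bone[inb] <- 1L
      bone[br2 <= (b$marrow_frac * b$radius_mm)^2] <- 2L
    }
  }
  list(code = code, u = u, limb = limb, subcut = subcut, bone = bone)
}

## u-interval of the programmed lesion for one muscle: centred span
## whose CSA-weighted share of the tube equals `fraction`. For untapered
## tubes the share is just the length fraction; for tapered tubes the
## interval is found by inverting the CSA-weighted cumulative integral.
lesion_interval <- function(m, fraction) {
  if (fraction <= 0) return(c(NA_real_, NA_real_))
  if (fraction >= 1) return(c(0, 1))
  csa2 <- function(u) taper_value(m$taper, u, m$taper_floor)^2
  total <- integrate(csa2, 0, 1)$value
  target <- fraction * total
  half <- function(h) integrate(csa2, max(0, 0.5 - h), min(1, 0.5 + h))$value - target
  h <- stats::uniroot(half, c(1e-6, 0.5))$root
  c(0.5 - h, 0.5 + h)
}

## Sub-voxel offset table for partial-volume rendering (mm), centred on
## the voxel centre.
supersample_offsets <- function(ss, sp) {
  ax <- function(k) if (ss[k] == 1L) 0 else
    ((seq_len(ss[k]) - 0.5) / ss[k] - 0.5) * sp[k]
  as.matrix(expand.grid(ax(1), ax(2), ax(3)))
}

## Tissue class -> (FF %, signal scale, water edema boost) at evaluated
## points. Outside the limb both signals vanish (scale 0). STIR+
## lesions are edematous: their Dixon water signal is mildly elevated
## (factor `edema_water_boost`, default 1.1), as inflamed muscle is on
## water-sensitive sequences.
phantom_class_ff <- function(spec, ev, lesions = NULL) {
  n <- length(ev$code)
  ff <- numeric(n); scale <- numeric(n)
  wboost <- rep(1, n)
  ff[ev$limb] <- 15; scale[ev$limb] <- 1          # unlabelled limb tissue
  ff[ev$subcut] <- 90                              # subcutaneous fat
  boost <- if (!is.null(spec$stir) && !is.null(spec$stir$edema_water_boost))
    spec$stir$edema_water_boost else 1.1
  for (i in seq_len(nrow(spec$muscles))) {
    m <- spec$muscles[i, ]
    sel <- ev$code == m$code
    if (!any(sel)) next
    ff[sel] <- ff_pattern_value(spec$patterns[[as.character(m$code)]],
                                ev$u[sel])
    les <- if (!is.null(lesions)) lesions[lesions$code == m$code, ] else NULL
    if (!is.null(les) && nrow(les) == 1 && !is.na(les$u0))
      wboost[sel & ev$u >= les$u0 & ev$u <= les$u1] <- boost
  }
  ff[ev$bone == 1L] <- 50; scale[ev$bone == 1L] <- 0.15  # cortical bone
  ff[ev$bone == 2L] <- 85                                # fatty marrow
  list(ff = ff, scale = scale, wboost = wboost)
}

## Logical lesion membership at evaluated points.
lesion_indicator <- function(spec, ev, lesions) {
  out <- rep(FALSE, length(ev$code))
  for (i in seq_len(nrow(lesions))) {
    les <- lesions[i, ]
    if (is.na(les$u0)) next
    out <- out | (ev$code == les$code & ev$u >= les$u0 & ev$u <= les$u1)
  }
  out
}

## STIR intensity of the tissue classes at evaluated points.
phantom_stir_intensity <- function(spec, ev, lesions) {
  st <- spec$stir
  n <- length(ev$code)
  intensity <- numeric(n)
  intensity[ev$limb] <- st$other_intensity
  intensity[ev$subcut] <- st$fat_intensity
  is_lesion <- rep(FALSE, n)
  for (i in seq_len(nrow(spec$muscles))) {
    m <- spec$muscles[i, ]
    sel <- ev$code == m$code
    if (!any(sel)) next
    ffm <- ff_pattern_value(spec$patterns[[as.character(m$code)]], ev$u[sel])
    base <- st$base_intensity * (1 - st$ff_attenuation * ffm / 100)
    les <- if (!is.null(lesions)) lesions[lesions$code == m$code, ] else NULL
    if (!is.null(les) && nrow(les) == 1 && isTRUE(les$mild))
      base <- base * st$mild_lift
    intensity[sel] <- base
    if (!is.null(les) && nrow(les) == 1 && !is.na(les$u0)) {
      inles <- sel & ev$u >= les$u0 & ev$u <= les$u1
      intensity[inles] <- st$lesion_intensity
      is_lesion <- is_lesion | inles
    }
  }
  intensity[ev$bone == 1L] <- 12
  intensity[ev$bone == 2L] <- 30
  list(intensity = intensity, is_lesion = is_lesion)
}

#' Generate a phantom dataset
#'
#' Rasterizes the continuous phantom onto the Dixon grid (water + fat
#' channels, label map, voxelwise truth FF) and, if specified, onto a
#' STIR grid through the known rigid transform (STIR signal + truth
#' STIR+ mask). Noiseless channels satisfy
#' water = S0 (1 - FF/100), fat = S0 FF/100 exactly, so the downstream
#' fat-fraction computation recovers the truth field to numerical
#' precision. Deterministic for a fixed seed.
#'
#' @param spec a [phantom_spec].
#' @return object of class `phantom_dataset`: `water`, `fat`
#'   ([volumetric_image]s), `labelmap` ([muscle_labelmap]),
#'   `truth_ff` (3D array, `NA` outside the limb), `truth_composition`
#'   (per-code mean truth FF and voxel count over the labelled voxels),
#'   `stir`, `truth_stir_mask`, `truth_labels_stir`,
#'   `truth_stir_fraction` (per-code, computed on the STIR grid),
#'   `dixon_to_stir` ([rigid_transform]), `lesions`, `spec`.
#' @export
generate_phantom <- function(spec) {
  set.seed(spec$seed)
  d <- spec$shape; sp <- spec$spacing
  pts <- grid_points(d, sp)
  ev <- phantom_eval(spec, pts)
  lesions <- NULL
  if (!is.null(spec$stir)) {
    lesions <- spec$stir$lesions
    lesions$u0 <- NA_real_; lesions$u1 <- NA_real_
    for (i in seq_len(nrow(lesions))) {
      m <- spec$muscles[spec$muscles$code == lesions$code[i], ]
      iv <- lesion_interval(m, lesions$fraction[i])
      lesions$u0[i] <- iv[1]; lesions$u1[i] <- iv[2]
    }
  }
  ## fractional water/fat signal (units of S0) averaged over sub-voxel
  ## sample points: partial-volume rendering at supersample > 1
  offs <- supersample_offsets(spec$supersample, sp)
  wfrac <- numeric(nrow(pts)); ffrac <- numeric(nrow(pts))
  les_occ <- numeric(nrow(pts))
  for (o in seq_len(nrow(offs))) {
    evo <- if (nrow(offs) == 1L) ev else
      phantom_eval(spec, sweep(pts, 2, -offs[o, ]))
    cl <- phantom_class_ff(spec, evo, lesions)
    wfrac <- wfrac + cl$scale * cl$wboost * (1 - cl$ff / 100)
    ffrac <- ffrac + cl$scale * cl$ff / 100
    if (!is.null(lesions))
      les_occ <- les_occ + lesion_indicator(spec, evo, lesions)
  }
  les_occ <- les_occ / nrow(offs)
  wfrac <- wfrac / nrow(offs); ffrac <- ffrac / nrow(offs)
  tot <- wfrac + ffrac
  ff <- ifelse(tot > 0, 100 * ffrac / tot, NA_real_)
  limb <- tot > 0
  S0 <- spec$S0; sdn <- spec$noise_sd_frac * S0
  water <- S0 * wfrac; fat <- S0 * ffrac
  if (sdn > 0) {
    nlimb <- sum(limb)
    water[limb] <- pmax(0, water[limb] + rnorm(nlimb, 0, sdn))
    fat[limb] <- pmax(0, fat[limb] + rnorm(nlimb, 0, sdn))
  }
  labels <- ev$code
  truth_ff_arr <- array(ff, d)
  labels_arr <- array(as.integer(labels), d)
  dict <- spec$muscles[, c("code", "name", "side")]
  labelmap <- muscle_labelmap(labels_arr, dict, sp)
  if (spec$label_jitter_p > 0) {
    off1 <- disc_offsets(1L)
    for (code in dict$code) {
      msk <- labelmap$labels == code
      if (!any(msk)) next
      boundary <- msk & !erode_mask_slicewise(msk, off1)
      idx <- which(boundary)
      drop <- idx[stats::runif(length(idx)) < spec$label_jitter_p]
      labelmap$labels[drop] <- 0L
    }
  }
  truth_comp <- do.call(rbind, lapply(dict$code, function(code) {
    sel <- labelmap$labels == code
    data.frame(code = code, voxels = sum(sel),
               mean_ff = mean(truth_ff_arr[sel]))
  }))
  out <- list(
    water = volumetric_image(array(water, d), sp, kind = "dixon_water"),
    fat = volumetric_image(array(fat, d), sp, kind = "dixon_fat"),
    labelmap = labelmap,
    truth_ff = truth_ff_arr,
    truth_composition = truth_comp,
    lesions = lesions,
    spec = spec)
  if (!is.null(spec$stir)) {
    st <- spec$stir
    dstir <- as.integer(st$shape); spstir <- as.numeric(st$spacing)
    pts_s <- grid_points(dstir, spstir)
    pd <- transform_points(st$transform, pts_s)
    evs <- phantom_eval(spec, pd)
    offs_s <- supersample_offsets(spec$supersample, spstir)
    intensity <- numeric(nrow(pd))
    les_frac <- numeric(nrow(pd))
    all_codes <- c(0L, spec$muscles$code)
    code_tally <- matrix(0L, nrow(pd), length(all_codes))
    for (o in seq_len(nrow(offs_s))) {
      evo <- if (nrow(offs_s) == 1L) evs else
        phantom_eval(spec, transform_points(st$transform,
                                            sweep(pts_s, 2, -offs_s[o, ])))
      si <- phantom_stir_intensity(spec, evo, lesions)
      intensity <- intensity + si$intensity
      les_frac <- les_frac + si$is_lesion
      code_tally <- code_tally + outer(evo$code, all_codes, "==")
    }
    intensity <- intensity / nrow(offs_s)
    ## truth STIR+ mask by majority volume occupancy, the binarization
    ## an ideal mid-intensity thresholder of the rendered signal implies
    is_lesion <- les_frac / nrow(offs_s) > 0.5
    in_limb_s <- evs$limb
    if (st$noise_sd > 0) {
      nl <- sum(in_limb_s)
      intensity[in_limb_s] <- pmax(0, intensity[in_limb_s] +
                                     rnorm(nl, 0, st$noise_sd))
    }
    ## majority-occupancy truth labels (consistent with the rendered
    ## partial-volume signal and with vote-based label resampling)
    maj_code <- all_codes[max.col(code_tally, ties.method = "first")]
    truth_labels_stir <- muscle_labelmap(array(as.integer(maj_code), dstir),
                                         dict, spstir)
    ## truth STIR+ fraction on the STIR grid with the same
    ## majority-occupancy convention as the truth mask and labels: the
    ## share of each muscle's voxels whose majority volume is lesion.
    ## (A Dixon-frame count of the same lesion differs by the relative
    ## half-slice quantisation of the two grids; content is measured in
    ## the STIR frame, so truth is defined there.)
    frac <- do.call(rbind, lapply(dict$code, function(code) {
      sel <- maj_code == code
      data.frame(code = code,
                 fraction_pct = if (any(sel))
                   100 * sum(is_lesion[sel]) / sum(sel) else NA_real_,
                 mild = !is.null(lesions) &&
                   isTRUE(lesions$mild[match(code, lesions$code)]))
    }))
    out$stir <- volumetric_image(array(intensity, dstir), spstir, kind = "stir")
    out$truth_stir_mask <- array(is_lesion, dstir)
    out$truth_labels_stir <- truth_labels_stir
    out$truth_stir_fraction <- frac
    out$dixon_to_stir <- st$transform
  }
  structure(out, class = "phantom_dataset")
}

#' Analytic cross-sectional area of a phantom muscle
#'
#' Closed-form boundary CSA (mm^2) of the continuous tube at axial
#' position `z_mm`: `pi a b taper(u)^2`, zero outside the extent.
#'
#' @param spec a [phantom_spec].
#' @param code muscle code.
#' @param z_mm axial positions (mm).
#' @export
phantom_csa <- function(spec, code, z_mm) {
  m <- spec$muscles[spec$muscles$code == code, ]
  if (nrow(m) != 1) mq_stop("unknown code", "mq_spec_error")
  u <- (z_mm - m$z0_mm) / (m$z1_mm - m$z0_mm)
  ifelse(u >= 0 & u <= 1,
         pi * m$a_mm * m$b_mm * taper_value(m$taper, pmin(1, pmax(0, u)),
                                            m$taper_floor)^2,
         0)
}

#' Follow-up timepoint with progression in FF transition zones
#'
#' Fatty replacement in FSHD advances preferentially where the FF field
#' transitions between high and low values. The increment applied to
#' each muscle is proportional to |d FF / dz| raised to
#' `concentration`, renormalized so the muscle-mean increase equals the
#' programmed `delta_ff`; spatially homogeneous muscles (zero gradient)
#' fall back to a uniform increment. FF is clipped at 100 with the
#' clipped mass reported via a warning and the `clip_mass` field.
#'
#' @param dataset a baseline [generate_phantom] result.
#' @param delta_ff named numeric: programmed mean FF increase
#'   (percentage points) per muscle code.
#' @param concentration exponent on the axial FF gradient magnitude.
#' @return a new `phantom_dataset` at t+1 (fresh noise realization);
#'   `$progression` records the programmed and realized per-muscle
#'   change and any clipped mass.
#' @export
make_followup <- function(dataset, delta_ff, concentration = 2) {
  spec <- dataset$spec
  set.seed(spec$seed + 7919L)
  d <- spec$shape; sp <- spec$spacing
  ff <- dataset$truth_ff
  labels <- dataset$labelmap$labels
  clip_total <- 0
  prog <- NULL
  for (code_chr in names(delta_ff)) {
    code <- as.integer(code_chr)
    dffv <- delta_ff[[code_chr]]
    sel <- labels == code
    if (!any(sel)) next
    ## axial FF gradient within the muscle only (one-sided at the
    ## ends); using the global field would create spurious spikes at
    ## the muscle boundary where it meets unrelated tissue
    ffm <- ff
    ffm[!sel] <- NA
    nz <- d[3]; h <- sp[3]
    up <- array(NA_real_, d); up[, , 1:(nz - 1)] <- ffm[, , 2:nz]
    dn <- array(NA_real_, d); dn[, , 2:nz] <- ffm[, , 1:(nz - 1)]
    g <- array(0, d)
    both <- !is.na(up) & !is.na(dn)
    g[both] <- (up[both] - dn[both]) / (2 * h)
    upo <- !is.na(up) & is.na(dn) & !is.na(ffm)
    g[upo] <- (up[upo] - ffm[upo]) / h
    dno <- is.na(up) & !is.na(dn) & !is.na(ffm)
    g[dno] <- (ffm[dno] - dn[dno]) / h
    w <- abs(g[sel])^concentration
    if (mean(w) == 0 || !is.finite(mean(w))) w <- rep(1, sum(sel))
    inc <- dffv * w / mean(w)
    newff <- ff[sel] + inc
    clipped <- sum(pmax(0, newff - 100))
    clip_total <- clip_total + clipped
    ff[sel] <- pmin(100, newff)
    prog <- rbind(prog, data.frame(code = code, programmed_dff = dffv,
                                   realized_dff = mean(ff[sel]) -
                                     mean(dataset$truth_ff[sel]),
                                   clip_mass = clipped))
  }
  if (clip_total > 0)
    mq_warn(sprintf("FF clipped at 100%% (total clipped mass %.3g pp-voxels)",
                    clip_total))
  S0 <- spec$S0; sdn <- spec$noise_sd_frac * S0
  limb <- !is.na(ff)
  water <- numeric(length(ff)); fat <- numeric(length(ff))
  water[limb] <- S0 * (1 - ff[limb] / 100)
  fat[limb] <- S0 * ff[limb] / 100
  if (sdn > 0) {
    nlimb <- sum(limb)
    water[limb] <- pmax(0, water[limb] + rnorm(nlimb, 0, sdn))
    fat[limb] <- pmax(0, fat[limb] + rnorm(nlimb, 0, sdn))
  }
  out <- dataset
  out$truth_ff <- array(ff, d)
  out$water <- volumetric_image(array(water, d), sp, kind = "dixon_water")
  out$fat <- volumetric_image(array(fat, d), sp, kind = "dixon_fat")
  out$truth_composition <- do.call(rbind, lapply(dataset$labelmap$dictionary$code,
    function(code) {
      sel <- labels == code
      data.frame(code = code, voxels = sum(sel), mean_ff = mean(out$truth_ff[sel]))
    }))
  out$progression <- prog
  out
}

#' Ground-truth clinical ratings of a phantom
#'
#' Fat rating (1-6) from each muscle's volumetric truth FF via
#' [fat_rating_from_ff]; STIR grade (0-4) from the truth STIR+ fraction
#' via [stir_grade_from_pct] (grade 1 for programmed mild diffuse
#' elevation).
#'
#' @param dataset a [generate_phantom] result.
#' @return data.frame: `code`, `fat_rating`, `stir_grade` (`NA` when
#'   the phantom has no STIR arm).
#' @export
truth_ratings <- function(dataset) {
  tc <- dataset$truth_composition
  out <- data.frame(code = tc$code,
                    fat_rating = fat_rating_from_ff(tc$mean_ff))
  if (!is.null(dataset$truth_stir_fraction)) {
    fr <- dataset$truth_stir_fraction
    idx <- match(out$code, fr$code)
    out$stir_grade <- stir_grade_from_pct(fr$fraction_pct[idx], fr$mild[idx])
  } else {
    out$stir_grade <- NA_integer_
  }
  out
}
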