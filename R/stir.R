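## STIR+ quantification: limb masking, limb-local Otsu segmentation of
## hyperintense regions, and per-muscle STIR content (%).

as_ebimage <- function(m) EBImage::Image(m)

#' Slice-wise limb foreground mask
#'
#' Per slice: global Otsu on the slice separates limb from air, holes
#' are filled, and only large connected components (>= `keep_fraction`
#' of the largest) are retained, so bilateral limbs survive but specks
#' do not. Constant slices yield empty mask slices.
#'
#' @param stir a STIR [volumetric_image].
#' @param keep_fraction component-size cutoff relative to the largest.
#' @return logical 3D array on the STIR grid.
#' @export
limb_mask <- function(stir, keep_fraction = 0.2) {
  d <- dim(stir$data)
  out <- array(FALSE, d)
  for (k in seq_len(d[3])) {
    sl <- stir$data[, , k]
    rg <- range(sl)
    if (diff(rg) <= 0) { mq_log("limb_mask: constant slice ", k); next }
    ## Otsu on log intensity: air-vs-tissue stays the dominant
    ## bimodality even when small very bright lesions are present
    lsl <- log1p(sl)
    thr <- EBImage::otsu(as_ebimage(lsl), range = range(lsl))
    m <- lsl > thr
    if (!any(m)) next
    m <- EBImage::fillHull(as_ebimage(m)) > 0
    cc <- EBImage::bwlabel(as_ebimage(m))
    sizes <- tabulate(as.integer(cc[cc > 0]))
    keep <- which(sizes >= keep_fraction * max(sizes))
    out[, , k] <- matrix(as.integer(cc) %in% keep, d[1], d[2]) & m
  }
  out
}

## Disc of pixel indices around a centre, intersected with the slice.
window_pixels <- function(cx, cy, r_px, d) {
  xr <- max(1L, floor(cx - r_px)):min(d[1], ceiling(cx + r_px))
  yr <- max(1L, floor(cy - r_px)):min(d[2], ceiling(cy + r_px))
  g <- expand.grid(x = xr, y = yr)
  g <- g[(g$x - cx)^2 + (g$y - cy)^2 <= r_px^2, , drop = FALSE]
  cbind(g$x, g$y)
}

#' Segment STIR-hyperintense voxels
#'
#' Emulates the interactive limb-local thresholding workflow with a
#' deterministic tiling: on each slice, circular windows of diameter
#' `region_fraction` times the limb's equivalent diameter tile the limb
#' with 50% overlap; an Otsu threshold inside each window marks bright
#' pixels, and a pixel is STIR+ if marked in any covering window.
#' The Otsu split is refined to the midpoint of the two class medians,
#' which implements a ~50% partial-volume occupancy rule at lesion
#' boundaries. Pixels within `edge_margin_px` of the limb boundary are
#' excluded (smooth edge artifacts). A degenerate-window guard
#' suppresses detections whose threshold does not exceed a brightness
#' floor: by default a Tukey fence (q75 + `guard_k` IQR) over the limb
#' interior of the whole volume, treating hyperintensity as a
#' brightness outlier against the pooled normal-tissue distribution;
#' `"slice"` restricts the reference to the current slice, and
#' `"window"` uses the window's own mean + k SD (suitable only for
#' sparse lesions). A final consolidation pass (`global_refine`)
#' removes candidates dimmer than the midpoint between the pooled
#' normal-tissue and detected-lesion medians, stripping partial-volume
#' rims. Optionally, candidate voxels whose Dixon fat fraction
#' (resampled to the STIR grid) exceeds `ff_veto_pct` are removed,
#' encoding the manual fat-vs-STIR check against the Dixon images.
#'
#' @param stir STIR [volumetric_image].
#' @param limb logical limb mask from [limb_mask].
#' @param region_fraction window diameter as a fraction of the limb
#'   equivalent diameter (default 0.20).
#' @param edge_margin_px limb-boundary exclusion margin in pixels.
#' @param guard_reference `"volume"`, `"slice"`, `"window"` or `"none"`.
#' @param guard_k scale multiplier of the degenerate guard floor.
#' @param global_refine apply the consolidation pass (default `TRUE`).
#' @param ff_on_stir optional `ff_map`-like 3D array of Dixon FF (%) on
#'   the STIR grid for the fat veto; `NA` where undefined.
#' @param ff_veto_pct veto threshold in percent (default 50).
#' @return object of class `stir_mask`: `mask` (logical array),
#'   `provenance = "threshold"`, `spacing`.
#' @export
segment_stir <- function(stir, limb, region_fraction = 0.20,
                         edge_margin_px = 2L,
                         guard_reference = c("volume", "slice", "window", "none"),
                         guard_k = 1.5, global_refine = TRUE,
                         ff_on_stir = NULL, ff_veto_pct = 50) {
  guard_reference <- match.arg(guard_reference)
  if (!(region_fraction > 0 && region_fraction <= 1))
    mq_stop("region_fraction must be in (0, 1]", "mq_parameter_error")
  d <- dim(stir$data)
  if (!identical(dim(limb), d))
    mq_stop("limb mask does not match the STIR grid", "mq_alignment_error")
  out <- array(FALSE, d)
  core_off <- if (edge_margin_px >= 1) disc_offsets(edge_margin_px) else NULL
  core <- if (is.null(core_off)) limb else erode_mask_slicewise(limb, core_off)
  ## Tukey upper fence over the whole limb core: hyperintense voxels
  ## are brightness outliers relative to the pooled normal-tissue
  ## distribution, in which even extensive lesions are a small volume
  ## fraction (per-slice statistics can be majority-lesion)
  fence_vol <- if (guard_reference == "volume" && any(core)) {
    qv <- stats::quantile(stir$data[core], c(0.25, 0.75), names = FALSE)
    qv[2] + guard_k * (qv[2] - qv[1])
  } else -Inf
  for (k in seq_len(d[3])) {
    lm <- limb[, , k]
    if (!any(lm)) next
    sl <- stir$data[, , k]
    ck <- core[, , k]
    if (!any(ck)) next
    eq_diam_px <- 2 * sqrt(sum(lm) / pi)
    r_px <- region_fraction * eq_diam_px / 2
    if (pi * r_px^2 < 9) {
      ## a tiny limb remnant (end slices) is skipped; a healthy limb
      ## with a window this small means region_fraction is misconfigured
      if (sum(lm) < 200) { mq_log("segment_stir: skipping slice ", k); next }
      mq_stop(sprintf("slice %d: tiling window of %.1f px^2 is below the 9 px^2 minimum",
                      k, pi * r_px^2), "mq_parameter_error")
    }
    ref_vals <- sl[ck]
    ## Tukey upper fence of the limb-core intensities: STIR+ voxels are
    ## treated as brightness outliers above the normal-tissue spread.
    ## Quartiles are robust both to the lesions themselves (unlike a
    ## mean + SD floor) and to near-homogeneous slices (unlike a MAD
    ## floor, which collapses to the noise scale)
    floor_val <- if (guard_reference == "volume") {
      fence_vol
    } else if (guard_reference == "slice") {
      qs <- stats::quantile(ref_vals, c(0.25, 0.75), names = FALSE)
      qs[2] + guard_k * (qs[2] - qs[1])
    } else -Inf
    ## window centres on a hexagonal-ish square grid with 50% overlap
    wh <- which(lm, arr.ind = TRUE)
    bx <- range(wh[, 1]); by <- range(wh[, 2])
    cxs <- seq(bx[1], bx[2], by = max(1, r_px))
    cys <- seq(by[1], by[2], by = max(1, r_px))
    det <- matrix(FALSE, d[1], d[2])
    for (cx in cxs) for (cy in cys) {
      px <- window_pixels(cx, cy, r_px, d)
      inside <- ck[px]
      px <- px[inside, , drop = FALSE]
      if (nrow(px) < 9L) next
      vals <- sl[px]
      rg <- range(vals)
      if (diff(rg) <= 0) next                       # homogeneous window
      thr <- EBImage::otsu(as_ebimage(matrix(vals, ncol = 1)), range = rg)
      ## midpoint refinement: the raw Otsu split sits at the low edge of
      ## its plateau for well-separated classes, which would label every
      ## partial-volume boundary voxel; the midpoint of the class
      ## medians (robust to the ramp tails) implements the ~50%
      ## occupancy rule instead
      lo <- vals[vals <= thr]; hi <- vals[vals > thr]
      if (!length(hi)) next
      thr <- (stats::median(lo) + stats::median(hi)) / 2
      wfloor <- if (guard_reference == "window")
        mean(vals) + guard_k * sd(vals) else floor_val
      if (guard_reference != "none" && thr <= wfloor) next
      hit <- vals > thr
      det[px[hit, , drop = FALSE]] <- TRUE
    }
    out[, , k] <- det
  }
  if (global_refine && any(out) && any(core & !out)) {
    ## consolidation pass: a voxel marked by some local window still has
    ## to be brighter than the midpoint between the pooled normal-tissue
    ## and detected-lesion medians. This removes partial-volume rims at
    ## lesion margins whose windows are locally bimodal but whose
    ## brightness is clearly sub-lesional in the global picture
    gthr <- (stats::median(stir$data[core & !out]) +
               stats::median(stir$data[out])) / 2
    out <- out & stir$data > gthr
  }
  if (!is.null(ff_on_stir)) {
    veto <- !is.na(ff_on_stir) & ff_on_stir > ff_veto_pct
    out <- out & !veto
  }
  structure(list(mask = out, provenance = "threshold", spacing = stir$spacing),
            class = "stir_mask")
}

#' Wrap an externally produced STIR+ mask
#' @param mask logical 3D array on the STIR grid.
#' @param stir the STIR [volumetric_image] it belongs to.
#' @param provenance `"manual"` or `"external"`.
#' @export
stir_mask <- function(mask, stir, provenance = c("external", "manual", "threshold")) {
  provenance <- match.arg(provenance)
  if (!identical(dim(mask), dim(stir$data)))
    mq_stop("mask shape does not match the STIR grid", "mq_alignment_error")
  structure(list(mask = mask, provenance = provenance, spacing = stir$spacing),
            class = "stir_mask")
}

#' Per-muscle STIR content (%)
#'
#' The number of STIR+ voxels inside each muscle boundary as a
#' percentage of the total voxels in the boundary. Labels are eroded by
#' one pixel layer first (default) to absorb residual registration
#' error at the muscle rim; muscles left empty by erosion are flagged.
#'
#' @param stir_mask a [stir_mask] / [segment_stir] result.
#' @param labels_on_stir [muscle_labelmap] resampled onto the STIR grid.
#' @param erode_first erode labels one layer before counting.
#' @return data.frame per dictionary code: `code`, `name`, `side`,
#'   `stir_voxels`, `total_voxels`, `stir_pct`, `flagged`.
#' @export
stir_content <- function(stir_mask, labels_on_stir, erode_first = TRUE) {
  if (!identical(dim(stir_mask$mask), dim(labels_on_stir$labels)))
    mq_stop("STIR mask and labels are not on the same grid", "mq_alignment_error")
  lm <- if (erode_first) erode_labels(labels_on_stir, erosion_spec("one_layer"))
        else labels_on_stir
  dict <- lm$dictionary
  rows <- lapply(seq_len(nrow(dict)), function(i) {
    m <- lm$labels == dict$code[i]
    tot <- sum(m)
    sv <- sum(m & stir_mask$mask)
    data.frame(code = dict$code[i], name = dict$name[i], side = dict$side[i],
               stir_voxels = sv, total_voxels = tot,
               stir_pct = if (tot > 0) 100 * sv / tot else NA_real_,
               flagged = tot == 0L,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
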