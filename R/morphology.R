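## Slice-wise label erosion. Two modes mirror the two uses in the
## pipeline: a ~4 mm radial footprint for the chemical-shift sensitivity
## analysis, and a one-pixel-layer erosion applied after registration in
## the STIR pathway. Erosion is always 2D in-plane, never across slices.

#' Erosion specification
#'
#' @param mode `"radial_mm"` (disc of physical radius `radius_mm`) or
#'   `"one_layer"` (remove the outermost pixel layer; radius-1 disc,
#'   i.e. a 4-connected cross).
#' @param radius_mm physical radius, radial mode only. The pixel radius
#'   is `round(radius_mm / in-plane spacing)`.
#' @return object of class `erosion_spec`.
#' @export
erosion_spec <- function(mode = c("radial_mm", "one_layer"), radius_mm = 4) {
  mode <- match.arg(mode)
  if (mode == "radial_mm" && (!is.finite(radius_mm) || radius_mm <= 0))
    mq_stop("radius_mm must be positive", "mq_parameter_error")
  structure(list(mode = mode, radius_mm = radius_mm), class = "erosion_spec")
}

#' Discrete disc structuring element
#'
#' Offsets (dx, dy) with dx^2 + dy^2 <= r^2, inclusive at the exact
#' radius. Radius 1 gives the 4-connected cross.
#'
#' @param r_px integer pixel radius >= 1.
#' @return two-column integer matrix of offsets.
#' @export
disc_offsets <- function(r_px) {
  r_px <- as.integer(r_px)
  if (r_px < 1L) mq_stop("pixel radius must be >= 1", "mq_parameter_error")
  g <- expand.grid(dx = -r_px:r_px, dy = -r_px:r_px)
  as.matrix(g[g$dx^2 + g$dy^2 <= r_px^2, , drop = FALSE])
}

## In-plane binary erosion of a 3D logical array by a set of 2D offsets:
## a voxel survives iff every offset neighbour (same slice) is TRUE.
## Implemented as an AND-reduction over shifted copies; shifting in x/y
## never crosses slices, so all slices are eroded in one pass.
erode_mask_slicewise <- function(mask, offsets) {
  d <- dim(mask)
  out <- mask
  for (i in seq_len(nrow(offsets))) {
    dx <- offsets[i, 1]; dy <- offsets[i, 2]
    if (dx == 0L && dy == 0L) next
    sh <- array(FALSE, d)
    xs <- seq_len(d[1]) + dx
    ys <- seq_len(d[2]) + dy
    okx <- xs >= 1L & xs <= d[1]
    oky <- ys >= 1L & ys <= d[2]
    sh[which(okx), which(oky), ] <- mask[xs[okx], ys[oky], , drop = FALSE]
    out <- out & sh
    if (!any(out)) break
  }
  out
}

in_plane_radius_px <- function(spacing, radius_mm) {
  if (abs(spacing[1] - spacing[2]) > 1e-6)
    mq_stop("radial erosion requires isotropic in-plane spacing", "mq_parameter_error")
  r_px <- round(radius_mm / spacing[1])
  if (r_px < 1L)
    mq_stop(sprintf("erosion radius %g mm is below half the in-plane spacing (empty footprint)",
                    radius_mm), "mq_parameter_error")
  as.integer(r_px)
}

#' Erode every muscle label slice-by-slice
#'
#' Each code is eroded independently in-plane; codes can therefore never
#' merge or grow. Slices whose label vanishes under erosion are dropped
#' for that code and counted in the attached report.
#'
#' @param labelmap a [muscle_labelmap].
#' @param spec an [erosion_spec].
#' @return an eroded `muscle_labelmap`; `attr(, "erosion_report")` is a
#'   data.frame with per-code `voxels_before`, `voxels_after`,
#'   `slices_dropped`.
#' @export
erode_labels <- function(labelmap, spec = erosion_spec("one_layer")) {
  offsets <- if (spec$mode == "radial_mm") {
    disc_offsets(in_plane_radius_px(labelmap$spacing, spec$radius_mm))
  } else {
    disc_offsets(1L)
  }
  codes <- label_counts(labelmap)
  codes <- codes$code[codes$voxels > 0L]
  out <- array(0L, dim(labelmap$labels))
  rep_rows <- lapply(codes, function(code) {
    m <- labelmap$labels == code
    e <- erode_mask_slicewise(m, offsets)
    out[e] <<- as.integer(code)
    occ_before <- which(apply(m, 3, any))
    occ_after <- which(apply(e, 3, any))
    data.frame(code = code, voxels_before = sum(m), voxels_after = sum(e),
               slices_dropped = length(setdiff(occ_before, occ_after)))
  })
  eroded <- muscle_labelmap(out, labelmap$dictionary, labelmap$spacing,
                            superior_direction = labelmap$superior_direction)
  attr(eroded, "erosion_report") <- do.call(rbind, rep_rows)
  eroded
}

#' Chemical-shift sensitivity of longitudinal FF change
#'
#' For two timepoints, computes each muscle's fat-fraction change with
#' the original labels and again with eroded labels. The paired deltas
#' feed the reliability module's correlation/regression; a strong
#' agreement indicates rim (chemical-shift) contamination is negligible.
#'
#' @param water,fat,labelmap baseline images and labels.
#' @param water2,fat2,labelmap2 follow-up images and labels.
#' @param spec an [erosion_spec]; default 4 mm radial.
#' @return data.frame per shared muscle: `code`, `dff_raw`,
#'   `dff_eroded` (percentage points, follow-up minus baseline),
#'   `flagged` for muscles empty (before or after erosion) at either
#'   timepoint, whose deltas are `NA`.
#' @export
erosion_sensitivity <- function(water, fat, labelmap,
                                water2, fat2, labelmap2,
                                spec = erosion_spec("radial_mm", 4)) {
  er1 <- erode_labels(labelmap, spec)
  er2 <- erode_labels(labelmap2, spec)
  ff_of <- function(w, f, lm, code) {
    if (!any(lm$labels == code)) return(NA_real_)
    muscle_composition(w, f, lm, code)$fat_fraction_pct
  }
  codes <- sort(intersect(labelmap$dictionary$code, labelmap2$dictionary$code))
  rows <- lapply(codes, function(code) {
    r1 <- ff_of(water, fat, labelmap, code);  r2 <- ff_of(water2, fat2, labelmap2, code)
    e1 <- ff_of(water, fat, er1, code);       e2 <- ff_of(water2, fat2, er2, code)
    flagged <- any(is.na(c(r1, r2, e1, e2)))
    data.frame(code = code,
               dff_raw = if (flagged) NA_real_ else r2 - r1,
               dff_eroded = if (flagged) NA_real_ else e2 - e1,
               flagged = flagged)
  })
  do.call(rbind, rows)
}
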