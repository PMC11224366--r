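## Slice-wise CSA decomposition and length-normalized (0-100%) profiles.

#' Per-slice cross-sectional metrics of one muscle
#'
#' For every axial slice containing labeled voxels: boundary CSA is the
#' labeled pixel count times the pixel area; area fat fraction is the
#' voxelwise FF mean restricted to the slice; fat and lean CSA split the
#' boundary CSA by FF exactly as volumes do, so lean + fat = boundary on
#' every slice.
#'
#' @inheritParams muscle_composition
#' @param min_voxels minimum labeled voxels for a slice to count as
#'   "muscle present" (default 1; end effects are normally handled by
#'   [trim_profile] instead).
#' @return data.frame ordered inferior to superior: `slice`,
#'   `z_mm` (physical axial position), `n_voxels`, `boundary_csa_mm2`,
#'   `lean_csa_mm2`, `fat_csa_mm2`, `area_ff_pct`, `excluded_voxels`.
#' @export
slice_metrics <- function(water, fat, labelmap, code, min_voxels = 1L) {
  check_same_grid(water, list(data = labelmap$labels, spacing = labelmap$spacing),
                  "image and label map")
  mask <- code_mask(labelmap, code)
  if (!any(mask))
    mq_stop(sprintf("muscle code %d has no labeled voxels", code),
            "mq_empty_muscle_error")
  ff <- voxel_ff(water, fat, mask)
  nz <- dim(mask)[3]
  counts <- vapply(seq_len(nz), function(k) sum(mask[, , k]), integer(1))
  occ <- which(counts >= max(1L, min_voxels))
  pa <- pixel_area(water)
  zpos <- slice_positions(water)
  rows <- lapply(occ, function(k) {
    mk <- mask[, , k]
    exk <- ff$excluded[, , k] & mk
    vals <- ff$values[, , k][mk & !exk]
    affk <- if (length(vals)) mean(vals) else NA_real_
    bcsa <- counts[k] * pa
    data.frame(slice = k, z_mm = zpos[k], n_voxels = counts[k],
               boundary_csa_mm2 = bcsa,
               lean_csa_mm2 = bcsa * (1 - affk / 100),
               fat_csa_mm2 = bcsa * affk / 100,
               area_ff_pct = affk,
               excluded_voxels = sum(exk))
  })
  out <- do.call(rbind, rows)
  ## inferior first regardless of storage direction
  if (labelmap$superior_direction < 0) out <- out[rev(seq_len(nrow(out))), ]
  rownames(out) <- NULL
  out
}

profile_metric_names <- c("boundary_csa_mm2", "lean_csa_mm2",
                          "fat_csa_mm2", "area_ff_pct")

#' Length-normalized profile (0-100% of muscle length)
#'
#' Slice positions are mapped to percent of muscle length, 0% at the
#' inferior-most occupied slice and 100% at the superior-most, using
#' physical axial positions (mm) so gapped or anisotropic acquisitions
#' normalize correctly. Each metric is interpolated piecewise-linearly
#' onto the 1% grid; linearity preserves the lean + fat = boundary
#' closure at every grid point.
#'
#' @param slices output of [slice_metrics].
#' @return object of class `length_profile`: `percent` (0:100), one
#'   numeric vector per metric, `inferior_slice`, `superior_slice`,
#'   `length_mm`, and the source `slices`.
#' @export
normalize_profile <- function(slices) {
  if (!is.data.frame(slices) || nrow(slices) < 1L)
    mq_stop("need at least one occupied slice", "mq_empty_muscle_error")
  grid <- 0:100
  prof <- list(percent = grid)
  if (nrow(slices) == 1L) {
    mq_warn("single-slice muscle: profile is constant")
    for (m in profile_metric_names) prof[[m]] <- rep(slices[[m]], 101L)
  } else {
    span <- slices$z_mm[nrow(slices)] - slices$z_mm[1]
    pct <- 100 * (slices$z_mm - slices$z_mm[1]) / span
    for (m in profile_metric_names)
      prof[[m]] <- approx(pct, slices[[m]], xout = grid, rule = 2)$y
  }
  prof$inferior_slice <- slices$slice[1]
  prof$superior_slice <- slices$slice[nrow(slices)]
  prof$length_mm <- abs(slices$z_mm[nrow(slices)] - slices$z_mm[1])
  prof$slices <- slices
  structure(prof, class = "length_profile")
}

#' Trim a profile to a central percent range
#'
#' The muscle ends contribute tiny CSAs that amplify relative errors, so
#' plots and end-insensitive summaries use the central 10-90% span by
#' default. The untrimmed profile is retained in `$full` for metrics.
#'
#' @param profile a [normalize_profile] result.
#' @param low,high integer percent bounds, `0 <= low < high <= 100`.
#' @return a `length_profile` restricted to `low:high`.
#' @export
trim_profile <- function(profile, low = 10, high = 90) {
  if (!(low >= 0 && high <= 100 && low < high))
    mq_stop("need 0 <= low < high <= 100", "mq_parameter_error")
  keep <- profile$percent >= low & profile$percent <= high
  out <- profile
  out$percent <- profile$percent[keep]
  for (m in profile_metric_names) out[[m]] <- profile[[m]][keep]
  out$full <- if (is.null(profile$full)) profile else profile$full
  out
}

#' Per-percent profile differences (follow-up minus baseline)
#'
#' @param baseline,followup [length_profile]s on the same percent grid.
#' @return data.frame: `percent` plus the four metric deltas.
#' @export
profile_delta <- function(baseline, followup) {
  if (!identical(baseline$percent, followup$percent))
    mq_stop("profiles are not on the same percent grid", "mq_alignment_error")
  out <- data.frame(percent = baseline$percent)
  for (m in profile_metric_names)
    out[[paste0("d_", m)]] <- followup[[m]] - baseline[[m]]
  out
}

#' @export
print.length_profile <- function(x, ...) {
  cat(sprintf("<length_profile> %d points (%d-%d%%), length %.1f mm, slices %d..%d\n",
              length(x$percent), min(x$percent), max(x$percent),
              x$length_mm, x$inferior_slice, x$superior_slice))
  invisible(x)
}

#' Plot a length-normalized profile
#'
#' CSA panel (boundary/lean/fat) and area-FF panel against percent of
#' muscle length, optionally overlaying a follow-up profile (dashed) and
#' shaded error clouds (+-5% of CSA, +-2.5 FF points by default).
#'
#' @param x a `length_profile`.
#' @param followup optional second profile on the same grid.
#' @param band_csa,band_ff half-widths of the shaded clouds; `NULL` to omit.
#' @param ... unused.
#' @export
plot.length_profile <- function(x, followup = NULL, band_csa = 5,
                                band_ff = 2.5, ...) {
  op <- graphics::par(mfrow = c(2, 1), mar = c(4, 4, 1.5, 1))
  on.exit(graphics::par(op))
  p <- x$percent
  ylim <- range(0, x$boundary_csa_mm2, followup$boundary_csa_mm2)
  graphics::plot(p, x$boundary_csa_mm2, type = "n", ylim = ylim,
                 xlab = "muscle length (%)", ylab = "CSA (mm²)")
  shade <- function(y, frac, col) {
    if (!is.null(frac))
      graphics::polygon(c(p, rev(p)), c(y * (1 + frac / 100), rev(y * (1 - frac / 100))),
                        col = col, border = NA)
  }
  shade(x$lean_csa_mm2, band_csa, grDevices::adjustcolor("firebrick", 0.15))
  shade(x$fat_csa_mm2, band_csa, grDevices::adjustcolor("goldenrod", 0.15))
  graphics::lines(p, x$boundary_csa_mm2, col = "grey30")
  graphics::lines(p, x$lean_csa_mm2, col = "firebrick")
  graphics::lines(p, x$fat_csa_mm2, col = "goldenrod3")
  if (!is.null(followup)) {
    graphics::lines(p, followup$boundary_csa_mm2, col = "grey30", lty = 2)
    graphics::lines(p, followup$lean_csa_mm2, col = "firebrick", lty = 2)
    graphics::lines(p, followup$fat_csa_mm2, col = "goldenrod3", lty = 2)
  }
  graphics::legend("topright", bty = "n", lty = 1, cex = 0.8,
                   col = c("grey30", "firebrick", "goldenrod3"),
                   legend = c("boundary", "lean", "fat"))
  graphics::plot(p, x$area_ff_pct, type = "n", ylim = c(0, 100),
                 xlab = "muscle length (%)", ylab = "area fat fraction (%)")
  if (!is.null(band_ff))
    graphics::polygon(c(p, rev(p)),
                      c(pmin(100, x$area_ff_pct + band_ff),
                        rev(pmax(0, x$area_ff_pct - band_ff))),
                      col = grDevices::adjustcolor("steelblue", 0.15), border = NA)
  graphics::lines(p, x$area_ff_pct, col = "steelblue4")
  if (!is.null(followup))
    graphics::lines(p, followup$area_ff_pct, col = "steelblue4", lty = 2)
  invisible(x)
}
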