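## Per-muscle composition: boundary volume, fat fraction (voxelwise-ratio
## mean of fat / (fat + water), in percent), fat and lean volumes.

check_same_grid <- function(a, b, what = "volumes") {
  if (!identical(dim(a$data), dim(b$data)) ||
      any(abs(a$spacing - b$spacing) > 1e-4))
    mq_stop(sprintf("%s are not on the same grid", what), "mq_alignment_error")
  invisible(TRUE)
}

#' Voxelwise fat-fraction map
#'
#' For every voxel in `mask`, FF = fat / (fat + water) * 100. Voxels
#' where fat + water == 0 carry no defined FF: they are marked excluded
#' and left `NA` rather than propagated.
#'
#' @param water,fat co-registered Dixon component [volumetric_image]s.
#' @param mask logical 3D array, same shape.
#' @return object of class `ff_map`: fields `values` (3D array, percent,
#'   `NA` outside mask and at excluded voxels), `mask`, `excluded`
#'   (logical array of in-mask zero-signal voxels), `spacing`.
#' @export
voxel_ff <- function(water, fat, mask) {
  check_same_grid(water, fat, "water/fat volumes")
  if (!identical(dim(mask), dim(water$data)))
    mq_stop("mask shape does not match the image grid", "mq_alignment_error")
  if (!any(mask)) mq_stop("mask is empty", "mq_empty_muscle_error")
  total <- water$data + fat$data
  excluded <- mask & total == 0
  values <- array(NA_real_, dim(mask))
  ok <- mask & !excluded
  values[ok] <- fat$data[ok] / total[ok] * 100
  structure(list(values = values, mask = mask, excluded = excluded,
                 spacing = water$spacing),
            class = "ff_map")
}

#' Per-muscle composition metrics
#'
#' Boundary volume is the labeled voxel count times the voxel volume
#' (zero-signal voxels included). The muscle fat fraction is the mean of
#' the voxelwise FF ratio over voxels with nonzero total signal; fat and
#' lean volumes split the boundary volume by FF/100 and 1 - FF/100, so
#' fat + lean = boundary by construction.
#'
#' @param water,fat Dixon component images.
#' @param labelmap a [muscle_labelmap] on the same grid.
#' @param code muscle code to quantify.
#' @param on_zero_signal what to do when every voxel of the muscle has
#'   zero total signal: `"na"` (FF and the derived volumes become `NA`,
#'   with a warning) or `"error"`.
#' @return one-row data.frame: `code`, `name`, `side`, `tp` (voxels with
#'   defined FF), `excluded_voxels`, `boundary_volume_mm3`,
#'   `fat_fraction_pct`, `fat_volume_mm3`, `lean_volume_mm3`, `present`.
#' @export
muscle_composition <- function(water, fat, labelmap, code,
                               on_zero_signal = c("na", "error")) {
  on_zero_signal <- match.arg(on_zero_signal)
  check_same_grid(water, list(data = labelmap$labels, spacing = labelmap$spacing),
                  "image and label map")
  mask <- code_mask(labelmap, code)
  row <- labelmap$dictionary[labelmap$dictionary$code == code, ]
  if (!any(mask))
    mq_stop(sprintf("muscle code %d (%s) has no labeled voxels", code, row$name),
            "mq_empty_muscle_error")
  ff <- voxel_ff(water, fat, mask)
  n_total <- sum(mask)
  n_excl <- sum(ff$excluded)
  tp <- n_total - n_excl
  bv <- n_total * voxel_volume(water)
  if (tp == 0L) {
    if (on_zero_signal == "error")
      mq_stop(sprintf("muscle code %d has zero total signal everywhere", code),
              "mq_validation_error")
    mq_warn(sprintf("muscle code %d has zero total signal everywhere; FF undefined", code))
    ffm <- NA_real_
  } else {
    ffm <- mean(ff$values[ff$mask & !ff$excluded])
  }
  data.frame(code = as.integer(code), name = row$name, side = row$side,
             tp = tp, excluded_voxels = n_excl,
             boundary_volume_mm3 = bv,
             fat_fraction_pct = ffm,
             fat_volume_mm3 = bv * ffm / 100,
             lean_volume_mm3 = bv * (1 - ffm / 100),
             present = TRUE,
             stringsAsFactors = FALSE)
}

#' Fat-fraction histogram
#'
#' Uniform bins `[0,w), [w,2w), ..., [100-w, 100]` (last bin closed) over
#' the defined FF values of a map. Counts always sum to the number of
#' valued voxels.
#'
#' @param ffmap an [voxel_ff] result.
#' @param bin_width bin width in percent; must divide 100.
#' @return object of class `ff_histogram`: `bin_edges`, `counts`,
#'   `normalized`, `tp`.
#' @export
ff_histogram <- function(ffmap, bin_width = 1) {
  if (bin_width <= 0 || abs(100 / bin_width - round(100 / bin_width)) > 1e-9)
    mq_stop("bin_width must be positive and divide 100", "mq_parameter_error")
  v <- ffmap$values[ffmap$mask & !ffmap$excluded]
  edges <- seq(0, 100, by = bin_width)
  nb <- length(edges) - 1L
  if (length(v) == 0L) {
    mq_warn("empty fat-fraction map: returning empty histogram")
    counts <- integer(nb)
  } else {
    idx <- pmin(nb, findInterval(v, edges, rightmost.closed = FALSE)) # fold 100 into last bin
    counts <- tabulate(idx, nbins = nb)
  }
  structure(list(bin_edges = edges, counts = counts,
                 normalized = if (sum(counts) > 0) counts / sum(counts) else rep(0, nb),
                 tp = length(v)),
            class = "ff_histogram")
}

#' Composition table for every dictionary code
#'
#' One record per dictionary code in ascending order. Muscles listed in
#' the dictionary but absent from the grid yield flagged zero rows
#' (`present = FALSE`) rather than errors, keeping multi-site tables
#' rectangular when coverage differs.
#'
#' @inheritParams muscle_composition
#' @return data.frame, one row per dictionary code.
#' @export
composition_table <- function(water, fat, labelmap,
                              on_zero_signal = c("na", "error")) {
  on_zero_signal <- match.arg(on_zero_signal)
  cnt <- label_counts(labelmap)
  rows <- lapply(seq_len(nrow(cnt)), function(i) {
    if (cnt$voxels[i] == 0L) {
      data.frame(code = cnt$code[i], name = cnt$name[i], side = cnt$side[i],
                 tp = 0L, excluded_voxels = 0L, boundary_volume_mm3 = 0,
                 fat_fraction_pct = NA_real_, fat_volume_mm3 = NA_real_,
                 lean_volume_mm3 = NA_real_, present = FALSE,
                 stringsAsFactors = FALSE)
    } else {
      muscle_composition(water, fat, labelmap, cnt$code[i],
                         on_zero_signal = on_zero_signal)
    }
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
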