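## Volumetric data model: 3D scalar grids with voxel spacing.

#' Construct a volumetric image
#'
#' A `volumetric_image` is a 3D scalar grid (signal intensity, arbitrary
#' units) with per-axis voxel spacing in mm. Internally the array is
#' always stored with the axial (inferior--superior) axis third; if the
#' input has its axial axis elsewhere, the array is permuted at
#' construction so every downstream operation can assume the canonical
#' (x, y, z) layout.
#'
#' @param data 3D numeric array.
#' @param spacing length-3 positive numeric, voxel size in mm per axis
#'   (in the order of the axes of `data`).
#' @param axial_axis which axis of `data` runs inferior--superior
#'   (1, 2 or 3; default 3).
#' @param superior_direction +1 if increasing slice index is superior,
#'   -1 otherwise.
#' @param kind optional content tag, one of `"dixon_water"`,
#'   `"dixon_fat"`, `"stir"`, `"label"` or `NULL`. Dixon and STIR signal
#'   images must be non-negative.
#' @return An object of class `volumetric_image` with fields `data`,
#'   `spacing` (x, y, z after canonicalization), `superior_direction`
#'   and `kind`.
#' @export
volumetric_image <- function(data, spacing, axial_axis = 3L,
                             superior_direction = 1L, kind = NULL) {
  if (!is.array(data) || length(dim(data)) != 3L)
    mq_stop(sprintf("expected a 3D array, got %d dimension(s)",
                    length(dim(data))), "mq_dimensionality_error")
  spacing <- as.numeric(spacing)
  if (length(spacing) != 3L || any(!is.finite(spacing)) || any(spacing <= 0))
    mq_stop("voxel spacing must be three strictly positive values (mm)",
            "mq_header_error")
  if (!axial_axis %in% 1:3)
    mq_stop("axial_axis must be 1, 2 or 3", "mq_parameter_error")
  if (!superior_direction %in% c(-1L, 1L))
    mq_stop("superior_direction must be +1 or -1", "mq_parameter_error")
  if (axial_axis != 3L) {
    perm <- c(setdiff(1:3, axial_axis), axial_axis)
    data <- aperm(data, perm)
    spacing <- spacing[perm]
  }
  if (any(!is.finite(data)))
    mq_stop("volume contains non-finite values", "mq_validation_error")
  if (!is.null(kind)) {
    kind <- match.arg(kind, c("dixon_water", "dixon_fat", "stir", "label"))
    if (kind %in% c("dixon_water", "dixon_fat", "stir") && any(data < 0))
      mq_stop(sprintf("negative intensities in %s volume", kind),
              "mq_validation_error")
  }
  structure(list(data = data, spacing = spacing,
                 superior_direction = as.integer(superior_direction),
                 kind = kind),
            class = "volumetric_image")
}

#' @export
print.volumetric_image <- function(x, ...) {
  cat(sprintf("<volumetric_image%s> %s voxels @ (%g, %g, %g) mm, range [%g, %g]\n",
              if (is.null(x$kind)) "" else paste0(" ", x$kind),
              paste(dim(x$data), collapse = "x"),
              x$spacing[1], x$spacing[2], x$spacing[3],
              min(x$data), max(x$data)))
  invisible(x)
}

#' Voxel volume and pixel area
#'
#' `voxel_volume()` is the product of all three spacings (mm^3);
#' `pixel_area()` the product of the two in-plane spacings (mm^2), so
#' `voxel_volume(x) == pixel_area(x) * x$spacing[3]` exactly.
#'
#' @param x a `volumetric_image` or `muscle_labelmap`.
#' @return scalar, mm^3 resp. mm^2.
#' @export
voxel_volume <- function(x) pixel_area(x) * x$spacing[3]

#' @rdname voxel_volume
#' @export
pixel_area <- function(x) x$spacing[1] * x$spacing[2]

## Plain array from an RNifti image (drop header attributes/pointer).
strip_nifti <- function(img) {
  arr <- as.array(img)
  d <- dim(arr)
  a <- as.vector(arr)
  dim(a) <- d
  a
}

#' Physical axial positions of slice centres
#'
#' Slice k sits at (k - 1) * axial spacing, in mm.
#' @noRd
slice_positions <- function(x) (seq_len(dim(x$data)[3]) - 1) * x$spacing[3]

#' Load a 3D NIfTI volume
#'
#' Reads a NIfTI-1 volume, takes voxel spacing from the header, and
#' validates it as a signal carrier of the given kind. Dixon and STIR
#' inputs must be non-negative.
#'
#' @param path path to a `.nii` / `.nii.gz` file.
#' @param kind `"dixon_water"`, `"dixon_fat"` or `"stir"`.
#' @param axial_axis,superior_direction orientation overrides; by
#'   default the third array axis is taken as axial with increasing
#'   index superior.
#' @return a [volumetric_image].
#' @export
load_volume <- function(path, kind = c("dixon_water", "dixon_fat", "stir"),
                        axial_axis = 3L, superior_direction = 1L) {
  kind <- match.arg(kind)
  if (!file.exists(path))
    mq_stop(sprintf("file not found: %s", path), "mq_io_error")
  img <- RNifti::readNifti(path)
  arr <- strip_nifti(img)
  if (length(dim(arr)) != 3L)
    mq_stop(sprintf("%s: expected a 3D volume, got %dD", path,
                    length(dim(arr))), "mq_dimensionality_error")
  sp <- RNifti::pixdim(img)[1:3]
  if (any(!is.finite(sp)) || any(sp <= 0))
    mq_stop(sprintf("%s: non-positive voxel spacing in header", path),
            "mq_header_error")
  mq_log("loaded ", kind, " volume ", paste(dim(arr), collapse = "x"),
         " from ", path)
  volumetric_image(arr, sp, axial_axis = axial_axis,
                   superior_direction = superior_direction, kind = kind)
}

#' Write a volumetric image or label map to NIfTI
#'
#' Signal volumes are written as float64 so that a save/load round trip
#' is bit-identical; label maps as int32.
#'
#' @param x a `volumetric_image`, `muscle_labelmap`, or bare 3D array.
#' @param path output `.nii` / `.nii.gz` path.
#' @param spacing required when `x` is a bare array.
#' @return `path`, invisibly.
#' @export
write_volume <- function(x, path, spacing = NULL) {
  if (inherits(x, "muscle_labelmap")) {
    arr <- x$labels; sp <- x$spacing; dt <- "int32"
  } else if (inherits(x, "volumetric_image")) {
    arr <- x$data; sp <- x$spacing; dt <- "double"
  } else {
    arr <- x; sp <- spacing; dt <- if (is.integer(arr)) "int32" else "double"
    if (is.null(sp)) mq_stop("spacing required for bare arrays", "mq_parameter_error")
  }
  img <- RNifti::asNifti(arr)
  RNifti::pixdim(img) <- sp
  RNifti::writeNifti(img, path, datatype = dt)
  invisible(path)
}
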