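## Muscle label maps: 3D integer grids plus a code -> (name, side) dictionary.

#' Construct a muscle label map
#'
#' @param labels 3D integer array; 0 is background, positive codes are
#'   muscles. Must match the reference image's shape and spacing.
#' @param dictionary data.frame with columns `code` (positive integer),
#'   `name` (muscle name) and `side` (`"left"`, `"right"` or
#'   `"midline"`). Every nonzero code present in `labels` must appear.
#' @param spacing length-3 voxel spacing in mm.
#' @param superior_direction +1 if increasing slice index is superior.
#' @return object of class `muscle_labelmap` with fields `labels`,
#'   `dictionary`, `spacing`, `superior_direction`.
#' @export
muscle_labelmap <- function(labels, dictionary, spacing,
                            superior_direction = 1L) {
  if (!is.array(labels) || length(dim(labels)) != 3L)
    mq_stop("labels must be a 3D array", "mq_dimensionality_error")
  storage.mode(labels) <- "integer"
  dictionary <- validate_dictionary(dictionary)
  present <- sort(unique(labels[labels != 0L]))
  orphan <- setdiff(present, dictionary$code)
  if (length(orphan))
    mq_stop(sprintf("label codes present in grid but absent from dictionary: [%s]",
                    paste(orphan, collapse = ", ")), "mq_dictionary_error")
  spacing <- as.numeric(spacing)
  if (length(spacing) != 3L || any(spacing <= 0))
    mq_stop("spacing must be three positive values (mm)", "mq_header_error")
  structure(list(labels = labels, dictionary = dictionary, spacing = spacing,
                 superior_direction = as.integer(superior_direction)),
            class = "muscle_labelmap")
}

validate_dictionary <- function(dictionary) {
  if (!is.data.frame(dictionary) ||
      !all(c("code", "name", "side") %in% names(dictionary)))
    mq_stop("dictionary must be a data.frame with columns code, name, side",
            "mq_dictionary_error")
  dictionary$code <- as.integer(dictionary$code)
  if (any(dictionary$code <= 0L) || anyDuplicated(dictionary$code))
    mq_stop("dictionary codes must be unique positive integers (0 is background)",
            "mq_dictionary_error")
  if (!all(dictionary$side %in% c("left", "right", "midline")))
    mq_stop("dictionary side must be left, right or midline", "mq_dictionary_error")
  dictionary <- dictionary[order(dictionary$code),
                           c("code", "name", "side"), drop = FALSE]
  rownames(dictionary) <- NULL
  dictionary
}

#' @export
print.muscle_labelmap <- function(x, ...) {
  n <- label_counts(x)
  cat(sprintf("<muscle_labelmap> %s voxels @ (%g, %g, %g) mm, %d code(s), %d present\n",
              paste(dim(x$labels), collapse = "x"),
              x$spacing[1], x$spacing[2], x$spacing[3],
              nrow(x$dictionary), sum(n$voxels > 0)))
  invisible(x)
}

#' Per-code voxel counts
#'
#' One row per dictionary code (code ascending), including codes absent
#' from the grid (0 voxels).
#' @param labelmap a [muscle_labelmap].
#' @return data.frame with columns `code`, `name`, `side`, `voxels`.
#' @export
label_counts <- function(labelmap) {
  tab <- tabulate(labelmap$labels, nbins = max(labelmap$dictionary$code))
  data.frame(labelmap$dictionary,
             voxels = tab[labelmap$dictionary$code],
             stringsAsFactors = FALSE)
}

#' Load a label map plus its JSON dictionary sidecar
#'
#' The label grid must match the reference image's shape, and its
#' spacing must agree within 1e-4 mm (absorbing header float noise).
#' Every nonzero code in the grid must appear in the dictionary.
#'
#' @param path NIfTI label volume.
#' @param dictionary_path JSON sidecar: an array of objects with fields
#'   `code`, `name`, `side`.
#' @param reference the [volumetric_image] the labels were drawn on.
#' @return a validated [muscle_labelmap]; per-code voxel counts are
#'   logged when verbose.
#' @export
load_labelmap <- function(path, dictionary_path, reference) {
  img <- RNifti::readNifti(path)
  arr <- strip_nifti(img)
  if (length(dim(arr)) != 3L)
    mq_stop(sprintf("%s: expected a 3D label volume", path),
            "mq_dimensionality_error")
  sp <- RNifti::pixdim(img)[1:3]
  if (!identical(dim(arr), dim(reference$data)))
    mq_stop(sprintf("label grid %s does not match reference %s",
                    paste(dim(arr), collapse = "x"),
                    paste(dim(reference$data), collapse = "x")),
            "mq_alignment_error")
  if (any(abs(sp - reference$spacing) > 1e-4))
    mq_stop(sprintf("label spacing (%s) mm differs from reference (%s) mm by more than 1e-4",
                    paste(signif(sp, 6), collapse = ", "),
                    paste(signif(reference$spacing, 6), collapse = ", ")),
            "mq_alignment_error")
  dict <- read_label_dictionary(dictionary_path)
  lm <- muscle_labelmap(arr, dict, reference$spacing,
                        superior_direction = reference$superior_direction)
  cnt <- label_counts(lm)
  mq_log("label map ", path, ": ",
         paste(sprintf("%d=%d", cnt$code, cnt$voxels), collapse = " "))
  lm
}

#' Read / write a label dictionary JSON sidecar
#'
#' @param path JSON file: array of `{code, name, side}` objects.
#' @return data.frame with columns `code`, `name`, `side`.
#' @export
read_label_dictionary <- function(path) {
  if (!file.exists(path))
    mq_stop(sprintf("dictionary not found: %s", path), "mq_io_error")
  validate_dictionary(jsonlite::fromJSON(path))
}

#' @rdname read_label_dictionary
#' @param dictionary data.frame to write.
#' @export
write_label_dictionary <- function(dictionary, path) {
  dictionary <- validate_dictionary(dictionary)
  jsonlite::write_json(dictionary, path, auto_unbox = FALSE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' Binary mask of one muscle code
#' @noRd
code_mask <- function(labelmap, code) {
  if (!code %in% labelmap$dictionary$code)
    mq_stop(sprintf("code %d not in dictionary", code), "mq_dictionary_error")
  labelmap$labels == code
}
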