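#' Write and read BOLD runs as NIfTI
#'
#' `write_bold()` stores the 4D data as NIfTI-1 (tr in the 4th pixdim), the
#' brain mask as `<stem>_mask.nii.gz`, and subject metadata in a JSON sidecar
#' `<stem>.json`. `read_bold()` restores the `bold_series`.
#'
#' @param series A `bold_series`.
#' @param path Path to the `.nii` / `.nii.gz` file.
#' @return `write_bold()` returns `path` invisibly; `read_bold()` a
#'   `bold_series`.
#' @export
write_bold <- function(series, path) {
  stopifnot(inherits(series, "bold_series"))
  img <- RNifti::asNifti(series$data, pixdim = c(1, 1, 1, series$tr))
  RNifti::writeNifti(img, path)
  stem <- sub("\\.nii(\\.gz)?$", "", path)
  RNifti::writeNifti(RNifti::asNifti(array(as.integer(series$brain_mask),
                                           dim = dim(series$brain_mask))),
                     paste0(stem, "_mask.nii.gz"), datatype = "uint8")
  jsonlite::write_json(
    list(subject_id = series$subject_id, group = series$group, tr = series$tr),
    paste0(stem, ".json"), auto_unbox = TRUE)
  invisible(path)
}

#' @rdname write_bold
#' @export
read_bold <- function(path) {
  img <- RNifti::readNifti(path)
  d <- dim(img)
  if (length(d) != 4L)
    abort(sprintf("`data`: expected a 4D BOLD file, got %d dimensions", length(d)))
  stem <- sub("\\.nii(\\.gz)?$", "", path)
  side <- paste0(stem, ".json")
  meta <- if (file.exists(side)) jsonlite::read_json(side) else list()
  tr <- meta$tr %||% RNifti::pixdim(img)[4]
  maskfile <- paste0(stem, "_mask.nii.gz")
  mask <- if (file.exists(maskfile)) {
    array(as.logical(RNifti::readNifti(maskfile)), dim = d[1:3])
  } else {
    array(TRUE, dim = d[1:3])
  }
  structure(
    list(data = array(as.numeric(img), dim = d), tr = as.numeric(tr),
         brain_mask = mask,
         subject_id = meta$subject_id %||% basename(stem),
         group = meta$group %||% "control"),
    class = "bold_series"
  )
}

#' Write and read a label atlas as NIfTI
#'
#' The label volume is stored as integer NIfTI (exact round-trip), the brain
#' mask as `<stem>_mask.nii.gz`, and the structure-to-network registry as a
#' JSON sidecar.
#'
#' @param atlas An `atlas_set`.
#' @param path Path to the `.nii` / `.nii.gz` file.
#' @return `write_atlas()` returns `path` invisibly; `read_atlas()` an
#'   `atlas_set`.
#' @export
write_atlas <- function(atlas, path) {
  stopifnot(inherits(atlas, "atlas_set"))
  RNifti::writeNifti(RNifti::asNifti(atlas$labels), path, datatype = "int32")
  stem <- sub("\\.nii(\\.gz)?$", "", path)
  RNifti::writeNifti(RNifti::asNifti(array(as.integer(atlas$brain_mask),
                                           dim = atlas$dims)),
                     paste0(stem, "_mask.nii.gz"), datatype = "uint8")
  jsonlite::write_json(atlas$structures, paste0(stem, ".json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_atlas
#' @export
read_atlas <- function(path) {
  img <- RNifti::readNifti(path)
  d <- dim(img)
  if (length(d) != 3L)
    abort(sprintf("`labels`: expected a 3D label file, got %d dimensions", length(d)))
  stem <- sub("\\.nii(\\.gz)?$", "", path)
  side <- paste0(stem, ".json")
  if (!file.exists(side))
    abort(sprintf("`structures`: missing registry sidecar '%s'", side))
  structures <- as_tibble(jsonlite::read_json(side, simplifyVector = TRUE))
  maskfile <- paste0(stem, "_mask.nii.gz")
  mask <- if (file.exists(maskfile)) {
    array(as.logical(RNifti::readNifti(maskfile)), dim = d)
  } else {
    array(img > 0, dim = d)
  }
  structure(
    list(labels = array(as.integer(img), dim = d), brain_mask = mask,
         structures = structures, dims = as.integer(d)),
    class = "atlas_set"
  )
}
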