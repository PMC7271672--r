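# Thin NIfTI wrappers (RNifti) used by every stage for standard-format I/O.

#' Read a NIfTI volume
#'
#' @param path path to a `.nii` / `.nii.gz` file.
#' @return List with `data` (plain numeric array) and `affine` (4x4
#'   voxel-to-world matrix).
#' @export
read_nifti_volume <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  img <- tryCatch(RNifti::readNifti(path),
                  error = function(e) stop("not a readable NIfTI file: ",
                                           path, " (", conditionMessage(e), ")"))
  aff <- structure(RNifti::xform(img), class = NULL)
  list(data = array(as.numeric(img), dim(img)), affine = unclass(aff))
}

#' Write a NIfTI volume
#'
#' @param volume numeric array (3D or 4D).
#' @param affine 4x4 voxel-to-world matrix; a diagonal voxel-size affine
#'   is typical for synthetic data.
#' @param path destination path (`.nii` or `.nii.gz`).
#' @return `path`, invisibly.
#' @export
write_nifti_volume <- function(volume, affine, path) {
  stopifnot(length(dim(volume)) %in% c(3, 4), all(dim(affine) == c(4, 4)))
  img <- RNifti::asNifti(volume)
  RNifti::pixdim(img) <- affine_voxel_size(affine)
  RNifti::qform(img) <- structure(affine, code = 2L)
  img <- RNifti::`sform<-`(img, structure(affine, code = 2L))
  RNifti::writeNifti(img, path, datatype = "double")
  invisible(path)
}

# voxel sizes (mm) from a diagonal-ish affine
affine_voxel_size <- function(affine) {
  sqrt(colSums(affine[1:3, 1:3]^2))
}
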