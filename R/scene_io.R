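# plain array from a niftiImage (drop header attributes)
strip_nifti <- function(img) {
  a <- as.array(img)
  array(as.vector(a), dim = dim(a))
}

#' Write / read a tissue scene
#'
#' Serializes a [tissue_grid] as a multi-channel NIfTI volume (one channel
#' per material fraction, 4th dimension), a label NIfTI, and a JSON sidecar
#' naming the channels and carrying spacing and geometry metadata. The round
#' trip is lossless for fractions, labels and spacing; fraction closure is
#' re-validated on read so externally produced scenes are accepted only if
#' their channels sum to 1.
#'
#' @param grid a [tissue_grid]
#' @param path basename for the scene files; writes `<path>_fractions.nii.gz`,
#'   `<path>_labels.nii.gz`, `<path>.json`
#' @return `write_scene`: `path`, invisibly. `read_scene`: a [tissue_grid].
#' @export
write_scene <- function(grid, path) {
  validate_tissue_grid(grid)
  fr_img <- RNifti::asNifti(grid$fractions,
                            pixdim = c(grid$spacing, 1))
  RNifti::writeNifti(fr_img, paste0(path, "_fractions.nii.gz"))
  lab_img <- RNifti::asNifti(grid$labels + 0L, pixdim = grid$spacing)
  RNifti::writeNifti(lab_img, paste0(path, "_labels.nii.gz"))
  sidecar <- list(format = "pdtsim-scene", version = 1L,
                  channels = pdt_materials(),
                  spacing_cm = grid$spacing,
                  regions = as.list(region_names()),
                  meta = grid$meta)
  jsonlite::write_json(sidecar, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(path)
}

#' @rdname write_scene
#' @export
read_scene <- function(path) {
  side_path <- paste0(path, ".json")
  if (!file.exists(side_path)) stop("missing scene sidecar: ", side_path)
  side <- jsonlite::read_json(side_path, simplifyVector = TRUE)
  if (!identical(side$format, "pdtsim-scene"))
    stop("not a pdtsim scene sidecar: ", side_path)
  if (!identical(as.character(side$channels), pdt_materials()))
    stop("scene channels do not match the expected materials")
  fr <- strip_nifti(RNifti::readNifti(paste0(path, "_fractions.nii.gz")))
  lab_arr <- strip_nifti(RNifti::readNifti(paste0(path, "_labels.nii.gz")))
  storage.mode(lab_arr) <- "integer"
  if (length(dim(fr)) != 4L || dim(fr)[4] != 5L)
    stop("fraction volume must have 5 material channels")
  if (!identical(dim(lab_arr), dim(fr)[1:3]))
    stop("label volume shape does not match the fraction channels")
  dimnames(fr) <- list(NULL, NULL, NULL, pdt_materials())
  spacing <- as.numeric(side$spacing_cm)
  meta <- side$meta
  grid <- new_tissue_grid(fr, lab_arr, spacing,
                          meta = if (is.null(meta)) list() else meta)
  validate_tissue_grid(grid, tol = 1e-5)  # float storage round-off
  grid
}
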