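# NIfTI and JSON input/output for the pipeline artefacts.

#' Write a volume to NIfTI
#'
#' Accepts a [CTScan-class], a [HabitatMap-class], a [SuperpixelMap-class],
#' a logical mask or a plain array.  Label and mask volumes are written as
#' integers.
#'
#' @param x the volume.
#' @param path output path (`.nii` or `.nii.gz`).
#' @param spacing voxel spacing in mm (taken from the object when it
#'   carries one).
#' @return the path, invisibly.
#' @export
writeVolumeNifti <- function(x, path, spacing = c(1, 1, 2.5)) {
  if (is(x, "CTScan")) { spacing <- x@spacing; x <- x@values }
  else if (is(x, "HabitatMap")) x <- x@labels
  else if (is(x, "SuperpixelMap")) x <- x@labels
  if (is.logical(x)) x <- array(as.integer(x), dim = dim(x))
  img <- RNifti::asNifti(x)
  RNifti::pixdim(img) <- spacing[seq_along(dim(x))]
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Read a volume from NIfTI
#'
#' @param path NIfTI file.
#' @return plain array with a `"spacing"` attribute (mm).
#' @export
readVolumeNifti <- function(path) {
  img <- RNifti::readNifti(path)
  sp <- RNifti::pixdim(img)
  out <- array(as.vector(img), dim = dim(img))
  attr(out, "spacing") <- sp
  out
}

#' Write / read a composite image as 4-D NIfTI
#'
#' Channel order is fixed (lung, med, lungEntropy, medEntropy) and
#' round-trips through the file.
#'
#' @param composite a [CompositeImage-class].
#' @param path NIfTI file.
#' @return `writeCompositeNifti`: the path; `readCompositeNifti`: a
#'   [CompositeImage-class].
#' @export
writeCompositeNifti <- function(composite, path) {
  stopifnot(is(composite, "CompositeImage"))
  img <- RNifti::asNifti(composite@channels)
  RNifti::pixdim(img) <- c(composite@spacing, 1)
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' @rdname writeCompositeNifti
#' @param spacing,entropyBins metadata restored on read.
#' @export
readCompositeNifti <- function(path, spacing = c(1, 1, 2.5),
                               entropyBins = 32L) {
  img <- RNifti::readNifti(path)
  sp <- RNifti::pixdim(img)
  new("CompositeImage", channels = array(as.vector(img), dim = dim(img)),
      channelNames = c("lung", "med", "lungEntropy", "medEntropy"),
      spacing = as.numeric(sp[1:3]), entropyBins = as.integer(entropyBins))
}

#' Serialize a habitat model to JSON (and back)
#'
#' The JSON carries K, the centroids, the feature names, the z-scoring
#' parameters and the fit metadata, so a model can be re-used to assign
#' habitats to new patients.
#'
#' @param model a [HabitatModel-class].
#' @param path JSON file.
#' @return `saveHabitatModel`: the path; `readHabitatModel`: the model.
#' @export
saveHabitatModel <- function(model, path) {
  stopifnot(is(model, "HabitatModel"))
  meta <- model@metadata
  if (!is.null(meta$gap)) meta$gap <- as.list(meta$gap)
  jsonlite::write_json(
    list(K = model@K, centers = model@centers,
         featureNames = model@featureNames,
         featureCenter = model@featureCenter,
         featureScale = model@featureScale, metadata = meta),
    path, digits = NA, auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}

#' @rdname saveHabitatModel
#' @export
readHabitatModel <- function(path) {
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  centers <- as.matrix(j$centers)
  colnames(centers) <- j$featureNames
  rownames(centers) <- paste0("SR", seq_len(j$K))
  new("HabitatModel", K = as.integer(j$K), centers = centers,
      featureNames = as.character(j$featureNames),
      featureCenter = stats::setNames(as.numeric(j$featureCenter),
                                      j$featureNames),
      featureScale = stats::setNames(as.numeric(j$featureScale),
                                     j$featureNames),
      metadata = as.list(j$metadata))
}
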