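#' Normalize a brain volume to its global mean uptake
#'
#' Divides every voxel by the mean intensity over the brain mask, so the
#' masked mean of the returned volume is exactly 1. This removes global
#' inter-individual differences in tracer uptake before any regional
#' analysis. The operation is idempotent.
#'
#' @param volume 3D numeric array of voxel intensities.
#' @param mask logical array of the same dimensions; voxels included in the
#'   global mean. Typically `brainMask(atlas)`.
#' @return the rescaled array.
#' @export
#' @examples
#' v <- array(5, c(2, 2, 2))
#' normalizeGlobalMean(v, array(TRUE, dim(v)))  # all 1
normalizeGlobalMean <- function(volume, mask) {
  if (!identical(dim(volume), dim(mask)))
    stop("volume and mask dimensions differ")
  mask <- as.logical(mask)
  if (!any(mask)) stop("mask is empty: no voxels to average")
  if (any(!is.finite(volume[mask]))) stop("non-finite intensities inside mask")
  gm <- mean(volume[mask])
  if (!is.finite(gm) || gm <= 0)
    stop(sprintf("global mean over mask is %.4g; must be > 0", gm))
  volume / gm
}

#' Brain mask from an atlas label volume
#'
#' Default definition of the "global brain" for mean normalization: the
#' union of all nonzero atlas labels.
#'
#' @param atlas 3D integer array of region labels (0 = background).
#' @return logical array of the same dimensions.
#' @export
brainMask <- function(atlas) {
  array(atlas > 0, dim(atlas))
}

#' Extract per-region voxel intensity samples
#'
#' Splits the (already globally normalized) volume into the sample arrays
#' of each atlas region. Regions with fewer than `minVoxels` voxels are
#' dropped with a warning (or raise an error with `onSmall = "error"`):
#' kernel density estimation is unstable on tiny samples.
#'
#' @param volume 3D numeric array, same grid as `atlas`.
#' @param atlas 3D integer label array (0 = background, labels 1..R).
#' @param minVoxels minimum region size kept (default 10).
#' @param onSmall "drop" (default) or "error" for undersized regions.
#' @param subjectId subject identifier stored in the result.
#' @param lookup optional region lookup table; labels present in the lookup
#'   but absent from the atlas image produce a warning.
#' @return a [RoiSampleSet-class].
#' @export
extractRoiSamples <- function(volume, atlas, minVoxels = 10L,
                              onSmall = c("drop", "error"),
                              subjectId = "subject", lookup = NULL) {
  onSmall <- match.arg(onSmall)
  if (!identical(dim(volume), dim(atlas)))
    stop("volume and atlas grids differ: ",
         paste(dim(volume), collapse = "x"), " vs ",
         paste(dim(atlas), collapse = "x"))
  keep <- atlas > 0
  if (!any(keep)) stop("atlas contains no nonzero labels")
  labs <- as.integer(atlas[keep])
  vals <- as.numeric(volume[keep])
  samples <- split(vals, labs)           # names sorted numerically by split
  ord <- order(as.integer(names(samples)))
  samples <- samples[ord]
  if (!is.null(lookup)) {
    missing <- setdiff(lookup$label, as.integer(names(samples)))
    if (length(missing))
      warning("lookup labels absent from atlas image: ",
              paste(missing, collapse = ", "))
  }
  small <- names(samples)[lengths(samples) < minVoxels]
  if (length(small)) {
    if (onSmall == "error")
      stop("regions below minVoxels = ", minVoxels, ": ",
           paste(small, collapse = ", "))
    warning("dropping regions below minVoxels = ", minVoxels, ": ",
            paste(small, collapse = ", "))
    samples <- samples[!names(samples) %in% small]
  }
  if (!length(samples)) stop("no regions left after size filtering")
  new("RoiSampleSet", subjectId = subjectId, samples = samples,
      nRegions = length(samples))
}

#' Read a brain volume or label atlas from NIfTI
#'
#' Thin wrappers over [RNifti::readNifti()]; `readAtlasVolume()` rounds to
#' integer labels and refuses negative values.
#'
#' @param path path to a `.nii` / `.nii.gz` file.
#' @return a 3D array (numeric for volumes, integer for atlases).
#' @export
readBrainVolume <- function(path) {
  img <- RNifti::readNifti(path)
  arr <- array(as.numeric(img), dim(img))
  attr(arr, "pixdim") <- RNifti::pixdim(img)
  arr
}

#' @rdname readBrainVolume
#' @export
readAtlasVolume <- function(path) {
  img <- RNifti::readNifti(path)
  arr <- array(as.integer(round(img)), dim(img))
  if (any(arr < 0L)) stop("atlas contains negative labels")
  arr
}

#' Read a region lookup table
#'
#' Expects delimited text with header
#' `label,name,x_mni,y_mni,z_mni,lobe`.
#'
#' @param path file path.
#' @param sep field separator (default ",").
#' @return data.frame with those columns, label as integer.
#' @export
readRoiLookup <- function(path, sep = ",") {
  lk <- read.csv(path, sep = sep, stringsAsFactors = FALSE)
  need <- c("label", "name", "x_mni", "y_mni", "z_mni", "lobe")
  if (!all(need %in% names(lk)))
    stop("lookup must have columns: ", paste(need, collapse = ", "))
  lk$label <- as.integer(lk$label)
  if (anyNA(lk$label) || any(lk$label <= 0L) || anyDuplicated(lk$label))
    stop("lookup labels must be distinct positive integers")
  lk[need]
}

#' Read a subject manifest
#'
#' Delimited text with header `subject_id,image_path,group`; group must be
#' `sMCI` or `pMCI`.
#'
#' @param path file path.
#' @param sep field separator (default ",").
#' @return data.frame with those three columns.
#' @export
readManifest <- function(path, sep = ",") {
  mf <- read.csv(path, sep = sep, stringsAsFactors = FALSE)
  need <- c("subject_id", "image_path", "group")
  if (!all(need %in% names(mf)))
    stop("manifest must have columns: ", paste(need, collapse = ", "))
  if (!all(mf$group %in% c("sMCI", "pMCI")))
    stop("manifest group must be 'sMCI' or 'pMCI'")
  mf[need]
}
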