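## Reading, writing and resampling of CT volumes and lung masks.
## NIfTI-1 is the canonical on-disk format: int16 for HU images, uint8 for
## masks; voxel spacing travels in pixdim. Masks and images must share a grid
## (no registration is performed), which checkAligned() verifies.

#' Read a CT volume or segmentation mask from a NIfTI file
#'
#' Images are returned as [CTVolume-class] (HU values); masks are binarized
#' with the rule \code{value > 0} and returned as [SegmentationMask-class].
#' Voxel spacing is taken from the NIfTI pixdim field and must be strictly
#' positive.
#'
#' @param path path to a \code{.nii} or \code{.nii.gz} file.
#' @param kind \code{"image"} or \code{"mask"}.
#' @param patientId,state,observer metadata labels attached to the object
#'   (NIfTI does not carry them).
#' @return A [CTVolume-class] or [SegmentationMask-class].
#' @seealso [writeVolume()], [resampleIsotropic()]
#' @export
readVolume <- function(path, kind = c("image", "mask"), patientId = "P",
                       state = "EXP_PEEP5", observer = "REFERENCE") {
  kind <- match.arg(kind)
  if (!file.exists(path))
    stop("cannot read volume: file does not exist: ", path)
  img <- tryCatch(RNifti::readNifti(path),
                  error = function(e) stop("unreadable volume file '", path,
                                           "': ", conditionMessage(e)))
  vals <- array(as.numeric(img), dim(img))
  if (length(dim(vals)) != 3L)
    stop("expected a 3-D volume, got ", length(dim(vals)), " dimensions")
  sp <- RNifti::pixdim(img)[seq_len(3)]
  if (length(sp) < 3L || any(!is.finite(sp)) || any(sp <= 0))
    stop("metadata error: voxel spacing (pixdim) missing or non-positive in ", path)
  if (kind == "image") {
    if (any(!is.finite(vals)))
      stop("metadata error: non-finite HU values in ", path)
    CTVolume(vals, spacing = sp, patientId = patientId, state = state)
  } else {
    SegmentationMask(vals, spacing = sp, patientId = patientId, state = state,
                     observer = observer)
  }
}

#' Write a CT volume or segmentation mask to a NIfTI file
#'
#' HU volumes are stored as 16-bit integers, masks as 8-bit 0/1; spacing is
#' written to pixdim so the round trip is lossless for integer HU.
#'
#' @param object a [CTVolume-class] or [SegmentationMask-class].
#' @param path destination \code{.nii} or \code{.nii.gz} path.
#' @return \code{path}, invisibly.
#' @export
writeVolume <- function(object, path) {
  isMask <- is(object, "SegmentationMask")
  vals <- voxelData(object)
  storage <- if (isMask) array(as.integer(vals), dim(vals)) else vals
  img <- RNifti::asNifti(storage)
  RNifti::pixdim(img) <- voxelSpacing(object)
  RNifti::writeNifti(img, path, datatype = if (isMask) "uint8" else "int16")
  invisible(path)
}

#' Resample a volume or mask to an isotropic grid
#'
#' HU volumes are interpolated trilinearly; masks by nearest neighbour so they
#' stay boolean. The output grid has spacing \code{(t, t, t)} and per-axis
#' extent equal to the input physical extent to within one voxel. Output voxel
#' centres sit at world coordinates \code{index * t} on the same axes as the
#' input (\code{index * spacing}).
#'
#' @param object a [CTVolume-class] or [SegmentationMask-class].
#' @param targetSpacing isotropic voxel size in mm (default 1).
#' @return An object of the same class on the resampled grid.
#' @examples
#' vol <- CTVolume(array(-300, c(10, 10, 10)), spacing = 2)
#' dim(voxelData(resampleIsotropic(vol, 1)))  # 20 x 20 x 20
#' @export
resampleIsotropic <- function(object, targetSpacing = 1) {
  if (!is.numeric(targetSpacing) || length(targetSpacing) != 1L ||
      !is.finite(targetSpacing) || targetSpacing <= 0)
    stop("targetSpacing must be a single positive number (mm)")
  vals <- voxelData(object)
  sp <- voxelSpacing(object)
  dIn <- dim(vals)
  dOut <- pmax(1L, as.integer(round(dIn * sp / targetSpacing)))
  isMask <- is(object, "SegmentationMask")
  # input-index coordinates of the output voxel centres, per axis
  coords <- lapply(1:3, function(ax)
    (seq_len(dOut[ax]) - 1) * targetSpacing / sp[ax])
  if (isMask) {
    idx <- lapply(1:3, function(ax)
      pmin(pmax(round(coords[[ax]]) + 1, 1), dIn[ax]))
    out <- vals[idx[[1]], idx[[2]], idx[[3]], drop = FALSE]
    dim(out) <- dOut
    SegmentationMask(out, spacing = rep(targetSpacing, 3),
                     patientId = patientId(object),
                     state = acquisitionState(object),
                     observer = observerId(object))
  } else {
    out <- trilinearSample(vals, coords)
    CTVolume(out, spacing = rep(targetSpacing, 3),
             patientId = patientId(object), state = acquisitionState(object))
  }
}

#' Check that a mask shares the grid of a CT volume
#'
#' Report-style contract: never errors. The pair is aligned when the grid
#' shapes are identical and the spacings agree within a relative tolerance of
#' \code{1e-6}.
#'
#' @param volume a [CTVolume-class].
#' @param mask a [SegmentationMask-class].
#' @return A list with elements \code{pass} (logical) and \code{mismatches}
#'   (character vector naming each failing axis).
#' @export
checkAligned <- function(volume, mask) {
  mism <- character()
  dv <- dim(voxelData(volume)); dm <- dim(voxelData(mask))
  for (ax in 1:3)
    if (dv[ax] != dm[ax])
      mism <- c(mism, sprintf("shape mismatch on axis %d: %d vs %d",
                              ax, dv[ax], dm[ax]))
  sv <- voxelSpacing(volume); sm <- voxelSpacing(mask)
  for (ax in 1:3)
    if (abs(sv[ax] - sm[ax]) > 1e-6 * max(abs(sv[ax]), abs(sm[ax])))
      mism <- c(mism, sprintf("spacing mismatch on axis %d: %g vs %g",
                              ax, sv[ax], sm[ax]))
  list(pass = length(mism) == 0L, mismatches = mism)
}
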