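#' @import methods
#' @importFrom stats median pnorm qnorm qt quantile rnorm runif sd setNames
#' @importFrom utils read.csv write.csv
#' @importFrom Rcpp sourceCpp
#' @useDynLib lungqct, .registration = TRUE
NULL

#' Recognised acquisition states and observer labels
#'
#' Each patient is imaged in up to four ventilatory states: end-expiration and
#' end-inspiration at the clinically selected PEEP, and end-expiration at PEEP
#' 5 and 15 cmH2O. Each CT volume may carry several segmentations: two
#' repeated runs by observer 1 (repeatability), one by observer 2 and one by a
#' machine-learning model (reproducibility).
#'
#' @format Character vectors of the admissible labels.
#' @export
ctStates <- c("EXP_PEEPclin", "INSP_PEEPclin", "EXP_PEEP5", "EXP_PEEP15")

#' @rdname ctStates
#' @export
ctObservers <- c("REFERENCE", "OBS1_RUN1", "OBS1_RUN2", "OBS2", "ML")

#' @rdname ctStates
#' @export
aerationCompartments <- c("non_aerated", "poorly", "normal", "hyper")

#' @rdname ctStates
#' @export
comparisonTypes <- c("intra_observer", "inter_human_human", "inter_human_ml")

setClass("VoxelGrid", representation("VIRTUAL",
  values = "array",
  spacing = "numeric",
  patientId = "character",
  state = "character"
))

validVoxelGrid <- function(object) {
  msg <- character()
  if (length(dim(object@values)) != 3L)
    msg <- c(msg, "values must be a 3-D array")
  if (any(dim(object@values) < 1L))
    msg <- c(msg, "all grid dimensions must be >= 1")
  if (length(object@spacing) != 3L || any(!is.finite(object@spacing)) ||
      any(object@spacing <= 0))
    msg <- c(msg, "spacing must be 3 strictly positive finite values (mm)")
  if (length(object@state) != 1L || !(object@state %in% ctStates))
    msg <- c(msg, sprintf("state must be one of: %s",
                          paste(ctStates, collapse = ", ")))
  if (length(msg)) msg else TRUE
}

#' CTVolume: a 3-D CT image in Hounsfield units
#'
#' A scalar voxel grid of CT numbers (HU) with physical voxel spacing in mm,
#' tagged with the patient and the ventilatory state of the acquisition.
#' HU values must be finite; \code{-1000} is pure gas and \code{0} water-like
#' tissue.
#'
#' @slot values 3-D numeric array of HU.
#' @slot spacing numeric(3), mm per voxel along each axis.
#' @slot patientId opaque patient label.
#' @slot state one of \code{ctStates}.
#'
#' @seealso [SegmentationMask()], [aerationProfile()]
#' @export
setClass("CTVolume", contains = "VoxelGrid")

setValidity("CTVolume", function(object) {
  msg <- validVoxelGrid(object)
  msg <- if (isTRUE(msg)) character() else msg
  if (!is.numeric(object@values))
    msg <- c(msg, "HU values must be numeric")
  else if (any(!is.finite(object@values)))
    msg <- c(msg, "HU values must be finite (no NA/NaN/Inf)")
  if (length(msg)) msg else TRUE
})

#' Construct a CTVolume
#'
#' @param values 3-D numeric array of HU values.
#' @param spacing voxel spacing in mm; a scalar is recycled to the three axes.
#' @param patientId opaque patient label.
#' @param state acquisition state, one of \code{ctStates}.
#' @return A [CTVolume-class] object.
#' @examples
#' vol <- CTVolume(array(-500, c(8, 8, 8)), spacing = 1)
#' voxelVolume(vol)  # 0.001 mL
#' @export
CTVolume <- function(values, spacing = c(1, 1, 1), patientId = "P", state = "EXP_PEEP5") {
  if (length(spacing) == 1L) spacing <- rep(spacing, 3L)
  new("CTVolume", values = values, spacing = as.numeric(spacing),
      patientId = as.character(patientId), state = as.character(state))
}

#' SegmentationMask: a binary lung mask aligned to a CTVolume
#'
#' A 3-D logical grid on the same voxel lattice as its CT volume, tagged with
#' the observer (or repeated run) that produced it.
#'
#' @slot values 3-D logical array; \code{TRUE} marks lung voxels.
#' @slot spacing numeric(3), mm per voxel.
#' @slot patientId opaque patient label.
#' @slot state one of \code{ctStates}.
#' @slot observer one of \code{ctObservers}.
#' @export
setClass("SegmentationMask", contains = "VoxelGrid",
         representation(observer = "character"))

setValidity("SegmentationMask", function(object) {
  msg <- validVoxelGrid(object)
  msg <- if (isTRUE(msg)) character() else msg
  if (!is.logical(object@values))
    msg <- c(msg, "mask values must be logical")
  else if (anyNA(object@values))
    msg <- c(msg, "mask values must not contain NA")
  if (length(object@observer) != 1L || !(object@observer %in% ctObservers))
    msg <- c(msg, sprintf("observer must be one of: %s",
                          paste(ctObservers, collapse = ", ")))
  if (length(msg)) msg else TRUE
})

#' Construct a SegmentationMask
#'
#' Any numeric input is binarized with the rule \code{value > 0}, matching how
#' multi-label mask files are collapsed to a lung/non-lung decision.
#'
#' @param values 3-D logical or numeric array.
#' @param spacing voxel spacing in mm; a scalar is recycled.
#' @param patientId,state as for [CTVolume()].
#' @param observer observer label, one of \code{ctObservers}.
#' @return A [SegmentationMask-class] object.
#' @export
SegmentationMask <- function(values, spacing = c(1, 1, 1), patientId = "P",
                             state = "EXP_PEEP5", observer = "REFERENCE") {
  if (length(spacing) == 1L) spacing <- rep(spacing, 3L)
  if (!is.logical(values)) {
    dm <- dim(values)
    values <- array(as.vector(values) > 0, dm)
  }
  new("SegmentationMask", values = values, spacing = as.numeric(spacing),
      patientId = as.character(patientId), state = as.character(state),
      observer = as.character(observer))
}

#' AerationProfile: per-compartment weights and volumes of one segmented lung
#'
#' Holds the quantitative-CT summary of one (volume, mask) pair: total and
#' per-compartment tissue weight (g, assuming tissue density 1 g/mL), gas and
#' tissue volumes (mL), voxel counts and the voxel volume. Compartments follow
#' the HU classification: non-aerated (>= -100 HU), poorly (-500 to -100),
#' normally (-900 to -500) and hyper-aerated (< -900 HU).
#'
#' @slot weightTotal total lung weight, g.
#' @slot weightByCompartment named numeric(4), g per compartment.
#' @slot gasVolumeTotal total gas volume, mL.
#' @slot gasVolumeByCompartment named numeric(4), mL.
#' @slot tissueVolumeTotal total tissue volume, mL.
#' @slot nVoxels number of masked voxels.
#' @slot nVoxelsAbove100HU masked voxels denser than +100 HU (vessel-like).
#' @slot voxelVolume volume of one voxel, mL.
#' @slot patientId,state provenance labels.
#' @export
setClass("AerationProfile", representation(
  weightTotal = "numeric",
  weightByCompartment = "numeric",
  gasVolumeTotal = "numeric",
  gasVolumeByCompartment = "numeric",
  tissueVolumeTotal = "numeric",
  nVoxels = "numeric",
  nVoxelsAbove100HU = "numeric",
  voxelVolume = "numeric",
  patientId = "character",
  state = "character"
))

setValidity("AerationProfile", function(object) {
  msg <- character()
  relTol <- function(a, b) abs(a - b) <= 1e-6 * max(abs(a), abs(b), 1e-12)
  if (!identical(names(object@weightByCompartment), aerationCompartments))
    msg <- c(msg, "weightByCompartment must be named by the four compartments")
  if (!relTol(object@weightTotal, sum(object@weightByCompartment)))
    msg <- c(msg, "compartment weights must sum to the total weight (mass conservation)")
  if (any(c(object@weightTotal, object@weightByCompartment,
            object@gasVolumeTotal, object@gasVolumeByCompartment,
            object@tissueVolumeTotal) < 0))
    msg <- c(msg, "weights and volumes must be non-negative")
  if (object@nVoxelsAbove100HU > object@nVoxels)
    msg <- c(msg, "nVoxelsAbove100HU cannot exceed nVoxels")
  if (length(msg)) msg else TRUE
})

#' PairedMeasurementSet: one scalar CT parameter measured twice per patient
#'
#' The unit of all precision statistics: per patient, the same parameter
#' measured under two conditions (two runs of one observer, two observers, or
#' human vs machine). The patient is the resampling unit of the bootstrap.
#'
#' @slot patientIds opaque labels, one per patient.
#' @slot valuesA,valuesB paired measurements, same units and length.
#' @slot parameter parameter label (units included).
#' @slot comparison one of \code{comparisonTypes}.
#' @export
setClass("PairedMeasurementSet", representation(
  patientIds = "character",
  valuesA = "numeric",
  valuesB = "numeric",
  parameter = "character",
  comparison = "character"
))

setValidity("PairedMeasurementSet", function(object) {
  msg <- character()
  n <- length(object@patientIds)
  if (n < 2L) msg <- c(msg, "at least two patients are required")
  if (length(object@valuesA) != n || length(object@valuesB) != n)
    msg <- c(msg, "valuesA and valuesB must match patientIds in length")
  if (anyDuplicated(object@patientIds))
    msg <- c(msg, "one entry per patient (the patient is the resampling unit)")
  if (anyNA(object@valuesA) || anyNA(object@valuesB))
    msg <- c(msg, "paired values must not contain NA")
  if (!(object@comparison %in% comparisonTypes))
    msg <- c(msg, sprintf("comparison must be one of: %s",
                          paste(comparisonTypes, collapse = ", ")))
  if (length(msg)) msg else TRUE
})

#' Construct a PairedMeasurementSet
#'
#' @param patientIds patient labels (unique).
#' @param valuesA,valuesB paired measurements.
#' @param parameter parameter label.
#' @param comparison one of \code{comparisonTypes}.
#' @return A [PairedMeasurementSet-class].
#' @export
pairedMeasurements <- function(patientIds, valuesA, valuesB,
                               parameter = "parameter",
                               comparison = "intra_observer") {
  new("PairedMeasurementSet", patientIds = as.character(patientIds),
      valuesA = as.numeric(valuesA), valuesB = as.numeric(valuesB),
      parameter = parameter, comparison = comparison)
}

## ---- accessors ------------------------------------------------------------

#' Accessors for voxel-grid objects
#'
#' @param object a [CTVolume-class], [SegmentationMask-class] or
#'   [AerationProfile-class].
#' @return \code{voxelData} the raw 3-D array; \code{voxelSpacing} mm per
#'   voxel; \code{voxelVolume} the volume of one voxel in mL;
#'   \code{patientId}/\code{acquisitionState}/\code{observerId} the labels.
#' @name grid-accessors
NULL

#' @rdname grid-accessors
#' @export
setGeneric("voxelData", function(object) standardGeneric("voxelData"))
#' @rdname grid-accessors
#' @export
setGeneric("voxelSpacing", function(object) standardGeneric("voxelSpacing"))
#' @rdname grid-accessors
#' @export
setGeneric("voxelVolume", function(object) standardGeneric("voxelVolume"))
#' @rdname grid-accessors
#' @export
setGeneric("patientId", function(object) standardGeneric("patientId"))
#' @rdname grid-accessors
#' @export
setGeneric("acquisitionState", function(object) standardGeneric("acquisitionState"))
#' @rdname grid-accessors
#' @export
setGeneric("observerId", function(object) standardGeneric("observerId"))

#' @rdname grid-accessors
setMethod("voxelData", "VoxelGrid", function(object) object@values)
#' @rdname grid-accessors
setMethod("voxelSpacing", "VoxelGrid", function(object) object@spacing)
#' @rdname grid-accessors
setMethod("voxelVolume", "VoxelGrid", function(object) prod(object@spacing) / 1000)
#' @rdname grid-accessors
setMethod("voxelVolume", "AerationProfile", function(object) object@voxelVolume)
#' @rdname grid-accessors
setMethod("patientId", "VoxelGrid", function(object) object@patientId)
#' @rdname grid-accessors
setMethod("patientId", "AerationProfile", function(object) object@patientId)
#' @rdname grid-accessors
setMethod("acquisitionState", "VoxelGrid", function(object) object@state)
#' @rdname grid-accessors
setMethod("acquisitionState", "AerationProfile", function(object) object@state)
#' @rdname grid-accessors
setMethod("observerId", "SegmentationMask", function(object) object@observer)

#' Aeration-profile accessors
#'
#' @param object an [AerationProfile-class].
#' @param compartment optional compartment name to select one component.
#' @return Weights in g, volumes in mL.
#' @name profile-accessors
NULL

#' @rdname profile-accessors
#' @export
setGeneric("lungWeight", function(object, compartment = NULL) standardGeneric("lungWeight"))
#' @rdname profile-accessors
#' @export
setGeneric("gasVolume", function(object, compartment = NULL) standardGeneric("gasVolume"))
#' @rdname profile-accessors
#' @export
setGeneric("tissueVolume", function(object) standardGeneric("tissueVolume"))

#' @rdname profile-accessors
setMethod("lungWeight", "AerationProfile", function(object, compartment = NULL) {
  if (is.null(compartment)) return(object@weightTotal)
  compartment <- match.arg(compartment, aerationCompartments, several.ok = TRUE)
  object@weightByCompartment[compartment]
})
#' @rdname profile-accessors
setMethod("gasVolume", "AerationProfile", function(object, compartment = NULL) {
  if (is.null(compartment)) return(object@gasVolumeTotal)
  compartment <- match.arg(compartment, aerationCompartments, several.ok = TRUE)
  object@gasVolumeByCompartment[compartment]
})
#' @rdname profile-accessors
setMethod("tissueVolume", "AerationProfile", function(object) object@tissueVolumeTotal)

## ---- show methods ---------------------------------------------------------

setMethod("show", "CTVolume", function(object) {
  d <- dim(object@values)
  cat(sprintf("CTVolume '%s' [%s]\n  grid %d x %d x %d, spacing %s mm\n  HU range [%.0f, %.0f]\n",
              object@patientId, object@state, d[1], d[2], d[3],
              paste(format(object@spacing, digits = 3), collapse = " x "),
              min(object@values), max(object@values)))
})

setMethod("show", "SegmentationMask", function(object) {
  d <- dim(object@values)
  cat(sprintf("SegmentationMask '%s' [%s, %s]\n  grid %d x %d x %d, spacing %s mm, %d lung voxels\n",
              object@patientId, object@state, object@observer, d[1], d[2], d[3],
              paste(format(object@spacing, digits = 3), collapse = " x "),
              sum(object@values)))
})

setMethod("show", "AerationProfile", function(object) {
  cat(sprintf("AerationProfile '%s' [%s]\n", object@patientId, object@state))
  cat(sprintf("  lung weight %.1f g, gas volume %.1f mL, tissue volume %.1f mL\n",
              object@weightTotal, object@gasVolumeTotal, object@tissueVolumeTotal))
  pct <- 100 * object@weightByCompartment / max(object@weightTotal, 1e-12)
  cat(sprintf("  weight %%: non-aerated %.1f, poorly %.1f, normal %.1f, hyper %.1f\n",
              pct[1], pct[2], pct[3], pct[4]))
})

setMethod("show", "PairedMeasurementSet", function(object) {
  cat(sprintf("PairedMeasurementSet: %s (%s), n = %d patients\n",
              object@parameter, object@comparison, length(object@patientIds)))
})
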