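## Quantitative CT parameters of lung aeration.
##
## The gas fraction of a voxel is linear in its CT number, clamped to the
## physical range: -1000 HU is pure gas, 0 HU pure (water-like) tissue.
## Tissue weight assumes a tissue density of 1 g/mL. Aeration compartments
## are cut at -900 / -500 / -100 HU, half-open with closure on the denser
## side, which reproduces the integer-HU ranges non-aerated +100..-100,
## poorly -101..-500, normal -501..-900, hyper <= -901 exactly.

#' Gas and tissue fraction of a voxel from its CT number
#'
#' \code{gas = clamp(hu, -1000, 0) / (-1000)}, \code{tissue = 1 - gas}. HU
#' above 0 are fully tissue; below -1000 fully gas.
#'
#' @param hu numeric vector of finite HU values.
#' @return A list with numeric vectors \code{gas} and \code{tissue}, each in
#'   \code{[0, 1]}.
#' @examples
#' voxelFractions(c(-1000, -500, 0, 80))
#' @export
voxelFractions <- function(hu) {
  if (!is.numeric(hu) || any(!is.finite(hu)))
    stop("hu must be finite numeric")
  gas <- pmin(pmax(hu, -1000), 0) / (-1000)
  list(gas = gas, tissue = 1 - gas)
}

#' Classify CT numbers into the four aeration compartments
#'
#' Hyper-aerated below -900 HU, normally aerated in [-900, -500), poorly
#' aerated in [-500, -100), non-aerated at and above -100 HU. Dense voxels
#' above +100 HU (vessel-like) also fall in the non-aerated compartment and
#' are counted separately by [aerationProfile()].
#'
#' @param hu numeric vector of finite HU values.
#' @return A factor with levels \code{aerationCompartments}.
#' @examples
#' classifyCompartment(c(-950, -900, -300, -100, 40))
#' @export
classifyCompartment <- function(hu) {
  if (!is.numeric(hu) || any(!is.finite(hu)))
    stop("hu must be finite numeric")
  idx <- ifelse(hu < -900, 4L, ifelse(hu < -500, 3L, ifelse(hu < -100, 2L, 1L)))
  factor(aerationCompartments[idx], levels = aerationCompartments)
}

#' Aeration profile of one segmented CT volume
#'
#' Computes, over the masked voxels only, the gas and tissue volumes (mL) and
#' the tissue weight (g, density 1 g/mL), in total and per aeration
#' compartment.
#'
#' @param volume a [CTVolume-class].
#' @param mask an aligned, non-empty [SegmentationMask-class].
#' @return An [AerationProfile-class].
#' @examples
#' vol <- CTVolume(array(-500, c(10, 10, 10)), spacing = 1)
#' msk <- SegmentationMask(array(TRUE, c(10, 10, 10)), spacing = 1)
#' lungWeight(aerationProfile(vol, msk))  # 0.5 g
#' @export
aerationProfile <- function(volume, mask) {
  al <- checkAligned(volume, mask)
  if (!al$pass)
    stop("volume and mask are not aligned: ",
         paste(al$mismatches, collapse = "; "))
  sel <- voxelData(mask)
  if (!any(sel))
    stop("degenerate input: empty segmentation mask")
  hu <- voxelData(volume)[sel]
  vv <- voxelVolume(volume)
  fr <- voxelFractions(hu)
  comp <- classifyCompartment(hu)
  tissueByComp <- vapply(split(fr$tissue, comp), sum, numeric(1)) * vv
  gasByComp <- vapply(split(fr$gas, comp), sum, numeric(1)) * vv
  tissueByComp <- tissueByComp[aerationCompartments]
  gasByComp <- gasByComp[aerationCompartments]
  new("AerationProfile",
      weightTotal = sum(tissueByComp),
      weightByCompartment = tissueByComp,
      gasVolumeTotal = sum(gasByComp),
      gasVolumeByCompartment = gasByComp,
      tissueVolumeTotal = sum(tissueByComp),
      nVoxels = as.numeric(sum(sel)),
      nVoxelsAbove100HU = as.numeric(sum(hu > 100)),
      voxelVolume = vv,
      patientId = patientId(volume),
      state = acquisitionState(volume))
}

checkSamePatient <- function(...) {
  ids <- vapply(list(...), patientId, character(1))
  if (length(unique(ids)) != 1L)
    stop("profiles come from different patients: ",
         paste(unique(ids), collapse = ", "))
  invisible(ids[1])
}

#' PEEP-induced alveolar recruitment, in % of lung weight
#'
#' Weight of the non-aerated compartment at PEEP 5 minus its weight at PEEP
#' 15, standardized to total lung weight. The default denominator is the mean
#' of the total weights at the two PEEP levels (symmetric); \code{"peep5"}
#' uses the PEEP-5 weight alone. Negative values indicate derecruitment.
#'
#' @param profilePeep5,profilePeep15 [AerationProfile-class]s of the same
#'   patient at end-expiration, PEEP 5 and 15 cmH2O.
#' @param denominator \code{"mean"} (default) or \code{"peep5"}.
#' @return Recruitment in % of total lung weight.
#' @export
recruitmentPeep <- function(profilePeep5, profilePeep15,
                            denominator = c("mean", "peep5")) {
  denominator <- match.arg(denominator)
  checkSamePatient(profilePeep5, profilePeep15)
  w5 <- lungWeight(profilePeep5); w15 <- lungWeight(profilePeep15)
  den <- if (denominator == "mean") (w5 + w15) / 2 else w5
  if (den <= 0)
    stop("degenerate input: zero total lung weight")
  unname(100 * (lungWeight(profilePeep5, "non_aerated") -
                lungWeight(profilePeep15, "non_aerated")) / den)
}

#' Tidal recruitment, in % of lung weight
#'
#' Weight of the non-aerated compartment at end-expiration minus its weight at
#' end-inspiration, standardized to the end-expiratory total lung weight.
#'
#' @param profileExp,profileInsp [AerationProfile-class]s at end-expiration
#'   and end-inspiration (clinical PEEP) of the same patient.
#' @return Tidal recruitment in % of lung weight.
#' @export
tidalRecruitment <- function(profileExp, profileInsp) {
  checkSamePatient(profileExp, profileInsp)
  den <- lungWeight(profileExp)
  if (den <= 0)
    stop("degenerate input: zero total lung weight")
  unname(100 * (lungWeight(profileExp, "non_aerated") -
                lungWeight(profileInsp, "non_aerated")) / den)
}

#' Tidal hyperinflation, in mL per kg predicted body weight
#'
#' Aerated (gas) volume of the hyper-aerated compartment at end-inspiration
#' minus that at end-expiration, per kg PBW; tissue weight is negligible in
#' this compartment, so its gas volume is the standardized quantity.
#'
#' @param profileExp,profileInsp [AerationProfile-class]s as for
#'   [tidalRecruitment()].
#' @param pbw predicted body weight, kg (> 0).
#' @return Tidal hyperinflation in mL/kg PBW.
#' @export
tidalHyperinflation <- function(profileExp, profileInsp, pbw) {
  if (!is.numeric(pbw) || length(pbw) != 1L || !is.finite(pbw) || pbw <= 0)
    stop("pbw must be a single positive number (kg)")
  checkSamePatient(profileExp, profileInsp)
  unname((gasVolume(profileInsp, "hyper") - gasVolume(profileExp, "hyper")) / pbw)
}

#' End-expiratory lung volume
#'
#' The gas volume within the lung mask at an end-expiratory acquisition.
#'
#' @param profileExp an [AerationProfile-class] from an end-expiratory state.
#' @return EELV in mL.
#' @export
eelv <- function(profileExp) gasVolume(profileExp)

#' Predicted body weight by the Devine formula
#'
#' \code{50 + 0.91 (height - 152.4)} kg for males, \code{45.5 + 0.91 (height -
#' 152.4)} for females, height in cm.
#'
#' @param sex \code{"male"} or \code{"female"}.
#' @param heightCm height in centimetres.
#' @return PBW in kg.
#' @export
predictedBodyWeight <- function(sex = c("male", "female"), heightCm) {
  sex <- match.arg(sex)
  base <- if (sex == "male") 50 else 45.5
  base + 0.91 * (heightCm - 152.4)
}

#' Assemble all per-patient CT parameters from the four-state profiles
#'
#' Combines the aeration profiles of the four acquisition states into the full
#' per-patient parameter set: recruitment between PEEP 5 and 15, tidal
#' recruitment and hyperinflation, EELV, hyperinflated gas volume per kg PBW
#' and the non-aerated fraction at both PEEP levels, and total lung weights.
#' Missing states are allowed; parameters depending on an absent state are
#' returned as \code{NA}, never as silent zeros.
#'
#' @param profiles named list of [AerationProfile-class]s; names are states
#'   from \code{ctStates} (missing states simply absent from the list).
#' @param pbw predicted body weight, kg.
#' @param denominator recruitment denominator, see [recruitmentPeep()].
#' @return A one-row \code{data.frame} with columns \code{patient_id},
#'   \code{pbw_kg}, \code{recruitment_peep_5_15_pct},
#'   \code{tidal_recruitment_pct}, \code{tidal_hyperinflation_ml_kg},
#'   \code{eelv_peep5_ml}, \code{eelv_peep15_ml},
#'   \code{hyperinflation_peep5_ml_kg}, \code{hyperinflation_peep15_ml_kg},
#'   \code{nonaerated_peep5_pct}, \code{nonaerated_peep15_pct},
#'   \code{weight_peep5_g}, \code{weight_peep15_g}.
#' @export
patientParameters <- function(profiles, pbw, denominator = c("mean", "peep5")) {
  denominator <- match.arg(denominator)
  if (!is.numeric(pbw) || length(pbw) != 1L || !is.finite(pbw) || pbw <= 0)
    stop("pbw must be a single positive number (kg)")
  stopifnot(is.list(profiles), length(profiles) >= 1L)
  if (is.null(names(profiles)))
    names(profiles) <- vapply(profiles, acquisitionState, character(1))
  if (!all(names(profiles) %in% ctStates))
    stop("profile names must be states from ctStates")
  ids <- unique(vapply(profiles, patientId, character(1)))
  if (length(ids) != 1L)
    stop("profiles come from different patients: ", paste(ids, collapse = ", "))
  has <- function(s) s %in% names(profiles)
  p <- function(s) profiles[[s]]
  out <- data.frame(
    patient_id = ids, pbw_kg = pbw,
    recruitment_peep_5_15_pct = NA_real_,
    tidal_recruitment_pct = NA_real_,
    tidal_hyperinflation_ml_kg = NA_real_,
    eelv_peep5_ml = NA_real_, eelv_peep15_ml = NA_real_,
    hyperinflation_peep5_ml_kg = NA_real_,
    hyperinflation_peep15_ml_kg = NA_real_,
    nonaerated_peep5_pct = NA_real_, nonaerated_peep15_pct = NA_real_,
    weight_peep5_g = NA_real_, weight_peep15_g = NA_real_,
    stringsAsFactors = FALSE)
  if (has("EXP_PEEP5") && has("EXP_PEEP15"))
    out$recruitment_peep_5_15_pct <-
      recruitmentPeep(p("EXP_PEEP5"), p("EXP_PEEP15"), denominator)
  if (has("EXP_PEEPclin") && has("INSP_PEEPclin")) {
    out$tidal_recruitment_pct <-
      tidalRecruitment(p("EXP_PEEPclin"), p("INSP_PEEPclin"))
    out$tidal_hyperinflation_ml_kg <-
      tidalHyperinflation(p("EXP_PEEPclin"), p("INSP_PEEPclin"), pbw)
  }
  if (has("EXP_PEEP5")) {
    out$eelv_peep5_ml <- eelv(p("EXP_PEEP5"))
    out$hyperinflation_peep5_ml_kg <-
      unname(gasVolume(p("EXP_PEEP5"), "hyper")) / pbw
    out$nonaerated_peep5_pct <- unname(
      100 * lungWeight(p("EXP_PEEP5"), "non_aerated") / lungWeight(p("EXP_PEEP5")))
    out$weight_peep5_g <- lungWeight(p("EXP_PEEP5"))
  }
  if (has("EXP_PEEP15")) {
    out$eelv_peep15_ml <- eelv(p("EXP_PEEP15"))
    out$hyperinflation_peep15_ml_kg <-
      unname(gasVolume(p("EXP_PEEP15"), "hyper")) / pbw
    out$nonaerated_peep15_pct <- unname(
      100 * lungWeight(p("EXP_PEEP15"), "non_aerated") / lungWeight(p("EXP_PEEP15")))
    out$weight_peep15_g <- lungWeight(p("EXP_PEEP15"))
  }
  out
}
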