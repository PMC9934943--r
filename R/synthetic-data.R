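## Synthetic lung phantoms with programmed ground truth.
##
## A phantom patient is a pair of ellipsoidal lungs on a voxel grid. Masked
## voxels are assigned to the four aeration compartments in gravitational
## order (non-aerated most dependent, then poorly, normally, hyper-aerated)
## according to per-state compartment fractions; PEEP-induced recruitment is
## programmed by moving the least-dependent non-aerated voxels into the
## poorly aerated compartment between the PEEP-5 and PEEP-15 states, i.e.
## the non-aerated/poorly boundary recedes down the gravity axis. Voxel HU
## are drawn per compartment (uniform over the compartment's HU range, or a
## fixed representative value), with optional Gaussian noise clamped to the
## compartment range. Observer variability is emulated by displacing the
## mask boundary with a smooth random field acting on the signed distance
## transform. All generation is a pure function of (spec, seed).

compartmentHuRanges <- rbind(
  non_aerated = c(-100, 100),
  poorly      = c(-500, -101),
  normal      = c(-900, -501),
  hyper       = c(-1000, -901))

fixedHu <- c(non_aerated = 0, poorly = -300, normal = -700, hyper = -950)

# expected tissue fraction per compartment under each HU model
expectedTissueFraction <- function(huMode) {
  if (huMode == "fixed") {
    voxelFractions(fixedHu)$tissue
  } else {
    # uniform over the ranges; the clamp at 0 HU makes non-aerated nonlinear
    c(non_aerated = 0.975, poorly = 1 - 300.5 / 1000,
      normal = 1 - 700.5 / 1000, hyper = 1 - 950.5 / 1000)
  }
}

#' PhantomSpec: ground-truth description of one phantom patient
#'
#' @slot gridShape integer(3) voxel grid dimensions.
#' @slot spacing numeric(3) mm.
#' @slot lungCenters,lungSemiAxes 2 x 3 matrices (voxel units) describing the
#'   two ellipsoidal lungs.
#' @slot fractionsPeep5 named numeric(4): compartment voxel-count fractions at
#'   end-expiration, PEEP 5 (sum to 1).
#' @slot recruitmentTruth programmed PEEP 5 to 15 recruitment, % lung weight.
#' @slot tidalRecruitmentTruth programmed tidal recruitment, % lung weight.
#' @slot tidalHyperinflationTruth programmed tidal hyperinflation, mL/kg PBW.
#' @slot clinInterp position of the clinical PEEP between PEEP 5 (0) and 15
#'   (1), used to derive the clinical end-expiratory state.
#' @slot huMode \code{"uniform"} (HU drawn over each compartment's range) or
#'   \code{"fixed"} (one representative HU per compartment).
#' @slot huNoiseSd Gaussian HU noise SD, clamped to the compartment range.
#' @slot gravityAxis axis index (1-3) of the gravitational gradient.
#' @slot pbw predicted body weight, kg.
#' @slot patientId label.
#' @slot seed integer RNG seed.
#' @export
setClass("PhantomSpec", representation(
  gridShape = "integer", spacing = "numeric",
  lungCenters = "matrix", lungSemiAxes = "matrix",
  fractionsPeep5 = "numeric",
  recruitmentTruth = "numeric",
  tidalRecruitmentTruth = "numeric",
  tidalHyperinflationTruth = "numeric",
  clinInterp = "numeric",
  huMode = "character", huNoiseSd = "numeric",
  gravityAxis = "integer", pbw = "numeric",
  patientId = "character", seed = "integer"))

setValidity("PhantomSpec", function(object) {
  msg <- character()
  if (length(object@gridShape) != 3L || any(object@gridShape < 4L))
    msg <- c(msg, "gridShape must be 3 dimensions of at least 4 voxels")
  if (any(object@spacing <= 0)) msg <- c(msg, "spacing must be positive")
  if (!identical(names(object@fractionsPeep5), aerationCompartments))
    msg <- c(msg, "fractionsPeep5 must be named by the four compartments")
  else {
    if (abs(sum(object@fractionsPeep5) - 1) > 1e-9)
      msg <- c(msg, "compartment fractions must sum to 1 (tolerance 1e-9)")
    if (any(object@fractionsPeep5 < 0))
      msg <- c(msg, "compartment fractions must be non-negative")
  }
  if (!(object@huMode %in% c("uniform", "fixed")))
    msg <- c(msg, "huMode must be 'uniform' or 'fixed'")
  if (object@huNoiseSd < 0) msg <- c(msg, "huNoiseSd must be >= 0")
  if (!(object@gravityAxis %in% 1:3)) msg <- c(msg, "gravityAxis must be 1, 2 or 3")
  if (object@pbw <= 0) msg <- c(msg, "pbw must be positive")
  if (any(object@lungSemiAxes <= 0)) msg <- c(msg, "semi-axes must be positive")
  # the programmed recruitment must be realisable from the PEEP-5 fractions
  ok <- tryCatch({
    shiftNonToPoorly(object@fractionsPeep5, object@recruitmentTruth,
                     expectedTissueFraction(object@huMode))
    TRUE
  }, error = function(e) conditionMessage(e))
  if (!isTRUE(ok)) msg <- c(msg, ok)
  if (length(msg)) msg else TRUE
})

# count-fraction shift delta realizing a programmed recruitment (% weight):
# R/100 = delta * tf_non / (Sigma5 - delta * (tf_non - tf_poor) / 2)
shiftNonToPoorly <- function(fractions, recruitPct, tf) {
  sigma5 <- sum(fractions * tf)
  r <- recruitPct / 100
  delta <- r * sigma5 / (tf["non_aerated"] + r * (tf["non_aerated"] - tf["poorly"]) / 2)
  delta <- unname(delta)
  if (delta > fractions["non_aerated"] + 1e-12)
    stop("programmed recruitment exceeds the available non-aerated fraction")
  out <- fractions
  out["non_aerated"] <- out["non_aerated"] - delta
  out["poorly"] <- out["poorly"] + delta
  out
}

#' Construct a PhantomSpec
#'
#' @param gridShape grid dimensions (default 48 x 48 x 40).
#' @param spacing voxel spacing in mm (scalar recycled).
#' @param lungCenters,lungSemiAxes 2 x 3 matrices in voxel units; defaults
#'   place two lungs filling most of the grid.
#' @param fractionsPeep5 compartment count fractions at PEEP 5 (named or in
#'   the order non_aerated, poorly, normal, hyper).
#' @param recruitmentTruth,tidalRecruitmentTruth programmed recruitment and
#'   tidal recruitment, % lung weight.
#' @param tidalHyperinflationTruth programmed tidal hyperinflation, mL/kg.
#' @param clinInterp clinical-PEEP interpolation weight in [0, 1].
#' @param huMode,huNoiseSd HU sampling model, see [PhantomSpec-class].
#' @param gravityAxis axis of the gravitational gradient (default 2).
#' @param pbw predicted body weight, kg.
#' @param patientId label.
#' @param seed integer seed.
#' @return A [PhantomSpec-class].
#' @export
phantomSpec <- function(gridShape = c(48L, 48L, 40L), spacing = 1,
                        lungCenters = NULL, lungSemiAxes = NULL,
                        fractionsPeep5 = c(non_aerated = 0.45, poorly = 0.25,
                                           normal = 0.27, hyper = 0.03),
                        recruitmentTruth = 5.8,
                        tidalRecruitmentTruth = 4.2,
                        tidalHyperinflationTruth = 0.005,
                        clinInterp = 0.3,
                        huMode = c("uniform", "fixed"), huNoiseSd = 10,
                        gravityAxis = 2L, pbw = 70, patientId = "P01",
                        seed = 1L) {
  huMode <- match.arg(huMode)
  gridShape <- as.integer(gridShape)
  if (length(spacing) == 1L) spacing <- rep(spacing, 3L)
  if (is.null(lungCenters))
    lungCenters <- rbind(c(0.30, 0.52, 0.50), c(0.70, 0.52, 0.50)) *
      rep(gridShape, each = 2)
  if (is.null(lungSemiAxes))
    lungSemiAxes <- rbind(c(0.19, 0.30, 0.36), c(0.19, 0.30, 0.36)) *
      rep(gridShape, each = 2)
  names(fractionsPeep5) <- aerationCompartments
  new("PhantomSpec", gridShape = gridShape, spacing = as.numeric(spacing),
      lungCenters = lungCenters, lungSemiAxes = lungSemiAxes,
      fractionsPeep5 = fractionsPeep5,
      recruitmentTruth = recruitmentTruth,
      tidalRecruitmentTruth = tidalRecruitmentTruth,
      tidalHyperinflationTruth = tidalHyperinflationTruth,
      clinInterp = clinInterp,
      huMode = huMode, huNoiseSd = huNoiseSd,
      gravityAxis = as.integer(gravityAxis), pbw = pbw,
      patientId = patientId, seed = as.integer(seed))
}

#' ObserverModel: boundary-perturbation model of one segmenting observer
#'
#' @slot boundaryJitterMm target magnitude of the realized average symmetric
#'   surface distance against the unperturbed mask, mm.
#' @slot erosionDilationBias systematic boundary shift, mm (positive =
#'   over-segmentation).
#' @slot smoothnessMm correlation length of the boundary perturbation, mm.
#' @slot label observer label from \code{ctObservers}.
#' @export
setClass("ObserverModel", representation(
  boundaryJitterMm = "numeric", erosionDilationBias = "numeric",
  smoothnessMm = "numeric", label = "character"))

setValidity("ObserverModel", function(object) {
  msg <- character()
  if (object@boundaryJitterMm < 0) msg <- c(msg, "jitter must be >= 0")
  if (object@smoothnessMm <= 0) msg <- c(msg, "smoothness must be positive")
  if (!(object@label %in% ctObservers)) msg <- c(msg, "unknown observer label")
  if (length(msg)) msg else TRUE
})

#' Construct an ObserverModel
#'
#' @param boundaryJitterMm target realized ASSD vs the unperturbed mask, mm.
#' @param erosionDilationBias systematic over-/under-segmentation, mm.
#' @param smoothnessMm correlation length of the perturbation field, mm.
#' @param label observer label.
#' @return An [ObserverModel-class].
#' @export
observerModel <- function(boundaryJitterMm = 1, erosionDilationBias = 0,
                          smoothnessMm = 8, label = "OBS1_RUN1") {
  new("ObserverModel", boundaryJitterMm = boundaryJitterMm,
      erosionDilationBias = erosionDilationBias,
      smoothnessMm = smoothnessMm, label = label)
}

# deterministic sub-seed derivation, kept inside 32-bit integer range
mixSeed <- function(seed, ...) {
  ks <- c(...)
  s <- as.double(seed)
  for (k in ks) s <- (s * 1009 + as.double(k) * 101 + 17) %% 2147483629
  as.integer(s)
}

withSeed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv()))
    get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv())
          else if (exists(".Random.seed", globalenv()))
            rm(".Random.seed", envir = globalenv()))
  set.seed(seed)
  force(expr)
}

ellipsoidMaskArray <- function(gridShape, centers, semiAxes) {
  idx <- lapply(1:3, function(ax) seq_len(gridShape[ax]) - 1)
  m <- array(FALSE, gridShape)
  for (l in 1:2) {
    dx2 <- ((idx[[1]] - centers[l, 1]) / semiAxes[l, 1])^2
    dy2 <- ((idx[[2]] - centers[l, 2]) / semiAxes[l, 2])^2
    dz2 <- ((idx[[3]] - centers[l, 3]) / semiAxes[l, 3])^2
    r2 <- outer(outer(dx2, dy2, "+"), dz2, "+")
    m <- m | (r2 <= 1)
  }
  m
}

# per-state compartment count fractions, derived from the programmed truths
stateFractions <- function(spec, state, nVoxels) {
  tf <- expectedTissueFraction(spec@huMode)
  f5 <- spec@fractionsPeep5
  f15 <- shiftNonToPoorly(f5, spec@recruitmentTruth, tf)
  fClin <- f5 + spec@clinInterp * (f15 - f5)
  f <- switch(state,
    EXP_PEEP5 = f5,
    EXP_PEEP15 = f15,
    EXP_PEEPclin = fClin,
    INSP_PEEPclin = {
      fi <- shiftNonToPoorly(fClin, spec@tidalRecruitmentTruth, tf)
      # tidal hyperinflation: promote normally aerated voxels to hyper so the
      # hyper-compartment gas volume grows by the programmed mL/kg
      gfHyper <- 1 - tf["hyper"]
      vv <- prod(spec@spacing) / 1000
      gamma <- spec@tidalHyperinflationTruth * spec@pbw /
        (nVoxels * vv * gfHyper)
      gamma <- unname(gamma)
      if (gamma > fi["normal"])
        stop("programmed tidal hyperinflation exceeds the normal compartment")
      fi["normal"] <- fi["normal"] - gamma
      fi["hyper"] <- fi["hyper"] + gamma
      fi
    },
    stop("unknown state: ", state))
  f
}

# deterministic gravitational compartment labels for the masked voxels:
# integer codes 1..4 in aerationCompartments order, most dependent first
gravityCompartments <- function(maskIdx, gravityAxis, fractions) {
  n <- nrow(maskIdx)
  counts <- diff(round(cumsum(c(0, fractions)) * n))
  counts[1] <- counts[1] + (n - sum(counts))  # rounding residue
  ord <- order(-maskIdx[, gravityAxis], seq_len(n))  # most dependent first
  comp <- integer(n)
  comp[ord] <- rep.int(seq_along(fractions), counts)
  comp
}

#' Generate one phantom CT volume and its reference lung mask
#'
#' Builds the two-ellipsoid lung mask, assigns masked voxels to compartments
#' in gravitational order according to the state's programmed fractions, and
#' samples HU per compartment. Background (non-lung) voxels are soft-tissue
#' like (around +20 HU). Bit-reproducible for a given (spec, state).
#'
#' @param spec a [PhantomSpec-class].
#' @param state one of \code{ctStates}.
#' @return A list with elements \code{volume} ([CTVolume-class]) and
#'   \code{mask} (the reference [SegmentationMask-class]).
#' @export
generatePhantom <- function(spec, state = "EXP_PEEP5") {
  stopifnot(is(spec, "PhantomSpec"))
  state <- match.arg(state, ctStates)
  gs <- matrix(spec@gridShape, 2, 3, byrow = TRUE)
  if (any(spec@lungCenters - spec@lungSemiAxes < -0.5) ||
      any(spec@lungCenters + spec@lungSemiAxes > gs - 0.5))
    stop("lung geometry exceeds the grid")
  m <- ellipsoidMaskArray(spec@gridShape, spec@lungCenters, spec@lungSemiAxes)
  maskIdx <- which(m, arr.ind = TRUE)
  n <- nrow(maskIdx)
  if (n == 0L) stop("lung geometry produced an empty mask")
  fr <- stateFractions(spec, state, n)
  comp <- gravityCompartments(maskIdx, spec@gravityAxis, fr)
  hu <- withSeed(mixSeed(spec@seed, match(state, ctStates)), {
    lo <- compartmentHuRanges[comp, 1]
    hi <- compartmentHuRanges[comp, 2]
    base <- if (spec@huMode == "uniform") runif(n, lo, hi) else fixedHu[comp]
    if (spec@huNoiseSd > 0)
      base <- pmin(pmax(base + rnorm(n, 0, spec@huNoiseSd), lo), hi)
    bg <- rnorm(prod(spec@gridShape), 20, max(spec@huNoiseSd, 1e-9))
    list(lung = base, bg = bg)
  })
  vals <- array(hu$bg, spec@gridShape)
  vals[m] <- hu$lung
  list(volume = CTVolume(vals, spacing = spec@spacing,
                         patientId = spec@patientId, state = state),
       mask = SegmentationMask(m, spacing = spec@spacing,
                               patientId = spec@patientId, state = state,
                               observer = "REFERENCE"))
}

# trilinear sampling of a 3-D array at per-axis positions (0-based, in
# input-index units); shared by the resampler and the perturbation field
trilinearSample <- function(vals, coords) {
  dIn <- dim(vals)
  dOut <- lengths(coords)
  lo <- lapply(1:3, function(ax)
    pmin(pmax(floor(coords[[ax]]), 0), max(dIn[ax] - 2, 0)))
  fr <- lapply(1:3, function(ax) pmin(pmax(coords[[ax]] - lo[[ax]], 0), 1))
  out <- array(0, dOut)
  for (a in 0:1) for (b in 0:1) for (c in 0:1) {
    ia <- pmin(lo[[1]] + a + 1, dIn[1])
    jb <- pmin(lo[[2]] + b + 1, dIn[2])
    kc <- pmin(lo[[3]] + c + 1, dIn[3])
    sub <- vals[ia, jb, kc, drop = FALSE]
    dim(sub) <- dOut
    wx <- if (a == 0) 1 - fr[[1]] else fr[[1]]
    wy <- if (b == 0) 1 - fr[[2]] else fr[[2]]
    wz <- if (c == 0) 1 - fr[[3]] else fr[[3]]
    sub <- sub * wx
    sub <- sweep(sub, 2, wy, "*")
    sub <- sweep(sub, 3, wz, "*")
    out <- out + sub
  }
  out
}

# pointwise-standardized smooth Gaussian random field on the mask grid:
# white noise on a coarse lattice of cell size `lengthMm`, trilinearly
# upsampled, then rescaled to the requested pointwise SD
smoothField <- function(gridShape, spacing, lengthMm, sdTarget) {
  coarseDim <- pmax(2L, as.integer(ceiling(gridShape * spacing / lengthMm)) + 1L)
  noise <- array(rnorm(prod(coarseDim)), coarseDim)
  coords <- lapply(1:3, function(ax)
    (seq_len(gridShape[ax]) - 1) * spacing[ax] / lengthMm)
  f <- trilinearSample(noise, coords)
  f * (sdTarget / max(sd(f), 1e-12))
}

# amplitude calibration: pointwise displacement SD producing a realized ASSD
# close to the requested jitter on lung-sized masks at 1 mm spacing
jitterFieldSd <- function(jitterMm) 1.45 * jitterMm + 0.42 * jitterMm^2

# variance share of the scan-level offset within the total displacement:
# observer disagreement has a systematic per-scan component (global over- or
# under-segmentation of one reading) on top of regional boundary variation
scanShiftShare <- 0.15

#' Perturb a lung mask with a smooth observer-variability field
#'
#' The mask boundary is displaced by adding a random displacement to the
#' signed distance transform of the boundary and re-thresholding. The
#' displacement is the sum of a scan-level random offset (the systematic
#' over- or under-segmentation of one reading), a smooth Gaussian random
#' field (correlation length \code{smoothnessMm}) modelling regional
#' disagreement, and the fixed erosion/dilation bias. The total displacement
#' SD is calibrated so the realized ASSD against the input approximates
#' \code{boundaryJitterMm}; zero jitter and zero bias return the mask
#' unchanged.
#'
#' @param mask a non-empty [SegmentationMask-class].
#' @param model an [ObserverModel-class].
#' @param seed integer seed (the perturbation is deterministic given it).
#' @return A [SegmentationMask-class] on the same grid, labelled with the
#'   model's observer.
#' @export
perturbMask <- function(mask, model, seed = 1L) {
  stopifnot(is(mask, "SegmentationMask"), is(model, "ObserverModel"))
  m <- voxelData(mask)
  if (!any(m)) stop("degenerate input: empty segmentation mask")
  perturbMaskCore(mask, NULL, model, seed)
}

# signed boundary distance (mm, positive inside), zero level between the
# boundary voxel centres
signedBoundaryDistance <- function(m, sp) {
  dToFg <- distanceToSites(m, sp)
  dToBg <- distanceToSites(!m, sp)
  h <- mean(sp)
  ifelse(m, dToBg - h / 2, -(dToFg - h / 2))
}

# worker sharing a precomputed signed distance across observer models
perturbMaskCore <- function(mask, signedD, model, seed) {
  m <- voxelData(mask)
  sp <- voxelSpacing(mask)
  if (model@boundaryJitterMm == 0 && model@erosionDilationBias == 0) {
    out <- m
  } else {
    if (is.null(signedD)) signedD <- signedBoundaryDistance(m, sp)
    eps <- if (model@boundaryJitterMm > 0) {
      sdTot <- jitterFieldSd(model@boundaryJitterMm)
      withSeed(as.integer(seed), {
        shift <- rnorm(1, 0, sqrt(scanShiftShare) * sdTot)
        shift + smoothField(dim(m), sp, model@smoothnessMm,
                            sqrt(1 - scanShiftShare) * sdTot)
      })
    } else 0
    out <- (signedD + model@erosionDilationBias + eps) > 0
    dim(out) <- dim(m)
  }
  if (!any(out))
    stop("degenerate output: perturbation emptied the mask")
  SegmentationMask(out, spacing = sp, patientId = patientId(mask),
                   state = acquisitionState(mask), observer = model@label)
}

#' PhantomStudy: a generated synthetic cohort
#'
#' @slot specs list of per-patient [PhantomSpec-class]s.
#' @slot volumes named list of [CTVolume-class], keys
#'   \code{"<patient>.<state>"}.
#' @slot masks named list of [SegmentationMask-class], keys
#'   \code{"<patient>.<state>.<observer>"}.
#' @slot truth \code{data.frame} of programmed per-patient parameters.
#' @slot seed integer study seed.
#' @export
setClass("PhantomStudy", representation(
  specs = "list", volumes = "list", masks = "list",
  truth = "data.frame", seed = "integer"))

setMethod("show", "PhantomStudy", function(object) {
  cat(sprintf("PhantomStudy: %d patients, %d volumes, %d masks (seed %d)\n",
              length(object@specs), length(object@volumes),
              length(object@masks), object@seed))
})

#' PhantomStudy accessors
#'
#' @param study a [PhantomStudy-class].
#' @param patient,state,observer labels selecting one object.
#' @return \code{studyVolume}/\code{studyMask} return the stored object,
#'   \code{studyTruth} the programmed ground-truth table.
#' @name study-accessors
NULL

#' @rdname study-accessors
#' @export
studyVolume <- function(study, patient, state) {
  study@volumes[[paste(patient, state, sep = ".")]]
}
#' @rdname study-accessors
#' @export
studyMask <- function(study, patient, state, observer = "REFERENCE") {
  study@masks[[paste(patient, state, observer, sep = ".")]]
}
#' @rdname study-accessors
#' @export
studyTruth <- function(study) study@truth

#' Default observer panel of the study design
#'
#' Two repeated runs of observer 1 (intra-observer repeatability), observer 2
#' and a machine observer, with boundary jitters set to the magnitudes the
#' agreement analysis typically shows for human intra-observer (0.8 mm),
#' human-human (1.0 mm) and human-machine (1.1 mm) comparisons.
#'
#' @param intraJitter,obs2Jitter,mlJitter target ASSD magnitudes, mm.
#' @return A list of four [ObserverModel-class]s.
#' @export
defaultObserverModels <- function(intraJitter = 0.8, obs2Jitter = 1.0,
                                  mlJitter = 1.1) {
  list(observerModel(intraJitter, 0, 8, "OBS1_RUN1"),
       observerModel(intraJitter, 0, 8, "OBS1_RUN2"),
       observerModel(obs2Jitter, 0, 8, "OBS2"),
       observerModel(mlJitter, 0, 8, "ML"))
}

drawPatientSpec <- function(patientId, seed, gridShape, spacing, huMode,
                            huNoiseSd) {
  fNon <- runif(1, 0.35, 0.60)
  fHyper <- runif(1, 0.01, 0.04)
  rem <- 1 - fNon - fHyper
  fPoor <- rem * runif(1, 0.35, 0.55)
  fNormal <- rem - fPoor
  centers <- rbind(c(0.30, 0.52, 0.50), c(0.70, 0.52, 0.50)) *
    rep(gridShape, each = 2)
  axes <- rbind(runif(3, 0.95, 1.05), runif(3, 0.95, 1.05)) *
    (rbind(c(0.17, 0.28, 0.34), c(0.17, 0.28, 0.34)) * rep(gridShape, each = 2))
  pbw <- runif(1, 50, 85)
  # the programmed hyper-aerated gas increase must fit the phantom's size:
  # draw it as a count fraction of the lung and convert to mL/kg
  nEst <- sum(4 / 3 * pi * axes[, 1] * axes[, 2] * axes[, 3])
  gfHyper <- 1 - expectedTissueFraction(huMode)[["hyper"]]
  gammaTidal <- runif(1, 0.005, 0.02)
  phantomSpec(gridShape = gridShape, spacing = spacing,
              lungCenters = centers, lungSemiAxes = axes,
              fractionsPeep5 = c(non_aerated = fNon, poorly = fPoor,
                                 normal = fNormal, hyper = fHyper),
              recruitmentTruth = runif(1, 3, 9),
              tidalRecruitmentTruth = runif(1, 1.5, 6.5),
              tidalHyperinflationTruth =
                gammaTidal * nEst * prod(spacing) / 1000 * gfHyper / pbw,
              clinInterp = runif(1, 0.2, 0.5),
              huMode = huMode, huNoiseSd = huNoiseSd,
              gravityAxis = 2L, pbw = pbw,
              patientId = patientId, seed = seed)
}

# generate one patient's volumes and masks (all requested states/observers)
generatePatientSet <- function(spec, observers, states, missing = NULL) {
  pid <- spec@patientId
  volumes <- masks <- list()
  for (s in states) {
    if (!is.null(missing) &&
        any(missing$patient_id == pid & missing$state == s)) next
    ph <- generatePhantom(spec, s)
    key <- paste(pid, s, sep = ".")
    volumes[[key]] <- ph$volume
    masks[[paste(key, "REFERENCE", sep = ".")]] <- ph$mask
    signedD <- signedBoundaryDistance(voxelData(ph$mask),
                                      voxelSpacing(ph$mask))
    for (oi in seq_along(observers)) {
      om <- observers[[oi]]
      masks[[paste(key, om@label, sep = ".")]] <-
        perturbMaskCore(ph$mask, signedD, om,
                        seed = mixSeed(spec@seed, match(s, ctStates), oi))
    }
  }
  list(volumes = volumes, masks = masks)
}

truthRow <- function(spec) {
  data.frame(
    patient_id = spec@patientId, pbw_kg = spec@pbw,
    recruitment_peep_5_15_pct = spec@recruitmentTruth,
    tidal_recruitment_pct = spec@tidalRecruitmentTruth,
    tidal_hyperinflation_ml_kg = spec@tidalHyperinflationTruth,
    nonaerated_fraction_peep5 = unname(spec@fractionsPeep5["non_aerated"]),
    seed = spec@seed, stringsAsFactors = FALSE)
}

#' Generate a full synthetic study
#'
#' Per patient: the four acquisition states (volumes plus reference masks)
#' and one perturbed mask per observer model, with per-patient ground-truth
#' parameters recorded. Optional missingness removes listed (patient, state)
#' volumes, mimicking incomplete acquisitions.
#'
#' @param nPatients number of patients (the study design uses 13).
#' @param observers list of [ObserverModel-class]s (default
#'   [defaultObserverModels()]).
#' @param seed integer study seed; every volume and mask derives its own
#'   sub-seed from it.
#' @param states states to generate (default all four).
#' @param gridShape,spacing phantom grid (default 48 x 48 x 40 at 1 mm).
#' @param huMode,huNoiseSd HU sampling model for all patients.
#' @param missing optional \code{data.frame} with columns \code{patient_id},
#'   \code{state}: volumes to drop.
#' @return A [PhantomStudy-class].
#' @export
generateStudy <- function(nPatients = 13, observers = defaultObserverModels(),
                          seed = 1L, states = ctStates,
                          gridShape = c(48L, 48L, 40L), spacing = 1,
                          huMode = "uniform", huNoiseSd = 10,
                          missing = NULL) {
  stopifnot(nPatients >= 1)
  if (!length(observers)) stop("at least one observer model is required")
  states <- match.arg(states, ctStates, several.ok = TRUE)
  gridShape <- as.integer(gridShape)
  if (length(spacing) == 1L) spacing <- rep(spacing, 3L)
  specs <- volumes <- masks <- list()
  truthRows <- list()
  for (p in seq_len(nPatients)) {
    pid <- sprintf("P%02d", p)
    pseed <- mixSeed(seed, p)
    spec <- withSeed(pseed, drawPatientSpec(pid, pseed, gridShape, spacing,
                                            huMode, huNoiseSd))
    specs[[pid]] <- spec
    ps <- generatePatientSet(spec, observers, states, missing)
    volumes <- c(volumes, ps$volumes)
    masks <- c(masks, ps$masks)
    truthRows[[pid]] <- truthRow(spec)
  }
  new("PhantomStudy", specs = specs, volumes = volumes, masks = masks,
      truth = do.call(rbind, truthRows), seed = as.integer(seed))
}

#' Simulate a precision study patient-by-patient
#'
#' Generates the same cohort as [generateStudy()] but quantifies each patient
#' immediately and discards the voxel data, so arbitrarily large cohorts fit
#' in memory. This is the workhorse for simulation experiments on the
#' precision statistics (repeatability vs reproducibility of recruitment
#' under different observer-jitter settings).
#'
#' @inheritParams generateStudy
#' @param denominator recruitment denominator, see [recruitmentPeep()].
#' @return Wide parameter \code{data.frame} (one row per patient x observer,
#'   as [studyParameters()]) with the ground-truth table in attribute
#'   \code{"truth"}.
#' @export
simulateMeasurements <- function(nPatients = 13,
                                 observers = defaultObserverModels(),
                                 seed = 1L, states = ctStates,
                                 gridShape = c(48L, 48L, 40L), spacing = 1,
                                 huMode = "uniform", huNoiseSd = 10,
                                 missing = NULL,
                                 denominator = c("mean", "peep5")) {
  stopifnot(nPatients >= 1)
  if (!length(observers)) stop("at least one observer model is required")
  denominator <- match.arg(denominator)
  states <- match.arg(states, ctStates, several.ok = TRUE)
  gridShape <- as.integer(gridShape)
  if (length(spacing) == 1L) spacing <- rep(spacing, 3L)
  obsLabels <- vapply(observers, function(o) o@label, character(1))
  rows <- truthRows <- list()
  for (p in seq_len(nPatients)) {
    pid <- sprintf("P%02d", p)
    pseed <- mixSeed(seed, p)
    spec <- withSeed(pseed, drawPatientSpec(pid, pseed, gridShape, spacing,
                                            huMode, huNoiseSd))
    ps <- generatePatientSet(spec, observers, states, missing)
    for (obs in obsLabels) {
      profiles <- list()
      for (s in states) {
        vol <- ps$volumes[[paste(pid, s, sep = ".")]]
        msk <- ps$masks[[paste(pid, s, obs, sep = ".")]]
        if (is.null(vol) || is.null(msk)) next
        profiles[[s]] <- aerationProfile(vol, msk)
      }
      if (!length(profiles)) next
      pp <- patientParameters(profiles, pbw = spec@pbw,
                              denominator = denominator)
      pp$observer <- obs
      rows[[length(rows) + 1L]] <- pp
    }
    truthRows[[pid]] <- truthRow(spec)
  }
  out <- do.call(rbind, rows)
  attr(out, "truth") <- do.call(rbind, truthRows)
  out
}
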