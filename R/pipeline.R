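## End-to-end orchestration: simulate -> quantify -> compare-masks ->
## precision, either in memory from a PhantomStudy or manifest-driven from
## NIfTI files on disk. The manifest is a CSV mapping (patient, state,
## observer) to files; outputs are plain CSVs, each run accompanied by a
## provenance file recording the seed and the conventions in force.

parameterColumns <- c(
  "recruitment_peep_5_15_pct", "tidal_recruitment_pct",
  "tidal_hyperinflation_ml_kg", "eelv_peep5_ml", "eelv_peep15_ml",
  "hyperinflation_peep5_ml_kg", "hyperinflation_peep15_ml_kg",
  "nonaerated_peep5_pct", "nonaerated_peep15_pct",
  "weight_peep5_g", "weight_peep15_g")

writeProvenance <- function(outDir, seed, extra = list()) {
  info <- c(list(package = "lungqct",
                 version = as.character(utils::packageVersion("lungqct")),
                 seed = seed,
                 timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S")),
            extra)
  df <- data.frame(key = names(info),
                   value = vapply(info, function(x) paste(x, collapse = ";"),
                                  character(1)))
  write.csv(df, file.path(outDir, "provenance.csv"), row.names = FALSE)
}

#' Write a phantom study to disk as NIfTI files plus manifests
#'
#' Creates \code{<outDir>/} with one NIfTI volume per (patient, state), one
#' NIfTI mask per (patient, state, observer), \code{manifest.csv} mapping
#' labels to files (including per-patient PBW), \code{truth.csv} with the
#' programmed ground-truth parameters, and \code{provenance.csv}.
#'
#' @param study a [PhantomStudy-class], e.g. from [generateStudy()].
#' @param outDir output directory (created if absent).
#' @return The manifest \code{data.frame}, invisibly.
#' @export
simulateStudy <- function(study, outDir) {
  stopifnot(is(study, "PhantomStudy"))
  dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
  rows <- list()
  for (key in names(study@volumes)) {
    parts <- strsplit(key, ".", fixed = TRUE)[[1]]
    pid <- parts[1]; state <- parts[2]
    vfile <- sprintf("%s_%s.nii.gz", pid, state)
    writeVolume(study@volumes[[key]], file.path(outDir, vfile))
    obsKeys <- grep(paste0("^", pid, "\\.", state, "\\."), names(study@masks),
                    value = TRUE)
    for (mk in names(study@masks)[names(study@masks) %in% obsKeys]) {
      obs <- strsplit(mk, ".", fixed = TRUE)[[1]][3]
      mfile <- sprintf("%s_%s_%s.nii.gz", pid, state, obs)
      writeVolume(study@masks[[mk]], file.path(outDir, mfile))
      rows[[length(rows) + 1L]] <- data.frame(
        patient_id = pid, state = state, observer = obs,
        volume_path = vfile, mask_path = mfile,
        pbw_kg = study@truth$pbw_kg[study@truth$patient_id == pid],
        stringsAsFactors = FALSE)
    }
  }
  manifest <- do.call(rbind, rows)
  write.csv(manifest, file.path(outDir, "manifest.csv"), row.names = FALSE)
  write.csv(study@truth, file.path(outDir, "truth.csv"), row.names = FALSE)
  writeProvenance(outDir, study@seed)
  invisible(manifest)
}

readManifest <- function(manifest) {
  if (is.character(manifest)) {
    dir <- dirname(manifest)
    manifest <- read.csv(manifest, stringsAsFactors = FALSE)
    for (col in c("volume_path", "mask_path"))
      manifest[[col]] <- ifelse(file.exists(manifest[[col]]),
                                manifest[[col]],
                                file.path(dir, manifest[[col]]))
  }
  need <- c("patient_id", "state", "observer", "volume_path", "mask_path")
  if (!nrow(manifest) || !all(need %in% names(manifest)))
    stop("configuration error: manifest needs columns ",
         paste(need, collapse = ", "), " and at least one row")
  manifest
}

#' Quantify every (patient, observer) of a manifest
#'
#' Reads each aligned volume/mask pair, computes its aeration profile and
#' assembles the per-patient CT parameters per observer. Failures on single
#' pairs are collected and reported (attribute \code{"errors"}); the run
#' continues.
#'
#' @param manifest manifest \code{data.frame} or path to \code{manifest.csv}
#'   (columns \code{patient_id, state, observer, volume_path, mask_path,
#'   pbw_kg}).
#' @param denominator recruitment denominator, see [recruitmentPeep()].
#' @param outDir if given, \code{parameters.csv} and \code{summary.csv} are
#'   written there.
#' @param seed recorded in the provenance file (no randomness is involved).
#' @return \code{data.frame} of parameters, one row per (patient, observer),
#'   with a cohort summary (median, IQR, range of each parameter) in
#'   attribute \code{"summary"} and any per-file errors in attribute
#'   \code{"errors"}.
#' @export
quantifyCohort <- function(manifest, denominator = c("mean", "peep5"),
                           outDir = NULL, seed = NA_integer_) {
  denominator <- match.arg(denominator)
  manifest <- readManifest(manifest)
  if (!("pbw_kg" %in% names(manifest)))
    stop("configuration error: manifest lacks a pbw_kg column")
  rows <- list(); errs <- character()
  for (pid in unique(manifest$patient_id)) {
    sub <- manifest[manifest$patient_id == pid, ]
    for (obs in unique(sub$observer)) {
      if (obs == "REFERENCE" && length(unique(sub$observer)) > 1L) next
      so <- sub[sub$observer == obs, ]
      profiles <- list()
      for (i in seq_len(nrow(so))) {
        res <- tryCatch({
          vol <- readVolume(so$volume_path[i], "image", patientId = pid,
                            state = so$state[i])
          msk <- readVolume(so$mask_path[i], "mask", patientId = pid,
                            state = so$state[i], observer = obs)
          aerationProfile(vol, msk)
        }, error = function(e) conditionMessage(e))
        if (is.character(res))
          errs <- c(errs, sprintf("%s/%s/%s: %s", pid, so$state[i], obs, res))
        else profiles[[so$state[i]]] <- res
      }
      if (!length(profiles)) next
      pp <- patientParameters(profiles, pbw = so$pbw_kg[1],
                              denominator = denominator)
      pp$observer <- obs
      rows[[length(rows) + 1L]] <- pp
    }
  }
  if (!length(rows)) stop("no quantifiable (patient, observer) pairs")
  out <- do.call(rbind, rows)
  smry <- cohortSummary(out)
  attr(out, "summary") <- smry
  attr(out, "errors") <- errs
  if (!is.null(outDir)) {
    dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
    write.csv(out, file.path(outDir, "parameters.csv"), row.names = FALSE)
    write.csv(smry, file.path(outDir, "summary.csv"), row.names = FALSE)
    writeProvenance(outDir, seed, list(denominator = denominator))
  }
  out
}

cohortSummary <- function(params) {
  present <- intersect(parameterColumns, names(params))
  do.call(rbind, lapply(present, function(col) {
    v <- params[[col]]
    v <- v[is.finite(v)]
    if (!length(v)) return(NULL)
    data.frame(parameter = col, n = length(v),
               median = median(v),
               iqr_lower = unname(quantile(v, 0.25)),
               iqr_upper = unname(quantile(v, 0.75)),
               min = min(v), max = max(v), stringsAsFactors = FALSE)
  }))
}

#' Segmentation-agreement table of a manifest
#'
#' For every volume with the required mask pair, computes DSC, ASSD and MSSD
#' for the requested comparisons (intra-observer: observer 1 run 1 vs run 2;
#' human-human: run 1 vs observer 2; human-ML: run 1 vs the machine), plus a
#' median [IQR] summary per comparison.
#'
#' @param manifest as in [quantifyCohort()].
#' @param comparisons subset of \code{comparisonTypes}.
#' @param outDir if given, \code{agreement.csv} and
#'   \code{agreement_summary.csv} are written there.
#' @param seed recorded in provenance only.
#' @return Per-volume \code{data.frame} (\code{patient_id, state, comparison,
#'   dsc, assd_mm, mssd_mm}) with the summary in attribute \code{"summary"}.
#' @export
compareMasks <- function(manifest, comparisons = comparisonTypes,
                         outDir = NULL, seed = NA_integer_) {
  manifest <- readManifest(manifest)
  comparisons <- match.arg(comparisons, comparisonTypes, several.ok = TRUE)
  if (length(unique(manifest$observer)) < 2L)
    stop("configuration error: at least two mask sets per volume are required")
  rows <- list(); errs <- character()
  for (pid in unique(manifest$patient_id)) {
    sub <- manifest[manifest$patient_id == pid, ]
    for (st in unique(sub$state)) {
      ss <- sub[sub$state == st, ]
      for (cmp in comparisons) {
        obs <- comparisonObservers(cmp)
        pa <- ss$mask_path[ss$observer == obs[1]]
        pb <- ss$mask_path[ss$observer == obs[2]]
        if (!length(pa) || !length(pb)) next
        res <- tryCatch({
          ma <- readVolume(pa[1], "mask", patientId = pid, state = st,
                           observer = obs[1])
          mb <- readVolume(pb[1], "mask", patientId = pid, state = st,
                           observer = obs[2])
          cbind(data.frame(patient_id = pid, state = st,
                           stringsAsFactors = FALSE),
                agreementMetrics(ma, mb, comparison = cmp))
        }, error = function(e) conditionMessage(e))
        if (is.character(res))
          errs <- c(errs, sprintf("%s/%s/%s: %s", pid, st, cmp, res))
        else rows[[length(rows) + 1L]] <- res
      }
    }
  }
  if (!length(rows)) stop("no comparable mask pairs found in the manifest")
  out <- do.call(rbind, rows)
  smry <- do.call(rbind, lapply(split(out, out$comparison), function(g)
    data.frame(comparison = g$comparison[1], n = nrow(g),
               dsc_median = median(g$dsc),
               assd_median_mm = median(g$assd_mm),
               assd_iqr_lower = unname(quantile(g$assd_mm, 0.25)),
               assd_iqr_upper = unname(quantile(g$assd_mm, 0.75)),
               mssd_median_mm = median(g$mssd_mm),
               stringsAsFactors = FALSE)))
  attr(out, "summary") <- smry
  attr(out, "errors") <- errs
  if (!is.null(outDir)) {
    dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
    write.csv(out, file.path(outDir, "agreement.csv"), row.names = FALSE)
    write.csv(smry, file.path(outDir, "agreement_summary.csv"),
              row.names = FALSE)
    writeProvenance(outDir, seed)
  }
  out
}

#' Long measurement table from a wide parameter table
#'
#' Reshapes the output of [quantifyCohort()] or [studyParameters()] to the
#' long (patient, observer, parameter, value) form [precisionReport()]
#' expects.
#'
#' @param params wide parameter \code{data.frame} with \code{patient_id} and
#'   \code{observer} columns.
#' @return Long \code{data.frame} with one row per measurement.
#' @export
measurementsLong <- function(params) {
  present <- intersect(parameterColumns, names(params))
  do.call(rbind, lapply(present, function(col)
    data.frame(patient_id = params$patient_id, observer = params$observer,
               parameter = col, value = params[[col]],
               stringsAsFactors = FALSE)))
}

#' Quantify a PhantomStudy in memory
#'
#' Computes the per-(patient, observer) CT parameters of a generated study
#' without touching disk.
#'
#' @param study a [PhantomStudy-class].
#' @param observers observer labels to quantify (default the perturbed ones
#'   present).
#' @param denominator recruitment denominator.
#' @return Wide parameter \code{data.frame} as from [quantifyCohort()].
#' @export
studyParameters <- function(study, observers = NULL,
                            denominator = c("mean", "peep5")) {
  stopifnot(is(study, "PhantomStudy"))
  denominator <- match.arg(denominator)
  maskKeys <- strsplit(names(study@masks), ".", fixed = TRUE)
  allObs <- unique(vapply(maskKeys, `[`, character(1), 3))
  if (is.null(observers)) observers <- setdiff(allObs, "REFERENCE")
  rows <- list()
  for (pid in names(study@specs)) {
    pbw <- study@specs[[pid]]@pbw
    for (obs in observers) {
      profiles <- list()
      for (s in ctStates) {
        vol <- studyVolume(study, pid, s)
        msk <- studyMask(study, pid, s, obs)
        if (is.null(vol) || is.null(msk)) next
        profiles[[s]] <- aerationProfile(vol, msk)
      }
      if (!length(profiles)) next
      pp <- patientParameters(profiles, pbw = pbw, denominator = denominator)
      pp$observer <- obs
      rows[[length(rows) + 1L]] <- pp
    }
  }
  do.call(rbind, rows)
}

#' Precision tables from a quantified cohort
#'
#' Runs [precisionReport()] on the long form of a wide parameter table and
#' optionally writes the resulting bias / RC / RDC table.
#'
#' @param params wide parameter table ([quantifyCohort()] /
#'   [studyParameters()] output).
#' @param comparisons subset of \code{comparisonTypes}.
#' @param nBoot,seed bootstrap settings.
#' @param outDir if given, \code{precision.csv} is written there.
#' @return The [precisionReport()] \code{data.frame}.
#' @export
precisionTables <- function(params, comparisons = comparisonTypes,
                            nBoot = 1000, seed = 1L, outDir = NULL) {
  long <- measurementsLong(params)
  rep <- precisionReport(long, comparisons = comparisons,
                         nBoot = nBoot, seed = seed)
  if (!is.null(outDir)) {
    dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
    write.csv(rep, file.path(outDir, "precision.csv"), row.names = FALSE)
    writeProvenance(outDir, seed, list(n_boot = nBoot))
  }
  rep
}
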