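## Repeatability and reproducibility of paired per-patient CT measurements.
##
## Every comparison in the study design yields exactly two measurements per
## patient (two runs of one observer, or two observers), so the within- and
## between-observer SDs are both estimated by the duplicate-difference
## estimator S = sqrt(sum(d_i^2) / 2n), which for two measurements per
## subject coincides with the one-way ANOVA within-subject SD. The
## repeatability / reproducibility coefficient (the smallest real difference
## exceeding measurement error) is S * sqrt(2) * 1.96, with BCa bootstrap
## confidence intervals resampling patients.

differences <- function(pairs) pairs@valuesA - pairs@valuesB

#' Bland-Altman bias and limits of agreement
#'
#' Per-patient differences \code{d = a - b}; bias is their mean, with a
#' t-based 95\% CI (n - 1 df), and the limits of agreement are
#' \code{bias +/- 1.96 SD(d)} with the n - 1 sample SD.
#'
#' @param pairs a [PairedMeasurementSet-class] (n >= 2).
#' @return A list: \code{bias}, \code{biasCi95} (length 2), \code{loaLower},
#'   \code{loaUpper}, \code{sd}, \code{n}.
#' @export
blandAltman <- function(pairs) {
  stopifnot(is(pairs, "PairedMeasurementSet"))
  d <- differences(pairs)
  n <- length(d)
  bias <- mean(d)
  s <- sd(d)
  half <- qt(0.975, df = n - 1) * s / sqrt(n)
  list(bias = bias,
       biasCi95 = c(bias - half, bias + half),
       loaLower = bias - 1.96 * s,
       loaUpper = bias + 1.96 * s,
       sd = s, n = n)
}

#' Within-pair standard deviation of duplicate measurements
#'
#' The duplicate-measurement estimator \code{S = sqrt(sum(d_i^2) / (2 n))} of
#' the within-subject (intra-observer) or between-observer SD.
#'
#' @param pairs a [PairedMeasurementSet-class] with one pair per patient.
#' @return S, in the units of the parameter.
#' @export
withinPairSd <- function(pairs) {
  stopifnot(is(pairs, "PairedMeasurementSet"))
  d <- differences(pairs)
  sqrt(sum(d^2) / (2 * length(d)))
}

#' Repeatability and reproducibility coefficients
#'
#' \code{RC = S_W * sqrt(2) * 1.96} (same observer, repeated measurements) and
#' \code{RDC = S_B * sqrt(2) * 1.96} (different observers): the smallest real
#' difference exceeding measurement error in each condition.
#'
#' @param sw,sb within- / between-observer SD (>= 0), e.g. from
#'   [withinPairSd()].
#' @return The coefficient, in the units of the SD.
#' @examples
#' repeatabilityCoefficient(1)  # 2.772
#' @export
repeatabilityCoefficient <- function(sw) {
  if (!is.numeric(sw) || any(sw < 0)) stop("sw must be non-negative")
  sw * sqrt(2) * 1.96
}

#' @rdname repeatabilityCoefficient
#' @export
reproducibilityCoefficient <- function(sb) {
  if (!is.numeric(sb) || any(sb < 0)) stop("sb must be non-negative")
  sb * sqrt(2) * 1.96
}

#' RC of a paired set in one step
#'
#' \code{repeatabilityCoefficient(withinPairSd(pairs))}; the natural statistic
#' to bootstrap with [bcaCi()].
#'
#' @param pairs a [PairedMeasurementSet-class].
#' @return The repeatability (or reproducibility) coefficient.
#' @export
rcStatistic <- function(pairs) repeatabilityCoefficient(withinPairSd(pairs))

# bootstrap/jackknife resamples repeat or drop patients, so they bypass the
# one-entry-per-patient validity of the public constructor
resampleSet <- function(pairs, idx) {
  out <- pairs
  out@patientIds <- sprintf("r%d", seq_along(idx))
  out@valuesA <- pairs@valuesA[idx]
  out@valuesB <- pairs@valuesB[idx]
  out
}

#' BCa bootstrap confidence interval of a paired-set statistic
#'
#' Non-parametric bootstrap resampling patients with replacement; the interval
#' is bias-corrected and accelerated: the bias correction z0 comes from the
#' fraction of replicates below the point estimate, the acceleration from the
#' jackknife skewness. Replicates on which the statistic is undefined
#' (non-finite, e.g. an SD of an all-identical resample) are dropped and
#' counted. Deterministic under a fixed seed.
#'
#' @param statistic function mapping a [PairedMeasurementSet-class] to a
#'   scalar.
#' @param pairs a [PairedMeasurementSet-class].
#' @param nBoot number of replicates (default 1000).
#' @param seed integer RNG seed.
#' @param conf confidence level (default 0.95).
#' @return A list: \code{lower}, \code{upper}, \code{estimate},
#'   \code{nBoot}, \code{nDropped}, \code{seed}.
#' @export
bcaCi <- function(statistic, pairs, nBoot = 1000, seed = 1L, conf = 0.95) {
  stopifnot(is(pairs, "PairedMeasurementSet"), nBoot >= 2)
  n <- length(pairs@patientIds)
  t0 <- statistic(pairs)
  res <- local({
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
    set.seed(as.integer(seed))
    vapply(seq_len(nBoot), function(b) {
      idx <- sample.int(n, n, replace = TRUE)
      statistic(resampleSet(pairs, idx))
    }, numeric(1))
  })
  keep <- is.finite(res)
  nDropped <- sum(!keep)
  tb <- res[keep]
  if (!length(tb))
    stop("statistic undefined on every bootstrap replicate")
  out <- list(estimate = t0, nBoot = nBoot, nDropped = nDropped,
              seed = as.integer(seed))
  if (all(tb == tb[1]) && tb[1] == t0) {  # constant statistic
    out$lower <- t0; out$upper <- t0
    return(out)
  }
  alpha <- c((1 - conf) / 2, 1 - (1 - conf) / 2)
  propBelow <- (sum(tb < t0) + 0.5 * sum(tb == t0)) / length(tb)
  propBelow <- min(max(propBelow, 1 / (2 * length(tb))), 1 - 1 / (2 * length(tb)))
  z0 <- qnorm(propBelow)
  # jackknife acceleration
  tj <- vapply(seq_len(n), function(i)
    statistic(resampleSet(pairs, setdiff(seq_len(n), i))), numeric(1))
  u <- mean(tj) - tj
  denom <- sum(u^2)^1.5
  a <- if (denom > 0) sum(u^3) / (6 * denom) else 0
  zadj <- z0 + qnorm(alpha)
  padj <- pnorm(z0 + zadj / (1 - a * zadj))
  ci <- quantile(tb, probs = padj, names = FALSE, type = 7)
  out$lower <- ci[1]; out$upper <- ci[2]
  out
}

#' Subjects needed to estimate the within-subject SD to a given precision
#'
#' \code{n = z^2_(1 - alpha/2) / (2 precision^2 (m - 1))}, reported as its
#' integer part, for \code{m} replicate measurements per subject and a target
#' relative precision of the within-subject SD estimate.
#'
#' @param precision relative precision of S_W, in (0, 1) (0.40 = 40\%).
#' @param alpha two-sided error level (default 0.05).
#' @param replicatesPerSubject measurements per subject, m >= 2 (default 2).
#' @return Required number of subjects (integer).
#' @examples
#' planSampleSize(0.40, 0.05, 2)  # 12
#' @export
planSampleSize <- function(precision, alpha = 0.05, replicatesPerSubject = 2) {
  if (!is.numeric(precision) || length(precision) != 1L ||
      precision <= 0 || precision >= 1)
    stop("precision must lie strictly between 0 and 1")
  if (!is.numeric(alpha) || alpha <= 0 || alpha >= 1)
    stop("alpha must lie strictly between 0 and 1")
  m <- replicatesPerSubject
  if (!is.numeric(m) || m < 2)
    stop("replicatesPerSubject must be >= 2")
  z <- qnorm(1 - alpha / 2)
  as.integer(floor(z^2 / (2 * precision^2 * (m - 1))))
}

# observer pair defining each comparison (run 1 of observer 1 is the
# reference against the second run, observer 2 and the machine)
comparisonObservers <- function(comparison, reference = "OBS1_RUN1") {
  switch(comparison,
         intra_observer = c(reference, "OBS1_RUN2"),
         inter_human_human = c(reference, "OBS2"),
         inter_human_ml = c(reference, "ML"),
         stop("unknown comparison: ", comparison))
}

#' Precision report across parameters and observer comparisons
#'
#' From a long table of per-(patient, observer) parameter values, builds the
#' paired sets for each requested comparison (intra-observer: observer 1 run 1
#' vs run 2; human-human: run 1 vs observer 2; human-ML: run 1 vs the machine
#' segmentation), and reports Bland-Altman bias with 95\% CI and the RC / RDC
#' with BCa bootstrap CIs.
#'
#' @param measurements \code{data.frame} with columns \code{patient_id},
#'   \code{observer} (labels from \code{ctObservers}), \code{parameter},
#'   \code{value}.
#' @param comparisons subset of \code{comparisonTypes}.
#' @param nBoot,seed bootstrap settings, see [bcaCi()].
#' @param reference observer used as reference measurement (default
#'   \code{"OBS1_RUN1"}).
#' @return A \code{data.frame}, one row per (parameter, comparison):
#'   bias, bias CI, limits of agreement, S, coefficient (RC for
#'   intra-observer, RDC otherwise) and its CI, n, and the number of dropped
#'   bootstrap replicates.
#' @export
precisionReport <- function(measurements, comparisons = comparisonTypes,
                            nBoot = 1000, seed = 1L,
                            reference = "OBS1_RUN1") {
  need <- c("patient_id", "observer", "parameter", "value")
  if (!all(need %in% names(measurements)))
    stop("measurements must have columns: ", paste(need, collapse = ", "))
  comparisons <- match.arg(comparisons, comparisonTypes, several.ok = TRUE)
  rows <- list()
  for (param in unique(measurements$parameter)) {
    sub <- measurements[measurements$parameter == param, ]
    for (cmp in comparisons) {
      obs <- comparisonObservers(cmp, reference)
      a <- sub[sub$observer == obs[1], c("patient_id", "value")]
      b <- sub[sub$observer == obs[2], c("patient_id", "value")]
      if (!nrow(a) || !nrow(b))
        stop("configuration error: observer column '",
             obs[!c(nrow(a), nrow(b))][1],
             "' missing for comparison ", cmp)
      mrg <- merge(a, b, by = "patient_id", suffixes = c("_a", "_b"))
      mrg <- mrg[is.finite(mrg$value_a) & is.finite(mrg$value_b), ]
      if (nrow(mrg) < 2L) {
        warning("fewer than two complete pairs for ", param, " / ", cmp,
                "; skipped")
        next
      }
      pm <- pairedMeasurements(mrg$patient_id, mrg$value_a, mrg$value_b,
                               parameter = param, comparison = cmp)
      ba <- blandAltman(pm)
      s <- withinPairSd(pm)
      coefFun <- if (cmp == "intra_observer") repeatabilityCoefficient
                 else reproducibilityCoefficient
      ci <- bcaCi(function(p) coefFun(withinPairSd(p)), pm,
                  nBoot = nBoot, seed = seed)
      rows[[length(rows) + 1L]] <- data.frame(
        parameter = param, comparison = cmp, n = ba$n,
        bias = ba$bias, bias_ci_lower = ba$biasCi95[1],
        bias_ci_upper = ba$biasCi95[2],
        loa_lower = ba$loaLower, loa_upper = ba$loaUpper,
        s = s,
        coefficient_type = if (cmp == "intra_observer") "RC" else "RDC",
        coefficient = coefFun(s),
        coefficient_ci_lower = ci$lower, coefficient_ci_upper = ci$upper,
        n_boot = ci$nBoot, n_dropped = ci$nDropped, seed = ci$seed,
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}
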