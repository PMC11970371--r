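#' Confusion counts of carrier calls against simulation truth
#'
#' @param calls data.frame with columns individual_id and call (logical), as
#'   returned by [callCarriers()].
#' @param truth data.frame with columns individual_id and is_case.
#' @return named integer vector c(tp, fp, tn, fn).
#' @export
confusionCounts <- function(calls, truth) {
  if (!setequal(calls$individual_id, truth$individual_id))
    stop("calls and truth refer to different individual sets")
  isCase <- truth$is_case[match(calls$individual_id, truth$individual_id)]
  c(tp = sum(calls$call & isCase), fp = sum(calls$call & !isCase),
    tn = sum(!calls$call & !isCase), fn = sum(!calls$call & isCase))
}

#' Precision-recall curve and AUPRC
#'
#' Sweeps all score thresholds and computes the area under the PR curve in
#' the average-precision (step-interpolation) form,
#' \code{sum_k (R_k - R_(k-1)) * P_k} over decreasing thresholds.  Linear
#' (trapezoidal) interpolation of precision is deliberately not used: it is
#' optimistic on PR curves.  The random-classifier reference value is the
#' baseline rate, cases / cohort size.
#'
#' @param scores named numeric vector of per-individual scores.
#' @param truth data.frame with individual_id and is_case; at least one case.
#' @return list: \code{points} (data.frame threshold, precision, recall) and
#'   \code{auprc}.
#' @export
prCurve <- function(scores, truth) {
  isCase <- truth$is_case[match(names(scores), truth$individual_id)]
  if (anyNA(isCase)) stop("scores and truth refer to different individuals")
  nPos <- sum(isCase)
  if (nPos == 0L) stop("AUPRC undefined with zero cases")
  o <- order(-scores, names(scores))
  y <- isCase[o]
  s <- scores[o]
  cumTp <- cumsum(y)
  cumP <- seq_along(y)
  # group tied scores: a threshold admits every individual at that score
  last <- !duplicated(s, fromLast = TRUE)
  tp <- cumTp[last]
  p <- cumP[last]
  precision <- tp / p
  recall <- tp / nPos
  dR <- diff(c(0, recall))
  auprc <- sum(dR * precision)
  list(points = data.frame(threshold = s[last], precision = precision,
                           recall = recall, row.names = NULL),
       auprc = auprc)
}

#' Evaluation summary of one scored scenario
#'
#' Two sensitivity definitions are reported: \code{sensitivity} counts all
#' simulated cases (used when judging performance as a function of the
#' haplotype set), while \code{sensitivity_ancestral} restricts to cases
#' whose implanted segment descends from a haplotype present in the scoring
#' set (per-founder reporting).
#'
#' @param scores named numeric per-individual max IBD scores.
#' @param truth scenario truth table.
#' @param threshold critical value used for calls.
#' @param percentile the percentile the threshold came from (bookkeeping).
#' @param hapIdsUsed haplotype ids of the scoring set (for the ancestral
#'   sensitivity definition); default: every source hap in the truth table.
#' @return one-row data.frame: n_cases, n_controls, sensitivity,
#'   sensitivity_ancestral, fpr, auprc, baseline_rate, threshold, percentile.
#' @export
evalSummary <- function(scores, truth, threshold, percentile = NA_real_,
                        hapIdsUsed = NULL) {
  calls <- callCarriers(scores, threshold)
  cc <- confusionCounts(calls, truth)
  nCases <- sum(truth$is_case)
  nControls <- sum(!truth$is_case)
  called <- calls$individual_id[calls$call]
  if (is.null(hapIdsUsed))
    hapIdsUsed <- unique(stats::na.omit(truth$source_hap))
  anc <- truth$is_case & truth$source_hap %in% hapIdsUsed
  sensAnc <- if (any(anc)) mean(truth$individual_id[anc] %in% called)
             else NA_real_
  data.frame(
    n_cases = nCases, n_controls = nControls,
    sensitivity = if (nCases > 0) cc[["tp"]] / nCases else NA_real_,
    sensitivity_ancestral = sensAnc,
    fpr = if (nControls > 0) cc[["fp"]] / nControls else NA_real_,
    auprc = if (nCases > 0) prCurve(scores, truth)$auprc else NA_real_,
    baseline_rate = nCases / (nCases + nControls),
    threshold = threshold, percentile = percentile)
}

#' Run a scenario grid
#'
#' For each scenario: simulate, score every disease-test pair, take the
#' per-individual maximum, compare against the control cohort's percentile
#' critical value, and summarise.  Also reports sensitivity and AUPRC as a
#' function of the number of disease haplotypes in use (scoring with the
#' first k haplotypes, k = 1..n), which shows how accumulating unique
#' disease haplotypes improves detection.  Scoring is batch-parallelisable
#' over disease-test pairs; aggregation is deterministic and independent of
#' chunking.
#'
#' @param scenarios list of [ScenarioSpec-class].
#' @param cohort base [PhasedCohort-class] used to build test cohorts.
#' @param panel annotated [MarkerPanel-class].
#' @param controls [PhasedCohort-class] providing the empirical null.
#' @param params an [HMMParams-class].
#' @param percentile critical-value percentile (default 99).
#' @param byHapCounts also compute the by-number-of-haplotypes curves.
#' @return list: \code{summary} (one row per scenario) and \code{byHaps}
#'   (one row per scenario x haplotype count, when requested).
#' @export
runGrid <- function(scenarios, cohort, panel, controls,
                    params = HMMParams(), percentile = 99,
                    byHapCounts = TRUE) {
  summaries <- list()
  byHaps <- list()
  nullCache <- new.env(parent = emptyenv())
  for (si in seq_along(scenarios)) {
    spec <- scenarios[[si]]
    sim <- runScenario(spec, cohort, panel)
    m <- scoreMatrix(sim$diseaseHaps, sim$testCohort, panel, params)
    # disease haplotypes depend only on (mode, seed, n, locus, core), so the
    # control scores can be shared across sharing lengths
    key <- paste(spec@founderMode, spec@seed, spec@nDiseaseHaps,
                 spec@locusId, max(5, spec@sharingLengthCm), sep = "|")
    mNull <- get0(key, envir = nullCache, ifnotfound = NULL)
    if (is.null(mNull)) {
      mNull <- scoreMatrix(sim$diseaseHaps, controls, panel, params)
      assign(key, mNull, envir = nullCache)
    }
    hapIds <- colnames(m)
    maxAll <- apply(m, 1L, max)
    null <- NullDistribution(spec@locusId, apply(mNull, 1L, max),
                             panelFingerprint(panel))
    thr <- criticalValue(null, percentile)
    s <- evalSummary(maxAll, sim$truth, thr, percentile)
    s <- cbind(data.frame(locus_id = spec@locusId,
                          founder_mode = spec@founderMode,
                          sharing_cm = spec@sharingLengthCm,
                          seed = spec@seed), s)
    summaries[[si]] <- s
    if (byHapCounts) {
      cmT <- t(apply(m, 1L, cummax))     # max over first k haps
      cmN <- t(apply(mNull, 1L, cummax))
      rows <- lapply(seq_along(hapIds), function(k) {
        nk <- NullDistribution(spec@locusId, cmN[, k],
                               panelFingerprint(panel))
        sk <- evalSummary(stats::setNames(cmT[, k], rownames(m)), sim$truth,
                          criticalValue(nk, percentile), percentile,
                          hapIdsUsed = hapIds[seq_len(k)])
        cbind(data.frame(locus_id = spec@locusId,
                         founder_mode = spec@founderMode,
                         sharing_cm = spec@sharingLengthCm,
                         seed = spec@seed, n_haps_used = k), sk)
      })
      byHaps[[si]] <- do.call(rbind, rows)
    }
  }
  list(summary = do.call(rbind, summaries),
       byHaps = if (byHapCounts) do.call(rbind, byHaps) else NULL)
}
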