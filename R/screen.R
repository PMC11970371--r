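#' Screen a test cohort for carriers of a disease haplotype
#'
#' In-memory pipeline stage: scores every disease haplotype against every
#' test individual, takes the per-individual maximum, calibrates against the
#' control null and produces calls by percentile threshold (and optionally a
#' top-N ranking).
#'
#' @param diseaseHaps list of [DiseaseHaplotype-class].
#' @param test [PhasedCohort-class] of test individuals.
#' @param null a [NullDistribution-class] built on the same panel.
#' @param panel annotated [MarkerPanel-class].
#' @param params an [HMMParams-class].
#' @param percentile critical-value percentile (default 99).
#' @param nTop optional top-N prioritisation size; when given, the reported
#'   \code{call} column marks the top N instead of the threshold exceedance
#'   (both the rank and the empirical p remain available).
#' @return data.frame: individual_id, variant_id, best_hap_id, ibd_score,
#'   empirical_p, call, rank; attribute \code{"criticalValue"} holds the
#'   threshold used.
#' @export
screenCohort <- function(diseaseHaps, test, null, panel,
                         params = HMMParams(), percentile = 99,
                         nTop = NULL) {
  checkFingerprint(null, panel)
  res <- scoreCohort(diseaseHaps, test, panel, params)
  scores <- stats::setNames(res$score, res$individual_id)
  thr <- criticalValue(null, percentile)
  calls <- if (is.null(nTop)) callCarriers(scores, thr) else {
    ranked <- callCarriers(scores, thr)
    ranked$call <- ranked$rank <= min(nTop, nrow(ranked))
    ranked
  }
  out <- merge(res, calls, by = "individual_id")
  out$ibd_score <- out$score.x
  out$empirical_p <- empiricalP(out$ibd_score, null)
  out <- out[order(out$rank), c("individual_id", "variant_id",
                                "best_hap_id", "ibd_score", "empirical_p",
                                "call", "rank")]
  rownames(out) <- NULL
  attr(out, "criticalValue") <- thr
  out
}

#' Parse a flat key-value run configuration file
#'
#' One \code{key = value} (or \code{key: value}) pair per line; '#' starts a
#' comment.  Values are returned as character and coerced by the consumer.
#'
#' @param path config file path.
#' @return named list of character values.
#' @export
parseRunConfig <- function(path) {
  lines <- readLines(path)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines[nzchar(trimws(lines))])
  kv <- regmatches(lines, regexec("^([^=:]+)[=:](.*)$", lines))
  bad <- lengths(kv) != 3L
  if (any(bad)) stop(sprintf("unparseable config line: '%s'",
                             lines[bad][1L]))
  stats::setNames(lapply(kv, function(x) trimws(x[3L])),
                  vapply(kv, function(x) trimws(x[2L]), character(1)))
}

cfgNum <- function(cfg, key, default = NULL) {
  if (!is.null(cfg[[key]])) as.numeric(cfg[[key]])
  else if (!is.null(default)) default
  else stop(sprintf("config key '%s' is required", key))
}

cfgChr <- function(cfg, key, default = NULL) {
  if (!is.null(cfg[[key]])) cfg[[key]]
  else if (!is.null(default)) default
  else stop(sprintf("config key '%s' is required", key))
}

# shared load->trim->filter->annotate stage; cohortKey names the config
# entry holding the VCF whose samples become the scored cohort
prepareScreenInputs <- function(cfg, cohortKey = "test_vcf") {
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop(sprintf("[%s] %s", name, conditionMessage(e)), call. = FALSE))
  }
  dcvChrom <- cfgChr(cfg, "dcv_chrom")
  dcvPosBp <- cfgNum(cfg, "dcv_pos")
  params <- HMMParams(
    g = cfgNum(cfg, "g", 0.01),
    decayMeioses = cfgNum(cfg, "decay_meioses", 20),
    switchRatePerBp = cfgNum(cfg, "switch_rate_per_bp", 1 / 20.05e6),
    dropThreshold = cfgNum(cfg, "drop_threshold", 10))

  test <- stage("load-cohort", readPhasedVcf(cfgChr(cfg, cohortKey)))
  map <- stage("load-map", readGeneticMap(cfgChr(cfg, "map")))
  freq <- stage("load-frequencies",
                readFrequencyTable(cfgChr(cfg, "freq_table")))

  panel <- stage("annotate", {
    p <- setDcv(test$panel, dcvChrom, dcvPosBp)
    annotateGeneticMap(p, map)
  })
  cohort <- test$cohort

  flank <- cfgNum(cfg, "flank_cm", 10)
  idx <- stage("trim", windowIndices(panel, flank))
  panel <- panel[idx]; cohort <- cohort[idx, ]

  filt <- stage("filter",
                filterMarkers(panel, cohort,
                              minImputeR2 = cfgNum(cfg, "min_impute_r2", 0.3),
                              nMultiallelicDropped = test$nMultiallelicDropped))
  panel <- filt$panel; cohort <- filt$cohort
  message(paste(sprintf("marker filter: %s=%d", filt$report$rule,
                        filt$report$count), collapse = ", "))

  fr <- stage("frequencies", attachFrequencies(panel, freq, cohort))
  panel <- fr$panel; cohort <- fr$cohort

  dis <- stage("load-disease", readPhasedVcf(cfgChr(cfg, "disease_vcf")))
  disPanelIdx <- match(markerPos(panel), markerPos(dis$panel))
  if (anyNA(disPanelIdx))
    stop("[load-disease] disease VCF does not cover the analysis panel")
  variant <- cfgChr(cfg, "variant_id", "DCV")
  diseaseHaps <- lapply(individualIds(dis$cohort), function(id)
    DiseaseHaplotype(id, variant, hapA(dis$cohort)[disPanelIdx, id],
                     dcvChrom, dcvPosBp))

  list(panel = panel, cohort = cohort, diseaseHaps = diseaseHaps,
       params = params, stage = stage)
}

#' Score a control cohort and write its null distribution
#'
#' Uses the same config keys as [runScreen()]; the cohort read from
#' \code{control_vcf} is scored against the disease haplotypes and the
#' per-control maxima are written as a shippable tab-separated null
#' (see [writeNullDistribution()]).
#'
#' @param config named list or path to a flat key-value config file; keys as
#'   in [runScreen()], with \code{control_vcf} and \code{out} required.
#' @return the [NullDistribution-class], invisibly.
#' @export
runMakeNull <- function(config) {
  cfg <- if (is.character(config)) parseRunConfig(config) else config
  prep <- prepareScreenInputs(cfg, cohortKey = "control_vcf")
  null <- makeNullDistribution(prep$diseaseHaps, prep$cohort, prep$panel,
                               prep$params)
  writeNullDistribution(null, cfgChr(cfg, "out"))
  invisible(null)
}

#' Run the full screening pipeline from files
#'
#' load -> trim (plus/minus flankCm around the DCV) -> filter -> score ->
#' per-individual max -> empirical null -> calls -> write.  The marker
#' filter report and critical value are logged via \code{message()}.
#'
#' Config keys (flat key=value file or named list): \code{test_vcf},
#' \code{disease_vcf}, \code{map}, \code{freq_table}, \code{dcv_chrom},
#' \code{dcv_pos}, \code{out}; one of \code{control_vcf} /
#' \code{null_file}; optional \code{flank_cm} (10), \code{percentile} (99),
#' \code{top_n}, \code{min_impute_r2} (0.3), \code{g} (0.01),
#' \code{decay_meioses} (20), \code{switch_rate_per_bp} (1/20.05e6),
#' \code{drop_threshold} (10), \code{variant_id}.
#'
#' @param config named list or path to a config file.
#' @return the results data.frame, invisibly; side effect: results written
#'   to \code{out}.
#' @export
runScreen <- function(config) {
  cfg <- if (is.character(config)) parseRunConfig(config) else config
  prep <- prepareScreenInputs(cfg, cohortKey = "test_vcf")
  panel <- prep$panel; cohort <- prep$cohort
  diseaseHaps <- prep$diseaseHaps; params <- prep$params
  stage <- prep$stage

  null <- if (!is.null(cfg[["null_file"]])) {
    stage("load-null", readNullDistribution(cfg[["null_file"]]))
  } else if (!is.null(cfg[["control_vcf"]])) {
    stage("null", {
      ctl <- readPhasedVcf(cfg[["control_vcf"]])
      cIdx <- match(markerPos(panel), markerPos(ctl$panel))
      if (anyNA(cIdx)) stop("control VCF does not cover the analysis panel")
      makeNullDistribution(diseaseHaps, ctl$cohort[cIdx, ], panel, params)
    })
  } else stop("[null] a null source is required: ",
              "provide control_vcf or null_file")

  nTop <- if (is.null(cfg[["top_n"]])) NULL else as.integer(cfg[["top_n"]])
  res <- stage("score",
               screenCohort(diseaseHaps, cohort, null, panel, params,
                            percentile = cfgNum(cfg, "percentile", 99),
                            nTop = nTop))
  message(sprintf("critical value (percentile %g): %.6g",
                  cfgNum(cfg, "percentile", 99),
                  attr(res, "criticalValue")))
  if (!is.null(cfg[["out"]])) writeResults(res, cfg[["out"]])
  invisible(res)
}
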