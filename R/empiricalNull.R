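#' Build an empirical null distribution from a control cohort
#'
#' Scores every control individual against the same disease-haplotype set and
#' panel as the test cohort (the null is LD- and panel-specific, so mixing
#' panels is refused downstream via the recorded fingerprint).
#'
#' @param diseaseHaps list of [DiseaseHaplotype-class].
#' @param controls a [PhasedCohort-class] of presumed non-carriers.
#' @param panel annotated [MarkerPanel-class].
#' @param params an [HMMParams-class].
#' @return a [NullDistribution-class].  Fewer than 100 controls triggers a
#'   warning: the 99th percentile is unstable below that.
#' @export
makeNullDistribution <- function(diseaseHaps, controls, panel,
                                 params = HMMParams()) {
  res <- scoreCohort(diseaseHaps, controls, panel, params)
  NullDistribution(variantId = res$variant_id[1L],
                   scores = stats::setNames(res$score, res$individual_id),
                   panelFingerprint = panelFingerprint(panel))
}

#' Construct a null distribution from precomputed scores
#'
#' @param variantId DCV identifier.
#' @param scores named numeric vector of per-control max IBD scores.
#' @param panelFingerprint fingerprint of the panel used (see
#'   [panelFingerprint()]).
#' @return a [NullDistribution-class].
#' @export
NullDistribution <- function(variantId, scores, panelFingerprint = "") {
  if (length(scores) == 0L) stop("empty null distribution")
  if (length(scores) < 100L)
    warning(sprintf(
      "only %d controls; >= 100 recommended for a stable 99th percentile",
      length(scores)))
  new("NullDistribution", variantId = as.character(variantId),
      scores = scores, panelFingerprint = as.character(panelFingerprint))
}

#' @rdname haploScreen-generics
#' @export
setMethod("nullScores", "NullDistribution", function(x) x@scores)

#' @rdname haploScreen-generics
#' @export
setMethod("variantId", "NullDistribution", function(x) x@variantId)

setMethod("show", "NullDistribution", function(object) {
  cat(sprintf(
    "NullDistribution for %s: %d controls, 99th percentile = %.4g\n",
    object@variantId, length(object@scores), criticalValue(object, 99)))
  invisible(NULL)
})

checkFingerprint <- function(null, panel) {
  fp <- panelFingerprint(panel)
  if (nzchar(null@panelFingerprint) && !identical(null@panelFingerprint, fp))
    stop("null distribution was computed on a different marker panel; ",
         "refusing to mix panels")
  invisible(TRUE)
}

#' Percentile critical value of a control-score null
#'
#' The conservative (type-1, order-statistic) quantile: the
#' \code{ceiling(percentile/100 * n)}-th order statistic of the control
#' scores, with no interpolation.  By construction the fraction of controls
#' strictly above the threshold is at most \code{1 - percentile/100}.
#'
#' @param null a [NullDistribution-class].
#' @param percentile in (0, 100); default 99.
#' @return the threshold score.
#' @export
criticalValue <- function(null, percentile = 99) {
  stopifnot(is(null, "NullDistribution"),
            percentile > 0, percentile < 100)
  s <- sort(null@scores)
  s[[ceiling(percentile / 100 * length(s))]]
}

#' Empirical p-value of an IBD score
#'
#' Add-one permutation-style p-value
#' \code{(1 + #\{controls >= score\}) / (n + 1)}: never zero, monotone
#' non-increasing in the score.
#'
#' @param score numeric vector of test scores.
#' @param null a [NullDistribution-class].
#' @return numeric p-values in (0, 1].
#' @export
empiricalP <- function(score, null) {
  stopifnot(is(null, "NullDistribution"))
  s <- sort(null@scores)
  n <- length(s)
  # #{controls >= score} = n - #{controls < score}
  (1 + n - findInterval(score, s, left.open = TRUE)) / (n + 1)
}

#' Call carriers by score threshold
#'
#' An individual is called a carrier when its score strictly exceeds the
#' threshold.
#'
#' @param scores named numeric vector of per-individual max IBD scores.
#' @param threshold critical value (see [criticalValue()]).
#' @return data.frame: individual_id, score, rank (descending score, ties by
#'   id), call (logical).
#' @export
callCarriers <- function(scores, threshold) {
  ids <- names(scores)
  if (is.null(ids)) ids <- as.character(seq_along(scores))
  o <- order(-scores, ids)
  data.frame(individual_id = ids[o], score = unname(scores[o]),
             rank = seq_along(o), call = unname(scores[o] > threshold),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Top-N ranked individuals
#'
#' Prioritisation mode for large cohorts where the percentile threshold
#' yields more positives than can be followed up: take the \code{n}
#' highest-scoring individuals, ties broken by individual id.
#'
#' @param scores named numeric vector.
#' @param n number of individuals to keep.
#' @return data.frame as in [callCarriers()] restricted to the top n, all
#'   flagged \code{call = TRUE}.
#' @export
topN <- function(scores, n) {
  stopifnot(n >= 1)
  ranked <- callCarriers(scores, threshold = Inf)
  if (n > nrow(ranked)) {
    warning(sprintf("n = %d exceeds cohort size %d; returning everyone",
                    n, nrow(ranked)))
    n <- nrow(ranked)
  }
  out <- ranked[seq_len(n), , drop = FALSE]
  out$call <- TRUE
  out
}

#' Write / read a null distribution as tab-separated text
#'
#' Columns: individual_id, variant_id, ibd_score; the panel fingerprint is
#' carried in a '#fingerprint' header line so precomputed nulls can be
#' shipped and validated against the analysis panel.
#'
#' @param null a [NullDistribution-class].
#' @param path file path.
#' @return \code{writeNullDistribution} returns the path invisibly;
#'   \code{readNullDistribution} returns a [NullDistribution-class].
#' @export
writeNullDistribution <- function(null, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("#fingerprint\t%s", null@panelFingerprint), con)
  writeLines("individual_id\tvariant_id\tibd_score", con)
  writeLines(sprintf("%s\t%s\t%.10g", names(null@scores), null@variantId,
                     null@scores), con)
  invisible(path)
}

#' @rdname writeNullDistribution
#' @export
readNullDistribution <- function(path) {
  lines <- readLines(path)
  fp <- ""
  if (startsWith(lines[1L], "#fingerprint"))
    fp <- strsplit(lines[1L], "\t")[[1L]][2L]
  tab <- utils::read.table(text = lines[!startsWith(lines, "#")],
                           header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE)
  NullDistribution(variantId = tab$variant_id[1L],
                   scores = stats::setNames(tab$ibd_score,
                                            tab$individual_id),
                   panelFingerprint = fp)
}
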