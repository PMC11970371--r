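#' Emission probability of the IBD-scoring model
#'
#' Under an IBD state the test allele copies the disease allele up to a
#' uniform genotype/imputation error rate \code{g}: probability \code{1 - g}
#' on a match and \code{g} on a mismatch.  Under the non-IBD (population)
#' state the observed test allele is an independent population draw with
#' probability equal to its population frequency, regardless of the disease
#' allele.
#'
#' @param diseaseAllele,testAllele 0/1 alleles (vectors recycle).
#' @param altFreq alternate-allele frequency strictly in (0, 1).
#' @param g error rate in (0, 0.5).
#' @param state "IBD" or "nonIBD".
#' @return numeric probabilities in (0, 1).
#' @export
emissionProb <- function(diseaseAllele, testAllele, altFreq, g,
                         state = c("IBD", "nonIBD")) {
  state <- match.arg(state)
  if (anyNA(diseaseAllele) || anyNA(testAllele))
    stop("missing alleles must be handled by the caller (marker skipping)")
  if (state == "IBD") {
    ifelse(diseaseAllele == testAllele, 1 - g, g)
  } else {
    ifelse(testAllele == 1L, altFreq, 1 - altFreq)
  }
}

#' Transition kernel of the IBD-scoring model
#'
#' Between two markers separated by \code{deltaMorgans} on the genetic map and
#' \code{deltaBp} physically, an IBD state survives with probability
#' \code{exp(-decayMeioses * deltaMorgans)} (the waiting time to the next
#' recombination among all meioses separating the pair from their founder);
#' conditional on surviving it hops to the other test haplotype with the
#' phase-switch probability \code{s = min(1, switchRatePerBp * deltaBp)}.
#' The non-IBD state is absorbing: the IBD segment containing the DCV is
#' contiguous, so once sharing ends it does not resume within a chain.
#'
#' @param deltaMorgans genetic distance in Morgans (>= 0).
#' @param deltaBp physical distance in bp (>= 0).
#' @param params an [HMMParams-class].
#' @return 3x3 row-stochastic matrix over states
#'   \code{c("IBD_A", "IBD_B", "nonIBD")}.
#' @export
transitionProbs <- function(deltaMorgans, deltaBp, params = HMMParams()) {
  stopifnot(deltaMorgans >= 0, deltaBp >= 0)
  p <- exp(-params@decayMeioses * deltaMorgans)
  s <- min(1, params@switchRatePerBp * deltaBp)
  k <- matrix(c(p * (1 - s), p * s,       1 - p,
                p * s,       p * (1 - s), 1 - p,
                0,           0,           1),
              nrow = 3, byrow = TRUE,
              dimnames = list(c("IBD_A", "IBD_B", "nonIBD"),
                              c("IBD_A", "IBD_B", "nonIBD")))
  k
}

# Vectorised forward pass of one outward chain for N individuals at once.
#
# dAll: disease alleles in chain order (no NA; caller drops missing-disease
# markers so inter-marker distances accumulate across them).  A, B: matrices
# (chain markers x N).  cmPos/bpPos: marker coordinates in chain order;
# originCm/originBp: the DCV locus the chain starts from.  Per-individual
# markers where both test alleles are missing contribute no emission and no
# transition; their map distance accumulates so that skipping a marker is
# exactly equivalent to deleting it from the panel.
#
# Returns per-individual running-maximum llr (the chain score), the panel
# index where the maximum was attained, and the untruncated final llr.
chainForwardEngine <- function(dAll, A, B, f, cmPos, bpPos, originCm,
                               originBp, panelIdx, originIndex, params,
                               dropThreshold = params@dropThreshold) {
  nT <- length(dAll)
  N <- ncol(A)
  g <- params@g
  k <- params@decayMeioses
  r <- params@switchRatePerBp

  # Emission tables precomputed over the whole chain (d and f recycle down
  # the columns of the marker x individual matrices).
  naA <- is.na(A); naB <- is.na(B)
  EA <- matrix(ifelse(A == dAll, 1 - g, g), nT, N); EA[naA] <- 1
  EB <- matrix(ifelse(B == dAll, 1 - g, g), nT, N); EB[naB] <- 1
  FA <- matrix(ifelse(A == 1L, f, 1 - f), nT, N); FA[naA] <- 1
  FB <- matrix(ifelse(B == 1L, f, 1 - f), nT, N); FB[naB] <- 1
  INF <- !(naA & naB)

  a1 <- rep(0.5, N); a2 <- rep(0.5, N); a3 <- numeric(N)
  logL1 <- numeric(N)
  logL0 <- numeric(N)
  dMacc <- numeric(N); dBpacc <- numeric(N)
  M <- numeric(N)                 # running max llr (llr(origin) = 0)
  endIdx <- rep(originIndex, N)
  llrOut <- numeric(N)
  live <- seq_len(N)              # individuals whose chain is still open

  prevCm <- originCm
  prevBp <- originBp
  for (t in seq_len(nT)) {
    deltaM <- abs(cmPos[t] - prevCm) / 100
    deltaB <- abs(bpPos[t] - prevBp)
    prevCm <- cmPos[t]; prevBp <- bpPos[t]
    inf <- INF[t, live]

    dMacc <- dMacc + deltaM
    dBpacc <- dBpacc + deltaB
    dMe <- dMacc; dMe[!inf] <- 0      # uninformative marker: identity step
    dBe <- dBpacc; dBe[!inf] <- 0
    dMacc[inf] <- 0
    dBpacc[inf] <- 0

    p <- exp(-k * dMe)
    s <- pmin(1, r * dBe)
    ps <- p * s
    n3 <- a3 + (1 - p) * (a1 + a2)
    n1 <- p * a1 - ps * a1 + ps * a2
    n2 <- ps * a1 + p * a2 - ps * a2

    a1 <- n1 * EA[t, live]
    a2 <- n2 * EB[t, live]
    eN <- (FA[t, live] + FB[t, live]) * 0.5
    a3 <- n3 * eN
    ssum <- a1 + a2 + a3
    a1 <- a1 / ssum; a2 <- a2 / ssum; a3 <- a3 / ssum
    logL1 <- logL1 + log(ssum)
    # null: product over markers of the mean population emission of the two
    # observed alleles — identical to the nonIBD-state emission, so the llr
    # is exactly flat once the IBD mass has been absorbed
    logL0 <- logL0 + log(eN)
    llr <- logL1 - logL0
    llrOut[live] <- llr

    Ml <- M[live]
    better <- inf & (llr > Ml)
    if (any(better)) {
      endIdx[live[better]] <- panelIdx[t]
      M[live[better]] <- llr[better]
      Ml[better] <- llr[better]
    }
    dead <- inf & (llr < Ml - dropThreshold)
    if (any(dead)) {
      keep <- !dead
      live <- live[keep]
      if (length(live) == 0L) break
      a1 <- a1[keep]; a2 <- a2[keep]; a3 <- a3[keep]
      logL1 <- logL1[keep]; logL0 <- logL0[keep]
      dMacc <- dMacc[keep]; dBpacc <- dBpacc[keep]
    }
  }
  list(score = M, endIndex = endIdx, llrFinal = llrOut)
}

# chain marker order for a direction; includeOrigin controls whether the DCV
# marker itself is emitted (score_pair assigns it to the right chain only)
chainOrder <- function(panel, direction, includeOrigin) {
  d0 <- dcvIndex(panel)
  n <- nMarkers(panel)
  if (direction == "right") {
    from <- if (includeOrigin) d0 else d0 + 1L
    if (from > n) integer(0) else seq.int(from, n)
  } else {
    from <- if (includeOrigin) d0 else d0 - 1L
    if (from < 1L) integer(0) else seq.int(from, 1L)
  }
}

checkScoringInputs <- function(disease, panel) {
  if (is.na(dcvIndex(panel))) stop("panel has no DCV set")
  f <- altFreq(panel)
  if (anyNA(f))
    stop("panel lacks altFreq annotation; run attachFrequencies()")
  cm <- markerCm(panel)
  if (anyNA(cm))
    stop("panel lacks cm annotation; run annotateGeneticMap()")
  if (is.na(alleles(disease)[dcvIndex(panel)]))
    stop(sprintf(
      "invalid disease haplotype %s: allele at the DCV marker is missing",
      hapId(disease)))
  invisible(TRUE)
}

# run one chain for all individuals of a cohort-like pair of matrices
runChain <- function(disease, Amat, Bmat, panel, direction, params,
                     includeOrigin = (direction == "right"),
                     dropThreshold = params@dropThreshold) {
  checkScoringInputs(disease, panel)
  ord <- chainOrder(panel, direction, includeOrigin)
  dAll <- alleles(disease)[ord]
  keep <- !is.na(dAll)        # missing disease alleles: marker skipped
  ord <- ord[keep]
  if (length(ord) == 0L)
    return(list(score = numeric(ncol(Amat)),
                endIndex = rep(dcvIndex(panel), ncol(Amat)),
                llrFinal = numeric(ncol(Amat))))
  d0 <- dcvIndex(panel)
  chainForwardEngine(
    dAll = dAll[keep],
    A = Amat[ord, , drop = FALSE], B = Bmat[ord, , drop = FALSE],
    f = altFreq(panel)[ord],
    cmPos = markerCm(panel)[ord], bpPos = markerPos(panel)[ord],
    originCm = markerCm(panel)[d0], originBp = markerPos(panel)[d0],
    panelIdx = ord, originIndex = d0,
    params = params, dropThreshold = dropThreshold)
}

#' Log-likelihood ratio of one outward chain
#'
#' Runs the forward pass of the three-state alternative model (IBD on test
#' haplotype A, IBD on haplotype B, non-IBD absorbing) against the null of
#' independent population draws (per marker, the mean population emission of
#' the two observed alleles, multiplied over markers), scanning outward from
#' the DCV marker in one direction.  The cumulative ln LLR is tracked; the chain terminates at the
#' first marker where it falls more than \code{dropThreshold} ln-units below
#' its running maximum (sharing around the DCV has stopped), or at the window
#' edge.  The chain's value is the running maximum.
#'
#' @param disease a [DiseaseHaplotype-class].
#' @param hapA,hapB integer allele vectors of the test individual.
#' @param panel a [MarkerPanel-class], trimmed and fully annotated.
#' @param direction "left" or "right" from the DCV.
#' @param params an [HMMParams-class].
#' @param includeOrigin whether the DCV marker itself is emitted; defaults to
#'   TRUE for the right chain only, so the marker is counted once per pair.
#' @param dropThreshold override of the termination threshold (use \code{Inf}
#'   for an untruncated full-window pass).
#' @return list with \code{llr} (running maximum, ln units), \code{endIndex}
#'   (panel index where it was attained) and \code{llrFinal} (cumulative llr
#'   at the last evaluated marker; the window edge when
#'   \code{dropThreshold = Inf}).
#' @export
chainLLR <- function(disease, hapA, hapB, panel,
                     direction = c("right", "left"), params = HMMParams(),
                     includeOrigin = (direction[1L] == "right"),
                     dropThreshold = params@dropThreshold) {
  direction <- match.arg(direction)
  res <- runChain(disease, matrix(as.integer(hapA), ncol = 1),
                  matrix(as.integer(hapB), ncol = 1), panel, direction,
                  params, includeOrigin, dropThreshold)
  list(llr = res$score[1L], endIndex = res$endIndex[1L],
       llrFinal = res$llrFinal[1L])
}

#' Score one disease haplotype against one test individual
#'
#' The IBD score is the sum of the left- and right-chain ln likelihood
#' ratios; the DCV marker is assigned to the right chain only so that it is
#' counted exactly once.
#'
#' @param disease a [DiseaseHaplotype-class].
#' @param hapA,hapB the test individual's phased allele vectors.
#' @param panel annotated, trimmed [MarkerPanel-class].
#' @param params an [HMMParams-class].
#' @param individualId optional id recorded in the result.
#' @return one-row data.frame: individual_id, variant_id, hap_id, score,
#'   left_end_index, right_end_index, n_markers_used.
#' @export
scorePair <- function(disease, hapA, hapB, panel, params = HMMParams(),
                      individualId = NA_character_) {
  A <- matrix(as.integer(hapA), ncol = 1)
  B <- matrix(as.integer(hapB), ncol = 1)
  left <- runChain(disease, A, B, panel, "left", params)
  right <- runChain(disease, A, B, panel, "right", params)
  used <- sum(!is.na(alleles(disease)[left$endIndex[1]:right$endIndex[1]]))
  data.frame(individual_id = individualId, variant_id = variantId(disease),
             hap_id = hapId(disease),
             score = left$score[1] + right$score[1],
             left_end_index = left$endIndex[1],
             right_end_index = right$endIndex[1],
             n_markers_used = used, stringsAsFactors = FALSE)
}

#' Score a set of disease haplotypes against one individual
#'
#' When several disease haplotypes tag the same variant, the individual's IBD
#' score is the maximum over the set; ties are broken toward the
#' lexicographically lowest haplotype id.
#'
#' @param diseaseHaps list of [DiseaseHaplotype-class] tagging one variant.
#' @inheritParams scorePair
#' @return the winning one-row data.frame as in [scorePair()].
#' @export
scoreAgainstSet <- function(diseaseHaps, hapA, hapB, panel,
                            params = HMMParams(),
                            individualId = NA_character_) {
  if (length(diseaseHaps) == 0L) stop("empty disease-haplotype set")
  rows <- lapply(diseaseHaps, scorePair, hapA = hapA, hapB = hapB,
                 panel = panel, params = params, individualId = individualId)
  tab <- do.call(rbind, rows)
  tab <- tab[order(-tab$score, tab$hap_id), , drop = FALSE]
  tab[1L, , drop = FALSE]
}

#' Per-pair IBD score matrix for a cohort
#'
#' Scores every disease haplotype against every individual of a phased
#' cohort (the chain forward pass is vectorised across individuals).
#'
#' @param diseaseHaps list of [DiseaseHaplotype-class].
#' @param cohort a [PhasedCohort-class].
#' @param panel annotated [MarkerPanel-class].
#' @param params an [HMMParams-class].
#' @param chunkSize optional number of individuals per processing chunk;
#'   results are identical for any chunking.
#' @return numeric matrix, individuals x disease haplotypes, dimnames set.
#' @export
scoreMatrix <- function(diseaseHaps, cohort, panel, params = HMMParams(),
                        chunkSize = NULL) {
  if (length(diseaseHaps) == 0L) stop("empty disease-haplotype set")
  ids <- individualIds(cohort)
  hapIds <- vapply(diseaseHaps, hapId, character(1))
  if (anyDuplicated(hapIds)) stop("disease haplotype ids must be unique")
  n <- nIndividuals(cohort)
  chunks <- if (is.null(chunkSize)) list(seq_len(n)) else
    split(seq_len(n), ceiling(seq_len(n) / chunkSize))
  out <- matrix(NA_real_, n, length(diseaseHaps),
                dimnames = list(ids, hapIds))
  for (cols in chunks) {
    A <- hapA(cohort)[, cols, drop = FALSE]
    B <- hapB(cohort)[, cols, drop = FALSE]
    for (j in seq_along(diseaseHaps)) {
      left <- runChain(diseaseHaps[[j]], A, B, panel, "left", params)
      right <- runChain(diseaseHaps[[j]], A, B, panel, "right", params)
      out[cols, j] <- left$score + right$score
    }
  }
  out
}

#' Best-haplotype IBD score per individual
#'
#' @inheritParams scoreMatrix
#' @return data.frame with one row per individual: individual_id,
#'   variant_id, best_hap_id, score.  The full per-pair matrix is attached as
#'   attribute \code{"scoreMatrix"}.
#' @export
scoreCohort <- function(diseaseHaps, cohort, panel, params = HMMParams(),
                        chunkSize = NULL) {
  m <- scoreMatrix(diseaseHaps, cohort, panel, params, chunkSize)
  ord <- order(colnames(m))          # tie-break: lowest hap id
  best <- apply(m[, ord, drop = FALSE], 1L, which.max)
  res <- data.frame(
    individual_id = rownames(m),
    variant_id = variantId(diseaseHaps[[1L]]),
    best_hap_id = colnames(m)[ord][best],
    score = m[cbind(seq_len(nrow(m)), ord[best])],
    stringsAsFactors = FALSE, row.names = NULL)
  attr(res, "scoreMatrix") <- m
  res
}
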