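#' Simulate founder haplotypes and a marker panel
#'
#' Draws per-marker alternate-allele frequencies from a truncated
#' Beta(0.8, 0.8) spectrum truncated to 0.01-0.99 (U-shaped, array-like) and founder
#' haplotype alleles Bernoulli at those frequencies.  Markers monomorphic
#' across the founders are dropped (fixed markers carry no information and
#' are rejected by the panel class).  The genetic map is linear at
#' \code{mapCmPerMb}; markers are evenly spaced over \code{spanCm} with the
#' DCV at the centre.
#'
#' @param nMarkers number of markers drawn (the retained panel is smaller by
#'   the monomorphic fraction).
#' @param nFounders number of founder haplotypes (>= 2).
#' @param spanCm genetic span of the panel in cM.
#' @param mapCmPerMb map density, cM per Mb (default 1).
#' @param freqSpectrum function(n) returning n frequencies in (0, 1).
#' @param chrom chromosome label.
#' @param seed RNG seed.
#' @return list with \code{founders} (marker x founder 0/1 matrix) and
#'   \code{panel} (a [MarkerPanel-class]; altFreq is filled later from the
#'   realised cohort by [synthCohort()]).
#' @export
synthFounders <- function(nMarkers, nFounders = 150, spanCm = 20,
                          mapCmPerMb = 1,
                          freqSpectrum = function(n)
                            pmin(pmax(stats::rbeta(n, 0.8, 0.8), 0.01), 0.99),
                          chrom = "chr1", seed = 1L) {
  stopifnot(nFounders >= 2, nMarkers >= 10)
  set.seed(seed)
  f <- freqSpectrum(nMarkers)
  if (all(f <= 0) || all(f >= 1))
    stop("degenerate frequency spectrum")
  founders <- matrix(stats::rbinom(nMarkers * nFounders, 1L, rep(f, nFounders)),
                     nrow = nMarkers, ncol = nFounders)
  poly <- rowSums(founders) > 0 & rowSums(founders) < nFounders
  founders <- founders[poly, , drop = FALSE]
  n <- nrow(founders)
  spanBp <- spanCm * 1e6 / mapCmPerMb
  pos <- round(seq(1e6, 1e6 + spanBp, length.out = n))
  cm <- (pos - pos[1L]) * mapCmPerMb / 1e6
  panel <- MarkerPanel(chrom = chrom, posBp = pos, cm = cm,
                       ref = "A", alt = "G", altFreq = NA_real_,
                       dcvPos = pos[ceiling(n / 2)])
  list(founders = founders, panel = panel, mapCmPerMb = mapCmPerMb)
}

#' Sample a phased cohort as mosaics of founder haplotypes
#'
#' Each haplotype copies founders along the chromosome with switch events
#' drawn as a Poisson process on the genetic map (rate
#' \code{1/founderSwitchCm} per cM) and a uniformly re-drawn founder after
#' each switch.  Nearby markers therefore tend to descend from the same
#' founder, inducing linkage disequilibrium whose scale grows with
#' \code{founderSwitchCm}.
#'
#' @param founderSet result of [synthFounders()].
#' @param nIndividuals cohort size.
#' @param founderSwitchCm mean cM between founder switches; \code{Inf} makes
#'   every haplotype a full founder copy.
#' @param seed RNG seed.
#' @param idPrefix prefix of generated individual ids.
#' @return a [PhasedCohort-class].
#' @export
sampleCohort <- function(founderSet, nIndividuals, founderSwitchCm = 0.15,
                         seed = 1L, idPrefix = "ind") {
  set.seed(seed)
  panel <- founderSet$panel
  founders <- founderSet$founders
  nm <- nrow(founders)
  K <- ncol(founders)
  cm <- markerCm(panel)
  span <- cm[nm] - cm[1L]
  drawHap <- function() {
    nSwitch <- if (is.finite(founderSwitchCm))
      stats::rpois(1L, span / founderSwitchCm) else 0L
    bounds <- c(cm[1L], sort(stats::runif(nSwitch, cm[1L], cm[nm])))
    fid <- sample.int(K, nSwitch + 1L, replace = TRUE)
    seg <- findInterval(cm, bounds, rightmost.closed = FALSE)
    founders[cbind(seq_len(nm), fid[seg])]
  }
  A <- matrix(0L, nm, nIndividuals)
  B <- matrix(0L, nm, nIndividuals)
  for (i in seq_len(nIndividuals)) {
    A[, i] <- drawHap()
    B[, i] <- drawHap()
  }
  ids <- sprintf("%s%04d", idPrefix, seq_len(nIndividuals))
  colnames(A) <- colnames(B) <- ids
  PhasedCohort(A, B)
}

#' Simulate a phased cohort with LD over a fresh marker panel
#'
#' Convenience wrapper: draws founders, samples a mosaic cohort, records each
#' marker's realised cohort alternate-allele frequency on the panel, and
#' drops markers monomorphic in the realised cohort (their frequency would
#' leave (0, 1)).
#'
#' @inheritParams synthFounders
#' @inheritParams sampleCohort
#' @param nIndividuals cohort size (503 matches a 1000-Genomes-sized
#'   European reference cohort).
#' @return list with \code{cohort} ([PhasedCohort-class]), \code{panel}
#'   ([MarkerPanel-class] with realised altFreq and centred DCV) and
#'   \code{founderSet} (for drawing further same-population cohorts with
#'   [sampleCohort()]).
#' @export
synthCohort <- function(nIndividuals = 503, nMarkers = 2400, nFounders = 150,
                        founderSwitchCm = 0.15, spanCm = 20, mapCmPerMb = 1,
                        freqSpectrum = function(n)
                          pmin(pmax(stats::rbeta(n, 0.8, 0.8), 0.01), 0.99),
                        chrom = "chr1", seed = 1L) {
  fs <- synthFounders(nMarkers, nFounders, spanCm, mapCmPerMb, freqSpectrum,
                      chrom, seed)
  cohort <- sampleCohort(fs, nIndividuals, founderSwitchCm, seed = seed + 1L)
  freq <- (rowSums(hapA(cohort)) + rowSums(hapB(cohort))) /
    (2 * nIndividuals)
  keep <- freq > 0 & freq < 1
  fs$founders <- fs$founders[keep, , drop = FALSE]
  panel <- fs$panel[which(keep)]
  mcols(panel@markers)$altFreq <- freq[keep]
  fs$panel <- panel
  list(cohort = cohort[which(keep), ], panel = panel, founderSet = fs)
}

#' Derive disease haplotypes from a cohort
#'
#' Single founder mode: one ancestral haplotype is picked; each disease
#' haplotype copies the ancestor over a window around the DCV whose length is
#' drawn uniformly between \code{coreLengthCm} and the panel span, spliced
#' onto a distinct randomly chosen background individual's haplotype.  All
#' versions therefore share an error-free ancestral core of at least
#' \code{coreLengthCm} around the DCV.  Multiple founder mode: the
#' haplotypes are taken from distinct individuals with no enforced core.
#' Donor individuals (and the ancestor) must be excluded from the test
#' cohort; their ids are returned.
#'
#' @param cohort a [PhasedCohort-class].
#' @param panel annotated [MarkerPanel-class] with a DCV.
#' @param mode "single" or "multiple".
#' @param nHaps number of disease haplotypes.
#' @param coreLengthCm guaranteed shared core length (single mode); must be
#'   at least the largest sharing length to be simulated.
#' @param variantId label recorded on the haplotypes.
#' @param seed RNG seed.
#' @return list with \code{haps} (list of [DiseaseHaplotype-class]) and
#'   \code{donorIds} (individuals to drop from the test cohort).
#' @export
deriveDiseaseHaplotypes <- function(cohort, panel,
                                    mode = c("single", "multiple"),
                                    nHaps = 10L, coreLengthCm = 5,
                                    variantId = "DCV", seed = 1L) {
  mode <- match.arg(mode)
  set.seed(seed)
  ids <- individualIds(cohort)
  need <- if (mode == "single") nHaps + 1L else nHaps
  if (need > length(ids))
    stop(sprintf("need %d donor individuals but cohort has only %d",
                 need, length(ids)))
  cm <- markerCm(panel)
  d0 <- dcvIndex(panel)
  c0 <- cm[d0]
  dcvP <- dcvPos(panel)
  chrom <- panelChrom(panel)
  span <- cm[length(cm)] - cm[1L]
  pickHap <- function(ind) {
    if (stats::runif(1) < 0.5) hapA(cohort)[, ind] else hapB(cohort)[, ind]
  }
  donors <- sample(ids, need)
  if (mode == "single") {
    ancestor <- pickHap(donors[1L])
    haps <- lapply(seq_len(nHaps), function(i) {
      len <- stats::runif(1L, coreLengthCm, max(span, coreLengthCm))
      bg <- pickHap(donors[i + 1L])
      core <- cm >= c0 - len / 2 & cm <= c0 + len / 2
      bg[core] <- ancestor[core]
      DiseaseHaplotype(sprintf("hap%02d", i), variantId, bg, chrom, dcvP)
    })
  } else {
    haps <- lapply(seq_len(nHaps), function(i)
      DiseaseHaplotype(sprintf("hap%02d", i), variantId, pickHap(donors[i]),
                       chrom, dcvP))
  }
  list(haps = haps, donorIds = donors)
}

#' Implant a disease haplotype into a test individual
#'
#' Replaces the alleles of one randomly chosen haplotype of the individual by
#' the disease haplotype's alleles over the symmetric genetic interval
#' \code{[cm(dcv) - L/2, cm(dcv) + L/2]}, emulating an inherited IBD segment
#' of length L around the DCV.  Alleles outside the interval are untouched.
#'
#' @param cohort a [PhasedCohort-class].
#' @param individual index or id of the individual to modify.
#' @param diseaseHap a [DiseaseHaplotype-class].
#' @param panel annotated [MarkerPanel-class].
#' @param sharingLengthCm implanted segment length L in cM.
#' @return list with the modified \code{cohort}, the replaced haplotype
#'   (\code{"A"}/\code{"B"}) and the cm \code{interval}.
#' @export
implantCase <- function(cohort, individual, diseaseHap, panel,
                        sharingLengthCm) {
  cm <- markerCm(panel)
  c0 <- cm[dcvIndex(panel)]
  lo <- c0 - sharingLengthCm / 2
  hi <- c0 + sharingLengthCm / 2
  idx <- which(cm >= lo & cm <= hi)
  if (length(idx) == 0L) stop("implant interval contains no markers")
  which.hap <- if (stats::runif(1) < 0.5) "A" else "B"
  if (which.hap == "A") cohort@hapA[idx, individual] <-
      alleles(diseaseHap)[idx]
  else cohort@hapB[idx, individual] <- alleles(diseaseHap)[idx]
  list(cohort = cohort, haplotype = which.hap, interval = c(lo, hi))
}

#' Inject genotype errors
#'
#' Flips each non-missing haplotype allele independently with probability
#' \code{rate} (0 <-> 1), emulating the combined genotyping + imputation
#' error process.  The RNG stream is derived from the seed together with the
#' cohort content, so the operation is reproducible for a given input yet
#' re-applying it (even with the same seed) draws fresh flips rather than
#' undoing the first pass — it is not an involution.
#'
#' @param cohort a [PhasedCohort-class].
#' @param rate flip probability in [0, 1).
#' @param seed RNG seed.
#' @return the perturbed [PhasedCohort-class].
#' @export
injectGenotypeErrors <- function(cohort, rate = 0.01, seed = 1L) {
  stopifnot(rate >= 0, rate < 1)
  mix <- function(m) {
    v <- as.numeric(m)
    sum(v * (seq_along(v) %% 997), na.rm = TRUE) %% 100003
  }
  set.seed((seed + mix(cohort@hapA) + 2 * mix(cohort@hapB)) %%
             .Machine$integer.max)
  flip <- function(m) {
    hit <- !is.na(m) & stats::runif(length(m)) < rate
    m[hit] <- 1L - m[hit]
    m
  }
  cohort@hapA <- flip(cohort@hapA)
  cohort@hapB <- flip(cohort@hapB)
  validObject(cohort)
  cohort
}

#' Inject phase-switch errors
#'
#' For each individual, switch points are drawn as a Poisson process along
#' the physical (bp) axis at \code{ratePerBp} (default one switch per
#' 20.05 Mbp); the A/B haplotype labels are exchanged after each switch
#' point, so consecutive switch points produce switched blocks, emulating
#' block phasing errors from LD-based statistical phasing.
#'
#' @param cohort a [PhasedCohort-class].
#' @param panel matching [MarkerPanel-class] (for marker bp positions).
#' @param ratePerBp switch rate per bp (>= 0).
#' @param seed RNG seed.
#' @return the perturbed [PhasedCohort-class].
#' @export
injectPhaseSwitchErrors <- function(cohort, panel,
                                    ratePerBp = 1 / 20.05e6, seed = 1L) {
  stopifnot(ratePerBp >= 0)
  set.seed(seed)
  pos <- markerPos(panel)
  spanBp <- max(pos) - min(pos)
  for (i in seq_len(nIndividuals(cohort))) {
    nSwitch <- stats::rpois(1L, ratePerBp * spanBp)
    if (nSwitch == 0L) next
    cuts <- sort(stats::runif(nSwitch, min(pos), max(pos)))
    swapped <- (findInterval(pos, cuts) %% 2L) == 1L
    a <- cohort@hapA[swapped, i]
    cohort@hapA[swapped, i] <- cohort@hapB[swapped, i]
    cohort@hapB[swapped, i] <- a
  }
  cohort
}

#' Construct a scenario specification
#'
#' @param locusId label of the simulated locus.
#' @param founderMode "single" or "multiple".
#' @param nDiseaseHaps disease haplotypes per scenario (default 10).
#' @param nCasesPerHap implanted cases per haplotype (default 5).
#' @param sharingLengthCm implanted sharing length; the evaluation grid uses
#'   0.5, 1, 2 and 5 cM.
#' @param genotypeErrorRate allele flip rate (default 0.01).
#' @param phaseSwitchRatePerBp phase-switch rate (default 1/20.05e6).
#' @param seed integer seed; all scenario randomness derives from it.
#' @return a [ScenarioSpec-class].
#' @export
ScenarioSpec <- function(locusId = "locus1",
                         founderMode = c("single", "multiple"),
                         nDiseaseHaps = 10L, nCasesPerHap = 5L,
                         sharingLengthCm = 2, genotypeErrorRate = 0.01,
                         phaseSwitchRatePerBp = 1 / 20.05e6, seed = 1L) {
  new("ScenarioSpec", locusId = locusId,
      founderMode = match.arg(founderMode),
      nDiseaseHaps = as.integer(nDiseaseHaps),
      nCasesPerHap = as.integer(nCasesPerHap),
      sharingLengthCm = sharingLengthCm,
      genotypeErrorRate = genotypeErrorRate,
      phaseSwitchRatePerBp = phaseSwitchRatePerBp, seed = as.integer(seed))
}

setMethod("show", "ScenarioSpec", function(object) {
  cat(sprintf(
    "ScenarioSpec %s: %s founder, %d haps x %d cases, %g cM sharing, seed %d\n",
    object@locusId, object@founderMode, object@nDiseaseHaps,
    object@nCasesPerHap, object@sharingLengthCm, object@seed))
  invisible(NULL)
})

#' Run one founder-effect simulation scenario
#'
#' Composes the full simulation pipeline: derive disease haplotypes (donors
#' leave the test cohort) -> implant \code{nCasesPerHap} cases per haplotype
#' -> inject genotype errors -> inject phase-switch errors.  Disease
#' haplotypes themselves are never passed through the error operations.  The
#' remaining unmodified individuals act as within-cohort controls.  Fully
#' deterministic given \code{spec@seed}.
#'
#' @param spec a [ScenarioSpec-class].
#' @param cohort the base [PhasedCohort-class].
#' @param panel annotated [MarkerPanel-class].
#' @param coreLengthCm guaranteed single-founder core (default 5 cM, the
#'   largest sharing length in the evaluation grid).
#' @return list: \code{testCohort} (donors removed, errors injected),
#'   \code{diseaseHaps}, and \code{truth} (data.frame individual_id,
#'   is_case, source_hap, interval_lo_cm, interval_hi_cm).
#' @export
runScenario <- function(spec, cohort, panel, coreLengthCm = 5) {
  stopifnot(is(spec, "ScenarioSpec"))
  dh <- deriveDiseaseHaplotypes(cohort, panel, spec@founderMode,
                                spec@nDiseaseHaps,
                                coreLengthCm = max(coreLengthCm,
                                                   spec@sharingLengthCm),
                                variantId = spec@locusId,
                                seed = spec@seed)
  ids <- setdiff(individualIds(cohort), dh$donorIds)
  test <- cohort[, ids]
  nCases <- spec@nDiseaseHaps * spec@nCasesPerHap
  if (nCases >= length(ids))
    stop("cohort too small for the requested number of cases")
  set.seed(spec@seed + 1L)
  caseIds <- sample(ids, nCases)
  truth <- data.frame(individual_id = individualIds(test),
                      is_case = individualIds(test) %in% caseIds,
                      source_hap = NA_character_,
                      interval_lo_cm = NA_real_, interval_hi_cm = NA_real_,
                      stringsAsFactors = FALSE)
  assign <- rep(seq_len(spec@nDiseaseHaps), each = spec@nCasesPerHap)
  for (k in seq_along(caseIds)) {
    hp <- dh$haps[[assign[k]]]
    imp <- implantCase(test, caseIds[k], hp, panel, spec@sharingLengthCm)
    test <- imp$cohort
    row <- match(caseIds[k], truth$individual_id)
    truth$source_hap[row] <- hapId(hp)
    truth$interval_lo_cm[row] <- imp$interval[1L]
    truth$interval_hi_cm[row] <- imp$interval[2L]
  }
  test <- injectGenotypeErrors(test, spec@genotypeErrorRate,
                               seed = spec@seed + 2L)
  test <- injectPhaseSwitchErrors(test, panel, spec@phaseSwitchRatePerBp,
                                  seed = spec@seed + 3L)
  list(testCohort = test, diseaseHaps = dh$haps, truth = truth)
}
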