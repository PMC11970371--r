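#' Construct a phased cohort
#'
#' @param hapA,hapB integer matrices (markers x individuals), entries in
#'   \{0, 1, NA\}; column names are individual ids.
#' @return a [PhasedCohort-class].
#' @export
PhasedCohort <- function(hapA, hapB) {
  storage.mode(hapA) <- "integer"
  storage.mode(hapB) <- "integer"
  new("PhasedCohort", hapA = hapA, hapB = hapB)
}

#' @rdname haploScreen-generics
#' @export
setMethod("nMarkers", "PhasedCohort", function(x) nrow(x@hapA))

#' @rdname haploScreen-generics
#' @export
setMethod("nIndividuals", "PhasedCohort", function(x) ncol(x@hapA))

#' @rdname haploScreen-generics
#' @export
setMethod("individualIds", "PhasedCohort", function(x) colnames(x@hapA))

#' @rdname haploScreen-generics
#' @export
setMethod("hapA", "PhasedCohort", function(x) x@hapA)

#' @rdname haploScreen-generics
#' @export
setMethod("hapB", "PhasedCohort", function(x) x@hapB)

setMethod("show", "PhasedCohort", function(object) {
  miss <- mean(is.na(object@hapA)) + mean(is.na(object@hapB))
  cat(sprintf("PhasedCohort: %d individuals x %d markers (%.2f%% missing)\n",
              nIndividuals(object), nMarkers(object),
              50 * ifelse(is.nan(miss), 0, miss)))
  invisible(NULL)
})

#' Subset a cohort by marker and/or individual
#'
#' @param x a [PhasedCohort-class].
#' @param i integer marker indices.
#' @param j integer or character individual selector.
#' @param ...,drop ignored.
#' @export
setMethod("[", "PhasedCohort", function(x, i, j, ..., drop = FALSE) {
  if (missing(i)) i <- seq_len(nMarkers(x))
  if (missing(j)) j <- seq_len(nIndividuals(x))
  PhasedCohort(x@hapA[i, j, drop = FALSE], x@hapB[i, j, drop = FALSE])
})

#' Construct a disease haplotype
#'
#' @param hapId haplotype identifier.
#' @param variantId identifier of the disease-causing variant it tags.
#' @param alleles integer vector over the panel (0/1/NA).
#' @param dcvChrom,dcvPos DCV locus coordinates.
#' @return a [DiseaseHaplotype-class].
#' @export
DiseaseHaplotype <- function(hapId, variantId, alleles, dcvChrom, dcvPos) {
  new("DiseaseHaplotype", hapId = as.character(hapId),
      variantId = as.character(variantId), alleles = as.integer(alleles),
      dcvChrom = as.character(dcvChrom), dcvPos = as.numeric(dcvPos))
}

#' @rdname haploScreen-generics
#' @export
setMethod("alleles", "DiseaseHaplotype", function(x) x@alleles)

#' @rdname haploScreen-generics
#' @export
setMethod("hapId", "DiseaseHaplotype", function(x) x@hapId)

#' @rdname haploScreen-generics
#' @export
setMethod("variantId", "DiseaseHaplotype", function(x) x@variantId)

setMethod("show", "DiseaseHaplotype", function(object) {
  cat(sprintf(
    "DiseaseHaplotype %s tagging %s at %s:%d (%d markers, %d missing)\n",
    object@hapId, object@variantId, object@dcvChrom,
    as.integer(object@dcvPos), length(object@alleles),
    sum(is.na(object@alleles))))
  invisible(NULL)
})

#' Model parameters constructor
#'
#' @param g genotype/imputation error rate in (0, 0.5).
#' @param decayMeioses expected meioses to the common founder (> 0).
#' @param switchRatePerBp phase-switch rate per bp (>= 0).
#' @param dropThreshold chain-termination drop in ln-units (> 0, may be Inf).
#' @return an [HMMParams-class].
#' @export
HMMParams <- function(g = 0.01, decayMeioses = 20,
                      switchRatePerBp = 1 / 20.05e6, dropThreshold = 10) {
  new("HMMParams", g = g, decayMeioses = decayMeioses,
      switchRatePerBp = switchRatePerBp, dropThreshold = dropThreshold)
}

setMethod("show", "HMMParams", function(object) {
  cat(sprintf(
    "HMMParams: g=%.4g, decayMeioses=%g, switchRate=1/%.4g Mbp, drop=%g ln\n",
    object@g, object@decayMeioses, 1e-6 / object@switchRatePerBp,
    object@dropThreshold))
  invisible(NULL)
})
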