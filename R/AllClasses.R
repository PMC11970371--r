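#' @import methods
#' @importFrom GenomicRanges GRanges seqnames start
#' @importFrom IRanges IRanges
#' @importFrom S4Vectors mcols mcols<-
NULL

setClassUnion("integerOrNULL", c("integer", "NULL"))

#' Genetic map (bp to cM anchor points)
#'
#' A set of (chromosome, physical position, genetic position) anchors used to
#' interpolate the genetic (cM) position of any marker by piecewise-linear
#' interpolation.  This is the usual HapMap-style sex-averaged map.
#'
#' @slot chrom character vector of chromosome labels, one per anchor.
#' @slot posBp numeric, physical positions (1-based bp), strictly increasing
#'   within a chromosome.
#' @slot cm numeric, genetic positions in centiMorgans, non-decreasing with
#'   \code{posBp} within a chromosome.
#' @seealso [readGeneticMap()], [interpolateCm()]
#' @export
setClass("GeneticMap",
  representation(chrom = "character", posBp = "numeric", cm = "numeric"))

setValidity("GeneticMap", function(object) {
  if (length(object@chrom) != length(object@posBp) ||
      length(object@posBp) != length(object@cm))
    return("chrom, posBp and cm must have equal length")
  for (ch in unique(object@chrom)) {
    i <- object@chrom == ch
    if (is.unsorted(object@posBp[i], strictly = TRUE))
      return(sprintf("posBp not strictly increasing on chromosome %s", ch))
    if (is.unsorted(object@cm[i]))
      return(sprintf("cm decreasing on chromosome %s", ch))
  }
  TRUE
})

#' Ordered biallelic marker panel around a disease locus
#'
#' The coordinate system shared by all other objects: an ordered set of
#' biallelic SNP markers on one chromosome, each carrying a physical position,
#' a genetic position (cM) and an alternate-allele frequency, plus the index
#' of the marker nearest the disease-causing variant (DCV, "marker 0" of the
#' two outward Markov chains).
#'
#' Positions are held in a \link[GenomicRanges]{GRanges} with metadata columns
#' \code{cm}, \code{ref}, \code{alt}, \code{altFreq} and (optionally)
#' \code{imputeR2}.  \code{cm} and \code{altFreq} may be \code{NA} on a freshly
#' loaded skeleton and are filled by [annotateGeneticMap()] and
#' [attachFrequencies()]; scoring refuses unannotated panels.
#'
#' @slot markers GRanges of marker positions with the metadata columns above.
#' @slot dcvIndex integer index of the marker nearest the DCV, or NA until a
#'   DCV has been set (see [setDcv()]).
#' @slot dcvPos numeric bp position of the DCV itself (may fall between
#'   markers; NA until set).
#' @export
setClass("MarkerPanel",
  representation(markers = "GRanges", dcvIndex = "integer", dcvPos = "numeric"))

setValidity("MarkerPanel", function(object) {
  gr <- object@markers
  need <- c("cm", "ref", "alt", "altFreq")
  if (!all(need %in% colnames(mcols(gr))))
    return(paste("markers must carry metadata columns:",
                 paste(need, collapse = ", ")))
  n <- length(gr)
  if (n > 0) {
    if (length(unique(as.character(seqnames(gr)))) > 1)
      return("a panel spans a single chromosome")
    pos <- GenomicRanges::start(gr)
    if (is.unsorted(pos, strictly = TRUE))
      return("marker positions must be strictly increasing")
    cm <- mcols(gr)$cm
    if (is.unsorted(cm[!is.na(cm)]))
      return("marker cm positions must be non-decreasing")
    f <- mcols(gr)$altFreq
    bad <- !is.na(f) & (f <= 0 | f >= 1)
    if (any(bad))
      return("altFreq must lie strictly within (0, 1); fixed markers are rejected")
  }
  di <- object@dcvIndex
  if (length(di) != 1) return("dcvIndex must be a single integer (possibly NA)")
  if (!is.na(di) && (di < 1L || di > n)) return("dcvIndex out of range")
  TRUE
})

#' Phased cohort of test individuals
#'
#' Per-individual pairs of haplotype allele vectors over a [MarkerPanel].
#' Alleles are 0 (reference), 1 (alternate) or NA (missing); haplotype A/B is
#' the phase assignment as read from the VCF (left/right of the "|").
#'
#' @slot hapA,hapB integer matrices, markers x individuals, entries in
#'   \{0, 1, NA\}; column names are individual ids.
#' @export
setClass("PhasedCohort", representation(hapA = "matrix", hapB = "matrix"))

setValidity("PhasedCohort", function(object) {
  if (!identical(dim(object@hapA), dim(object@hapB)))
    return("hapA and hapB must have identical dimensions")
  if (!identical(colnames(object@hapA), colnames(object@hapB)))
    return("hapA and hapB must share column (individual) names")
  if (is.null(colnames(object@hapA)) && ncol(object@hapA) > 0)
    return("individual ids (column names) are required")
  for (m in list(object@hapA, object@hapB)) {
    v <- m[!is.na(m)]
    if (length(v) && !all(v %in% c(0L, 1L)))
      return("alleles must be 0, 1 or NA")
  }
  TRUE
})

#' A pedigree-phased disease haplotype
#'
#' One phased allele vector over a [MarkerPanel], known to carry the
#' disease-causing variant (DCV) it tags.  Missing alleles are allowed outside
#' the pedigree-resolved core but the allele at the panel's DCV marker must be
#' defined for scoring.
#'
#' @slot hapId character, identifier of this haplotype (e.g. family id).
#' @slot variantId character, identifier of the DCV it tags.
#' @slot alleles integer vector over the panel, entries in \{0, 1, NA\}.
#' @slot dcvChrom character, chromosome of the DCV.
#' @slot dcvPos numeric, bp position of the DCV.
#' @export
setClass("DiseaseHaplotype",
  representation(hapId = "character", variantId = "character",
                 alleles = "integer", dcvChrom = "character",
                 dcvPos = "numeric"))

setValidity("DiseaseHaplotype", function(object) {
  v <- object@alleles[!is.na(object@alleles)]
  if (length(v) && !all(v %in% c(0L, 1L)))
    return("alleles must be 0, 1 or NA")
  if (length(object@hapId) != 1 || length(object@variantId) != 1)
    return("hapId and variantId must be scalars")
  TRUE
})

#' Parameters of the IBD-scoring hidden Markov model
#'
#' @slot g numeric, combined genotype + imputation error rate (default 0.01).
#'   Genotyping and imputation errors are indistinguishable in the model and
#'   treated as one uniform flip rate.
#' @slot decayMeioses numeric, expected number of meioses separating the test
#'   and disease haplotypes from their common founder; the per-Morgan survival
#'   of the IBD state is exp(-decayMeioses * distance).  Default 20 (about ten
#'   generations to the founder on each lineage).
#' @slot switchRatePerBp numeric, prior phase-switch error rate per bp
#'   (default 1/20.05e6, one switch per 20.05 Mbp).
#' @slot dropThreshold numeric, ln-units a chain's cumulative log-likelihood
#'   ratio may fall below its running maximum before the chain terminates
#'   (default 10).  Use \code{Inf} to force full-window evaluation.
#' @export
setClass("HMMParams",
  representation(g = "numeric", decayMeioses = "numeric",
                 switchRatePerBp = "numeric", dropThreshold = "numeric"),
  prototype(g = 0.01, decayMeioses = 20, switchRatePerBp = 1 / 20.05e6,
            dropThreshold = 10))

setValidity("HMMParams", function(object) {
  if (!(object@g > 0 && object@g < 0.5)) return("g must lie in (0, 0.5)")
  if (!(object@decayMeioses > 0)) return("decayMeioses must be positive")
  if (object@switchRatePerBp < 0) return("switchRatePerBp must be >= 0")
  if (!(object@dropThreshold > 0)) return("dropThreshold must be positive")
  TRUE
})

#' Empirical null distribution of IBD scores in a control cohort
#'
#' Per-control maximum IBD scores against a disease-haplotype set, used to set
#' percentile critical values and empirical p-values.  The asymptotic
#' chi-square null of a likelihood-ratio statistic does not hold here because
#' of linkage disequilibrium, so calibration is purely empirical.
#'
#' @slot variantId character, DCV the scores refer to.
#' @slot scores named numeric, per-control max IBD score.
#' @slot panelFingerprint character, summary of the panel the scores were
#'   computed on; score comparison across different panels is refused.
#' @export
setClass("NullDistribution",
  representation(variantId = "character", scores = "numeric",
                 panelFingerprint = "character"))

setValidity("NullDistribution", function(object) {
  if (any(!is.finite(object@scores))) return("control scores must be finite")
  TRUE
})

#' Specification of one simulated founder-effect dataset
#'
#' @slot locusId character label of the simulated disease locus.
#' @slot founderMode "single" (all disease haplotypes descend from one
#'   ancestor and share a core around the DCV) or "multiple" (independent
#'   founders, no enforced core).
#' @slot nDiseaseHaps integer, number of disease haplotypes (default 10).
#' @slot nCasesPerHap integer, implanted cases per haplotype (default 5).
#' @slot sharingLengthCm numeric, cM length of the implanted shared segment.
#' @slot genotypeErrorRate numeric, allele flip rate applied to the test
#'   cohort (default 0.01).
#' @slot phaseSwitchRatePerBp numeric, phase-switch error rate (default
#'   1/20.05e6 per bp).
#' @slot seed integer RNG seed; every downstream draw derives from it.
#' @export
setClass("ScenarioSpec",
  representation(locusId = "character", founderMode = "character",
                 nDiseaseHaps = "integer", nCasesPerHap = "integer",
                 sharingLengthCm = "numeric", genotypeErrorRate = "numeric",
                 phaseSwitchRatePerBp = "numeric", seed = "integer"),
  prototype(locusId = "locus1", founderMode = "single", nDiseaseHaps = 10L,
            nCasesPerHap = 5L, sharingLengthCm = 2,
            genotypeErrorRate = 0.01, phaseSwitchRatePerBp = 1 / 20.05e6,
            seed = 1L))

setValidity("ScenarioSpec", function(object) {
  if (!object@founderMode %in% c("single", "multiple"))
    return("founderMode must be 'single' or 'multiple'")
  if (object@sharingLengthCm <= 0) return("sharingLengthCm must be positive")
  if (object@genotypeErrorRate < 0 || object@genotypeErrorRate > 1)
    return("genotypeErrorRate must lie in [0, 1]")
  if (object@phaseSwitchRatePerBp < 0)
    return("phaseSwitchRatePerBp must be >= 0")
  if (object@nDiseaseHaps < 1L || object@nCasesPerHap < 1L)
    return("nDiseaseHaps and nCasesPerHap must be >= 1")
  TRUE
})
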