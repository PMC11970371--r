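# fixture builders shared across test files; everything is generated in code

# small fully annotated panel: n markers, uniform spacing, DCV at the centre
# (or at dcvAt), 1 cM/Mb map
makePanel <- function(n, spacingBp = 1e4, cmPerMb = 1, altFreq = NULL,
                      dcvAt = ceiling(n / 2), seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (is.null(altFreq)) altFreq <- runif(n, 0.05, 0.95)
  pos <- 1e6 + spacingBp * (seq_len(n) - 1L)
  MarkerPanel("chr1", pos, cm = (pos - pos[1]) * cmPerMb / 1e6,
              altFreq = altFreq, dcvPos = pos[dcvAt])
}

randomHap <- function(panel) rbinom(nMarkers(panel), 1L, altFreq(panel))

makeDisease <- function(panel, alleles = NULL, hapId = "h1",
                        variantId = "VAR") {
  if (is.null(alleles)) alleles <- randomHap(panel)
  DiseaseHaplotype(hapId, variantId, alleles, panelChrom(panel),
                   dcvPos(panel))
}

makeCohort <- function(panel, nInd, seed = NULL, idPrefix = "ind") {
  if (!is.null(seed)) set.seed(seed)
  n <- nMarkers(panel)
  A <- matrix(rbinom(n * nInd, 1L, altFreq(panel)), n, nInd)
  B <- matrix(rbinom(n * nInd, 1L, altFreq(panel)), n, nInd)
  colnames(A) <- colnames(B) <- sprintf("%s%03d", idPrefix, seq_len(nInd))
  PhasedCohort(A, B)
}
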