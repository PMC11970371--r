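#' Construct a marker panel
#'
#' @param chrom chromosome label (scalar).
#' @param posBp numeric physical positions (1-based bp), strictly increasing.
#' @param cm numeric genetic positions (cM) or NA before map annotation.
#' @param ref,alt single-character allele labels.
#' @param altFreq alternate-allele frequencies strictly in (0, 1), or NA
#'   before frequency annotation.
#' @param dcvPos bp position of the disease-causing variant, or NA.
#' @param imputeR2 optional per-marker imputation quality (NA = genotyped).
#' @return a [MarkerPanel-class].  If \code{dcvPos} is given the DCV marker
#'   ("marker 0") is the marker nearest by bp, ties broken toward the lower
#'   index.
#' @export
MarkerPanel <- function(chrom, posBp, cm = NA_real_, ref = "A", alt = "G",
                        altFreq = NA_real_, dcvPos = NA_real_,
                        imputeR2 = NA_real_) {
  n <- length(posBp)
  gr <- GRanges(seqnames = rep_len(as.character(chrom), max(n, 0L)),
                ranges = IRanges(start = posBp, width = 1L))
  mcols(gr)$cm <- rep_len(as.numeric(cm), n)
  mcols(gr)$ref <- rep_len(as.character(ref), n)
  mcols(gr)$alt <- rep_len(as.character(alt), n)
  mcols(gr)$altFreq <- rep_len(as.numeric(altFreq), n)
  mcols(gr)$imputeR2 <- rep_len(as.numeric(imputeR2), n)
  di <- if (is.na(dcvPos)) NA_integer_ else nearestMarkerIndex(posBp, dcvPos)
  new("MarkerPanel", markers = gr, dcvIndex = di, dcvPos = as.numeric(dcvPos))
}

# nearest marker by bp; ties toward the lower index
nearestMarkerIndex <- function(posBp, dcvPos) {
  d <- abs(posBp - dcvPos)
  which.min(d)[1L]
}

#' @rdname haploScreen-generics
#' @export
setMethod("nMarkers", "MarkerPanel", function(x) length(x@markers))

#' @rdname haploScreen-generics
#' @export
setMethod("markerPos", "MarkerPanel",
          function(x) GenomicRanges::start(x@markers))

#' @rdname haploScreen-generics
#' @export
setMethod("markerCm", "MarkerPanel", function(x) mcols(x@markers)$cm)

#' @rdname haploScreen-generics
#' @export
setMethod("altFreq", "MarkerPanel", function(x) mcols(x@markers)$altFreq)

#' @rdname haploScreen-generics
#' @export
setMethod("dcvIndex", "MarkerPanel", function(x) x@dcvIndex)

#' @rdname haploScreen-generics
#' @export
setMethod("dcvPos", "MarkerPanel", function(x) x@dcvPos)

#' @rdname haploScreen-generics
#' @export
setMethod("panelChrom", "MarkerPanel", function(x) {
  if (nMarkers(x) == 0L) return(NA_character_)
  as.character(seqnames(x@markers))[1L]
})

#' Marker ranges of a panel
#'
#' @param panel a [MarkerPanel-class].
#' @return the underlying \link[GenomicRanges]{GRanges}.
#' @export
markerRanges <- function(panel) panel@markers

#' Ref/alt allele labels of a panel
#' @param panel a [MarkerPanel-class].
#' @return data.frame with columns ref, alt.
#' @export
markerAlleles <- function(panel)
  data.frame(ref = mcols(panel@markers)$ref, alt = mcols(panel@markers)$alt,
             stringsAsFactors = FALSE)

#' Per-marker imputation quality
#' @param panel a [MarkerPanel-class].
#' @return numeric vector (NA where the marker carried no quality score).
#' @export
imputeR2 <- function(panel) mcols(panel@markers)$imputeR2

setMethod("show", "MarkerPanel", function(object) {
  cat(sprintf("MarkerPanel: %d markers on %s", nMarkers(object),
              panelChrom(object)))
  if (nMarkers(object) > 0) {
    cmr <- range(markerCm(object), na.rm = TRUE)
    cat(sprintf(" [%d-%d bp", min(markerPos(object)), max(markerPos(object))))
    if (all(is.finite(cmr))) cat(sprintf(", %.3f-%.3f cM", cmr[1], cmr[2]))
    cat("]")
  }
  cat("\n")
  if (!is.na(object@dcvIndex))
    cat(sprintf("  DCV at %s:%d -> marker %d\n", panelChrom(object),
                as.integer(object@dcvPos), object@dcvIndex))
  invisible(NULL)
})

#' Subset a panel by marker index
#'
#' @param x a [MarkerPanel-class].
#' @param i integer marker indices (must stay ordered).
#' @param j,...,drop ignored.
#' @return a [MarkerPanel-class] over the selected markers; the DCV index is
#'   recomputed against the retained markers.
#' @export
setMethod("[", "MarkerPanel", function(x, i, j, ..., drop = FALSE) {
  gr <- x@markers[i]
  di <- if (is.na(x@dcvPos)) NA_integer_ else
    nearestMarkerIndex(GenomicRanges::start(gr), x@dcvPos)
  new("MarkerPanel", markers = gr, dcvIndex = di, dcvPos = x@dcvPos)
})

#' Set the disease-causing-variant locus of a panel
#'
#' Snaps the DCV to the nearest marker by bp (ties toward the lower index);
#' the DCV itself need not be genotyped on the panel.
#'
#' @param panel a [MarkerPanel-class].
#' @param chrom chromosome label; must match the panel.
#' @param posBp DCV physical position.
#' @return the panel with its DCV marker set.
#' @export
setDcv <- function(panel, chrom, posBp) {
  if (!identical(as.character(chrom), panelChrom(panel)))
    stop(sprintf("DCV chromosome %s does not match panel chromosome %s",
                 chrom, panelChrom(panel)))
  panel@dcvPos <- as.numeric(posBp)
  panel@dcvIndex <- nearestMarkerIndex(markerPos(panel), posBp)
  validObject(panel)
  panel
}

#' Indices of markers within a genetic window around the DCV
#'
#' @param panel a [MarkerPanel-class] with cm annotation and a DCV set.
#' @param flankCm genetic distance retained on either side of the DCV.
#' @return integer marker indices whose cm lies within
#'   \code{[cm(dcv) - flankCm, cm(dcv) + flankCm]}.
#' @export
windowIndices <- function(panel, flankCm) {
  stopifnot(flankCm > 0)
  if (is.na(dcvIndex(panel))) stop("panel has no DCV set")
  cm <- markerCm(panel)
  if (anyNA(cm)) stop("panel lacks cm annotation; run annotateGeneticMap()")
  c0 <- cm[dcvIndex(panel)]
  which(cm >= c0 - flankCm & cm <= c0 + flankCm)
}

#' Trim a panel to a genetic window around the DCV
#'
#' Retains markers within \code{flankCm} centiMorgans on either side of the
#' DCV marker (default analysis windows are 10 cM per side, a 20-cM region).
#' Idempotent: trimming a trimmed panel with the same flank is a no-op.
#'
#' @param panel a [MarkerPanel-class] with cm annotation and a DCV set.
#' @param flankCm genetic distance kept on either side (cM).
#' @return the trimmed [MarkerPanel-class].
#' @export
trimPanel <- function(panel, flankCm = 10) {
  idx <- windowIndices(panel, flankCm)
  if (length(idx) == 0L)
    stop("no markers survive trimming; empty panel")
  panel[idx]
}

#' Deterministic fingerprint of a panel
#'
#' A cheap summary string used to refuse comparison of scores computed on
#' different panels (the empirical null is panel- and LD-specific).
#'
#' @param panel a [MarkerPanel-class].
#' @return character scalar.
#' @export
panelFingerprint <- function(panel) {
  n <- nMarkers(panel)
  if (n == 0L) return("empty")
  pos <- markerPos(panel)
  cm <- markerCm(panel)
  paste(panelChrom(panel), n, pos[1L], pos[n], dcvIndex(panel),
        format(sum(as.numeric(pos)) %% 1e9, scientific = FALSE),
        format(round(sum(cm[!is.na(cm)]), 6), scientific = FALSE),
        sep = ":")
}
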