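#' Construct a genetic map from anchor points
#'
#' @param chrom character vector of chromosome labels (recycled if scalar).
#' @param posBp numeric physical positions (bp), strictly increasing within a
#'   chromosome.
#' @param cm numeric genetic positions (cM), non-decreasing within a
#'   chromosome.
#' @return a [GeneticMap-class] object.
#' @examples
#' gm <- GeneticMap("chr1", c(0, 1e6), c(0, 1))
#' interpolateCm(gm, "chr1", 5e5)
#' @export
GeneticMap <- function(chrom, posBp, cm) {
  n <- length(posBp)
  chrom <- rep_len(as.character(chrom), n)
  o <- order(chrom, posBp)
  new("GeneticMap", chrom = chrom[o], posBp = as.numeric(posBp)[o],
      cm = as.numeric(cm)[o])
}

#' Read a HapMap-style genetic map
#'
#' Reads the common 3-column whitespace/tab dialect (chromosome, bp position,
#' cumulative cM).  A header line is auto-detected (non-numeric second field)
#' and skipped.  Files with extra columns (e.g. a per-bp rate column in third
#' position and cumulative cM fourth, the other common dialect) are handled by
#' \code{columns = c(chrom = 1, pos = 2, cm = 4)}.
#'
#' @param path file path.
#' @param columns named integer vector giving the chrom/pos/cm column indices.
#' @return a [GeneticMap-class].
#' @export
readGeneticMap <- function(path, columns = c(chrom = 1L, pos = 2L, cm = 3L)) {
  first <- readLines(path, n = 1L)
  fields <- strsplit(trimws(first), "[ \t]+")[[1]]
  skip <- if (length(fields) >= columns[["pos"]] &&
              suppressWarnings(is.na(as.numeric(fields[columns[["pos"]]])))) 1L else 0L
  tab <- utils::read.table(path, header = FALSE, skip = skip,
                           stringsAsFactors = FALSE)
  GeneticMap(chrom = tab[[columns[["chrom"]]]],
             posBp = tab[[columns[["pos"]]]],
             cm = tab[[columns[["cm"]]]])
}

#' Interpolate genetic position at physical positions
#'
#' Piecewise-linear interpolation between flanking map anchors; exact at
#' anchors, monotone non-decreasing in \code{posBp}.
#'
#' @param map a [GeneticMap-class].
#' @param chrom chromosome label (scalar).
#' @param posBp numeric vector of physical positions, all within the map's
#'   anchor range for that chromosome.
#' @return numeric vector of cM positions.
#' @export
interpolateCm <- function(map, chrom, posBp) {
  stopifnot(is(map, "GeneticMap"))
  i <- map@chrom == as.character(chrom)
  if (!any(i))
    stop(sprintf("chromosome %s not present in genetic map", chrom))
  x <- map@posBp[i]
  y <- map@cm[i]
  lo <- min(x); hi <- max(x)
  out <- posBp < lo | posBp > hi
  if (any(out))
    stop(sprintf(
      "position(s) %s outside genetic-map range [%s, %s] on chromosome %s",
      paste(utils::head(posBp[out], 3), collapse = ", "), lo, hi, chrom))
  stats::approx(x, y, xout = posBp, method = "linear", ties = "ordered")$y
}

#' Annotate a marker panel with genetic positions
#'
#' Fills the panel's \code{cm} column by one interpolation pass over the map;
#' cM values are carried on the markers thereafter.
#'
#' @param panel a [MarkerPanel-class].
#' @param map a [GeneticMap-class] covering the panel's bp range.
#' @return the annotated panel.
#' @export
annotateGeneticMap <- function(panel, map) {
  stopifnot(is(panel, "MarkerPanel"))
  mcols(panel@markers)$cm <-
    interpolateCm(map, panelChrom(panel), markerPos(panel))
  validObject(panel)
  panel
}
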