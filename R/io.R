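#' Read a phased VCF into a cohort and panel skeleton
#'
#' Reads GT fields of a VCF 4.x file (plain text or gzipped) via
#' \pkg{vcfR}.  All genotypes in the region must be phased ("|" separator);
#' an unphased genotype is a hard error naming the offending record, because
#' the scoring model consumes haplotypes, not genotypes.  Multiallelic
#' records are dropped and counted.  "." alleles become missing.  The
#' returned panel skeleton carries bp positions, ref/alt labels and any
#' per-marker imputation quality found under \code{r2Key} in INFO; cM and
#' allele frequencies are attached later ([annotateGeneticMap()],
#' [attachFrequencies()]).
#'
#' @param path VCF path.
#' @param region optional "chrom:start-end" subset string.
#' @param r2Key INFO key holding imputation quality (default "R2").
#' @return list: \code{cohort} ([PhasedCohort-class]), \code{panel}
#'   ([MarkerPanel-class] skeleton), \code{nMultiallelicDropped}.
#' @export
readPhasedVcf <- function(path, region = NULL, r2Key = "R2") {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(v, getINFO = TRUE)
  if (is.null(dim(fix))) fix <- matrix(fix, nrow = 1,
                                       dimnames = list(NULL, names(fix)))
  chrom <- fix[, "CHROM"]
  pos <- as.numeric(fix[, "POS"])
  keep <- rep(TRUE, length(pos))
  if (!is.null(region)) {
    m <- regmatches(region, regexec("^([^:]+):([0-9]+)-([0-9]+)$", region))[[1]]
    if (length(m) != 4) stop("region must be 'chrom:start-end'")
    keep <- chrom == m[2] & pos >= as.numeric(m[3]) & pos <= as.numeric(m[4])
  }
  multi <- grepl(",", fix[, "ALT"], fixed = TRUE)
  nMulti <- sum(multi & keep)
  keep <- keep & !multi
  if (!any(keep)) stop("no biallelic records in the requested region")
  gt <- vcfR::extract.gt(v, element = "GT")[keep, , drop = FALSE]
  idRec <- paste0(chrom[keep], ":", pos[keep])
  # fully missing "./." is tolerated as missing, anything else unphased is not
  unph <- grepl("/", gt, fixed = TRUE) & gt != "./."
  if (any(unph, na.rm = TRUE)) {
    w <- which(unph, arr.ind = TRUE)[1L, ]
    stop(sprintf(
      "unphased genotype '%s' at %s (sample %s); phased input is required",
      gt[w[1L], w[2L]], idRec[w[1L]], colnames(gt)[w[2L]]))
  }
  gt[gt == "./."] <- ".|."       # fully missing, tolerated
  toAllele <- function(a) {
    a[a == "." | a == "" | is.na(a)] <- NA
    suppressWarnings(matrix(as.integer(a), nrow = nrow(gt),
                            dimnames = list(NULL, colnames(gt))))
  }
  A <- toAllele(sub("\\|.*$", "", gt))
  B <- toAllele(sub("^.*\\|", "", gt))
  info <- fix[keep, "INFO"]
  m <- regmatches(info, regexec(sprintf("(?:^|;)%s=([^;]+)", r2Key), info,
                                perl = TRUE))
  r2 <- suppressWarnings(vapply(m, function(x)
    if (length(x) == 2L) as.numeric(x[2L]) else NA_real_, numeric(1)))
  panel <- MarkerPanel(chrom = chrom[keep][1L], posBp = pos[keep],
                       cm = NA_real_, ref = fix[keep, "REF"],
                       alt = fix[keep, "ALT"], altFreq = NA_real_,
                       imputeR2 = r2)
  list(cohort = PhasedCohort(A, B), panel = panel,
       nMultiallelicDropped = nMulti)
}

#' Write a cohort as a phased VCF
#'
#' Plain-text VCF 4.2 with phased GT fields; missing alleles become ".".
#'
#' @param cohort a [PhasedCohort-class].
#' @param panel matching [MarkerPanel-class].
#' @param path output path.
#' @param imputeR2 optional per-marker quality written as INFO R2.
#' @return the path, invisibly.
#' @export
writePhasedVcf <- function(cohort, panel, path, imputeR2 = NULL) {
  stopifnot(nMarkers(cohort) == nMarkers(panel))
  al <- markerAlleles(panel)
  fmt <- function(m) ifelse(is.na(m), ".", as.character(m))
  gt <- matrix(paste(fmt(hapA(cohort)), fmt(hapB(cohort)), sep = "|"),
               nrow = nMarkers(panel))
  info <- if (is.null(imputeR2)) rep(".", nMarkers(panel)) else
    ifelse(is.na(imputeR2), ".", sprintf("R2=%g", imputeR2))
  body <- paste(panelChrom(panel), markerPos(panel),
                sprintf("m%d", seq_len(nMarkers(panel))), al$ref, al$alt,
                ".", "PASS", info, "GT",
                apply(gt, 1L, paste, collapse = "\t"), sep = "\t")
  header <- c("##fileformat=VCFv4.2",
              sprintf("##contig=<ID=%s>", panelChrom(panel)),
              "##INFO=<ID=R2,Number=1,Type=Float,Description=\"Imputation quality\">",
              "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
              paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                      "INFO", "FORMAT", individualIds(cohort)),
                    collapse = "\t"))
  writeLines(c(header, body), path)
  invisible(path)
}

#' Filter markers by the standard preprocessing rules
#'
#' Retains biallelic markers whose imputation quality is at least
#' \code{minImputeR2} (default 0.3, boundary inclusive).  Markers without a
#' quality score are kept with a warning (treated as directly genotyped, not
#' imputed).  Multiallelic removal happens at VCF load; its count can be
#' passed through for the report.
#'
#' @param panel a [MarkerPanel-class] (with imputeR2 where available).
#' @param cohort matching [PhasedCohort-class].
#' @param minImputeR2 retention threshold (markers with R2 >= this survive).
#' @param nMultiallelicDropped count from [readPhasedVcf()] for the report.
#' @return list: filtered \code{panel} and \code{cohort}, and \code{report}
#'   (data.frame rule/removed, with a retained row; removed + retained =
#'   input count, multiallelic included).
#' @export
filterMarkers <- function(panel, cohort, minImputeR2 = 0.3,
                          nMultiallelicDropped = 0L) {
  r2 <- imputeR2(panel)
  noScore <- is.na(r2)
  if (any(noScore))
    warning(sprintf(
      "%d markers lack an imputation quality score; kept as genotyped",
      sum(noScore)))
  keep <- noScore | r2 >= minImputeR2
  report <- data.frame(
    rule = c("non_biallelic", "imputation_quality", "retained"),
    count = c(nMultiallelicDropped, sum(!keep), sum(keep)))
  list(panel = panel[which(keep)], cohort = cohort[which(keep), ],
       report = report)
}

#' Attach population allele frequencies to a panel
#'
#' Joins a frequency table keyed by (chrom, pos, ref, alt) onto the panel.
#' Entries whose ref/alt are swapped relative to the panel have their
#' frequency complemented and are flagged.  Markers absent from the table,
#' with frequency 0 or 1, or with irreconcilable alleles (e.g. strand flips)
#' are dropped and counted.
#'
#' @param panel a [MarkerPanel-class].
#' @param freqTable data.frame with columns chrom, pos, ref, alt, alt_freq.
#' @param cohort optional matching [PhasedCohort-class], subset alongside.
#' @return list: annotated \code{panel}, \code{cohort} (if given),
#'   \code{keep} (retained marker indices), \code{nSwapped},
#'   \code{report} (data.frame rule/count).
#' @export
attachFrequencies <- function(panel, freqTable, cohort = NULL) {
  key <- function(chrom, pos, a1, a2) paste(chrom, pos, a1, a2, sep = ":")
  al <- markerAlleles(panel)
  pk <- key(panelChrom(panel), markerPos(panel), al$ref, al$alt)
  tk <- key(freqTable$chrom, freqTable$pos, freqTable$ref, freqTable$alt)
  hit <- match(pk, tk)
  swappedKey <- key(panelChrom(panel), markerPos(panel), al$alt, al$ref)
  hitSw <- match(swappedKey, tk)
  f <- freqTable$alt_freq[hit]
  swapped <- is.na(hit) & !is.na(hitSw)
  f[swapped] <- 1 - freqTable$alt_freq[hitSw[swapped]]
  if (any(swapped))
    warning(sprintf(
      "%d markers matched the frequency table with ref/alt swapped; %s",
      sum(swapped), "frequencies complemented"))
  missing <- is.na(f)
  fixed <- !missing & (f <= 0 | f >= 1)
  keep <- which(!missing & !fixed)
  if (length(keep) == 0L) stop("no markers carry a usable frequency")
  out <- panel[keep]
  mcols(out@markers)$altFreq <- f[keep]
  report <- data.frame(
    rule = c("frequency_missing", "frequency_fixed", "allele_swapped",
             "retained"),
    count = c(sum(missing), sum(fixed), sum(swapped & !fixed),
              length(keep)))
  list(panel = out,
       cohort = if (is.null(cohort)) NULL else cohort[keep, ],
       keep = keep, nSwapped = sum(swapped), report = report)
}

#' Read a frequency table
#'
#' Tab-separated with header columns chrom, pos, ref, alt, alt_freq.
#'
#' @param path file path.
#' @return data.frame.
#' @export
readFrequencyTable <- function(path)
  utils::read.table(path, header = TRUE, sep = "\t",
                    stringsAsFactors = FALSE)

#' Write screening results
#'
#' Tab-separated: individual_id, variant_id, best_hap_id, ibd_score,
#' empirical_p, call, rank; rows ordered by descending score then id, scores
#' at 6 significant digits (re-reading reproduces ranks exactly).
#'
#' @param results data.frame from [screenCohort()]/[scoreCohort()] merged
#'   with calls (columns as above).
#' @param path output path.
#' @return the path, invisibly.
#' @export
writeResults <- function(results, path) {
  cols <- c("individual_id", "variant_id", "best_hap_id", "ibd_score",
            "empirical_p", "call", "rank")
  results <- results[, cols, drop = FALSE]
  o <- order(-results$ibd_score, results$individual_id)
  results <- results[o, , drop = FALSE]
  results$ibd_score <- signif(results$ibd_score, 6)
  results$empirical_p <- signif(results$empirical_p, 6)
  utils::write.table(results, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname writeResults
#' @export
readResults <- function(path)
  utils::read.table(path, header = TRUE, sep = "\t",
                    stringsAsFactors = FALSE)

#' Write / read a simulation truth table
#'
#' @param truth truth data.frame from [runScenario()].
#' @param path file path.
#' @return path invisibly (write); data.frame (read).
#' @export
writeTruthTable <- function(truth, path) {
  utils::write.table(truth, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname writeTruthTable
#' @export
readTruthTable <- function(path)
  utils::read.table(path, header = TRUE, sep = "\t",
                    stringsAsFactors = FALSE)
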