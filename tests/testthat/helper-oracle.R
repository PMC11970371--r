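# independent oracles used to pin down the scoring model and the PR curve;
# these never call the code paths they check

# Exhaustive hidden-state-path enumeration of one chain's ln LLR.
# States 1 = IBD on hap A, 2 = IBD on hap B, 3 = non-IBD (absorbing); start
# mass (0.5, 0.5, 0) at the DCV locus.  Vectorised over the 3^T paths.
chainOracle <- function(disease, hA, hB, panel, params,
                        direction = "right",
                        includeOrigin = (direction == "right")) {
  d0 <- dcvIndex(panel)
  nn <- nMarkers(panel)
  ord <- if (direction == "right") {
    from <- if (includeOrigin) d0 else d0 + 1L
    if (from > nn) integer(0) else from:nn
  } else {
    from <- if (includeOrigin) d0 else d0 - 1L
    if (from < 1L) integer(0) else from:1L
  }
  d <- alleles(disease)[ord]
  ord <- ord[!is.na(d)]
  d <- d[!is.na(d)]
  # markers missing on the disease haplotype or on both test haplotypes are
  # skipped: no emission, no transition, distance accrues to the next
  # informative marker (same convention as the forward engine)
  keep <- !(is.na(hA[ord]) & is.na(hB[ord]))
  ord <- ord[keep]
  d <- d[keep]
  T <- length(ord)
  if (T == 0L) return(0)
  cm <- markerCm(panel)[ord]; bp <- markerPos(panel)[ord]
  f <- altFreq(panel)[ord]
  A <- hA[ord]; B <- hB[ord]
  g <- params@g; k <- params@decayMeioses; r <- params@switchRatePerBp
  pcm <- c(markerCm(panel)[d0], cm[-T]); pbp <- c(markerPos(panel)[d0],
                                                  bp[-T])
  dM <- abs(cm - pcm) / 100; dB <- abs(bp - pbp)
  eA <- ifelse(is.na(A), 1, ifelse(A == d, 1 - g, g))
  eB <- ifelse(is.na(B), 1, ifelse(B == d, 1 - g, g))
  fA <- ifelse(is.na(A), 1, ifelse(A == 1, f, 1 - f))
  fB <- ifelse(is.na(B), 1, ifelse(B == 1, f, 1 - f))
  eN <- (fA + fB) / 2
  E <- rbind(eA, eB, eN)                      # 3 x T
  # per-interval transition kernels
  Ks <- lapply(seq_len(T), function(t) {
    p <- exp(-k * dM[t]); s <- min(1, r * dB[t])
    matrix(c(p * (1 - s), p * s, 1 - p,
             p * s, p * (1 - s), 1 - p,
             0, 0, 1), 3, byrow = TRUE)
  })
  paths <- as.matrix(expand.grid(rep(list(1:3), T)))
  init <- c(0.5, 0.5, 0)
  w <- (init[1] * Ks[[1]][1, paths[, 1]] +
        init[2] * Ks[[1]][2, paths[, 1]]) * E[cbind(paths[, 1], 1L)]
  if (T > 1) for (t in 2:T)
    w <- w * Ks[[t]][cbind(paths[, t - 1], paths[, t])] *
      E[cbind(paths[, t], t)]
  log(sum(w)) - sum(log(eN))
}

# brute-force average precision: enumerate every threshold
apOracle <- function(scores, labels) {
  thr <- sort(unique(scores), decreasing = TRUE)
  nPos <- sum(labels)
  prevR <- 0
  ap <- 0
  for (th in thr) {
    sel <- scores >= th
    p <- sum(labels[sel]) / sum(sel)
    r <- sum(labels[sel]) / nPos
    ap <- ap + (r - prevR) * p
    prevR <- r
  }
  ap
}
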