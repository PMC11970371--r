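test_that("emission probabilities follow the error model and the null", {
  expect_equal(emissionProb(1, 1, 0.2, 0.01, "IBD"), 0.99)
  expect_equal(emissionProb(1, 0, 0.2, 0.01, "IBD"), 0.01)
  expect_equal(emissionProb(0, 1, 0.2, 0.30, "nonIBD"), 0.2)
  expect_equal(emissionProb(0, 0, 0.2, 0.01, "nonIBD"), 0.8)
  expect_error(emissionProb(NA, 1, 0.2, 0.01, "IBD"), "missing")
  # probabilities stay inside (0, 1) across the parameter box
  set.seed(1)
  f <- runif(50, 0.01, 0.99); g <- runif(50, 0.001, 0.49)
  da <- rbinom(50, 1, 0.5); ta <- rbinom(50, 1, 0.5)
  for (st in c("IBD", "nonIBD")) {
    e <- emissionProb(da, ta, f, g, st)
    expect_true(all(e > 0 & e < 1))
  }
})

test_that("transition kernel: identity at zero distance, exponential decay, absorbing nonIBD", {
  expect_equal(transitionProbs(0, 0), diag(3), ignore_attr = TRUE)
  k <- transitionProbs(0.01, 0, HMMParams(decayMeioses = 20,
                                          switchRatePerBp = 0))
  expect_equal(k["IBD_A", "IBD_A"], exp(-0.2))
  expect_equal(k["IBD_A", "nonIBD"], 1 - exp(-0.2))
  expect_equal(k["IBD_A", "IBD_B"], 0)
  # large distance: IBD is lost
  kL <- transitionProbs(10, 0)
  expect_lt(kL["IBD_A", "IBD_A"], 1e-80)
  # rows always sum to 1, nonIBD absorbing, for random distances
  set.seed(2)
  for (i in 1:25) {
    k <- transitionProbs(runif(1, 0, 0.5), runif(1, 0, 5e7),
                         HMMParams(g = 0.01,
                                   decayMeioses = runif(1, 1, 60),
                                   switchRatePerBp = runif(1, 0, 1e-6)))
    expect_equal(rowSums(k), c(IBD_A = 1, IBD_B = 1, nonIBD = 1))
    expect_equal(k["nonIBD", ], c(IBD_A = 0, IBD_B = 0, nonIBD = 1))
  }
})

test_that("chain llr equals exhaustive path enumeration on small panels", {
  set.seed(11)
  params <- HMMParams()
  for (i in 1:12) {
    n <- sample(4:9, 1)
    panel <- makePanel(n, spacingBp = sample(c(1e4, 2e5), 1))
    dis <- makeDisease(panel)
    hA <- randomHap(panel); hB <- randomHap(panel)
    if (i %% 3 == 0) hA[sample(n, 1)] <- NA        # one-hap missing
    if (i %% 4 == 0) { j <- sample(n, 1); hA[j] <- NA; hB[j] <- NA }
    for (dir in c("left", "right")) {
      got <- chainLLR(dis, hA, hB, panel, dir, params, dropThreshold = Inf)
      expect_equal(got$llrFinal, chainOracle(dis, hA, hB, panel, params, dir),
                   tolerance = 1e-9)
    }
  }
})

test_that("perfect sharing keeps the chain alive to the window edge with positive llr", {
  panel <- makePanel(60, altFreq = rep(0.5, 60), seed = 3)
  dis <- makeDisease(panel)
  hB <- randomHap(panel)
  r <- chainLLR(dis, alleles(dis), hB, panel, "right")
  expect_gt(r$llr, 0)
  expect_equal(r$endIndex, nMarkers(panel))
  l <- chainLLR(dis, alleles(dis), hB, panel, "left")
  expect_equal(l$endIndex, 1L)
})

test_that("unrelated haplotypes score below the perfect match on average", {
  set.seed(7)
  panel <- makePanel(50, altFreq = rep(0.5, 50))
  dis <- makeDisease(panel)
  perfect <- chainLLR(dis, alleles(dis), randomHap(panel), panel, "right",
                      dropThreshold = Inf)$llrFinal
  rand <- replicate(40, chainLLR(dis, randomHap(panel), randomHap(panel),
                                 panel, "right",
                                 dropThreshold = Inf)$llrFinal)
  expect_lt(mean(rand), perfect)
})

test_that("left and right chains agree on data mirrored around the DCV", {
  set.seed(9)
  n <- 21                                     # DCV at 11; 10 markers per side
  f <- runif(10, 0.1, 0.9)
  panel <- makePanel(n, altFreq = c(rev(f), 0.5, f))
  half <- rbinom(10, 1, 0.5)
  dis <- makeDisease(panel, alleles = c(rev(half), 1L, half))
  ha <- rbinom(10, 1, 0.5); hb <- rbinom(10, 1, 0.5)
  hA <- c(rev(ha), 1L, ha); hB <- c(rev(hb), 0L, hb)
  left <- chainLLR(dis, hA, hB, panel, "left", includeOrigin = FALSE)
  right <- chainLLR(dis, hA, hB, panel, "right", includeOrigin = FALSE)
  expect_equal(left$llr, right$llr, tolerance = 1e-12)
})

test_that("score is invariant under ref/alt relabelling with complemented frequency", {
  set.seed(13)
  panel <- makePanel(30)
  dis <- makeDisease(panel)
  hA <- randomHap(panel); hB <- randomHap(panel)
  base <- scorePair(dis, hA, hB, panel)$score
  flip <- sample(30, 10)
  f2 <- altFreq(panel); f2[flip] <- 1 - f2[flip]
  panel2 <- MarkerPanel("chr1", markerPos(panel), cm = markerCm(panel),
                        altFreq = f2, dcvPos = dcvPos(panel))
  sw <- function(v) { v[flip] <- 1L - v[flip]; v }
  dis2 <- makeDisease(panel2, alleles = sw(alleles(dis)))
  expect_equal(scorePair(dis2, sw(hA), sw(hB), panel2)$score, base,
               tolerance = 1e-12)
})

test_that("a marker missing everywhere scores the same as a deleted marker", {
  set.seed(17)
  panel <- makePanel(25)
  dis <- makeDisease(panel)
  hA <- randomHap(panel); hB <- randomHap(panel)
  drop <- c(5L, 18L)
  hA2 <- hA; hB2 <- hB
  hA2[drop] <- NA; hB2[drop] <- NA
  skipped <- scorePair(dis, hA2, hB2, panel)$score
  panel2 <- panel[setdiff(seq_len(25), drop)]
  dis2 <- makeDisease(panel2, alleles = alleles(dis)[-drop])
  deleted <- scorePair(dis2, hA[-drop], hB[-drop], panel2)$score
  expect_equal(skipped, deleted, tolerance = 1e-12)
})

test_that("as g -> 0, a doubly matching marker contributes ln(stay/f)", {
  params <- HMMParams(g = 1e-9)
  contrib <- function(f2) {
    panel <- makePanel(2, spacingBp = 1e3, altFreq = c(0.5, f2), dcvAt = 1)
    dis <- makeDisease(panel, alleles = c(1L, 1L))
    one <- chainLLR(dis, 1L, 1L, makePanel(1, altFreq = 0.5, dcvAt = 1),
                    "right", params, dropThreshold = Inf)
    both <- chainLLR(dis, c(1L, 1L), c(1L, 1L), panel, "right", params,
                     dropThreshold = Inf)
    both$llrFinal - one$llrFinal
  }
  stay <- exp(-params@decayMeioses * 1e-3 / 100)
  expect_equal(contrib(0.07), log(stay / 0.07), tolerance = 1e-3)
  expect_equal(contrib(0.4), log(stay / 0.4), tolerance = 1e-3)
  expect_gt(contrib(0.07), contrib(0.4))   # rarer matching alleles count more
})

test_that("the chain terminates after sharing stops and keeps its running maximum", {
  set.seed(19)
  n <- 400
  panel <- makePanel(n, altFreq = rep(0.4, n), dcvAt = 1)
  dis <- makeDisease(panel, alleles = rep(1L, n))
  # share the first 60 markers, then anti-share (mismatch everywhere)
  hA <- c(rep(1L, 60), rep(0L, n - 60))
  hB <- rbinom(n, 1, 0.4)
  r <- chainLLR(dis, hA, hB, panel, "right")
  expect_lt(r$endIndex, 100)        # stopped near the end of sharing
  rInf <- chainLLR(dis, hA, hB, panel, "right", dropThreshold = Inf)
  expect_gt(r$llr, rInf$llrFinal)   # running max, not the collapsed tail
})

test_that("scorePair splits chains around a DCV counted once", {
  set.seed(23)
  panel <- makePanel(15)
  dis <- makeDisease(panel)
  hA <- randomHap(panel); hB <- randomHap(panel)
  res <- scorePair(dis, hA, hB, panel)
  left <- chainLLR(dis, hA, hB, panel, "left")
  right <- chainLLR(dis, hA, hB, panel, "right")
  expect_equal(res$score, left$llr + right$llr)
  expect_lte(res$left_end_index, dcvIndex(panel))
  expect_gte(res$right_end_index, dcvIndex(panel))
})

test_that("score over a haplotype set is the max with deterministic tie-break", {
  set.seed(29)
  panel <- makePanel(20)
  hA <- randomHap(panel); hB <- randomHap(panel)
  d1 <- makeDisease(panel, hapId = "b")
  singleton <- scoreAgainstSet(list(d1), hA, hB, panel)
  expect_equal(singleton$score, scorePair(d1, hA, hB, panel)$score)
  # a duplicate haplotype under a lower id wins the tie
  d2 <- makeDisease(panel, alleles = alleles(d1), hapId = "a")
  expect_equal(scoreAgainstSet(list(d1, d2), hA, hB, panel)$hap_id, "a")
  # enlarging the set never decreases the score
  d3 <- makeDisease(panel, hapId = "c")
  best <- scoreAgainstSet(list(d1, d3, d2), hA, hB, panel)
  expect_gte(best$score, singleton$score)
  expect_error(scoreAgainstSet(list(), hA, hB, panel), "empty")
})

test_that("vectorised cohort scoring matches per-pair scoring and is chunk-invariant", {
  set.seed(31)
  panel <- makePanel(40)
  cohort <- makeCohort(panel, 7)
  cohort@hapA[cbind(sample(40, 5), sample(7, 5, replace = TRUE))] <- NA
  haps <- list(makeDisease(panel, hapId = "h1"),
               makeDisease(panel, hapId = "h2"))
  m <- scoreMatrix(haps, cohort, panel)
  for (i in seq_len(7)) for (j in 1:2) {
    expect_equal(m[i, j],
                 scorePair(haps[[j]], hapA(cohort)[, i], hapB(cohort)[, i],
                           panel)$score,
                 tolerance = 1e-12)
  }
  expect_identical(m, scoreMatrix(haps, cohort, panel, chunkSize = 3))
  expect_identical(m, scoreMatrix(haps, cohort, panel, chunkSize = 1))
  best <- scoreCohort(haps, cohort, panel)
  expect_equal(best$score, apply(m, 1, max), ignore_attr = TRUE)
})

test_that("a missing DCV allele on the disease haplotype is rejected", {
  panel <- makePanel(9)
  al <- randomHap(panel)
  al[dcvIndex(panel)] <- NA
  dis <- makeDisease(panel, alleles = al)
  expect_error(scorePair(dis, randomHap(panel), randomHap(panel), panel),
               "DCV")
})
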