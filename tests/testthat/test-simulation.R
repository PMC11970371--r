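test_that("the cohort generator is reproducible and well-formed", {
  a <- synthCohort(nIndividuals = 40, nMarkers = 300, spanCm = 5, seed = 3)
  b <- synthCohort(nIndividuals = 40, nMarkers = 300, spanCm = 5, seed = 3)
  expect_identical(hapA(a$cohort), hapA(b$cohort))
  expect_identical(markerPos(a$panel), markerPos(b$panel))
  expect_equal(nMarkers(a$cohort), nMarkers(a$panel))
  f <- altFreq(a$panel)
  expect_true(all(f > 0 & f < 1))
  # recorded frequency is the realised cohort frequency
  expect_equal(f, (rowSums(hapA(a$cohort)) + rowSums(hapB(a$cohort))) / 80)
  expect_false(is.na(dcvIndex(a$panel)))
})

test_that("without recombination every haplotype is a full founder copy", {
  fs <- synthFounders(nMarkers = 200, nFounders = 2, spanCm = 5, seed = 5)
  cohort <- sampleCohort(fs, 30, founderSwitchCm = Inf, seed = 6)
  H <- cbind(hapA(cohort), hapB(cohort))
  match1 <- colMeans(H == fs$founders[, 1])
  expect_true(all(match1 %in% c(0, 1)))   # pairwise identity is 0 or 100%
})

test_that("shorter founder segments weaken adjacent-marker LD", {
  r2At <- function(switchCm, seed) {
    fs <- synthFounders(nMarkers = 400, nFounders = 30, spanCm = 4,
                        seed = seed)
    cohort <- sampleCohort(fs, 120, founderSwitchCm = switchCm,
                           seed = seed + 1)
    H <- cbind(hapA(cohort), hapB(cohort))
    keep <- rowMeans(H) > 0.1 & rowMeans(H) < 0.9
    H <- H[keep, ]
    # r^2 at ~0.1 cM (10 markers apart on the 0.01 cM grid)
    mean(vapply(seq_len(nrow(H) - 10), function(i)
      suppressWarnings(cor(H[i, ], H[i + 10, ]))^2, numeric(1)),
      na.rm = TRUE)
  }
  long <- vapply(1:5, function(s) r2At(2, 10 * s), numeric(1))
  short <- vapply(1:5, function(s) r2At(0.05, 10 * s), numeric(1))
  expect_gt(mean(long), mean(short))
})

test_that("single-founder disease haplotypes share the ancestral core exactly", {
  sim <- synthCohort(nIndividuals = 60, nMarkers = 500, spanCm = 12,
                     seed = 21)
  dh <- deriveDiseaseHaplotypes(sim$cohort, sim$panel, "single", nHaps = 6,
                                coreLengthCm = 5, seed = 2)
  expect_length(dh$haps, 6)
  expect_length(dh$donorIds, 7)           # ancestor + 6 backgrounds
  cm <- markerCm(sim$panel)
  core <- which(abs(cm - cm[dcvIndex(sim$panel)]) <= 2.5)
  mat <- vapply(dh$haps, function(h) alleles(h)[core],
                integer(length(core)))
  expect_true(all(mat == mat[, 1]))       # no mismatches inside the core
})

test_that("multiple-founder haplotypes come from distinct donors; limits enforced", {
  sim <- synthCohort(nIndividuals = 30, nMarkers = 300, spanCm = 6,
                     seed = 22)
  dh <- deriveDiseaseHaplotypes(sim$cohort, sim$panel, "multiple",
                                nHaps = 10, seed = 3)
  expect_length(unique(dh$donorIds), 10)
  expect_error(deriveDiseaseHaplotypes(sim$cohort, sim$panel, "multiple",
                                       nHaps = 31, seed = 3), "donor")
  one <- deriveDiseaseHaplotypes(sim$cohort, sim$panel, "single",
                                 nHaps = 1, coreLengthCm = 2, seed = 4)
  expect_length(one$haps, 1)
})

test_that("implantation replaces exactly the symmetric cM interval", {
  sim <- synthCohort(nIndividuals = 20, nMarkers = 800, spanCm = 8,
                     seed = 23)
  panel <- sim$panel
  dis <- makeDisease(panel, alleles = rep(1L, nMarkers(panel)))
  set.seed(9)
  imp <- implantCase(sim$cohort, 5, dis, panel, sharingLengthCm = 5)
  cm <- markerCm(panel)
  inside <- abs(cm - cm[dcvIndex(panel)]) <= 2.5
  H <- if (imp$haplotype == "A") hapA(imp$cohort) else hapB(imp$cohort)
  H0 <- if (imp$haplotype == "A") hapA(sim$cohort) else hapB(sim$cohort)
  expect_true(all(H[inside, 5] == 1L))
  expect_identical(H[!inside, 5], H0[!inside, 5])
  other <- if (imp$haplotype == "A") hapB else hapA
  expect_identical(other(imp$cohort), other(sim$cohort))
  # 5 cM on a 1 cM/Mb map spans 5 Mb
  expect_equal(diff(range(markerPos(panel)[inside])), 5e6,
               tolerance = 0.01)
})

test_that("genotype error injection flips at the nominal binomial rate", {
  panel <- makePanel(1000, seed = 31)
  cohort <- makeCohort(panel, 500, seed = 32)
  cohort@hapA[1, 1] <- NA
  same <- injectGenotypeErrors(cohort, 0, seed = 1)
  expect_identical(hapA(same), hapA(cohort))
  err <- injectGenotypeErrors(cohort, 0.01, seed = 1)
  expect_true(is.na(hapA(err)[1, 1]))     # missingness preserved
  slots <- 2 * 1000 * 500 - 1
  flips <- sum(hapA(err) != hapA(cohort), na.rm = TRUE) +
    sum(hapB(err) != hapB(cohort), na.rm = TRUE)
  ci <- qbinom(c(0.005, 0.995), slots, 0.01)
  expect_gte(flips, ci[1]); expect_lte(flips, ci[2])
  # resampled, not an involution
  twice <- injectGenotypeErrors(err, 0.01, seed = 1)
  expect_false(identical(hapA(twice), hapA(cohort)))
})

test_that("phase-switch errors form blocks at about one switch per 20.05 Mbp", {
  # constant haplotypes make switch points directly observable
  n <- 402
  pos <- seq(1e6, 1e6 + 20.05e6, length.out = n)
  panel <- MarkerPanel("chr1", pos, cm = (pos - pos[1]) / 1e6,
                       altFreq = 0.5, dcvPos = pos[200])
  nInd <- 3000
  A <- matrix(0L, n, nInd); B <- matrix(1L, n, nInd)
  colnames(A) <- colnames(B) <- sprintf("i%04d", 1:nInd)
  cohort <- PhasedCohort(A, B)
  same <- injectPhaseSwitchErrors(cohort, panel, 0, seed = 2)
  expect_identical(hapA(same), hapA(cohort))
  sw <- injectPhaseSwitchErrors(cohort, panel, 1 / 20.05e6, seed = 2)
  # block boundaries per individual = number of drawn switch points
  boundaries <- colSums(abs(diff(hapA(sw)))) + hapA(sw)[1, ]
  expect_equal(mean(boundaries), 1, tolerance = 0.1)
  expect_gt(max(boundaries), 1)           # consecutive switches form blocks
})

test_that("scenarios are deterministic and produce the designed case structure", {
  sim <- synthCohort(nIndividuals = 120, nMarkers = 600, spanCm = 12,
                     seed = 41)
  spec <- ScenarioSpec("locusA", "single", nDiseaseHaps = 5,
                       nCasesPerHap = 4, sharingLengthCm = 2, seed = 7)
  r1 <- runScenario(spec, sim$cohort, sim$panel)
  r2 <- runScenario(spec, sim$cohort, sim$panel)
  expect_identical(hapA(r1$testCohort), hapA(r2$testCohort))
  expect_identical(r1$truth, r2$truth)
  expect_equal(sum(r1$truth$is_case), 5 * 4)
  expect_equal(table(r1$truth$source_hap[r1$truth$is_case]),
               table(rep(sprintf("hap%02d", 1:5), 4)), ignore_attr = TRUE)
  # donors are out; everyone not implanted is a control
  expect_equal(nIndividuals(r1$testCohort), 120 - 6)
  expect_true(all(is.na(r1$truth$source_hap[!r1$truth$is_case])))
  # default design: 10 haplotypes x 5 cases
  expect_equal(ScenarioSpec()@nDiseaseHaps * ScenarioSpec()@nCasesPerHap,
               50L)
})
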