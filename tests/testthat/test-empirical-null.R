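nullOf <- function(scores, id = "V") {
  names(scores) <- sprintf("c%04d", seq_along(scores))
  suppressWarnings(NullDistribution(id, scores))
}

test_that("critical value is the conservative order statistic", {
  expect_equal(criticalValue(nullOf(sample(1:100)), 99), 99)
  # degenerate null: everyone at c, nobody exceeds the threshold
  expect_equal(criticalValue(nullOf(rep(3.2, 150)), 99), 3.2)
  # n = 503 -> ceil(0.99 * 503) = 498th order statistic
  set.seed(5)
  s <- rnorm(503)
  expect_equal(criticalValue(nullOf(s), 99), sort(s)[498])
  # by construction at most 1% of controls lie strictly above
  expect_lte(mean(s > criticalValue(nullOf(s), 99)), 0.01)
  expect_error(criticalValue(nullOf(s), 0))
  expect_error(NullDistribution("V", numeric(0)), "empty")
  expect_warning(NullDistribution("V", rnorm(10)), "100")
})

test_that("critical value is monotone in the percentile", {
  set.seed(6)
  s <- rexp(400)
  p <- c(50, 75, 90, 95, 99)
  v <- vapply(p, function(x) criticalValue(nullOf(s), x), numeric(1))
  expect_true(all(diff(v) >= 0))
})

test_that("empirical p-values use the add-one permutation form", {
  set.seed(8)
  s <- rnorm(201)
  null <- nullOf(s)
  n <- length(s)
  expect_equal(empiricalP(max(s) + 1, null), 1 / (n + 1))
  expect_equal(empiricalP(min(s) - 1, null), 1)
  # at the median of an odd-sized null, about half the controls are >=
  expect_equal(empiricalP(stats::median(s), null), (1 + 101) / (n + 1))
  # exact tie counting (>= includes equals)
  null2 <- nullOf(c(1, 2, 2, 3, 110))
  expect_equal(empiricalP(2, null2), (1 + 4) / 6)
  # monotone non-increasing in the score
  q <- seq(min(s) - 1, max(s) + 1, length.out = 60)
  expect_true(all(diff(empiricalP(q, null)) <= 0))
})

test_that("carrier calls use strict exceedance and deterministic ranks", {
  expect_equal(nrow(callCarriers(setNames(numeric(0), character(0)), 1)), 0L)
  sc <- c(a = 0.5, b = 0.9, c = 1.0)
  expect_false(any(callCarriers(sc, 1.0)$call))   # equality is not a call
  calls <- callCarriers(sc, 0.7)
  expect_equal(calls$individual_id, c("c", "b", "a"))
  expect_equal(calls$call, c(TRUE, TRUE, FALSE))
  expect_equal(calls$rank, 1:3)
})

test_that("top-N ranking breaks ties by individual id and warns when N exceeds the cohort", {
  sc <- c(i1 = 5, i3 = 3, i2 = 3, i4 = 1)
  top <- topN(sc, 2)
  expect_equal(top$individual_id, c("i1", "i2"))
  expect_true(all(top$call))
  expect_warning(full <- topN(sc, 10), "everyone")
  expect_equal(nrow(full), 4L)
  expect_equal(full$individual_id, c("i1", "i2", "i3", "i4"))
})

test_that("null distributions round-trip through their text serialisation", {
  set.seed(10)
  null <- NullDistribution("VAR1", setNames(rnorm(120),
                                            sprintf("s%03d", 1:120)),
                           panelFingerprint = "chr1:10:1:99:5:50:12")
  path <- withr::local_tempfile()
  writeNullDistribution(null, path)
  back <- readNullDistribution(path)
  expect_equal(nullScores(back), nullScores(null), tolerance = 1e-9)
  expect_equal(variantId(back), "VAR1")
  expect_identical(back@panelFingerprint, null@panelFingerprint)
})

test_that("screening refuses a null computed on a different panel", {
  set.seed(12)
  panel <- makePanel(30)
  other <- makePanel(31)
  cohort <- makeCohort(panel, 4)
  haps <- list(makeDisease(panel))
  null <- suppressWarnings(
    NullDistribution("VAR", setNames(rnorm(50), sprintf("c%d", 1:50)),
                     panelFingerprint(other)))
  expect_error(screenCohort(haps, cohort, null, panel), "panel")
})

test_that("same-generator controls are called at about the nominal rate", {
  # scores drawn iid from the same process as the null: the 99th-percentile
  # threshold yields ~1% positives
  set.seed(14)
  null <- nullOf(rexp(1000))
  thr <- criticalValue(null, 99)
  draws <- rexp(20000)
  expect_lt(abs(mean(draws > thr) - 0.01), 0.005)
})
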