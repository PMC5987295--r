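# Evaluation metrics against hand and rank-statistic oracles, plus the two
# classification scenarios on synthetic cohorts.

test_that("Hamming distance counts differing positions", {
  expect_equal(hammingDistance(c(1, 0, 1), c(1, 0, 1)), 0)
  expect_equal(hammingDistance(c(1, 0, 1), c(0, 1, 0)), 1)
  # 10110010 vs 10011010 -> 2 of 8 positions differ
  a <- c(1, 0, 1, 1, 0, 0, 1, 0); b <- c(1, 0, 0, 1, 1, 0, 1, 0)
  expect_equal(hammingDistance(a, b), 0.25)
  expect_equal(hammingDistance(a, b, raw = TRUE), 2L)
  expect_error(hammingDistance(c(1, 0), c(1, 0, 1)), "length")
})

test_that("score sets have the combinatorially expected sizes", {
  mkcodes <- function(n) lapply(1:n, function(i) {
    set.seed(i); randomBits(16)
  })
  ss <- scoreCohort(mkcodes(4), c("a", "a", "b", "b"))
  expect_length(genuineScores(ss), 2L)
  expect_length(impostorScores(ss), 4L)
  ss3 <- scoreCohort(mkcodes(6), rep(c("a", "b", "c"), each = 2))
  expect_length(genuineScores(ss3), 3L)
  expect_length(impostorScores(ss3), 12L)
  expect_true(all(c(genuineScores(ss3), impostorScores(ss3)) >= 0 &
                  c(genuineScores(ss3), impostorScores(ss3)) <= 1))
  expect_error(scoreCohort(mkcodes(3), c("a", "b", "c")), "genuine")
})

mkScoreSet <- function(g, i, len = 100L) {
  new("ScoreSet", genuine = g, impostor = i,
      genuineBits = as.integer(round(g * len)),
      impostorBits = as.integer(round(i * len)), codeLength = len)
}

test_that("FAR/FRR curves follow the accept-iff-below-threshold convention", {
  ss <- mkScoreSet(c(0.1, 0.2), c(0.4, 0.6))
  cv <- farFrr(ss, thresholds = c(0, 0.05, 0.3, 1))
  expect_equal(cv$far, c(0, 0, 0, 1))
  expect_equal(cv$frr, c(1, 1, 0, 0))
  # monotone in the threshold, bounded
  cvAll <- farFrr(ss)
  expect_true(all(diff(cvAll$far) >= 0))
  expect_true(all(diff(cvAll$frr) <= 0))
  expect_true(all(cvAll$far >= 0 & cvAll$far <= 1))
  expect_error(farFrr(ss, thresholds = numeric(0)), "empty")
})

test_that("EER is 0 for separated scores, 0.5 for identical distributions,
           and matches hand enumeration on a crossing case", {
  expect_equal(eer(mkScoreSet(c(0.1, 0.2), c(0.4, 0.6)))$eer, 0)
  set.seed(101)
  v <- runif(1000)
  expect_lt(abs(eer(mkScoreSet(v, v))$eer - 0.5), 0.02)
  # interleaved case, enumerated by hand over the exact grid:
  # T = 0.2 minimizes |FAR - FRR| with FAR = FRR = 0.5
  res <- eer(mkScoreSet(c(0.1, 0.3), c(0.2, 0.4)))
  expect_equal(res$eer, 0.5)
  expect_equal(res$threshold, 0.2) # tie-break toward the smallest threshold
})

test_that("CCR is the fraction of correct decisions", {
  expect_equal(ccr(rep("a", 5), rep("a", 5)), 1)
  expect_equal(ccr(rep("a", 5), rep("b", 5)), 0)
  expect_equal(ccr(c(rep(1, 9), 0), rep(1, 10)), 0.9)
  expect_error(ccr(1, c(1, 2)), "mismatch")
})

test_that("AUC equals the normalized Mann-Whitney U statistic", {
  expect_equal(rocAuc(mkScoreSet(c(0.1, 0.2), c(0.6, 0.9))), 1)
  set.seed(102)
  v <- runif(500)
  expect_lt(abs(rocAuc(mkScoreSet(v, v)) - 0.5), 0.01)
  for (rep in 1:5) {
    g <- round(runif(50), 2); i <- round(runif(50), 2) # ties included
    u <- suppressWarnings(wilcox.test(i, g)$statistic) / (50 * 50)
    expect_equal(rocAuc(mkScoreSet(g, i)), unname(u), tolerance = 1e-12)
  }
})

test_that("identification recovers subjects on a separated cohort", {
  s1 <- scenario1(lowNoiseCodes(), subjectIds(lowNoiseCohort()))
  expect_gte(s1$meanCCR, 0.95)
  # confusion rows conserve each subject's probe count
  expect_true(all(rowSums(s1$confusion) == 2L))
  expect_equal(sum(diag(s1$confusion)) / sum(s1$confusion), s1$meanCCR)
})

test_that("indistinguishable classes fall to chance with deterministic ties", {
  code <- c(rep(0L, 8), rep(1L, 8))
  codes <- rep(list(code), 8)
  ids <- rep(c("s1", "s2", "s3", "s4"), each = 2)
  s1 <- scenario1(codes, ids)
  expect_equal(s1$meanCCR, 1 / 4) # ties resolve to the lowest subject index
  expect_warning(scenario1(c(codes, list(code)), c(ids, "s9")), "single")
})

test_that("identification accuracy degrades monotonically with session noise", {
  ccrs <- vapply(c(0.05, 0.3, 0.8), function(nz) {
    coh <- makeCohort(cohortConfig(10, 3, sessionNoise = nz, masterSeed = 77,
                                   nTimepoints = 600))
    scenario1(encodeCohort(coh), subjectIds(coh))$meanCCR
  }, numeric(1))
  expect_true(all(diff(ccrs) <= 0))
  expect_gte(ccrs[1], 0.95)
})

test_that("one-vs-rest verification balances classes and finds the target", {
  coh <- makeCohort(cohortConfig(12, 4, sessionNoise = 0.05, masterSeed = 33))
  codes <- encodeCohort(coh)
  s2 <- scenario2(codes, subjectIds(coh), target = "S03", seed = 5)
  expect_gte(s2$tpr, 0.95)
  expect_equal(sum(s2$confusion["target", ]), sum(s2$confusion["other", ]))
  expect_equal(sum(s2$confusion), 2L * sum(s2$confusion["other", ]))
  expect_error(scenario2(codes, subjectIds(coh), target = "nope"), "target")
})

test_that("McNemar with Yates correction matches the closed form", {
  expect_equal(mcnemarYates(5, 5)$statistic, 0.1) # (|0| - 1)^2 / 10
  expect_equal(mcnemarYates(0, 0)$statistic, 0)
  expect_equal(round(mcnemarYates(1, 2)$criticalValue95, 4), 3.8415)
  expect_false(mcnemarYates(5, 5)$significant)
  expect_true(mcnemarYates(30, 5)$significant)
  expect_error(mcnemarYates(-1, 2), "nonnegative")
})

test_that("Fisher-Z pooling back-transforms to the expected mean", {
  expect_equal(fisherZMean(c(0.7, 0.7, 0.7))$mean, 0.7, tolerance = 1e-12)
  v <- c(0.8, 0.9)
  expect_equal(fisherZMean(v)$mean, tanh(mean(atanh(v))), tolerance = 1e-12)
  # exact 1.0 is clipped, not an error
  out <- fisherZMean(c(1, 1))
  expect_lt(out$mean, 1)
  expect_gt(out$mean, 0.999)
  expect_error(fisherZMean(numeric(0)), "empty")
  expect_error(fisherZMean(c(0.5, 1.2)), "\\[0, 1\\]")
})

test_that("the error-tolerance crossing follows the histogram definition", {
  # genuine uniform on counts 0..10, impostor uniform on 8..20: the genuine
  # density (1/11) stays >= the impostor density (1/13) through count 10 and
  # first drops below it at 11
  ss <- new("ScoreSet", genuine = (0:10) / 20, impostor = (8:20) / 20,
            genuineBits = 0:10, impostorBits = 8:20, codeLength = 20L)
  expect_identical(errorToleranceBits(ss), 10L)
  # fully separated: crossing at or beyond the maximum genuine distance
  ss2 <- new("ScoreSet", genuine = c(0.1, 0.2), impostor = c(0.6, 0.7),
             genuineBits = c(2L, 4L), impostorBits = c(12L, 14L),
             codeLength = 20L)
  d <- errorToleranceBits(ss2)
  expect_gte(d, 4L)
  expect_true(d >= 0L && d <= 20L)
})

test_that("evaluation reports are written and parse back", {
  ss <- scoreCohort(lowNoiseCodes(), subjectIds(lowNoiseCohort()))
  dir <- withr::local_tempdir()
  writeEvalReport(ss, dir)
  curves <- read.csv(file.path(dir, "far_frr.csv"))
  expect_true(all(c("threshold", "far", "frr") %in% names(curves)))
  scal <- jsonlite::read_json(file.path(dir, "summary.json"))
  expect_true(scal$eer >= 0 && scal$eer <= 1)
  expect_true(scal$auc >= 0 && scal$auc <= 1)
})
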