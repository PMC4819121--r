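test_that("promoter generation is reproducible, 90 bp and well placed", {
  p1 <- generatePromoter(123, tataStrength = 0.9, tataCenter = -45)
  p2 <- generatePromoter(123, tataStrength = 0.9, tataCenter = -45)
  expect_identical(promoterSeq(p1), promoterSeq(p2))
  expect_identical(promoterLength(p1), 90L)
  expect_identical(alleleLabel(p1), "ancestral")
  p3 <- generatePromoter(124, tataStrength = 0.9, tataCenter = -45)
  expect_false(identical(promoterSeq(p1), promoterSeq(p3)))
  expect_error(generatePromoter(1, tataCenter = -10), "\\[-70, -20\\]")
  expect_error(
    generatePromoter(1, baseComposition = c(a = 0.5, c = 0.5, g = 0.5,
                                            t = 0.5)),
    "sum to 1"
  )
})

test_that("embedded sites reach the requested strength percentile", {
  pwm <- loadTataPwm()
  w <- pwmWeights(pwm)
  set.seed(37)
  # Monte-Carlo oracle: score of 1e4 random uniform 15-mers
  null_scores <- vapply(1:10000, function(k) {
    idx <- sample.int(4L, 15L, replace = TRUE)
    sum(w[cbind(idx, 1:15)])
  }, 0)
  for (strength in c(0.5, 0.9)) {
    hits <- 0L
    for (k in 1:10) {
      p <- generatePromoter(5000L + k, tataStrength = strength,
                            tataCenter = -45)
      site_score <- attr(p, "siteScore")
      if (site_score >= quantile(null_scores, strength)) hits <- hits + 1L
    }
    # PWM-model draws at a percentile sit far above the same percentile of
    # uniform random 15-mers
    expect_gte(hits, 9L)
  }
})

test_that("injected variants have internally consistent ground truth", {
  coeffs <- loadModelCoefficients()
  pwm <- loadTataPwm()
  p <- generatePromoter(61, tataStrength = 1, tataCenter = -45)
  inj <- injectVariant(p, "substitution", "in_tata", seed = 62)
  # trueEffect is exactly the rescoring delta
  expect_equal(
    inj$trueEffect,
    affinityMean(estimateAffinity(inj$seqMut, coeffs, pwm)) -
      affinityMean(estimateAffinity(p, coeffs, pwm)),
    tolerance = 1e-12
  )
  # deterministic under a fixed seed
  inj2 <- injectVariant(p, "substitution", "in_tata", seed = 62)
  expect_identical(rsId(inj$variant), rsId(inj2$variant))
  expect_identical(inj$trueEffect, inj2$trueEffect)
  # outside-region variants are exactly null, for every mutation class
  for (kind in c("substitution", "deletion", "insertion")) {
    injn <- injectVariant(p, kind, "outside_region", seed = 63)
    expect_identical(injn$trueEffect, 0)
  }
})

test_that("breaking a consensus core base lowers the affinity estimate", {
  coeffs <- loadModelCoefficients()
  pwm <- loadTataPwm()
  p <- generatePromoter(71, tataStrength = 1, tataCenter = -45)
  est0 <- affinityMean(estimateAffinity(p, coeffs, pwm))
  s <- promoterSeq(p)
  # corrupt the highest-information core position of the embedded site
  start0 <- (-45 + 90) - 7
  j <- which.max(apply(pwmWeights(pwm), 2, max) -
                   apply(pwmWeights(pwm), 2, min))
  i0 <- start0 + j - 1
  worst <- names(which.min(pwmWeights(pwm)[, j]))
  s2 <- paste0(substr(s, 1, i0), worst, substring(s, i0 + 2))
  if (substr(s, i0 + 1, i0 + 1) != worst) {
    est1 <- affinityMean(estimateAffinity(PromoterSequence("B", s2),
                                          coeffs, pwm))
    expect_lt(est1, est0)
  }
})

test_that("pseudo-EMSA noise has the requested spread and reproducibility", {
  pred <- rep(19, 10000)
  meas <- simulateMeasurements(pred, noiseSd = 0.5, seed = 99)
  resid_sd <- sd(meas - pred)
  n <- length(pred)
  expect_lt(abs(resid_sd - 0.5), 3 * 0.5 / sqrt(2 * n))
  expect_identical(meas, simulateMeasurements(pred, 0.5, seed = 99))
  # zero noise reproduces the predictions and saturates every coefficient
  pred2 <- seq(16, 21, length.out = 12)
  meas2 <- simulateMeasurements(pred2, 0, seed = 1)
  expect_identical(meas2, pred2)
  st <- concordanceStats(pred2, meas2)
  expect_equal(st$r, 1, tolerance = 1e-12)
  expect_equal(st$spearman_R, 1, tolerance = 1e-12)
  expect_equal(st$kendall_tau, 1, tolerance = 1e-12)
  expect_equal(st$gamma, 1, tolerance = 1e-12)
})

test_that("cohorts are reproducible and respect their effect classes", {
  coh <- generateCohort(7, n = 9)
  tt <- cohortTruth(coh)
  expect_identical(nrow(tt), 9L)
  expect_identical(tt, cohortTruth(generateCohort(7, n = 9)))
  expect_true(all(tt$true_effect[tt$class == "strong_up"] >= 1))
  expect_true(all(tt$true_effect[tt$class == "strong_down"] <= -1))
  expect_true(all(tt$true_effect[tt$class == "null"] == 0))
  # every variant anchors uniquely in its promoter
  for (e in coh$entries) {
    expect_silent(anchorVariant(e$seq, e$variant))
  }
})

test_that("cohort files round-trip through the standard formats", {
  coh <- generateCohort(8, n = 6)
  dir <- withr::local_tempdir()
  paths <- writeCohort(coh, dir)
  ps <- readPromoters(file.path(dir, "promoters.fa"))
  expect_length(ps, 6L)
  vs <- readVariantsTsv(file.path(dir, "variants.tsv"))
  expect_length(vs, 6L)
  for (i in seq_along(vs)) {
    expect_identical(rsId(vs[[i]]), rsId(coh$entries[[i]]$variant))
    expect_silent(anchorVariant(ps[[i]], vs[[i]]))
  }
  truth <- utils::read.delim(file.path(dir, "truth.tsv"),
                             comment.char = "#")
  expect_identical(nrow(truth), 6L)
  # the master seed is recorded in the outputs
  expect_match(readLines(file.path(dir, "variants.tsv"), n = 1), "seed=8")
})
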