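coeffs <- loadModelCoefficients()
pwm <- loadTataPwm()
slideVals <- scaleValues(loadDinucScale("slide"))
bendVals <- scaleValues(loadDinucScale("bend"))

.combinedWindow <- function(win, coeffs, pwm) {
  coeffs@intercept +
    coeffs@weightSlide * slideScore(win) +
    coeffs@weightPwm * pwmScore(pwm, win)$score +
    coeffs@weightBend * bendScore(win)
}

test_that("packaged coefficients load with calibrated provenance", {
  expect_s4_class(coeffs, "ModelCoefficients")
  expect_identical(coeffs@windowLength, 26L)
  expect_identical(coeffs@scanRegion, c(-70, -20))
  expect_identical(coeffs@provenance, "calibrated")
  expect_identical(coeffs@sdModel$method, "jackknife")
  expect_gt(coeffs@weightPwm, 0)
})

test_that("window-max estimate matches brute-force enumeration", {
  set.seed(101)
  for (k in 1:60) {
    s <- if (k %% 2 == 0) {
      promoterSeq(generatePromoter(1000L + k,
                                   tataStrength = runif(1),
                                   tataCenter = sample(-65:-25, 1)))
    } else {
      random_dna(90L)
    }
    want <- oracle_affinity(s, coeffs, pwm, slideVals, bendVals)
    got <- estimateAffinity(s, coeffs, pwm)
    expect_equal(affinityMean(got), want$mean, tolerance = 1e-9)
    # the reported window achieves the enumerated maximum (ties may pick a
    # different representative window of identical score)
    got_score <- oracle_window_score(s, bestWindowStart(got) + nchar(s),
                                     coeffs, pwm, slideVals, bendVals)
    expect_equal(got_score, want$mean, tolerance = 1e-9)
  }
})

test_that("the reported components reproduce the reported mean", {
  p <- generatePromoter(77, tataStrength = 0.8, tataCenter = -45)
  est <- estimateAffinity(p, coeffs, pwm)
  comp <- affinityComponents(est)
  expect_equal(
    affinityMean(est),
    coeffs@intercept + coeffs@weightSlide * comp[["slide"]] +
      coeffs@weightPwm * comp[["pwm"]] + coeffs@weightBend * comp[["bend"]],
    tolerance = 1e-12
  )
  expect_gte(affinitySd(est), 0)
})

test_that("edits outside every admissible window leave the estimate unchanged", {
  p <- generatePromoter(55, tataStrength = 1, tataCenter = -45)
  est0 <- affinityMean(estimateAffinity(p, coeffs, pwm))
  s <- promoterSeq(p)
  # position -1 (the base adjacent to the TSS) lies outside every window
  # whose best-site midpoint can fall in [-70, -20]
  for (b in setdiff(BASES, substr(s, 90, 90))) {
    edited <- PromoterSequence("E", paste0(substr(s, 1, 89), b))
    expect_identical(affinityMean(estimateAffinity(edited, coeffs, pwm)),
                     est0)
  }
  # appending upstream sequence beyond -90 cannot change the estimate either
  set.seed(3)
  extended <- PromoterSequence("X", paste0(random_dna(10L), s),
                               alleleLabel = "minor")
  expect_equal(affinityMean(estimateAffinity(extended, coeffs, pwm)),
               est0, tolerance = 1e-9)
})

test_that("degenerate sequences raise explicit errors", {
  expect_error(estimateAffinity(strrep("a", 20), coeffs, pwm),
               "shorter than")
  # in a 26-bp sequence the single window's site midpoint sits 3' of -20
  expect_error(estimateAffinity(strrep("a", 26), coeffs, pwm),
               "no admissible window")
})

test_that("affinity converts to nM with half-away-from-zero rounding", {
  expect_equal(affinityToKdNM(20.15)$rounded, 2L)
  expect_equal(affinityToKdNM(19.21)$rounded, 5L)
  expect_equal(affinityToKdNM(0)$rounded, 1000000000L)
  # half-away-from-zero, not banker's rounding
  expect_identical(affinityToKdNM(kdNMToAffinity(4.5))$rounded, 5L)
  expect_identical(affinityToKdNM(kdNMToAffinity(1.8))$rounded, 2L)
  set.seed(21)
  kd <- runif(50, 0.5, 100)
  expect_equal(affinityToKdNM(kdNMToAffinity(kd))$nM, kd, tolerance = 1e-12)
})

test_that("re-running the documented calibration reproduces the packaged file", {
  recal <- calibrateCoefficients()
  expect_equal(recal@intercept, coeffs@intercept, tolerance = 1e-8)
  expect_equal(recal@weightSlide, coeffs@weightSlide, tolerance = 1e-8)
  expect_equal(recal@weightPwm, coeffs@weightPwm, tolerance = 1e-8)
  expect_equal(recal@weightBend, coeffs@weightBend, tolerance = 1e-8)
  expect_equal(recal@sdModel$scale, coeffs@sdModel$scale, tolerance = 1e-8)
})

test_that("consensus substitution at the best site does not lower the PWM term", {
  set.seed(31)
  for (k in 1:10) {
    p <- generatePromoter(2000L + k, tataStrength = runif(1),
                          tataCenter = sample(-60:-30, 1))
    est <- estimateAffinity(p, coeffs, pwm)
    s <- promoterSeq(p)
    i0 <- bestWindowStart(est) + 90L
    off <- pwmScore(pwm, substr(s, i0 + 1, i0 + 26))$offset
    s2 <- paste0(substr(s, 1, i0 + off), pwmConsensus(pwm),
                 substring(s, i0 + off + 16))
    est2 <- estimateAffinity(PromoterSequence("C", s2), coeffs, pwm)
    win2 <- substr(s2, i0 + 1, i0 + 26)
    expect_gte(pwmScore(pwm, win2)$score,
               affinityComponents(est)[["pwm"]] - 1e-9)
    # and the full model never scores the strengthened promoter below the
    # modified window itself (when that window remains admissible)
    off2 <- pwmScore(pwm, win2)$offset
    mid2 <- i0 + off2 + 7 - 90L
    if (mid2 >= -70 && mid2 <= -20) {
      expect_gte(affinityMean(est2) + 1e-9,
                 .combinedWindow(win2, coeffs, pwm))
    }
  }
})
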