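#' Load the packaged model coefficients
#'
#' The linear coefficients of the three-mechanism affinity model are data,
#' not code: they are read from a YAML file whose \code{provenance} field
#' records how they were obtained. The packaged default is the documented
#' "calibrated" mode: a least-squares fit of the four linear coefficients to
#' the -ln KD values of the packaged marker table, on flank-context
#' sequences padded to the window length (see
#' \code{\link{calibrateCoefficients}}).
#'
#' @param file YAML path; default is the packaged configuration.
#' @return a \linkS4class{ModelCoefficients}.
#' @export
loadModelCoefficients <- function(file = system.file(
                                    "extdata", "model_coefficients.yaml",
                                    package = "TBPscan"
                                  )) {
  key <- paste0("coeffs:", file)
  if (!is.null(.tbpscanCache[[key]])) return(.tbpscanCache[[key]])
  y <- yaml::read_yaml(file)
  for (f in c("intercept", "weight_slide", "weight_pwm", "weight_bend",
              "sd_model", "window_length", "provenance")) {
    if (is.null(y[[f]])) stop("model coefficient file lacks field '", f, "'")
  }
  out <- new("ModelCoefficients",
    intercept = as.numeric(y$intercept),
    weightSlide = as.numeric(y$weight_slide),
    weightPwm = as.numeric(y$weight_pwm),
    weightBend = as.numeric(y$weight_bend),
    sdModel = list(
      method = y$sd_model$method,
      scale = as.numeric(y$sd_model$scale)
    ),
    windowLength = as.integer(y$window_length),
    scanRegion = as.numeric(unlist(y$scan_region)),
    provenance = as.character(y$provenance)
  )
  .tbpscanCache[[key]] <- out
  out
}

# term vector (slide, pwm, bend) and pwm placement offset for one window
.windowTerms <- function(window, pwm, slideScale, bendScale) {
  ps <- pwmScore(pwm, window)
  c(
    slide = slideScore(window, slideScale),
    pwm = ps$score,
    bend = bendScore(window, bendScale),
    offset = ps$offset
  )
}

.combined <- function(terms, coeffs) {
  coeffs@intercept +
    coeffs@weightSlide * terms[["slide"]] +
    coeffs@weightPwm * terms[["pwm"]] +
    coeffs@weightBend * terms[["bend"]]
}

# 4x4 lookup matrix for a dinucleotide scale (rows = first base code)
.scaleMatrix <- function(scale) {
  m <- matrix(0, 4, 4, dimnames = list(DNA_ALPHABET, DNA_ALPHABET))
  for (d in names(scale@values)) {
    m[substr(d, 1, 1), substr(d, 2, 2)] <- scale@values[[d]]
  }
  m
}

# all windows of a sequence with terms, combined score and admissibility;
# vectorised: per-site PWM scores and dinucleotide step sums are computed
# once for the whole sequence, windows then read them out
.scanWindows <- function(s, coeffs, pwm, slideScale, bendScale) {
  L <- nchar(s)
  W <- coeffs@windowLength
  if (L < W) {
    stop(sprintf(
      "no admissible window: sequence of %d bp is shorter than the %d-bp window",
      L, W
    ))
  }
  codes <- .dnaToInt(s)
  wts <- pwm@weights
  pw <- ncol(wts)
  nSite <- L - pw + 1L
  siteScores <- numeric(nSite)
  for (j in seq_len(pw)) {
    siteScores <- siteScores + wts[cbind(codes[j:(j + nSite - 1L)], j)]
  }
  stepSlide <- .scaleMatrix(slideScale)[cbind(codes[-L], codes[-1L])]
  stepBend <- .scaleMatrix(bendScale)[cbind(codes[-L], codes[-1L])]
  cumSlide <- c(0, cumsum(stepSlide))
  cumBend <- c(0, cumsum(stepBend))
  starts0 <- 0:(L - W)
  nPlace <- W - pw + 1L
  bestOff <- integer(length(starts0))
  bestPwm <- numeric(length(starts0))
  for (k in seq_along(starts0)) {
    p0 <- starts0[k] + 1L
    sub <- siteScores[p0:(p0 + nPlace - 1L)]
    bestOff[k] <- which.max(sub) - 1L
    bestPwm[k] <- sub[bestOff[k] + 1L]
  }
  slideMean <- (cumSlide[starts0 + W] - cumSlide[starts0 + 1L]) / (W - 1L)
  bendMean <- (cumBend[starts0 + W] - cumBend[starts0 + 1L]) / (W - 1L)
  combined <- coeffs@intercept + coeffs@weightSlide * slideMean +
    coeffs@weightPwm * bestPwm + coeffs@weightBend * bendMean
  terms <- lapply(seq_along(starts0), function(k) {
    c(slide = slideMean[k], pwm = bestPwm[k], bend = bendMean[k],
      offset = bestOff[k])
  })
  if (length(coeffs@scanRegion) == 2L) {
    mid <- .indexToPosition(starts0 + bestOff + 7, L)
    admissible <- mid >= coeffs@scanRegion[1] & mid <= coeffs@scanRegion[2]
  } else {
    admissible <- rep(TRUE, length(starts0))
  }
  list(starts0 = starts0, terms = terms, combined = combined,
       admissible = admissible)
}

# delete-one-base jackknife sd of the best-window combined score
.jackknifeSd <- function(window, coeffs, pwm, slideScale, bendScale) {
  W <- nchar(window)
  scores <- vapply(seq_len(W), function(j) {
    wj <- paste0(substr(window, 1L, j - 1L), substr(window, j + 1L, W))
    .combined(.windowTerms(wj, pwm, slideScale, bendScale), coeffs)
  }, 0)
  sqrt((W - 1) / W * sum((scores - mean(scores))^2))
}

#' Estimate TBP binding affinity (-ln KD) of a promoter allele
#'
#' The estimate is the maximum over all admissible binding windows of the
#' linear combination intercept + w_slide * slide + w_pwm * pwm +
#' w_bend * bend, where slide and bend are mean dinucleotide property scores
#' of the window and pwm is the best 15-mer weight-matrix score within it.
#' A window is admissible when it lies fully inside the sequence and the
#' midpoint of its best 15-mer placement falls in the scan region
#' (default [-70, -20] TSS-relative); the leftmost window wins ties. The
#' uncertainty follows the configured sd model (delete-one-base jackknife of
#' the best window, scaled by a packaged calibration constant).
#'
#' @param seq a \linkS4class{PromoterSequence} (or plain DNA string, scored
#'   with the same rule).
#' @param coeffs a \linkS4class{ModelCoefficients}; default packaged.
#' @param pwm a \linkS4class{TataPwm}; default packaged.
#' @param ... unused.
#' @return an \linkS4class{AffinityEstimate}.
#' @export
setGeneric("estimateAffinity", function(seq,
                                        coeffs = loadModelCoefficients(),
                                        pwm = loadTataPwm(), ...) {
  standardGeneric("estimateAffinity")
})

.estimateAffinityChar <- function(s, coeffs, pwm) {
  slideScale <- loadDinucScale("slide")
  bendScale <- loadDinucScale("bend")
  scan <- .scanWindows(s, coeffs, pwm, slideScale, bendScale)
  if (!any(scan$admissible)) {
    stop("no admissible window: no best-site midpoint falls in the scan region")
  }
  idx <- which(scan$admissible)
  best <- idx[which.max(scan$combined[idx])]
  W <- coeffs@windowLength
  win <- substr(s, scan$starts0[best] + 1L, scan$starts0[best] + W)
  sd_raw <- .jackknifeSd(win, coeffs, pwm, slideScale, bendScale)
  scale <- coeffs@sdModel$scale
  if (is.null(scale) || !is.finite(scale)) scale <- 1
  new("AffinityEstimate",
    mean = scan$combined[best],
    sd = scale * sd_raw,
    bestWindowStart = .indexToPosition(scan$starts0[best], nchar(s)),
    components = scan$terms[[best]][c("slide", "pwm", "bend")]
  )
}

#' @rdname estimateAffinity
#' @export
setMethod("estimateAffinity", "PromoterSequence",
  function(seq, coeffs, pwm, ...) {
    .estimateAffinityChar(promoterSeq(seq), coeffs, pwm)
  }
)

#' @rdname estimateAffinity
#' @export
setMethod("estimateAffinity", "character",
  function(seq, coeffs, pwm, ...) {
    .estimateAffinityChar(tolower(seq), coeffs, pwm)
  }
)

#' Convert a -ln KD estimate to a dissociation constant in nM
#'
#' KD[nM] = 1e9 * exp(-A) for A in natural-log units of molar KD. The
#' integer view rounds half away from zero, matching how the marker tables
#' print integer nanomolar values (4.5 -> 5, 1.8 -> 2).
#'
#' @param mean affinity estimate(s) in ln-units (vectorised).
#' @return list(nM, rounded): exact value(s) and integer view(s).
#' @examples
#' affinityToKdNM(20.15)$rounded  # 2
#' affinityToKdNM(19.21)$rounded  # 5
#' @export
affinityToKdNM <- function(mean) {
  stopifnot(all(is.finite(mean)))
  kd <- 1e9 * exp(-mean)
  list(nM = kd, rounded = as.integer(sign(kd) * floor(abs(kd) + 0.5)))
}

#' Convert a KD in nM to ln-units of affinity
#'
#' Inverse of \code{\link{affinityToKdNM}}: -ln(KD[nM] * 1e-9).
#' @param kd_nM dissociation constant(s) in nM.
#' @return affinity in natural-log units of molar KD.
#' @export
kdNMToAffinity <- function(kd_nM) {
  stopifnot(all(kd_nM > 0))
  log(1e9 / kd_nM)
}

# flank-context sequence padded (centred, with padBase) to the window length
.contextSeq <- function(flank5, allele, flank3, windowLength, padBase = "c") {
  s <- paste0(flank5, allele, flank3)
  short <- windowLength - nchar(s)
  if (short > 0L) {
    left <- short %/% 2L
    s <- paste0(
      strrep(padBase, left), s, strrep(padBase, short - left)
    )
  }
  s
}

#' Calibrate the linear model coefficients against the marker table
#'
#' Fits (intercept, w_slide, w_pwm, w_bend) by iterated least squares to the
#' -ln KD values of the packaged marker table. Each table row contributes
#' two points (ancestral and first-alternate allele) whose sequences are the
#' printed flank context padded centrally to the window length. Window
#' features are extracted at the current best window and the fit is repeated
#' until the coefficients stabilise. The jackknife sd scale is then set so
#' that the IL1B worked-example contexts give ~0.095 ln-units. The result is
#' labelled \code{provenance = "calibrated"}; it is never presented as a
#' transcription of the original model.
#'
#' @param records marker table as returned by \code{\link{loadMarkerFixture}}.
#' @param pwm a \linkS4class{TataPwm}.
#' @param windowLength binding window, default 26.
#' @param padBase base used to pad short contexts, default "c" (the weakest
#'   TATA-core base, so padding never creates a spurious site).
#' @param maxIter,tol iteration control for the refit loop.
#' @return a \linkS4class{ModelCoefficients} with provenance "calibrated".
#' @export
calibrateCoefficients <- function(records = loadMarkerFixture(),
                                  pwm = loadTataPwm(),
                                  windowLength = 26L, padBase = "c",
                                  maxIter = 25L, tol = 1e-10) {
  slideScale <- loadDinucScale("slide")
  bendScale <- loadDinucScale("bend")
  contexts <- character(0)
  y <- numeric(0)
  firstAlt <- function(r) {
    alts <- trimws(strsplit(r$alts, ",", fixed = TRUE)[[1]])
    alts[alts == "-"] <- ""
    alts[1]
  }
  for (i in seq_len(nrow(records))) {
    r <- records[i, ]
    contexts <- c(
      contexts,
      .contextSeq(r$flank5, r$ref, r$flank3, windowLength, padBase),
      .contextSeq(r$flank5, firstAlt(r), r$flank3, windowLength, padBase)
    )
    y <- c(y, kdNMToAffinity(r$kd_wt_nM), kdNMToAffinity(r$kd_mut_nM))
  }
  coeffs <- new("ModelCoefficients",
    intercept = 0, weightSlide = 0, weightPwm = 1, weightBend = 0,
    sdModel = list(method = "jackknife", scale = 1),
    windowLength = as.integer(windowLength), scanRegion = numeric(0),
    provenance = "calibrating"
  )
  beta_old <- rep(Inf, 4)
  fit <- NULL
  for (it in seq_len(maxIter)) {
    feats <- t(vapply(contexts, function(s) {
      scan <- .scanWindows(s, coeffs, pwm, slideScale, bendScale)
      best <- which.max(scan$combined)
      scan$terms[[best]][c("slide", "pwm", "bend")]
    }, c(slide = 0, pwm = 0, bend = 0)))
    df <- data.frame(y = y, feats)
    fit <- lm(y ~ slide + pwm + bend, data = df)
    beta <- coef(fit)
    coeffs@intercept <- unname(beta[1])
    coeffs@weightSlide <- unname(beta["slide"])
    coeffs@weightPwm <- unname(beta["pwm"])
    coeffs@weightBend <- unname(beta["bend"])
    if (max(abs(beta - beta_old)) < tol) break
    beta_old <- beta
  }
  # sd calibration on the IL1B worked-example contexts
  il1b <- records[records$rs_id == "rs1143627", ]
  sds <- vapply(c(il1b$ref, firstAlt(il1b)), function(al) {
    s <- .contextSeq(il1b$flank5, al, il1b$flank3, windowLength, padBase)
    scan <- .scanWindows(s, coeffs, pwm, slideScale, bendScale)
    best <- which.max(scan$combined)
    W <- coeffs@windowLength
    win <- substr(s, scan$starts0[best] + 1L, scan$starts0[best] + W)
    .jackknifeSd(win, coeffs, pwm, slideScale, bendScale)
  }, 0)
  coeffs@sdModel <- list(method = "jackknife",
                         scale = 0.095 / mean(sds))
  coeffs@scanRegion <- c(-70, -20)
  coeffs@provenance <- "calibrated"
  coeffs
}
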