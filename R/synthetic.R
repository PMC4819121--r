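#' Generate a synthetic 90-bp promoter with an embedded TATA box
#'
#' Background bases are drawn i.i.d. from \code{baseComposition}; a 15-mer
#' sampled from the PWM probability model at the requested strength
#' percentile is embedded with its midpoint at \code{tataCenter} (which must
#' lie in the [-70, -20] TBP-binding region). Fully reproducible from the
#' seed.
#'
#' @param seed integer seed.
#' @param baseComposition named probabilities for a,c,g,t (must sum to 1).
#' @param tataStrength percentile in [0,1] of PWM-model site scores for the
#'   embedded site (1 = consensus-like).
#' @param tataCenter TSS-relative midpoint of the embedded site.
#' @param gene gene symbol for the record.
#' @param pwm a \linkS4class{TataPwm}.
#' @return an ancestral \linkS4class{PromoterSequence} with attributes
#'   "tataCenter" and "siteScore".
#' @export
generatePromoter <- function(seed,
                             baseComposition = c(a = 0.25, c = 0.25,
                                                 g = 0.25, t = 0.25),
                             tataStrength = 0.9,
                             tataCenter = -45L,
                             gene = sprintf("SYN%06d", seed %% 1000000L),
                             pwm = loadTataPwm()) {
  if (abs(sum(baseComposition) - 1) > 1e-8 || any(baseComposition < 0)) {
    stop("baseComposition must be non-negative and sum to 1")
  }
  if (!setequal(names(baseComposition), DNA_ALPHABET)) {
    stop("baseComposition must be named over a, c, g, t")
  }
  if (tataCenter < -70 || tataCenter > -20) {
    stop("tataCenter must lie in the [-70, -20] TBP-binding region")
  }
  stopifnot(tataStrength >= 0, tataStrength <= 1)
  set.seed(seed)
  bg <- sample(DNA_ALPHABET, 90L, replace = TRUE,
               prob = baseComposition[DNA_ALPHABET])
  site <- .samplePwmSite(pwm, tataStrength)
  mid0 <- .positionToIndex(tataCenter, 90L)  # 0-based midpoint index
  start0 <- mid0 - 7L
  s <- bg
  s[(start0 + 1L):(start0 + 15L)] <- strsplit(site, "")[[1]]
  p <- PromoterSequence(gene, paste(s, collapse = ""),
                        alleleLabel = "ancestral", source = "synthetic")
  attr(p, "tataCenter") <- tataCenter
  attr(p, "siteScore") <- sum(pwm@weights[cbind(.dnaToInt(site), 1:15)])
  p
}

# draw one 15-mer at the given percentile of PWM-model site scores:
# sample a pool from the per-position base probabilities implied by the
# weights, score the pool, return the member closest to the target quantile
.samplePwmSite <- function(pwm, strength, pool = 400L) {
  probs <- exp(pwm@weights)          # proportional to base frequencies
  probs <- sweep(probs, 2, colSums(probs), "/")
  w <- ncol(pwm@weights)
  baseMat <- vapply(seq_len(w), function(j) {
    sample.int(4L, pool, replace = TRUE, prob = probs[, j])
  }, integer(pool))                  # pool x w base codes
  scores <- numeric(pool)
  for (j in seq_len(w)) {
    scores <- scores + pwm@weights[cbind(baseMat[, j], j)]
  }
  target <- stats::quantile(scores, strength, names = FALSE)
  pick <- which.min(abs(scores - target))
  paste(DNA_ALPHABET[baseMat[pick, ]], collapse = "")
}

# build a flank-anchored substitution/indel at 0-based index i0 of seq;
# returns NULL if it cannot anchor uniquely
.makeVariantAt <- function(seq, i0, kind, alt = NULL, id = "syn",
                           reflen = NULL) {
  s <- promoterSeq(seq)
  L <- promoterLength(seq)
  if (is.null(reflen)) reflen <- if (kind == "insertion") 0L else 1L
  if (i0 - 10L < 0L || i0 + reflen + 10L > L) return(NULL)
  flank5 <- substr(s, i0 - 9L, i0)
  flank3 <- substr(s, i0 + reflen + 1L, i0 + reflen + 10L)
  ref <- if (reflen) substr(s, i0 + 1L, i0 + reflen) else ""
  alt <- switch(kind,
    substitution = if (is.null(alt)) {
      sample(setdiff(DNA_ALPHABET, ref), 1L)
    } else {
      alt
    },
    deletion = "",
    insertion = if (is.null(alt)) sample(DNA_ALPHABET, 1L) else alt
  )
  if (identical(alt, ref)) return(NULL)
  v <- VariantSpec(id, flank5, ref, alt, flank3)
  ok <- tryCatch(anchorVariant(seq, v), error = function(e) NULL)
  if (is.null(ok)) NULL else v
}

#' Inject a variant into a synthetic promoter
#'
#' Places a substitution, deletion or insertion either inside the embedded
#' TATA site ("in_tata") or strictly outside every potentially admissible
#' binding window ("outside_region"). The ground-truth effect is computed by
#' direct rescoring of both alleles with the same model that analyses them
#' (trueEffect = mean_mut - mean_wt), so truth and analysis are internally
#' consistent; outside-region variants are verified to have exactly zero
#' effect.
#'
#' @param seq an ancestral synthetic \linkS4class{PromoterSequence} from
#'   \code{\link{generatePromoter}}.
#' @param kind "substitution", "deletion" or "insertion".
#' @param target "in_tata" or "outside_region".
#' @param seed integer seed.
#' @param coeffs,pwm model data.
#' @param maxTries resampling cap before giving up.
#' @return list(variant = \linkS4class{VariantSpec}, trueEffect, seqMut).
#' @export
injectVariant <- function(seq, kind = c("substitution", "deletion",
                                        "insertion"),
                          target = c("in_tata", "outside_region"),
                          seed = 1L,
                          coeffs = loadModelCoefficients(),
                          pwm = loadTataPwm(),
                          maxTries = 200L) {
  kind <- match.arg(kind)
  target <- match.arg(target)
  set.seed(seed)
  L <- promoterLength(seq)
  estWt <- estimateAffinity(seq, coeffs, pwm)
  if (target == "in_tata") {
    center <- attr(seq, "tataCenter")
    if (is.null(center)) {
      stop("no admissible position: promoter has no recorded TATA placement")
    }
    mid0 <- .positionToIndex(center, L)
    cand0 <- (mid0 - 7L):(mid0 + 7L)
  } else {
    # any flankable interior position away from the embedded site; the
    # candidate only counts once direct rescoring confirms a zero effect
    center <- attr(seq, "tataCenter")
    excl <- if (is.null(center)) {
      integer(0)
    } else {
      m0 <- .positionToIndex(center, L)
      (m0 - 9L):(m0 + 9L)
    }
    cand0 <- setdiff(10:(L - 12L), excl)
  }
  cand0 <- cand0[cand0 - 10L >= 0L & cand0 + 11L <= L]
  if (length(cand0) == 0L) {
    stop("no admissible position for the requested variant")
  }
  for (try in seq_len(maxTries)) {
    i0 <- if (length(cand0) == 1L) cand0 else sample(cand0, 1L)
    v <- .makeVariantAt(seq, i0, kind,
                        id = sprintf("syn:%s:%d", kind, try))
    if (is.null(v)) next
    seqMut <- applyVariant(seq, v)
    if (promoterLength(seqMut) < coeffs@windowLength) next
    estMut <- tryCatch(estimateAffinity(seqMut, coeffs, pwm),
                       error = function(e) NULL)
    if (is.null(estMut)) next
    delta <- estMut@mean - estWt@mean
    if (target == "outside_region" && delta != 0) next
    return(list(variant = v, trueEffect = delta, seqMut = seqMut))
  }
  stop("no admissible position for the requested variant")
}

#' Simulate noisy pseudo-EMSA affinity measurements
#'
#' measured = predicted + i.i.d. Gaussian(0, noiseSd^2), emulating the
#' scatter of in-vitro affinity measurements around model predictions.
#'
#' @param predicted numeric vector of -ln KD predictions.
#' @param noiseSd measurement noise sd in ln-units, >= 0.
#' @param seed integer seed.
#' @return numeric vector of the same length.
#' @export
simulateMeasurements <- function(predicted, noiseSd, seed = 1L) {
  stopifnot(noiseSd >= 0)
  set.seed(seed)
  predicted + rnorm(length(predicted), 0, noiseSd)
}

# embed the consensus site corrupted at one high-information position;
# returns list(seq, corrupt0 = 0-based index of the corrupted base,
# consensusBase) so a "repair" substitution can be constructed
.promoterWithCorruptedSite <- function(seed, tataCenter, pwm,
                                       corruptPos = NULL) {
  set.seed(seed + 7L)
  p <- generatePromoter(seed, tataStrength = 1, tataCenter = tataCenter,
                        pwm = pwm)
  cons <- pwmConsensus(pwm)
  L <- promoterLength(p)
  mid0 <- .positionToIndex(tataCenter, L)
  start0 <- mid0 - 7L
  s <- promoterSeq(p)
  # force the exact consensus, then corrupt one core position (3..8)
  s <- paste0(substr(s, 1L, start0), cons, substr(s, start0 + 16L, L))
  j <- if (is.null(corruptPos)) sample(3:8, 1L) else corruptPos
  consBase <- substr(cons, j, j)
  worst <- DNA_ALPHABET[which.min(pwm@weights[, j])]
  if (worst == consBase) worst <- DNA_ALPHABET[order(pwm@weights[, j])][2]
  s <- paste0(substr(s, 1L, start0 + j - 1L), worst,
              substr(s, start0 + j + 1L, L))
  p2 <- PromoterSequence(geneSymbol(p), s, "ancestral", "synthetic")
  attr(p2, "tataCenter") <- tataCenter
  list(seq = p2, corrupt0 = start0 + j - 1L, consensusBase = consBase)
}

#' Generate a synthetic cohort of promoters, variants and ground truth
#'
#' Builds \code{n} (promoter, variant) pairs of the requested effect
#' classes. "strong_down" corrupts a strong embedded site (substitution or
#' deletion inside the 15-mer), "strong_up" repairs a site carrying a single
#' core mismatch, and "null" places a variant verified to leave the affinity
#' estimate exactly unchanged. Strong classes are rejection-sampled until
#' |trueEffect| >= \code{minStrongEffect}; all randomness derives from
#' \code{seed}.
#'
#' @param seed integer master seed.
#' @param n number of variants.
#' @param classes vector of class labels to cycle through, drawn from
#'   \{"strong_up", "strong_down", "null"\}.
#' @param minStrongEffect ln-unit threshold for the strong classes,
#'   default 1.
#' @param baseComposition background composition (see
#'   \code{\link{generatePromoter}}).
#' @param coeffs,pwm model data.
#' @return list(seed, params, entries) where entries is a list of
#'   list(seq, variant, class, trueEffect, seqMut).
#' @export
generateCohort <- function(seed, n = 30L,
                           classes = c("strong_up", "strong_down", "null"),
                           minStrongEffect = 1,
                           baseComposition = c(a = 0.25, c = 0.25,
                                               g = 0.25, t = 0.25),
                           coeffs = loadModelCoefficients(),
                           pwm = loadTataPwm()) {
  stopifnot(all(classes %in% c("strong_up", "strong_down", "null")))
  entries <- vector("list", n)
  for (k in seq_len(n)) {
    cls <- classes[(k - 1L) %% length(classes) + 1L]
    subseed <- (seed * 10007L + k) %% .Machine$integer.max
    entries[[k]] <- .generateCohortEntry(cls, subseed, minStrongEffect,
                                         baseComposition, coeffs, pwm)
    entries[[k]]$class <- cls
  }
  list(
    seed = seed,
    params = list(
      n = n, classes = classes, minStrongEffect = minStrongEffect,
      baseComposition = baseComposition
    ),
    entries = entries
  )
}

.generateCohortEntry <- function(cls, subseed, minStrongEffect,
                                 baseComposition, coeffs, pwm,
                                 maxTries = 60L) {
  for (try in seq_len(maxTries)) {
    s2 <- (subseed + 131L * try) %% .Machine$integer.max
    set.seed(s2)
    center <- sample(seq(-60L, -30L), 1L)
    if (cls == "strong_up") {
      # a TATA-less promoter gains a strong site by insertion of a
      # TA-rich 15-mer (mirrors gain-of-site variants); rejection-sampled
      # until the rescored gain reaches the strong-effect threshold
      seqWt <- generatePromoter(s2,
        baseComposition = baseComposition,
        tataStrength = 0.05, tataCenter = center, pwm = pwm
      )
      L <- promoterLength(seqWt)
      i0 <- .positionToIndex(center, L)
      set.seed(s2 + 1L)
      v <- .makeVariantAt(seqWt, i0, "insertion",
                          alt = pwmConsensus(pwm),
                          id = sprintf("syn:up:%d", s2))
      minDelta <- minStrongEffect
    } else if (cls == "strong_down") {
      # a strong embedded site is ablated by a deletion spanning its core
      seqWt <- generatePromoter(s2,
        baseComposition = baseComposition,
        tataStrength = 1, tataCenter = center, pwm = pwm
      )
      L <- promoterLength(seqWt)
      mid0 <- .positionToIndex(center, L)
      set.seed(s2 + 1L)
      dlen <- sample(8:15, 1L)
      v <- .makeVariantAt(seqWt, mid0 - 5L, "deletion",
                          id = sprintf("syn:down:%d", s2), reflen = dlen)
      minDelta <- NA
    } else {
      seqWt <- generatePromoter(s2,
        baseComposition = baseComposition,
        tataStrength = 0.9, tataCenter = center, pwm = pwm
      )
      inj <- tryCatch(
        injectVariant(seqWt, "substitution", "outside_region",
                      seed = s2 + 2L, coeffs = coeffs, pwm = pwm,
                      maxTries = 40L),
        error = function(e) NULL
      )
      if (is.null(inj)) next
      return(list(seq = seqWt, variant = inj$variant,
                  trueEffect = inj$trueEffect, seqMut = inj$seqMut))
    }
    if (is.null(v)) next
    seqMut <- tryCatch(applyVariant(seqWt, v), error = function(e) NULL)
    if (is.null(seqMut) || promoterLength(seqMut) < coeffs@windowLength) next
    delta <- tryCatch(
      estimateAffinity(seqMut, coeffs, pwm)@mean -
        estimateAffinity(seqWt, coeffs, pwm)@mean,
      error = function(e) NA_real_
    )
    if (is.na(delta)) next
    if (cls == "strong_up" && delta < minStrongEffect) next
    if (cls == "strong_down" && delta > -minStrongEffect) next
    return(list(seq = seqWt, variant = v, trueEffect = delta,
                seqMut = seqMut))
  }
  stop(sprintf("could not generate a '%s' cohort entry", cls))
}

#' Tabulate a synthetic cohort's ground truth
#'
#' @param cohort result of \code{\link{generateCohort}}.
#' @return data.frame(id, gene, class, true_effect).
#' @export
cohortTruth <- function(cohort) {
  do.call(rbind, lapply(cohort$entries, function(e) {
    data.frame(
      id = rsId(e$variant),
      gene = geneSymbol(e$seq),
      class = e$class,
      true_effect = e$trueEffect,
      stringsAsFactors = FALSE
    )
  }))
}

#' Write a synthetic cohort to FASTA + TSV files
#'
#' Writes promoters.fa (ancestral alleles), variants.tsv (flank-anchored
#' dialect) and truth.tsv (ground-truth effects); the master seed is
#' recorded in every header.
#'
#' @param cohort result of \code{\link{generateCohort}}.
#' @param dir output directory (created if needed).
#' @return character vector of the three paths, invisibly.
#' @export
writeCohort <- function(cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  fa <- file.path(dir, "promoters.fa")
  vtsv <- file.path(dir, "variants.tsv")
  ttsv <- file.path(dir, "truth.tsv")
  seqs <- Biostrings::DNAStringSet(
    vapply(cohort$entries, function(e) promoterSeq(e$seq), "")
  )
  names(seqs) <- vapply(cohort$entries, function(e) {
    sprintf("%s seed=%d", geneSymbol(e$seq), cohort$seed)
  }, "")
  Biostrings::writeXStringSet(seqs, fa)
  vdf <- do.call(rbind, lapply(cohort$entries, function(e) {
    v <- e$variant
    data.frame(
      gene = geneSymbol(e$seq), rs_id = rsId(v), flank5 = v@flank5,
      ref = if (nchar(v@refAllele)) v@refAllele else "-",
      alts = paste(ifelse(nchar(v@altAlleles) > 0, v@altAlleles, "-"),
                   collapse = ","),
      flank3 = v@flank3, stringsAsFactors = FALSE
    )
  }))
  writeLines(c(
    sprintf("# synthetic cohort, seed=%d", cohort$seed),
    paste(names(vdf), collapse = "\t"),
    vapply(seq_len(nrow(vdf)), function(i) {
      paste(vapply(vdf[i, ], as.character, ""), collapse = "\t")
    }, "")
  ), vtsv)
  tdf <- cohortTruth(cohort)
  writeLines(c(
    sprintf("# synthetic cohort ground truth, seed=%d", cohort$seed),
    paste(names(tdf), collapse = "\t"),
    vapply(seq_len(nrow(tdf)), function(i) {
      paste(vapply(tdf[i, ], as.character, ""), collapse = "\t")
    }, "")
  ), ttsv)
  invisible(c(fa, vtsv, ttsv))
}
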