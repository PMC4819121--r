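#' @import methods
#' @importFrom stats coef lm pnorm predict rnorm runif sd setNames cor.test
NULL

DNA_ALPHABET <- c("a", "c", "g", "t")

.validDna <- function(x) {
  chars <- strsplit(x, "", fixed = TRUE)[[1]]
  bad <- which(!chars %in% DNA_ALPHABET)
  if (length(bad)) bad[1] else 0L
}

#' PromoterSequence: a proximal core-promoter allele
#'
#' Holds one promoter sequence on the annotated (sense) strand with
#' TSS-relative coordinates: the stored string covers positions
#' \eqn{s_{-L} \ldots s_{-1}}, where position \eqn{s_0} (not stored) is the
#' transcription start site. Ancestral alleles are exactly 90 bp; minor
#' alleles may differ in length after indel application and stay anchored at
#' the 3' end, i.e. \eqn{s_{-1}} remains adjacent to the TSS.
#'
#' @slot geneSymbol gene symbol (free text).
#' @slot sequence lowercase DNA over \{a,c,g,t\}.
#' @slot alleleLabel "ancestral" or "minor".
#' @slot source one of "fasta", "fixture", "synthetic".
#' @exportClass PromoterSequence
setClass("PromoterSequence",
  representation(
    geneSymbol = "character",
    sequence = "character",
    alleleLabel = "character",
    source = "character"
  )
)

setValidity("PromoterSequence", function(object) {
  msgs <- character()
  if (length(object@sequence) != 1L) {
    msgs <- c(msgs, "sequence must be a single string")
  } else {
    off <- .validDna(object@sequence)
    if (off > 0L) {
      msgs <- c(msgs, sprintf(
        "non-acgt character at offset %d of '%s'", off, object@geneSymbol
      ))
    }
  }
  if (!object@alleleLabel %in% c("ancestral", "minor")) {
    msgs <- c(msgs, "alleleLabel must be 'ancestral' or 'minor'")
  }
  if (!object@source %in% c("fasta", "fixture", "synthetic")) {
    msgs <- c(msgs, "source must be 'fasta', 'fixture' or 'synthetic'")
  }
  if (length(msgs)) msgs else TRUE
})

#' Construct a PromoterSequence
#'
#' @param geneSymbol gene symbol.
#' @param sequence DNA string (case-insensitive; stored lowercase).
#' @param alleleLabel "ancestral" (default) or "minor".
#' @param source provenance tag: "fasta", "fixture" or "synthetic".
#' @param strictLength enforce the canonical 90-bp length for ancestral
#'   alleles (default); disable to carry promoters of other lengths.
#' @return A \linkS4class{PromoterSequence}.
#' @examples
#' p <- PromoterSequence("TOY", paste0(strrep("acgt", 22), "at"))
#' promoterLength(p)
#' @export
PromoterSequence <- function(geneSymbol, sequence,
                             alleleLabel = "ancestral",
                             source = "synthetic",
                             strictLength = identical(alleleLabel,
                                                      "ancestral")) {
  if (strictLength && identical(alleleLabel, "ancestral") &&
      nchar(sequence) != 90L) {
    stop(sprintf("ancestral promoter '%s' must be 90 bp, got %d",
                 geneSymbol, nchar(sequence)))
  }
  new("PromoterSequence",
    geneSymbol = as.character(geneSymbol),
    sequence = tolower(as.character(sequence)),
    alleleLabel = alleleLabel, source = source
  )
}

#' @describeIn PromoterSequence gene symbol accessor
#' @param x a PromoterSequence
#' @export
geneSymbol <- function(x) x@geneSymbol

#' @describeIn PromoterSequence sequence string accessor
#' @export
promoterSeq <- function(x) x@sequence

#' @describeIn PromoterSequence allele label accessor
#' @export
alleleLabel <- function(x) x@alleleLabel

#' @describeIn PromoterSequence sequence length in bp
#' @export
promoterLength <- function(x) nchar(x@sequence)

setMethod("show", "PromoterSequence", function(object) {
  cat(sprintf(
    "PromoterSequence %s (%s, %s): %d bp, positions %d..-1\n",
    object@geneSymbol, object@alleleLabel, object@source,
    nchar(object@sequence), -nchar(object@sequence)
  ))
  cat(" ", object@sequence, "\n")
})

#' VariantSpec: a flank-anchored promoter variant
#'
#' Variants are specified the way the marker tables print them: a 10-bp 5'
#' flank, the ancestral (reference) allele, one or more alternate alleles,
#' and a 10-bp 3' flank. A zero-length ref encodes a pure insertion; a
#' zero-length alt encodes a deletion. Anchoring into a promoter is by exact,
#' unique match of flank5 + ref + flank3.
#'
#' @slot rsId dbSNP id or a stable free label for unregistered variants.
#' @slot flank5,flank3 10-bp lowercase DNA flanks.
#' @slot refAllele lowercase DNA, length >= 0.
#' @slot altAlleles character vector of lowercase DNA alts, each != ref.
#' @exportClass VariantSpec
setClass("VariantSpec",
  representation(
    rsId = "character",
    flank5 = "character",
    refAllele = "character",
    altAlleles = "character",
    flank3 = "character"
  )
)

setValidity("VariantSpec", function(object) {
  msgs <- character()
  for (fl in c("flank5", "flank3")) {
    v <- slot(object, fl)
    if (nchar(v) != 10L) {
      msgs <- c(msgs, sprintf("%s must be exactly 10 bp, got %d (%s)",
                              fl, nchar(v), object@rsId))
    } else if (.validDna(v) > 0L) {
      msgs <- c(msgs, sprintf("%s has a non-acgt character (%s)", fl,
                              object@rsId))
    }
  }
  if (nchar(object@refAllele) > 0L && .validDna(object@refAllele) > 0L) {
    msgs <- c(msgs, "ref allele has a non-acgt character")
  }
  if (length(object@altAlleles) < 1L) {
    msgs <- c(msgs, "at least one alt allele is required")
  }
  for (a in object@altAlleles) {
    if (nchar(a) > 0L && .validDna(a) > 0L) {
      msgs <- c(msgs, "alt allele has a non-acgt character")
    }
    if (identical(a, object@refAllele)) {
      msgs <- c(msgs, sprintf("every alt must differ from ref ('%s', %s)",
                              a, object@rsId))
    }
  }
  if (length(msgs)) msgs else TRUE
})

#' Construct a VariantSpec
#'
#' @param rsId variant identifier.
#' @param flank5,flank3 10-bp flanks as printed in the marker tables.
#' @param ref reference (ancestral) allele; "" for a pure insertion.
#' @param alts character vector of alternate alleles; "" encodes a deletion.
#' @return A \linkS4class{VariantSpec}.
#' @examples
#' VariantSpec("rs1143627", "ttttgaaagc", "c", "t", "ataaaaacag")
#' @export
VariantSpec <- function(rsId, flank5, ref, alts, flank3) {
  new("VariantSpec",
    rsId = as.character(rsId),
    flank5 = tolower(flank5),
    refAllele = tolower(ref),
    altAlleles = tolower(as.character(alts)),
    flank3 = tolower(flank3)
  )
}

setMethod("show", "VariantSpec", function(object) {
  alts <- vapply(object@altAlleles, function(a) if (nchar(a)) a else "-", "")
  cat(sprintf(
    "VariantSpec %s: %s [%s -> %s] %s\n",
    object@rsId, object@flank5,
    if (nchar(object@refAllele)) object@refAllele else "-",
    paste(alts, collapse = ","), object@flank3
  ))
})

#' @describeIn VariantSpec variant id accessor
#' @param x a VariantSpec
#' @export
rsId <- function(x) x@rsId

#' @describeIn VariantSpec reference allele accessor
#' @export
refAllele <- function(x) x@refAllele

#' @describeIn VariantSpec alternate alleles accessor
#' @export
altAlleles <- function(x) x@altAlleles

#' TataPwm: a 15-position TATA-box position-weight matrix
#'
#' @slot weights 4 x 15 numeric matrix of log-odds weights, rows a,c,g,t.
#' @slot consensus the column-wise argmax 15-mer.
#' @slot provenance free-text provenance of the matrix data.
#' @exportClass TataPwm
setClass("TataPwm",
  representation(
    weights = "matrix",
    consensus = "character",
    provenance = "character"
  )
)

setValidity("TataPwm", function(object) {
  msgs <- character()
  if (!identical(dim(object@weights), c(4L, 15L))) {
    msgs <- c(msgs, sprintf(
      "weights must be 4 x 15 (rows a,c,g,t), got %s",
      paste(dim(object@weights), collapse = " x ")
    ))
  } else {
    if (!identical(rownames(object@weights), DNA_ALPHABET)) {
      msgs <- c(msgs, "weight rows must be named a,c,g,t")
    }
    if (any(!is.finite(object@weights))) {
      msgs <- c(msgs, "every position needs a finite score for each base")
    }
  }
  if (length(msgs)) msgs else TRUE
})

setMethod("show", "TataPwm", function(object) {
  cat(sprintf("TataPwm: 15 positions, consensus %s\n", object@consensus))
  cat(" provenance:", object@provenance, "\n")
})

#' @describeIn TataPwm PWM width (number of positions)
#' @param x a TataPwm
#' @export
pwmWidth <- function(x) ncol(x@weights)

#' @describeIn TataPwm consensus 15-mer (column-wise argmax)
#' @export
pwmConsensus <- function(x) x@consensus

#' @describeIn TataPwm log-odds weight matrix accessor
#' @export
pwmWeights <- function(x) x@weights

#' DinucScale: a 16-entry dinucleotide property scale
#'
#' @slot values named numeric of length 16 (names "aa".."tt").
#' @slot property property name ("slide" or "bend").
#' @slot orientation what larger values mean, free text.
#' @slot symmetric TRUE if value(xy) == value(yx) for all dinucleotides
#'   (i.e. invariant under string reversal of the window).
#' @slot provenance free-text provenance.
#' @exportClass DinucScale
setClass("DinucScale",
  representation(
    values = "numeric",
    property = "character",
    orientation = "character",
    symmetric = "logical",
    provenance = "character"
  )
)

setValidity("DinucScale", function(object) {
  dinucs <- as.vector(outer(DNA_ALPHABET, DNA_ALPHABET, paste0))
  msgs <- character()
  if (length(object@values) != 16L ||
      !setequal(names(object@values), dinucs)) {
    msgs <- c(msgs, "values must be a named numeric over the 16 dinucleotides")
  }
  # the symmetry flag must describe the data it ships with
  if (length(msgs) == 0L) {
    v <- object@values
    rev2 <- function(d) paste0(substr(d, 2, 2), substr(d, 1, 1))
    sym <- all(vapply(names(v), function(d) v[[d]] == v[[rev2(d)]], TRUE))
    if (!identical(sym, object@symmetric)) {
      msgs <- c(msgs, "declared symmetry flag contradicts the values")
    }
  }
  if (length(msgs)) msgs else TRUE
})

setMethod("show", "DinucScale", function(object) {
  cat(sprintf(
    "DinucScale '%s' (%s; reversal-symmetric: %s)\n",
    object@property, object@orientation, object@symmetric
  ))
})

#' @describeIn DinucScale named property values accessor
#' @param x a DinucScale
#' @export
scaleValues <- function(x) x@values

#' @describeIn DinucScale declared reversal-symmetry flag
#' @export
isReversalSymmetric <- function(x) x@symmetric

#' ModelCoefficients: the linear affinity model configuration
#'
#' The affinity estimate is the maximum over admissible windows of
#' intercept + weightSlide * slide + weightPwm * pwm + weightBend * bend,
#' in natural-log units of molar KD.
#'
#' @slot intercept,weightSlide,weightPwm,weightBend linear coefficients.
#' @slot sdModel list(method=, scale=): uncertainty rule. Method "jackknife"
#'   is the delete-one-base jackknife of the best-window score.
#' @slot windowLength binding-region window, default 26 bp.
#' @slot scanRegion TSS-relative interval for the site midpoint, default
#'   c(-70, -20); numeric(0) disables the region rule (context scoring).
#' @slot provenance "calibrated" or a transcription note.
#' @exportClass ModelCoefficients
setClass("ModelCoefficients",
  representation(
    intercept = "numeric",
    weightSlide = "numeric",
    weightPwm = "numeric",
    weightBend = "numeric",
    sdModel = "list",
    windowLength = "integer",
    scanRegion = "numeric",
    provenance = "character"
  )
)

setValidity("ModelCoefficients", function(object) {
  msgs <- character()
  if (object@windowLength < 15L) {
    msgs <- c(msgs, "windowLength must be >= the 15-bp PWM width")
  }
  if (length(object@scanRegion) == 2L) {
    if (object@scanRegion[1] > object@scanRegion[2] ||
        object@scanRegion[1] < -90 || object@scanRegion[2] > -1) {
      msgs <- c(msgs, "scanRegion must lie within [-90, -1]")
    }
  } else if (length(object@scanRegion) != 0L) {
    msgs <- c(msgs, "scanRegion must be numeric(2) or numeric(0)")
  }
  if (!all(is.finite(c(object@intercept, object@weightSlide,
                       object@weightPwm, object@weightBend)))) {
    msgs <- c(msgs, "coefficients must be finite")
  }
  if (length(msgs)) msgs else TRUE
})

setMethod("show", "ModelCoefficients", function(object) {
  cat(sprintf(
    paste0("ModelCoefficients (%s): intercept=%.4f slide=%.4f pwm=%.4f ",
           "bend=%.4f\n  window=%d bp, scan region [%s], sd model %s\n"),
    object@provenance, object@intercept, object@weightSlide,
    object@weightPwm, object@weightBend, object@windowLength,
    paste(object@scanRegion, collapse = ", "),
    object@sdModel$method
  ))
})

#' AffinityEstimate: -ln KD of TBP binding for one allele
#'
#' @slot mean -ln KD in natural-log units (KD in molar).
#' @slot sd uncertainty in ln-units, >= 0.
#' @slot bestWindowStart TSS-relative position of the winning window start.
#' @slot components named numeric (slide, pwm, bend) at the best window.
#' @exportClass AffinityEstimate
setClass("AffinityEstimate",
  representation(
    mean = "numeric",
    sd = "numeric",
    bestWindowStart = "numeric",
    components = "numeric"
  )
)

setValidity("AffinityEstimate", function(object) {
  msgs <- character()
  if (!is.finite(object@mean)) msgs <- c(msgs, "mean must be finite")
  if (!is.finite(object@sd) || object@sd < 0) {
    msgs <- c(msgs, "sd must be finite and >= 0")
  }
  if (length(msgs)) msgs else TRUE
})

setMethod("show", "AffinityEstimate", function(object) {
  cat(sprintf(
    "AffinityEstimate: -ln KD = %.2f +/- %.2f ln-units (%d nM), window @ %d\n",
    object@mean, object@sd, affinityToKdNM(object@mean)$rounded,
    object@bestWindowStart
  ))
})

#' @describeIn AffinityEstimate mean -ln KD accessor
#' @param x an AffinityEstimate
#' @export
affinityMean <- function(x) x@mean

#' @describeIn AffinityEstimate sd accessor
#' @export
affinitySd <- function(x) x@sd

#' @describeIn AffinityEstimate best-window start position (TSS-relative)
#' @export
bestWindowStart <- function(x) x@bestWindowStart

#' @describeIn AffinityEstimate per-term components at the best window
#' @export
affinityComponents <- function(x) x@components

#' AlleleComparison: wt vs mut affinity comparison
#'
#' @slot gene,rsIdLabel,alt identification of the comparison.
#' @slot estWt,estMut \linkS4class{AffinityEstimate}s of the two alleles.
#' @slot z non-negative Z statistic.
#' @slot alphaBound ladder bound in \{0.5, 0.05, 1e-2, 1e-3, 1e-6\}.
#' @slot direction "up", "down" or "none" (predicted expression change).
#' @slot zConvention convention tag used to compute z.
#' @exportClass AlleleComparison
setClass("AlleleComparison",
  representation(
    gene = "character",
    rsIdLabel = "character",
    alt = "character",
    estWt = "AffinityEstimate",
    estMut = "AffinityEstimate",
    z = "numeric",
    alphaBound = "numeric",
    direction = "character",
    zConvention = "character"
  )
)

setValidity("AlleleComparison", function(object) {
  msgs <- character()
  if (object@z < 0) msgs <- c(msgs, "z must be non-negative")
  if (!object@alphaBound %in% ALPHA_LADDER) {
    msgs <- c(msgs, "alphaBound must be on the ladder")
  }
  if (!object@direction %in% c("up", "down", "none")) {
    msgs <- c(msgs, "direction must be 'up', 'down' or 'none'")
  }
  if (object@alphaBound > 0.05 && object@direction != "none") {
    msgs <- c(msgs, "direction must be 'none' when alpha > 0.05")
  }
  if (length(msgs)) msgs else TRUE
})

setMethod("show", "AlleleComparison", function(object) {
  cat(sprintf(
    "AlleleComparison %s %s (alt %s): wt %.2f vs mut %.2f, Z=%.2f, alpha<=%g, %s\n",
    object@gene, object@rsIdLabel,
    if (nchar(object@alt)) object@alt else "-",
    object@estWt@mean, object@estMut@mean, object@z, object@alphaBound,
    directionSymbol(object@direction)
  ))
})

#' The significance ladder used for reporting
#'
#' Coarse alpha bounds: 0.5, 0.05, 1e-2, 1e-3, 1e-6.
#' @export
ALPHA_LADDER <- c(1e-6, 1e-3, 1e-2, 0.05, 0.5)

#' Map a direction code to its display arrow
#'
#' @param direction "up", "down" or "none" (vectorised).
#' @return "\eqn{\uparrow}", "\eqn{\downarrow}" or "=".
#' @export
directionSymbol <- function(direction) {
  unname(c(up = "↑", down = "↓", none = "=")[direction])
}
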