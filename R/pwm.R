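#' Load the packaged TATA-box position-weight matrix
#'
#' Reads a 15-row count table (columns a,c,g,t), converts counts to natural
#' log-odds against a uniform background with a total pseudocount of 1 per
#' position (0.25 per base), and derives the consensus by column-wise argmax
#' (leftmost base in a,c,g,t order on ties).
#'
#' @param file path to the count TSV; default is the packaged matrix.
#' @return a \linkS4class{TataPwm}.
#' @examples
#' pwm <- loadTataPwm()
#' pwmWidth(pwm)
#' pwmConsensus(pwm)
#' @export
loadTataPwm <- function(file = system.file("extdata", "tata_pwm_counts.tsv",
                                           package = "TBPscan")) {
  key <- paste0("pwm:", file)
  if (!is.null(.tbpscanCache[[key]])) return(.tbpscanCache[[key]])
  df <- utils::read.delim(file, comment.char = "#")
  if (!all(c("a", "c", "g", "t") %in% names(df))) {
    stop("PWM file must have columns a, c, g, t")
  }
  if (nrow(df) != 15L) {
    stop(sprintf("TATA PWM must have exactly 15 positions, got %d", nrow(df)))
  }
  counts <- t(as.matrix(df[, DNA_ALPHABET]))  # 4 x 15, rows a,c,g,t
  if (any(counts < 0) || any(!is.finite(counts))) {
    stop("PWM counts must be finite and non-negative")
  }
  n <- colSums(counts)
  freq <- sweep(counts + 0.25, 2, n + 1, "/")
  weights <- log(freq / 0.25)
  rownames(weights) <- DNA_ALPHABET
  consensus <- paste(DNA_ALPHABET[apply(weights, 2, which.max)],
                     collapse = "")
  prov <- grep("provenance", readLines(file, n = 10L), value = TRUE)
  out <- new("TataPwm",
    weights = weights, consensus = consensus,
    provenance = if (length(prov)) {
      sub("^#\\s*provenance:\\s*", "", prov[1])
    } else {
      "unspecified"
    }
  )
  .tbpscanCache[[key]] <- out
  out
}

# per-session cache for packaged model data (paths are stable)
.tbpscanCache <- new.env(parent = emptyenv())

# lowercase DNA string -> integer codes a=1 c=2 g=3 t=4
.dnaToInt <- function(s) {
  codes <- match(strsplit(s, "", fixed = TRUE)[[1]], DNA_ALPHABET)
  if (anyNA(codes)) stop("sequence contains a non-acgt character")
  codes
}

#' Score the best PWM placement within a window
#'
#' Slides the 15-position matrix over every placement inside the window and
#' returns the maximum additive log-odds score together with the 0-based
#' offset of the winning placement (leftmost placement wins ties).
#'
#' @param pwm a \linkS4class{TataPwm}.
#' @param window DNA string of length >= 15 (typically the 26-bp binding
#'   window).
#' @return list(score, offset) with offset 0-based within the window.
#' @export
pwmScore <- function(pwm, window) {
  stopifnot(is(pwm, "TataPwm"))
  window <- tolower(window)
  L <- nchar(window)
  w <- ncol(pwm@weights)
  if (L < w) {
    stop(sprintf("window of %d bp is shorter than the %d-bp PWM", L, w))
  }
  codes <- .dnaToInt(window)
  n_place <- L - w + 1L
  scores <- numeric(n_place)
  for (j in seq_len(w)) {
    scores <- scores + pwm@weights[cbind(codes[j:(j + n_place - 1L)], j)]
  }
  best <- which.max(scores)  # leftmost max
  list(score = scores[best], offset = best - 1L)
}

.loadDinucFile <- function(file, property) {
  lines <- readLines(file)
  meta <- grep("^#", lines, value = TRUE)
  getMeta <- function(key, default = "") {
    hit <- grep(paste0("^#\\s*", key, ":"), meta, value = TRUE)
    if (length(hit)) sub(paste0("^#\\s*", key, ":\\s*"), "", hit[1]) else default
  }
  df <- utils::read.delim(file, comment.char = "#")
  vals <- setNames(df$value, tolower(df$dinuc))
  new("DinucScale",
    values = vals,
    property = property,
    orientation = getMeta("orientation", "unspecified"),
    symmetric = identical(toupper(getMeta("symmetric", "FALSE")), "TRUE"),
    provenance = getMeta("provenance", "unspecified")
  )
}

#' Load a packaged dinucleotide property scale
#'
#' @param property "slide" (stacking-energy based sliding term) or "bend"
#'   (bendability term).
#' @param file optional path overriding the packaged table.
#' @return a \linkS4class{DinucScale}.
#' @export
loadDinucScale <- function(property = c("slide", "bend"), file = NULL) {
  property <- match.arg(property)
  if (is.null(file)) {
    file <- system.file("extdata", paste0("dinuc_", property, ".tsv"),
                        package = "TBPscan")
  }
  key <- paste0("dinuc:", property, ":", file)
  if (is.null(.tbpscanCache[[key]])) {
    .tbpscanCache[[key]] <- .loadDinucFile(file, property)
  }
  .tbpscanCache[[key]]
}

.dinucMean <- function(window, scale) {
  window <- tolower(window)
  L <- nchar(window)
  if (L < 2L) stop("window must be at least 2 bp for dinucleotide scoring")
  if (.validDna(window) > 0L) stop("unknown dinucleotide: non-acgt base")
  steps <- substring(window, seq_len(L - 1L), 2:L)
  mean(scale@values[steps])
}

#' Mean dinucleotide sliding score of a window
#'
#' Arithmetic mean of the packaged per-dinucleotide sliding property over
#' the nchar(window) - 1 steps of the window.
#'
#' @param window DNA string over \{a,c,g,t\}.
#' @param scale a \linkS4class{DinucScale}; defaults to the packaged sliding
#'   table.
#' @return numeric scalar.
#' @export
slideScore <- function(window, scale = loadDinucScale("slide")) {
  .dinucMean(window, scale)
}

#' Mean dinucleotide bending score of a window
#'
#' @inheritParams slideScore
#' @return numeric scalar.
#' @export
bendScore <- function(window, scale = loadDinucScale("bend")) {
  .dinucMean(window, scale)
}
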