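#' Load the packaged TATA-box SNP marker table
#'
#' Reads the curated, machine-readable transcription of the published
#' three-table marker compendium: one row per variant with its 10-bp flanks,
#' ancestral and alternate alleles, the un-merged wt/mut KD pair in integer
#' nM, the printed expression direction, integer Z and ladder alpha, plus
#' opaque disease-annotation text. Every row is validated: 10-bp flanks,
#' positive integer KDs, and the direction/KD-sign consistency rule
#' (direction "up" iff KD decreases, "eq" iff it is unchanged).
#'
#' @param file TSV path; default is the packaged fixture.
#' @return data.frame of marker records.
#' @export
loadMarkerFixture <- function(file = system.file(
                                "extdata", "marker_fixture.tsv",
                                package = "TBPscan"
                              )) {
  df <- utils::read.delim(file,
    comment.char = "#", stringsAsFactors = FALSE,
    colClasses = c(
      kd_wt_nM = "integer", kd_mut_nM = "integer",
      z_printed = "integer", alpha_printed = "numeric"
    )
  )
  needed <- c(
    "table_id", "gene", "omim_id", "rs_id", "flank5", "ref", "alts",
    "flank3", "kd_wt_nM", "kd_mut_nM", "direction", "z_printed",
    "alpha_printed", "note", "annotation"
  )
  if (!all(needed %in% names(df))) {
    stop("marker fixture lacks columns: ",
         paste(setdiff(needed, names(df)), collapse = ", "))
  }
  for (i in seq_len(nrow(df))) {
    r <- df[i, ]
    if (nchar(r$flank5) != 10L || nchar(r$flank3) != 10L) {
      stop(sprintf("marker row %d (%s): flanks must be 10 bp", i, r$rs_id))
    }
    if (r$kd_wt_nM < 1L || r$kd_mut_nM < 1L) {
      stop(sprintf("marker row %d (%s): KD values must be positive integers",
                   i, r$rs_id))
    }
    expected <- if (r$kd_wt_nM > r$kd_mut_nM) {
      "up"
    } else if (r$kd_wt_nM < r$kd_mut_nM) {
      "down"
    } else {
      "eq"
    }
    if (!identical(r$direction, expected)) {
      stop(sprintf(
        "marker row %d (%s): direction '%s' contradicts the KD pair %d -> %d",
        i, r$rs_id, r$direction, r$kd_wt_nM, r$kd_mut_nM
      ))
    }
    if (!r$alpha_printed %in% ALPHA_LADDER) {
      stop(sprintf("marker row %d (%s): alpha %g is not on the ladder",
                   i, r$rs_id, r$alpha_printed))
    }
    # the VariantSpec constructor re-validates alleles and flanks
    markerVariant(r)
  }
  df
}

#' Build the VariantSpec of a marker record
#'
#' @param record one row of \code{\link{loadMarkerFixture}}.
#' @return a \linkS4class{VariantSpec}.
#' @export
markerVariant <- function(record) {
  alts <- trimws(strsplit(record$alts, ",", fixed = TRUE)[[1]])
  alts[alts == "-"] <- ""
  VariantSpec(record$rs_id, record$flank5, record$ref, alts, record$flank3)
}

# effective direction implied by the printed KD pair and alpha
.effectiveDirection <- function(kd_wt, kd_mut, alpha) {
  ifelse(alpha > 0.05, "none",
    ifelse(kd_wt > kd_mut, "up", ifelse(kd_wt < kd_mut, "down", "none"))
  )
}

#' Count candidate markers passing filters
#'
#' Applies the candidate-marker rule (significant at \code{alphaMax} and a
#' non-null direction implied by the KD pair) with optional gene and
#' direction filters. Asking for direction "none" counts the rows whose
#' effective direction is null, without the alpha cut.
#'
#' @param records marker table (\code{\link{loadMarkerFixture}}).
#' @param genes optional character vector of gene symbols; unknown symbols
#'   are an error.
#' @param direction optional "up", "down" or "none".
#' @param alphaMax significance cut, default 0.05.
#' @return integer count.
#' @examples
#' \dontrun{
#' countCandidates(loadMarkerFixture(), genes = c("HBB", "HBD"),
#'                 direction = "down")  # 10
#' }
#' @export
countCandidates <- function(records, genes = NULL, direction = NULL,
                            alphaMax = 0.05) {
  if (!is.null(genes)) {
    unknown <- setdiff(genes, records$gene)
    if (length(unknown)) {
      stop("unknown gene symbol(s): ", paste(unknown, collapse = ", "))
    }
    records <- records[records$gene %in% genes, ]
  }
  eff <- .effectiveDirection(records$kd_wt_nM, records$kd_mut_nM,
                             records$alpha_printed)
  keep <- if (!is.null(direction) && direction == "none") {
    eff == "none"
  } else {
    pass <- eff != "none" & records$alpha_printed <= alphaMax
    if (is.null(direction)) pass else pass & eff == direction
  }
  sum(keep)
}

#' KD range over both alleles of a marker table
#'
#' @param records marker table.
#' @return c(min_nM, max_nM).
#' @export
kdRange <- function(records) {
  if (nrow(records) == 0L) stop("empty record list")
  kd <- c(records$kd_wt_nM, records$kd_mut_nM)
  c(min_nM = min(kd), max_nM = max(kd))
}

#' Per-row consistency checks of the marker table
#'
#' For every row: does the printed direction match the sign of the KD
#' change, and does the alpha ladder recomputed from the printed integer Z
#' reproduce the printed alpha. The recomputed ladder value is reported so
#' discrepant rows can be inspected.
#'
#' @param records marker table.
#' @param sidedness passed to \code{\link{alphaLadder}}.
#' @return data.frame(rs_id, gene, direction_ok, ladder_ok, alpha_expected,
#'   alpha_printed).
#' @export
consistencyReport <- function(records, sidedness = "two") {
  if (nrow(records) == 0L) {
    return(data.frame(
      rs_id = character(), gene = character(),
      direction_ok = logical(), ladder_ok = logical(),
      alpha_expected = numeric(), alpha_printed = numeric()
    ))
  }
  dir_expected <- ifelse(records$kd_wt_nM > records$kd_mut_nM, "up",
    ifelse(records$kd_wt_nM < records$kd_mut_nM, "down", "eq")
  )
  alpha_expected <- alphaLadder(records$z_printed, sidedness = sidedness)
  data.frame(
    rs_id = records$rs_id,
    gene = records$gene,
    direction_ok = records$direction == dir_expected,
    ladder_ok = alpha_expected == records$alpha_printed,
    alpha_expected = alpha_expected,
    alpha_printed = records$alpha_printed,
    stringsAsFactors = FALSE
  )
}

#' Render a marker table or comparison set as TSV or markdown
#'
#' Mirrors the published column layout, including the flank-anchored
#' "5' flank wtmut 3' flank" allele column split into its parts. The TSV
#' form round-trips: parsing it back recovers the rendered columns.
#'
#' @param x marker table data.frame or \linkS4class{AlleleComparison} list.
#' @param format "tsv" or "markdown".
#' @param path optional file to write to.
#' @return character vector of rendered lines, invisibly if \code{path}
#'   is given.
#' @export
renderReport <- function(x, format = c("tsv", "markdown"), path = NULL) {
  format <- match.arg(format)
  if (is(x, "AlleleComparison") ||
      (is.list(x) && !is.data.frame(x))) {
    df <- comparisonTable(x)
  } else {
    df <- x[, intersect(
      c("table_id", "gene", "rs_id", "flank5", "ref", "alts", "flank3",
        "kd_wt_nM", "kd_mut_nM", "direction", "z_printed", "alpha_printed"),
      names(x)
    ), drop = FALSE]
  }
  lines <- if (format == "tsv") {
    c(
      paste(names(df), collapse = "\t"),
      if (nrow(df)) {
        vapply(seq_len(nrow(df)), function(i) {
          paste(vapply(df[i, ], as.character, ""), collapse = "\t")
        }, "")
      }
    )
  } else {
    hdr <- names(df)
    hdr[hdr %in% c("flank5", "ref", "alts", "flank3")] <-
      c("5' flank", "wt", "mut", "3' flank")
    c(
      paste0("| ", paste(hdr, collapse = " | "), " |"),
      paste0("|", paste(rep("---", length(hdr)), collapse = "|"), "|"),
      if (nrow(df)) {
        vapply(seq_len(nrow(df)), function(i) {
          cells <- vapply(df[i, ], as.character, "")
          if ("direction" %in% names(df)) {
            d <- df$direction[i]
            cells[names(df) == "direction"] <-
              if (d == "eq") "=" else directionSymbol(d)
          }
          paste0("| ", paste(cells, collapse = " | "), " |")
        }, "")
      }
    )
  }
  if (!is.null(path)) {
    writeLines(lines, path)
    return(invisible(lines))
  }
  lines
}
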