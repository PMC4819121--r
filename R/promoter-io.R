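#' Read promoter sequences from FASTA
#'
#' One \linkS4class{PromoterSequence} per record; the first whitespace token
#' of each header is taken as the gene symbol. Sequences are lowercased and
#' validated against the \{a,c,g,t\} alphabet; with \code{strictLength}
#' (default) every record must be exactly 90 bp, the ancestral proximal
#' promoter length used throughout.
#'
#' @param fasta path to a FASTA file.
#' @param alleleLabel label to assign, "ancestral" (default) or "minor".
#' @param strictLength enforce the 90-bp ancestral length.
#' @return list of \linkS4class{PromoterSequence}.
#' @examples
#' fa <- tempfile(fileext = ".fa")
#' writeLines(c(">TOY", strrep("ca", 45)), fa)
#' readPromoters(fa)
#' @export
readPromoters <- function(fasta, alleleLabel = "ancestral",
                          strictLength = TRUE) {
  set <- Biostrings::readDNAStringSet(fasta)
  if (length(set) == 0L) {
    warning("no FASTA records in '", fasta, "'; returning an empty list")
    return(list())
  }
  genes <- vapply(strsplit(names(set), "\\s+"), `[`, "", 1L)
  out <- vector("list", length(set))
  for (i in seq_along(set)) {
    s <- tolower(as.character(set[[i]]))
    off <- .validDna(s)
    if (off > 0L) {
      stop(sprintf(
        "record '%s': non-acgt character '%s' at offset %d",
        genes[i], substr(s, off, off), off
      ))
    }
    if (strictLength && nchar(s) != 90L && alleleLabel == "ancestral") {
      stop(sprintf(
        "record '%s': expected 90 bp, got %d (disable with strictLength = FALSE)",
        genes[i], nchar(s)
      ))
    }
    out[[i]] <- PromoterSequence(genes[i], s,
      alleleLabel = alleleLabel, source = "fasta",
      strictLength = strictLength
    )
  }
  names(out) <- genes
  out
}

#' Write promoter sequences to FASTA
#'
#' @param promoters list of \linkS4class{PromoterSequence}.
#' @param path output file.
#' @return \code{path}, invisibly.
#' @export
writePromoters <- function(promoters, path) {
  seqs <- Biostrings::DNAStringSet(vapply(promoters, promoterSeq, ""))
  names(seqs) <- vapply(promoters, geneSymbol, "")
  Biostrings::writeXStringSet(seqs, path)
  invisible(path)
}

# 0-based index -> TSS-relative position (i = 0 is s_{-L}, last base is s_{-1})
.indexToPosition <- function(i0, len) i0 - len

.positionToIndex <- function(pos, len) pos + len

#' Anchor a variant in an ancestral promoter
#'
#' Finds the unique position where flank5 + ref + flank3 matches the
#' promoter and returns the TSS-relative position of the first ref base (for
#' a pure insertion, of the first 3' flank base). Zero matches and multiple
#' matches are both hard errors; the anchor is never guessed.
#'
#' @param seq an ancestral \linkS4class{PromoterSequence}.
#' @param variant a \linkS4class{VariantSpec}.
#' @return integer TSS-relative anchor position (negative).
#' @export
anchorVariant <- function(seq, variant) {
  stopifnot(is(seq, "PromoterSequence"), is(variant, "VariantSpec"))
  if (alleleLabel(seq) != "ancestral") {
    stop("variants anchor into the ancestral allele only")
  }
  context <- paste0(variant@flank5, variant@refAllele, variant@flank3)
  hits <- Biostrings::matchPattern(
    Biostrings::DNAString(context),
    Biostrings::DNAString(promoterSeq(seq))
  )
  if (length(hits) == 0L) {
    stop(sprintf(
      "context not found: '%s' (%s) does not occur in promoter '%s'",
      context, rsId(variant), geneSymbol(seq)
    ))
  }
  if (length(hits) > 1L) {
    stop(sprintf(
      "ambiguous anchor: context of %s occurs %d times in promoter '%s'",
      rsId(variant), length(hits), geneSymbol(seq)
    ))
  }
  anchor0 <- Biostrings::start(hits)[1] - 1L + 10L  # 0-based first ref base
  .indexToPosition(anchor0, promoterLength(seq))
}

#' Apply a variant to an ancestral promoter
#'
#' Replaces the reference allele by the chosen alternate at the anchored
#' position. Bases outside [anchor, anchor + nchar(ref)) are untouched; the
#' product is labelled "minor" and re-indexed from the 3' terminus, so
#' \eqn{s_{-1}} stays adjacent to the TSS and the sequence length changes by
#' nchar(alt) - nchar(ref).
#'
#' @param seq an ancestral \linkS4class{PromoterSequence}.
#' @param variant a \linkS4class{VariantSpec}.
#' @param altIndex which alternate allele to apply (default 1).
#' @return a minor-allele \linkS4class{PromoterSequence}.
#' @export
applyVariant <- function(seq, variant, altIndex = 1L) {
  if (altIndex < 1L || altIndex > length(altAlleles(variant))) {
    stop(sprintf(
      "altIndex %d out of range; available alternates for %s: %s",
      altIndex, rsId(variant),
      paste(sprintf("[%d] '%s'", seq_along(altAlleles(variant)),
                    altAlleles(variant)), collapse = ", ")
    ))
  }
  pos <- anchorVariant(seq, variant)
  len <- promoterLength(seq)
  i0 <- .positionToIndex(pos, len)            # 0-based index of first ref base
  ref <- refAllele(variant)
  alt <- altAlleles(variant)[altIndex]
  s <- promoterSeq(seq)
  new_seq <- paste0(
    substr(s, 1L, i0),
    alt,
    substr(s, i0 + nchar(ref) + 1L, len)
  )
  PromoterSequence(geneSymbol(seq), new_seq,
    alleleLabel = "minor", source = seq@source
  )
}

#' Read flank-anchored variants from TSV
#'
#' Expected columns: gene, rs_id, flank5, ref, alts, flank3. The alts cell is
#' comma-separated; an empty string (or "-") encodes a deletion; multi-allelic
#' cells like "a,t,g" expand into one \linkS4class{VariantSpec} carrying all
#' alternates.
#'
#' @param tsv path to a tab-separated file with a header row.
#' @return named list of \linkS4class{VariantSpec} (names = gene symbols).
#' @export
readVariantsTsv <- function(tsv) {
  df <- utils::read.delim(tsv,
    stringsAsFactors = FALSE,
    colClasses = "character", comment.char = "#"
  )
  needed <- c("gene", "rs_id", "flank5", "ref", "alts", "flank3")
  if (!all(needed %in% names(df))) {
    stop(
      "variant TSV must have columns: ", paste(needed, collapse = ", ")
    )
  }
  out <- vector("list", nrow(df))
  for (i in seq_len(nrow(df))) {
    row <- df[i, ]
    alts <- .parseAlleleCell(row$alts, i)
    ref <- .parseAlleleCell(row$ref, i)
    if (length(ref) != 1L) {
      stop(sprintf("row %d: ref cell must be a single allele", i))
    }
    out[[i]] <- tryCatch(
      VariantSpec(row$rs_id, row$flank5, ref, alts, row$flank3),
      error = function(e) {
        stop(sprintf("row %d: %s", i, conditionMessage(e)))
      }
    )
  }
  names(out) <- df$gene
  out
}

# allele cell dialect: "" or "-" = deletion; comma-separated multi-allelic
.parseAlleleCell <- function(cell, rownum) {
  cell <- tolower(trimws(cell))
  parts <- strsplit(cell, ",", fixed = TRUE)[[1]]
  if (length(parts) == 0L) parts <- ""
  parts <- trimws(parts)
  parts[parts == "-"] <- ""
  for (p in parts) {
    if (nchar(p) > 0L && .validDna(p) > 0L) {
      stop(sprintf("row %d: malformed allele cell '%s'", rownum, cell))
    }
  }
  parts
}

#' Convert VCF records to flank-anchored VariantSpecs
#'
#' Thin adapter: for each VCF record falling inside the promoter interval,
#' the 10-bp flanks are cut out of the supplied ancestral promoter sequence.
#' Indel left-alignment is taken from the VCF as-is (no re-normalisation).
#' Records whose REF disagrees with the promoter sequence, or that sit too
#' close to the promoter edge for full flanks, are errors.
#'
#' @param vcf path to a VCF file (requires the VariantAnnotation package).
#' @param seq ancestral \linkS4class{PromoterSequence} covered by the VCF.
#' @param promoterStart 1-based chromosomal position of the promoter's first
#'   (most 5', i.e. position -90) base.
#' @return list of \linkS4class{VariantSpec}.
#' @export
readVariantsVcf <- function(vcf, seq, promoterStart) {
  if (!requireNamespace("VariantAnnotation", quietly = TRUE)) {
    stop("readVariantsVcf requires the VariantAnnotation package")
  }
  v <- VariantAnnotation::readVcf(vcf)
  rr <- SummarizedExperiment::rowRanges(v)
  pos <- BiocGenerics::start(rr)
  ref <- tolower(as.character(VariantAnnotation::ref(v)))
  altList <- VariantAnnotation::alt(v)
  ids <- names(rr)
  s <- promoterSeq(seq)
  len <- promoterLength(seq)
  out <- list()
  for (i in seq_along(pos)) {
    off <- pos[i] - promoterStart + 1L   # 1-based offset into the promoter
    if (off < 1L || off + nchar(ref[i]) - 1L > len) {
      stop(sprintf("VCF record %s lies outside the promoter interval", ids[i]))
    }
    have <- substr(s, off, off + nchar(ref[i]) - 1L)
    if (!identical(have, ref[i])) {
      stop(sprintf(
        "VCF record %s: REF '%s' disagrees with promoter sequence '%s'",
        ids[i], ref[i], have
      ))
    }
    if (off - 10L < 1L || off + nchar(ref[i]) + 9L > len) {
      stop(sprintf("VCF record %s: not enough sequence for 10-bp flanks",
                   ids[i]))
    }
    alts <- tolower(as.character(altList[[i]]))
    # shared leading base convention for indels: strip it from both sides
    if (any(nchar(alts) != nchar(ref[i]))) {
      lead <- substr(ref[i], 1L, 1L)
      if (all(substr(alts, 1L, 1L) == lead)) {
        stripped_ref <- substr(ref[i], 2L, nchar(ref[i]))
        alts <- substr(alts, 2L, nchar(alts))
        off <- off + 1L
        ref_i <- stripped_ref
      } else {
        ref_i <- ref[i]
      }
    } else {
      ref_i <- ref[i]
    }
    flank5 <- substr(s, off - 10L, off - 1L)
    flank3 <- substr(s, off + nchar(ref_i), off + nchar(ref_i) + 9L)
    out[[length(out) + 1L]] <- VariantSpec(
      if (is.null(ids) || is.na(ids[i]) || ids[i] == ".") {
        sprintf("vcf:%d", pos[i])
      } else {
        ids[i]
      },
      flank5, ref_i, alts, flank3
    )
  }
  out
}
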