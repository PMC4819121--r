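test_that("FASTA reading validates alphabet, length and headers", {
  fa <- withr::local_tempfile(fileext = ".fa")
  writeLines(c(">GENE1 some description", strrep("acgt", 22), "at",
               ">GENE2", strrep("ca", 45)), fa)
  ps <- readPromoters(fa)
  expect_length(ps, 2L)
  expect_identical(geneSymbol(ps[[1]]), "GENE1")
  expect_identical(promoterLength(ps[[1]]), 90L)
  expect_identical(alleleLabel(ps[[2]]), "ancestral")

  bad <- withr::local_tempfile(fileext = ".fa")
  writeLines(c(">BAD", paste0(strrep("a", 40), "n", strrep("a", 49))), bad)
  expect_error(readPromoters(bad), "offset 41")

  short <- withr::local_tempfile(fileext = ".fa")
  writeLines(c(">SHORT", strrep("a", 89)), short)
  expect_error(readPromoters(short), "90 bp")
  expect_length(readPromoters(short, strictLength = FALSE), 1L)

  empty <- withr::local_tempfile(fileext = ".fa")
  writeLines(character(0), empty)
  expect_warning(out <- readPromoters(empty), "empty")
  expect_length(out, 0L)
})

test_that("variant anchoring finds the unique flank context", {
  v <- il1b_variant()
  p <- promoter_with_context(v@flank5, v@refAllele, v@flank3, -31L, seed = 3)
  expect_identical(anchorVariant(p, v), -31L)

  set.seed(9)
  other <- PromoterSequence("OTHER", random_dna(90L))
  expect_error(anchorVariant(other, v), "context not found")

  ctx <- paste0(v@flank5, v@refAllele, v@flank3)
  dup <- PromoterSequence("DUP", paste0(ctx, ctx, strrep("g", 90 - 2 * nchar(ctx))))
  expect_error(anchorVariant(dup, v), "ambiguous")
})

test_that("variant application handles substitutions, deletions, insertions", {
  v <- il1b_variant()
  p <- promoter_with_context(v@flank5, v@refAllele, v@flank3, -31L, seed = 3)
  minor <- applyVariant(p, v)
  expect_identical(alleleLabel(minor), "minor")
  expect_identical(promoterLength(minor), 90L)
  # the substitution converts the non-canonical CATAAAA context into the
  # canonical TATAAAA box
  expect_true(grepl("ttttgaaagctataaaaacag", promoterSeq(minor), fixed = TRUE))

  vdel <- VariantSpec("rs397509430", "gggctgggca", "t", "", "atacaacagt")
  pdel <- promoter_with_context(vdel@flank5, vdel@refAllele, vdel@flank3,
                                -30L, seed = 5)
  mdel <- applyVariant(pdel, vdel)
  expect_identical(promoterLength(mdel), 89L)

  vins <- VariantSpec("ins1", "acgtacgtac", "", "tt", "ggcaggcagg")
  pins <- promoter_with_context(vins@flank5, vins@refAllele, vins@flank3,
                                -40L, seed = 6)
  mins <- applyVariant(pins, vins)
  expect_identical(promoterLength(mins), 92L)

  expect_error(applyVariant(p, v, altIndex = 2L), "out of range")
  expect_error(VariantSpec("bad", "acgtacgtac", "c", "c", "ggcaggcagg"),
               "alt must differ")
})

test_that("apply/revert round-trips and never touches bases outside the ref", {
  cases <- list(
    VariantSpec("sub", "ttttgaaagc", "c", "t", "ataaaaacag"),
    VariantSpec("del", "gggctgggca", "ta", "", "atacaacagt"),
    VariantSpec("ins", "acgtaccgta", "", "gg", "ggcaggcagg")
  )
  for (seed in 1:8) {
    for (v in cases) {
      pos <- c(-60L, -45L, -31L)[seed %% 3 + 1]
      p <- promoter_with_context(v@flank5, v@refAllele, v@flank3, pos,
                                 seed = seed)
      a <- anchorVariant(p, v)
      expect_identical(a, pos)
      minor <- applyVariant(p, v)
      L <- promoterLength(p)
      i0 <- a + L
      # bases outside [anchor, anchor + nchar(ref)) are untouched
      expect_identical(substr(promoterSeq(minor), 1, i0),
                       substr(promoterSeq(p), 1, i0))
      expect_identical(
        substring(promoterSeq(minor), i0 + nchar(altAlleles(v)[1]) + 1),
        substring(promoterSeq(p), i0 + nchar(refAllele(v)) + 1)
      )
      # re-substituting ref at the anchor restores the ancestral sequence
      restored <- paste0(
        substr(promoterSeq(minor), 1, i0),
        refAllele(v),
        substring(promoterSeq(minor), i0 + nchar(altAlleles(v)[1]) + 1)
      )
      expect_identical(restored, promoterSeq(p))
    }
  }
})

test_that("variant TSV dialect parses multi-allelic and deletion cells", {
  tsv <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c(
    "gene\trs_id\tflank5\tref\talts\tflank3",
    "HBB\trs34500389\tcagggctggg\tc\ta,t,g\tataaaagtca",
    "HBB\trs63750953\tctgggcataa\taa\t-\tgtcagggcag",
    "IL1B\trs1143627\tttttgaaagc\tc\tt\tataaaaacag"
  ), tsv)
  vs <- readVariantsTsv(tsv)
  expect_length(vs, 3L)
  expect_identical(refAllele(vs[[1]]), "c")
  expect_identical(altAlleles(vs[[1]]), c("a", "t", "g"))
  expect_identical(refAllele(vs[[2]]), "aa")
  expect_identical(altAlleles(vs[[2]]), "")
  expect_identical(altAlleles(vs[[3]]), "t")

  bad <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c(
    "gene\trs_id\tflank5\tref\talts\tflank3",
    "X\trsX\tacgtacgtac\tc\tq\tacgtacgtac"
  ), bad)
  expect_error(readVariantsTsv(bad), "row 1")
})

test_that("VCF records convert to flank-anchored variants", {
  skip_if_not_installed("VariantAnnotation")
  v <- il1b_variant()
  p <- promoter_with_context(v@flank5, v@refAllele, v@flank3, -31L, seed = 3)
  promoterStart <- 1001L                      # position -90 in the genome
  i0 <- -31L + 90L                            # 0-based ref offset
  vcf <- withr::local_tempfile(fileext = ".vcf")
  writeLines(c(
    "##fileformat=VCFv4.2",
    "##contig=<ID=chr2,length=100000>",
    paste("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
          sep = "\t"),
    paste("chr2", promoterStart + i0, "rs1143627", "C", "T", ".", ".", ".",
          sep = "\t")
  ), vcf)
  out <- readVariantsVcf(vcf, p, promoterStart)
  expect_length(out, 1L)
  expect_identical(out[[1]]@flank5, v@flank5)
  expect_identical(out[[1]]@flank3, v@flank3)
  expect_identical(refAllele(out[[1]]), "c")
  expect_identical(altAlleles(out[[1]]), "t")
  expect_identical(anchorVariant(p, out[[1]]), -31L)
})
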