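test_that("well-formed miRBase-style GFF3 parses with no rejects", {
  gff <- make_gff(c(
    gff_line("chr1", "miRNA_primary_transcript", 1000, 1080, "+", "P1", "mir-1"),
    gff_line("chr1", "miRNA", 1000, 1021, "+", "M1", "mir-1-5p", "P1"),
    gff_line("chr1", "miRNA", 1059, 1080, "+", "M2", "mir-1-3p", "P1")))
  ann <- read_mirna_gff(gff)
  expect_equal(nrow(ann$precursors), 1L)
  expect_equal(nrow(ann$matures), 2L)
  expect_equal(sum(ann$rejects), 0L)
  expect_equal(ann$matures$precursor_id, c("P1", "P1"))
  expect_equal(ann$precursors$strand, "+")
})

test_that("invalid mature records are dropped with counted warnings", {
  gff <- make_gff(c(
    gff_line("chr1", "miRNA_primary_transcript", 1000, 1080, "+", "P1", "mir-1"),
    gff_line("chr1", "miRNA", 1000, 1005, "+", "M1", "mir-1-5p", "P1"),   # 6 nt
    gff_line("chr1", "miRNA", 1010, 1031, "+", "M2", "mir-1-3p", "PX"),   # dangling
    gff_line("chr2", "miRNA", 1040, 1061, "+", "M3", "mir-1-x", "P1")))   # chrom mismatch
  expect_warning(ann <- read_mirna_gff(gff), "dropped")
  expect_equal(nrow(ann$matures), 0L)
  expect_equal(unname(ann$rejects["mature_too_short"]), 1L)
  expect_equal(unname(ann$rejects["mature_dangling_parent"]), 1L)
  expect_equal(unname(ann$rejects["mature_parent_mismatch"]), 1L)
})

test_that("attach_sequences transcribes DNA, drops unmatched, and rejects length mismatches", {
  gff <- make_gff(c(
    gff_line("chr1", "miRNA_primary_transcript", 1000, 1080, "+", "P1", "mir-1"),
    gff_line("chr1", "miRNA", 1000, 1021, "+", "M1", "mir-1-5p", "P1"),
    gff_line("chr1", "miRNA", 1059, 1080, "+", "M2", "mir-1-3p", "P1")))
  ann <- read_mirna_gff(gff)

  fa <- make_fasta(c("mir-1-5p" = "UGAGGUAGUAGGUUGUAUAGUU",
                     "mir-1-3p" = "CTATACAATCTACTGTCTTTCC"))  # DNA input
  expect_warning(mat <- attach_sequences(ann$matures, fa), NA)
  expect_equal(mat$sequence[1], "UGAGGUAGUAGGUUGUAUAGUU")
  expect_equal(mat$sequence[2], "CUAUACAAUCUACUGUCUUUCC")

  fa_missing <- make_fasta(c("mir-1-5p" = "UGAGGUAGUAGGUUGUAUAGUU"))
  expect_warning(mat2 <- attach_sequences(ann$matures, fa_missing),
                 "no FASTA record")
  expect_equal(nrow(mat2), 1L)

  fa_short <- make_fasta(c("mir-1-5p" = "UGAGGUAGUAGGUUGUAUAGU",  # 21 nt
                           "mir-1-3p" = "CUAUACAAUCUACUGUCUUUCC"))
  expect_error(attach_sequences(ann$matures, fa_short), "untrustworthy")
})

test_that("VCF reader keeps SNVs (multiallelic included) and filters indels", {
  vcf <- make_vcf(c(
    vcf_rec("chr1", 100, "rs1", "A", "G", "AF=0.100000"),
    vcf_rec("chr1", 200, "rs2", "A", "G,T", "AF=0.200000,0.050000"),
    vcf_rec("chr1", 300, "rs3", "AT", "A"),      # deletion
    vcf_rec("chr1", 400, "rs4", "C", "CTT"),     # insertion ALT
    vcf_rec("chr1", 500, "rs5", "G", "A,GG")))   # mixed: keep A only
  snps <- suppressMessages(read_vcf_snps(vcf))
  expect_equal(snps$rsid, c("rs1", "rs2", "rs5"))
  expect_equal(snps$alts, c("G", "G,T", "A"))
  expect_equal(snps$maf[1], 0.1)
  expect_false(any(snps$multi_mapped))
})

test_that("MAF parsing handles AF, CAF and missing INFO", {
  vcf <- make_vcf(c(
    vcf_rec("chr1", 100, "rs1", "A", "G", "AF=0.300000"),
    vcf_rec("chr1", 200, "rs2", "A", "G", "CAF=0.9,0.1"),
    vcf_rec("chr1", 300, "rs3", "A", "G", "."),
    vcf_rec("chr1", 400, "rs4", "A", "G", "AF=0.800000")),
    info_header = c(
      "##INFO=<ID=AF,Number=A,Type=Float,Description=\"AF\">",
      "##INFO=<ID=CAF,Number=.,Type=String,Description=\"CAF\">"))
  snps <- suppressMessages(read_vcf_snps(vcf, maf_key = c("AF", "CAF")))
  expect_equal(snps$maf[1], 0.3)
  expect_equal(snps$maf[2], 0.1)    # CAF lists REF frequency first
  expect_true(is.na(snps$maf[3]))
  expect_equal(snps$maf[4], 0.2)    # minor allele is REF here
})

test_that("VCF with no parseable SNVs is fatal and duplicates are flagged", {
  vcf_bad <- make_vcf(vcf_rec("chr1", 300, "rs3", "AT", "A"))
  expect_error(suppressMessages(read_vcf_snps(vcf_bad)), "no single-nucleotide")

  vcf_dup <- make_vcf(c(vcf_rec("chr1", 100, "rs1", "A", "G"),
                        vcf_rec("chr2", 900, "rs1", "C", "T")))
  snps <- suppressMessages(read_vcf_snps(vcf_dup))
  expect_true(all(snps$multi_mapped))
  expect_equal(nrow(snps), 2L)      # both placements kept
})

test_that("miRNA set and UTR readers validate their inputs", {
  gmt <- write_lines_tmp(c("setA\tdesc\tmir-1\tmir-2",
                           "setB\tdesc",
                           "setC\tdesc\tmir-3"), ".gmt")
  expect_warning(sets <- read_mirna_sets(gmt), "empty")
  expect_named(sets, c("setA", "setC"))
  expect_equal(sets$setA, c("mir-1", "mir-2"))

  fa <- make_fasta(c(g1 = "ACGTACGT", g2 = "ACGTNNNN"))
  expect_warning(utrs <- read_utr_fasta(fa), "non-ACGT")
  expect_equal(names(utrs), "g1")

  fa_dup <- make_fasta(c(g1 = "ACGT", g1 = "ACGT"))
  expect_error(suppressWarnings(read_utr_fasta(fa_dup)), "duplicated")
})

test_that("generator output round-trips through the readers unchanged", {
  dir <- small_sim_dir()
  gt <- jsonlite::fromJSON(file.path(dir, "ground_truth.json"))
  ann <- read_mirna_gff(file.path(dir, "mirna.gff3"))
  mat <- attach_sequences(ann$matures, file.path(dir, "mature.fa"))

  expect_equal(ann$precursors[order(ann$precursors$id), ],
               gt$precursors[order(gt$precursors$id),
                             names(ann$precursors)],
               ignore_attr = TRUE)
  expect_equal(mat[order(mat$id), ],
               gt$matures[order(gt$matures$id), names(mat)],
               ignore_attr = TRUE)

  snps <- suppressMessages(read_vcf_snps(file.path(dir, "snps.vcf")))
  expect_setequal(snps$rsid, gt$snps$rsid)
  m <- match(gt$snps$rsid, snps$rsid)
  expect_equal(snps$pos[m], gt$snps$pos)
  expect_equal(snps$alts[m], gt$snps$alts)
})
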