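make_mature <- function(id, chrom, start, end, strand, seq) {
  data.frame(id = id, name = id, precursor_id = paste0("P", id),
             chrom = chrom, start = start, end = end, strand = strand,
             sequence = seq, stringsAsFactors = FALSE)
}

test_that("seed intervals are strand-aware, 7 bp, and carry positions 2-8", {
  m <- rbind(
    make_mature("plus", "chr1", 1000, 1021, "+", "UGAGGUAGUAGGUUGUAUAGUU"),
    make_mature("minus", "chr1", 1000, 1021, "-", "UGAGGUAGUAGGUUGUAUAGUU"))
  seeds <- compute_seed_intervals(m)
  expect_equal(seeds$start, c(1001, 1014))
  expect_equal(seeds$end, c(1007, 1020))
  expect_equal(seeds$end - seeds$start + 1, c(7, 7))
  expect_equal(seeds$seed_sequence, c("GAGGUAG", "GAGGUAG"))
})

test_that("strand mirror: reflecting coordinates and flipping strand mirrors the seed", {
  withr::local_seed(101)
  for (i in 1:50) {
    start <- sample(1000:100000, 1)
    end <- start + 21
    seq <- paste(sample(c("A", "C", "G", "U"), 22, TRUE), collapse = "")
    L <- 200000  # reflection axis
    fwd <- make_mature("f", "chr1", start, end, "+", seq)
    rev <- make_mature("r", "chr1", L - end, L - start, "-", seq)
    sf <- compute_seed_intervals(fwd)
    sr <- compute_seed_intervals(rev)
    expect_equal(sr$start, L - sf$end)
    expect_equal(sr$end, L - sf$start)
    # a SNP at mirrored positions lands at the same seed offset
    off <- sample(1:7, 1)
    pos_f <- sf$start + off - 1
    pos_r <- L - pos_f
    expect_equal(sr$end - pos_r + 1, off)
  }
})

test_that("SNPs project into seeds with strand-aware offsets and allele complementation", {
  m <- rbind(
    make_mature("plus", "chr1", 1000, 1021, "+", "UGAGGUAGUAGGUUGUAUAGUU"),
    make_mature("minus", "chr2", 1000, 1021, "-", "UGAGGUAGUAGGUUGUAUAGUU"))
  seeds <- compute_seed_intervals(m)
  # + strand: seed GAGGUAG at 1001-1007; position 1003 is offset 3, base G
  # - strand: seed at 1014-1020, offset 3 sits at 1018, miRNA base G, so the
  #   forward-strand REF is its complement C
  snps <- data.frame(rsid = c("rsP", "rsM"), chrom = c("chr1", "chr2"),
                     pos = c(1003, 1018), ref = c("G", "C"),
                     alts = c("A", "T"), maf = c(0.01, 0.2),
                     stringsAsFactors = FALSE)
  ss <- map_snps_to_seeds(seeds, m, snps)
  expect_equal(nrow(ss), 2L)
  expect_equal(ss$seed_offset, c(3L, 3L))
  expect_equal(ss$ref_seed, c("GAGGUAG", "GAGGUAG"))
  # + strand ALT A stays A; - strand ALT T complements to A
  expect_equal(ss$alt_base, c("A", "A"))
  expect_equal(ss$derived_seed, c("GAAGUAG", "GAAGUAG"))
  expect_equal(ss$rarity, c("rare", "common"))
  expect_equal(attr(ss, "n_ref_mismatch"), 0L)
})

test_that("reference-mismatch SNPs are excluded with a warning, not substituted", {
  m <- make_mature("plus", "chr1", 1000, 1021, "+", "UGAGGUAGUAGGUUGUAUAGUU")
  seeds <- compute_seed_intervals(m)
  snps <- data.frame(rsid = "rsX", chrom = "chr1", pos = 1003, ref = "T",
                     alts = "C", maf = NA_real_, stringsAsFactors = FALSE)
  expect_warning(ss <- map_snps_to_seeds(seeds, m, snps),
                 "reference mismatch")
  expect_equal(nrow(ss), 0L)
  expect_equal(attr(ss, "n_ref_mismatch"), 1L)
})

test_that("each derived seed differs from the reference seed exactly at its offset", {
  dir <- small_sim_dir()
  ann <- read_mirna_gff(file.path(dir, "mirna.gff3"))
  mat <- attach_sequences(ann$matures, file.path(dir, "mature.fa"))
  snps <- suppressMessages(read_vcf_snps(file.path(dir, "snps.vcf")))
  ss <- map_snps_to_seeds(compute_seed_intervals(mat), mat, snps)
  expect_gt(nrow(ss), 0)
  for (i in seq_len(nrow(ss))) {
    rebuilt <- ss$ref_seed[i]
    substr(rebuilt, ss$seed_offset[i], ss$seed_offset[i]) <- ss$alt_base[i]
    expect_identical(rebuilt, ss$derived_seed[i])
    diffs <- which(strsplit(ss$ref_seed[i], "")[[1]] !=
                     strsplit(ss$derived_seed[i], "")[[1]])
    expect_identical(diffs, ss$seed_offset[i])
  }
})

test_that("interval-indexed mapping agrees with the naive double-loop oracle", {
  withr::local_seed(202)
  n_seeds <- 100
  starts <- sample(seq(1000, 5e6, by = 40), n_seeds)
  m <- do.call(rbind, lapply(seq_len(n_seeds), function(i) {
    make_mature(paste0("M", i), sample(c("chrA", "chrB"), 1),
                starts[i], starts[i] + 21, sample(c("+", "-"), 1),
                paste(sample(c("A", "C", "G", "U"), 22, TRUE), collapse = ""))
  }))
  seeds <- compute_seed_intervals(m)
  n_snps <- 1000
  # half the SNPs thrown near seeds (matching chromosome) so plenty overlap,
  # half anywhere on a random chromosome
  near <- sample(nrow(seeds), n_snps / 2, TRUE)
  pos <- c(seeds$start[near] + sample(-3:9, n_snps / 2, TRUE),
           sample(5e6, n_snps / 2))
  snps <- data.frame(rsid = paste0("rs", seq_len(n_snps)),
                     chrom = c(seeds$chrom[near],
                               sample(c("chrA", "chrB"), n_snps / 2, TRUE)),
                     pos = pos, ref = "A", alts = "G", maf = NA_real_,
                     stringsAsFactors = FALSE)
  # give every SNP the correct forward-strand REF so none are excluded
  hits <- oracle_snp_seed_pairs(seeds, snps)
  for (h in strsplit(hits, " ")) {
    i <- match(h[1], snps$rsid); j <- match(h[2], seeds$mature_id)
    off <- if (seeds$strand[j] == "+") snps$pos[i] - seeds$start[j] + 1 else
      seeds$end[j] - snps$pos[i] + 1
    b <- chartr("U", "T", substr(seeds$seed_sequence[j], off, off))
    snps$ref[i] <- if (seeds$strand[j] == "-") chartr("ACGT", "TGCA", b) else b
  }
  snps$alts <- vapply(snps$ref, function(r) setdiff(c("A","C","G","T"), r)[1],
                      character(1))
  ss <- suppressWarnings(map_snps_to_seeds(seeds, m, snps))
  got <- sort(unique(paste(ss$rsid, ss$mature_id)))
  # the oracle set may include pairs excluded as reference-mismatch when one
  # rsid overlaps two seeds demanding different REF bases; drop those
  mismatching <- attr(ss, "n_ref_mismatch")
  expect_equal(length(got), length(hits) - mismatching)
  expect_true(all(got %in% hits))
  expect_gt(length(got), 200)  # the instance genuinely exercises overlap
})

test_that("rarity classification uses a strict 5% threshold", {
  expect_equal(classify_rarity(c(0.049, 0.05, NA, 0, 0.5)),
               c("rare", "common", "unknown", "rare", "common"))
  expect_equal(classify_rarity(0.09, threshold = 0.1), "rare")
})

test_that("snp_count_distribution counts distinct rsIDs over all matures", {
  matures <- data.frame(id = paste0("M", 1:5))
  ss <- data.frame(
    mature_id = c("M1", "M1", "M1", "M2", "M2", "M3"),
    rsid = c("rs1", "rs1", "rs2", "rs3", "rs4", "rs5"))  # rs1 multiallelic
  d <- snp_count_distribution(ss, matures)
  expect_equal(d, c("0" = 2L, "1" = 1L, "2" = 2L))
  expect_equal(sum(d), nrow(matures))
  expect_equal(sum(as.integer(names(d)) * d), 5L)  # distinct (mature, rsid)

  none <- snp_count_distribution(ss[0, ], matures)
  expect_equal(none, c("0" = 5L))
})
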