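# Fixture writers and independent brute-force oracles shared by the tests.

write_lines_tmp <- function(lines, ext) {
  path <- tempfile(fileext = ext)
  writeLines(lines, path)
  path
}

gff_line <- function(chrom, type, start, end, strand, id, name,
                     derives = NULL) {
  attrs <- paste0("ID=", id, ";Name=", name,
                  if (!is.null(derives)) paste0(";Derives_from=", derives))
  sprintf("%s\t.\t%s\t%d\t%d\t.\t%s\t.\t%s", chrom, type, start, end,
          strand, attrs)
}

make_gff <- function(lines) write_lines_tmp(c("##gff-version 3", lines), ".gff3")

make_fasta <- function(seqs) {
  write_lines_tmp(paste0(">", names(seqs), "\n", unname(seqs)), ".fa")
}

make_vcf <- function(records,
                     info_header = "##INFO=<ID=AF,Number=A,Type=Float,Description=\"AF\">") {
  write_lines_tmp(c("##fileformat=VCFv4.2", info_header,
                    "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO",
                    records), ".vcf")
}

vcf_rec <- function(chrom, pos, id, ref, alt, info = ".") {
  sprintf("%s\t%d\t%s\t%s\t%s\t.\t.\t%s", chrom, pos, id, ref, alt, info)
}

# a small but complete annotation: precursors with sequences attached
tiny_annotation <- function() {
  gff <- make_gff(c(
    gff_line("chr1", "miRNA_primary_transcript", 1000, 1080, "+", "P1", "mir-1"),
    gff_line("chr1", "miRNA", 1000, 1021, "+", "M1", "mir-1-5p", "P1"),
    gff_line("chr1", "miRNA", 1059, 1080, "+", "M2", "mir-1-3p", "P1"),
    gff_line("chr2", "miRNA_primary_transcript", 5000, 5080, "-", "P2", "mir-2"),
    gff_line("chr2", "miRNA", 5059, 5080, "-", "M3", "mir-2-5p", "P2")))
  fa <- make_fasta(c("mir-1-5p" = "UGAGGUAGUAGGUUGUAUAGUU",
                     "mir-1-3p" = "CUAUACAAUCUACUGUCUUUCC",
                     "mir-2-5p" = "ACGUACGUACGUACGUACGUAC"))
  ann <- read_mirna_gff(gff)
  list(precursors = ann$precursors,
       matures = attach_sequences(ann$matures, fa))
}

# brute-force oracles -------------------------------------------------------

# transitive closure over all same-chrom same-strand pairs with edge gap
# within max_gap (connected components via igraph)
oracle_cluster_sets <- function(precursors, max_gap = 10000) {
  n <- nrow(precursors)
  edges <- matrix(integer(0), ncol = 2)
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      if (precursors$chrom[i] != precursors$chrom[j]) next
      if (precursors$strand[i] != precursors$strand[j]) next
      gap <- max(0, max(precursors$start[i], precursors$start[j]) -
                   min(precursors$end[i], precursors$end[j]) - 1)
      if (gap <= max_gap) edges <- rbind(edges, c(i, j))
    }
  }
  g <- igraph::make_empty_graph(n, directed = FALSE)
  if (nrow(edges)) g <- igraph::add_edges(g, t(edges))
  comp <- igraph::components(g)$membership
  sets <- split(precursors$id, comp)
  sets <- sets[lengths(sets) >= 2]
  unname(lapply(sets, sort))
}

# naive per-seed scan of every SNP (the exhaustive pairing oracle)
oracle_snp_seed_pairs <- function(seeds, snps) {
  out <- character(0)
  for (j in seq_len(nrow(seeds))) {
    for (i in seq_len(nrow(snps))) {
      if (snps$chrom[i] == seeds$chrom[j] &&
          snps$pos[i] >= seeds$start[j] && snps$pos[i] <= seeds$end[j]) {
        out <- c(out, paste(snps$rsid[i], seeds$mature_id[j]))
      }
    }
  }
  sort(out)
}

# all (possibly overlapping) occurrences of a pattern by sliding window
oracle_match_positions <- function(pattern, utr) {
  w <- nchar(pattern)
  if (nchar(utr) < w) return(integer(0))
  pos <- seq_len(nchar(utr) - w + 1)
  pos[vapply(pos, function(i) substr(utr, i, i + w - 1) == pattern,
             logical(1))]
}

random_seed_rna <- function() {
  paste(sample(c("A", "C", "G", "U"), 7, replace = TRUE), collapse = "")
}

# a fast small simulation shared by several test files (built once)
small_sim_dir <- local({
  dir <- NULL
  function() {
    if (is.null(dir)) {
      dir <<- file.path(tempdir(), "mirseedclust-small-sim")
      cfg <- simulation_config(seed = 42, n_precursors = 60,
                               n_seed_snps = 60, n_background_snps = 20,
                               n_overlap_snps_per_group = 6, n_genes = 180)
      simulate_seed_snp_data(cfg, dir)
    }
    dir
  }
})
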