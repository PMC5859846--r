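#' Genomic seed intervals of mature miRNAs
#'
#' The seed of a mature miRNA is nucleotides 2-8 from its 5' end. On the `+`
#' strand the 5' end sits at the annotated `start`, so the seed occupies
#' `[start + 1, start + 7]`; on the `-` strand the 5' end sits at the
#' annotated `end`, so the seed occupies `[end - 7, end - 1]`. Every seed
#' interval is exactly 7 bp regardless of strand. The seed sequence is the
#' substring of the mature sequence from base 2 to base 8 (5'->3', RNA).
#'
#' @param matures Mature miRNA data.frame with sequences attached
#'   ([attach_sequences()]).
#' @return data.frame with columns `mature_id`, `chrom`, `start`, `end`,
#'   `strand`, `seed_sequence` (7 nt RNA).
#' @export
compute_seed_intervals <- function(matures) {
  if (any(is.na(matures$sequence))) {
    stop("compute_seed_intervals: matures must have sequences attached")
  }
  if (any(nchar(matures$sequence) < 8L)) {
    stop("compute_seed_intervals: mature shorter than 8 nt has no seed")
  }
  plus <- matures$strand == "+"
  data.frame(
    mature_id = matures$id,
    chrom = matures$chrom,
    start = ifelse(plus, matures$start + 1L, matures$end - 7L),
    end = ifelse(plus, matures$start + 7L, matures$end - 1L),
    strand = matures$strand,
    seed_sequence = substr(matures$sequence, 2L, 8L),
    stringsAsFactors = FALSE
  )
}

#' Classify SNPs as rare or common by minor allele frequency
#'
#' Rare means strictly below the threshold (default 5%); a missing MAF gives
#' `unknown` so the SNP stays in the mapping but drops out of rare/common
#' tabulations.
#'
#' @param maf Numeric vector of minor allele frequencies (NA allowed).
#' @param threshold Rarity threshold; the comparison is strict (`<`).
#' @return Character vector over `rare`, `common`, `unknown`.
#' @export
classify_rarity <- function(maf, threshold = 0.05) {
  ifelse(is.na(maf), "unknown", ifelse(maf < threshold, "rare", "common"))
}

#' Map SNPs into miRNA seed regions
#'
#' Intersects SNP positions with the seed intervals and projects the
#' forward-strand VCF alleles into miRNA sense. The offset within the seed is
#' strand-aware: `pos - start + 1` on `+`, `end - pos + 1` on `-` (1..7,
#' 5'->3' in the miRNA; mature position = offset + 1). On the `-` strand the
#' single-base REF/ALT alleles are complemented (not reverse-complemented)
#' and `T` becomes `U`. A (SNP, seed) pair is emitted only when the projected
#' REF base equals the seed base at that offset; mismatching pairs signal an
#' annotation/genome-build inconsistency and are excluded with a warning
#' (count available as `attr(result, "n_ref_mismatch")`).
#'
#' One row is emitted per (SNP placement, overlapping seed, ALT allele); a
#' multiallelic SNP therefore contributes one row per ALT but still counts as
#' a single rsID in [snp_count_distribution()].
#'
#' @param seeds Seed intervals from [compute_seed_intervals()].
#' @param matures Mature miRNA data.frame (for metadata joins; may be the
#'   same object the seeds were computed from).
#' @param snps SNP data.frame from [read_vcf_snps()].
#' @param maf_threshold Rarity threshold passed to [classify_rarity()].
#' @return data.frame with columns `rsid`, `mature_id`, `chrom`,
#'   `genomic_pos`, `strand`, `seed_offset`, `ref_seed`, `alt_fwd` (forward
#'   strand ALT base), `alt_base` (ALT projected into miRNA sense),
#'   `derived_seed`, `maf`, `rarity`.
#' @export
map_snps_to_seeds <- function(seeds, matures, snps, maf_threshold = 0.05) {
  empty <- data.frame(rsid = character(), mature_id = character(),
                      chrom = character(), genomic_pos = integer(),
                      strand = character(), seed_offset = integer(),
                      ref_seed = character(), alt_fwd = character(),
                      alt_base = character(), derived_seed = character(),
                      maf = numeric(), rarity = character(),
                      stringsAsFactors = FALSE)
  if (nrow(seeds) == 0L || nrow(snps) == 0L) {
    attr(empty, "n_ref_mismatch") <- 0L
    return(empty)
  }

  seed_gr <- GenomicRanges::GRanges(seeds$chrom,
                                    IRanges::IRanges(seeds$start, seeds$end))
  snp_gr <- GenomicRanges::GRanges(snps$chrom,
                                   IRanges::IRanges(snps$pos, snps$pos))
  hits <- GenomicRanges::findOverlaps(snp_gr, seed_gr, ignore.strand = TRUE)
  qi <- S4Vectors::queryHits(hits)
  si <- S4Vectors::subjectHits(hits)
  if (!length(qi)) {
    attr(empty, "n_ref_mismatch") <- 0L
    return(empty)
  }

  strand <- seeds$strand[si]
  minus <- strand == "-"
  offset <- ifelse(minus, seeds$end[si] - snps$pos[qi] + 1L,
                   snps$pos[qi] - seeds$start[si] + 1L)
  ref_seed <- seeds$seed_sequence[si]
  seed_base <- substr(ref_seed, offset, offset)
  proj_ref <- ifelse(minus, complement_base(snps$ref[qi], rna = TRUE),
                     dna_to_rna(snps$ref[qi]))

  ok <- proj_ref == seed_base
  n_mismatch <- sum(!ok)
  if (n_mismatch > 0L) {
    warning("map_snps_to_seeds: excluded ", n_mismatch,
            " (SNP, seed) pair(s) whose projected REF base does not match ",
            "the annotated seed (reference mismatch): ",
            paste(utils::head(unique(snps$rsid[qi[!ok]]), 5), collapse = ", "))
  }

  qi <- qi[ok]; si <- si[ok]
  offset <- offset[ok]; ref_seed <- ref_seed[ok]; minus <- minus[ok]

  alt_list <- strsplit(snps$alts[qi], ",", fixed = TRUE)
  n_alt <- lengths(alt_list)
  rep_i <- rep(seq_along(qi), n_alt)
  alt_fwd <- unlist(alt_list, use.names = FALSE)
  alt_base <- ifelse(minus[rep_i], complement_base(alt_fwd, rna = TRUE),
                     dna_to_rna(alt_fwd))
  derived_seed <- mapply(replace_base, ref_seed[rep_i], offset[rep_i],
                         alt_base, USE.NAMES = FALSE)

  maf <- snps$maf[qi][rep_i]
  out <- data.frame(
    rsid = snps$rsid[qi][rep_i],
    mature_id = seeds$mature_id[si][rep_i],
    chrom = seeds$chrom[si][rep_i],
    genomic_pos = snps$pos[qi][rep_i],
    strand = seeds$strand[si][rep_i],
    seed_offset = offset[rep_i],
    ref_seed = ref_seed[rep_i],
    alt_fwd = alt_fwd,
    alt_base = alt_base,
    derived_seed = derived_seed,
    maf = maf,
    rarity = classify_rarity(maf, maf_threshold),
    stringsAsFactors = FALSE
  )
  rownames(out) <- NULL
  attr(out, "n_ref_mismatch") <- n_mismatch
  out
}

#' Per-miRNA seed-SNP count distribution
#'
#' Tabulates, over all matures (including those with no SNP), how many carry
#' exactly k distinct seed rsIDs. The weighted sum over k equals the number
#' of (mature, rsID) pairs; the sum of the counts equals the number of
#' matures.
#'
#' @param seed_snps Seed SNP data.frame from [map_snps_to_seeds()].
#' @param matures Mature miRNA data.frame defining the full universe.
#' @return Named integer vector; names are k = 0, 1, 2, ...
#' @export
snp_count_distribution <- function(seed_snps, matures) {
  pairs <- unique(seed_snps[, c("mature_id", "rsid")])
  per_mature <- table(factor(pairs$mature_id, levels = matures$id))
  dist <- table(factor(as.integer(per_mature),
                       levels = 0:max(0L, as.integer(per_mature))))
  out <- as.integer(dist)
  names(out) <- names(dist)
  out
}
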