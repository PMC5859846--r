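# Deterministic synthetic-data generator. Emits a small genome of miRNA
# precursors (some in planted clusters straddling the 10 kb rule), mature
# sequences, seed and background SNPs with chosen MAF structure, 3'UTRs with
# planted allele-dependent seed-match sites, and a miRNA-set file with one
# planted enriched set -- plus a ground-truth JSON that verify_ground_truth()
# re-checks through the ordinary readers.

#' Configuration for the synthetic-data generator
#'
#' Defaults describe the study conditions the pipeline is exercised under:
#' a scaled-down genome whose proportions mirror the real miRNA annotation
#' (about 20% of precursors clustered, two matures per precursor, about 44%
#' of matures carrying a seed SNP, 97.5% of seed SNPs rare), intra-cluster
#' gaps of 0.5-9.5 kb against inter-locus gaps of 50-200 kb so the 10 kb
#' clustering rule is exercised on both sides, a planted clustered-vs-
#' nonclustered seed-SNP odds ratio of 2, and an overlap cohort whose
#' clustered SNPs have high planted target-set overlap (many common targets)
#' while nonclustered SNPs have low overlap.
#'
#' @param seed Integer RNG seed; the entire simulation is a pure function of
#'   it.
#' @param n_chromosomes,n_precursors Genome size.
#' @param cluster_fraction Fraction of precursors placed into planted
#'   clusters.
#' @param cluster_size_range Members per planted cluster (inclusive range).
#' @param intra_cluster_gap_range Gap in bp between neighbouring cluster
#'   members; must stay at or below 10 kb.
#' @param inter_locus_gap_range Gap in bp between independent loci; must
#'   exceed 10 kb.
#' @param matures_per_precursor 1 (5p only) or 2 (5p and 3p).
#' @param precursor_length_range,mature_length Locus geometry in bp.
#' @param n_seed_snps,n_background_snps SNP counts inside seeds / elsewhere.
#' @param maf_rare_fraction Fraction of SNPs drawn as rare (MAF < 5%).
#' @param maf_missing_fraction Fraction of SNPs with no frequency record.
#' @param multiallelic_fraction Fraction of seed SNPs given two ALT alleles.
#' @param enrichment_odds_ratio Planted odds that a clustered mature carries
#'   a seed SNP relative to a nonclustered one.
#' @param n_overlap_snps_per_group Number of clustered and of nonclustered
#'   biallelic seed SNPs given planted UTR target sites (the overlap
#'   cohort).
#' @param planted_overlap_spec List with `clustered` and `nonclustered`
#'   entries, each holding integer ranges `n_ref_only`, `n_der_only`,
#'   `n_common` from which the per-SNP planted target counts are drawn.
#' @param n_genes Total genes in the UTR collection (planted + background).
#' @param utr_length_range UTR length in bp.
#' @param n_mirna_sets Number of annotation sets (one planted enriched set
#'   plus decoys).
#' @param max_screen_attempts Rejection-sampling bound per UTR when
#'   screening out accidental seed matches.
#' @return A `simulation_config` list.
#' @export
simulation_config <- function(seed = 1L,
                              n_chromosomes = 3L,
                              n_precursors = 400L,
                              cluster_fraction = 0.2,
                              cluster_size_range = c(2L, 4L),
                              intra_cluster_gap_range = c(500L, 9500L),
                              inter_locus_gap_range = c(50000L, 200000L),
                              matures_per_precursor = 2L,
                              precursor_length_range = c(60L, 110L),
                              mature_length = 22L,
                              n_seed_snps = 350L,
                              n_background_snps = 100L,
                              maf_rare_fraction = 0.975,
                              maf_missing_fraction = 0.02,
                              multiallelic_fraction = 0.05,
                              enrichment_odds_ratio = 2,
                              n_overlap_snps_per_group = 20L,
                              planted_overlap_spec = list(
                                clustered = list(n_ref_only = 1:3,
                                                 n_der_only = 1:3,
                                                 n_common = 4:8),
                                nonclustered = list(n_ref_only = 3:6,
                                                    n_der_only = 3:6,
                                                    n_common = 0:2)),
                              n_genes = 600L,
                              utr_length_range = c(150L, 300L),
                              n_mirna_sets = 8L,
                              max_screen_attempts = 1000L) {
  cfg <- as.list(environment())
  stopifnot(cfg$n_chromosomes >= 1, cfg$n_precursors >= 2,
            cfg$cluster_fraction >= 0, cfg$cluster_fraction <= 1,
            cfg$maf_rare_fraction >= 0, cfg$maf_rare_fraction <= 1,
            cfg$maf_missing_fraction >= 0, cfg$maf_missing_fraction <= 1,
            cfg$multiallelic_fraction >= 0, cfg$multiallelic_fraction <= 1,
            cfg$matures_per_precursor %in% c(1L, 2L),
            cfg$n_seed_snps >= 1, cfg$n_genes >= 1,
            cfg$enrichment_odds_ratio > 0,
            all(cfg$cluster_size_range >= 2L),
            cfg$mature_length >= 8L,
            cfg$precursor_length_range[1] >= 2 * cfg$mature_length + 16L)
  if (cfg$intra_cluster_gap_range[2] > 10000L) {
    stop("simulation_config: intra_cluster_gap_range must stay <= 10 kb ",
         "so planted clusters satisfy the clustering rule")
  }
  if (cfg$inter_locus_gap_range[1] <= 10000L) {
    stop("simulation_config: inter_locus_gap_range must exceed 10 kb ",
         "so independent loci never merge")
  }
  max_genes_per_snp <- max(cfg$planted_overlap_spec$clustered$n_ref_only) +
    max(cfg$planted_overlap_spec$clustered$n_der_only) +
    max(cfg$planted_overlap_spec$clustered$n_common)
  max_genes_per_snp <- max(max_genes_per_snp,
    max(cfg$planted_overlap_spec$nonclustered$n_ref_only) +
      max(cfg$planted_overlap_spec$nonclustered$n_der_only) +
      max(cfg$planted_overlap_spec$nonclustered$n_common))
  if (2L * cfg$n_overlap_snps_per_group * max_genes_per_snp > cfg$n_genes) {
    stop("simulation_config: planted target sites could exceed the UTR ",
         "collection capacity (n_genes too small)")
  }
  if (cfg$utr_length_range[1] < 8L * (max_genes_per_snp > 0) * 2L + 30L) {
    stop("simulation_config: utr_length_range too short for planted sites")
  }
  structure(cfg, class = "simulation_config")
}

# sample() that never treats a length-1 vector as 1:n
resample <- function(x, n = 1L, ...) x[sample.int(length(x), n, ...)]

sim_maf <- function(n, cfg) {
  maf <- ifelse(stats::runif(n) < cfg$maf_rare_fraction,
                0.049 * stats::rbeta(n, 1, 3) + 1e-4,
                stats::runif(n, 0.05, 0.35))
  maf[stats::runif(n) < cfg$maf_missing_fraction] <- NA_real_
  maf
}

# allele patterns relevant under the default enabled site types: the 7mer-m8
# core M (whose absence also rules out the 8mer) and the 7mer-A1 heptamer
allele_patterns <- function(seed) {
  m <- reverse_complement_dna(rna_to_dna(seed))
  c(m, paste0(substr(m, 2L, 7L), "A"))
}

#' Generate a synthetic dataset with known ground truth
#'
#' Writes `mirna.gff3`, `mature.fa`, `snps.vcf`, `utrs.fa`,
#' `mirna_sets.gmt` and `ground_truth.json` into `output_dir`. The output
#' is byte-identical across runs with the same configuration. Seed SNPs are
#' placed at uniformly chosen seed offsets 1-7 on both strands; the UTRs of
#' the overlap cohort contain exactly the planted numbers of
#' reference-only / derived-only / common seed-match sites (sites injected
#' as 7mer-m8 matches into background sequence rejection-sampled to contain
#' no accidental matches for any cohort allele).
#'
#' @param config A [simulation_config()].
#' @param output_dir Directory to write into (created if needed).
#' @return The ground truth (class `seed_sim_truth`), invisibly; also
#'   serialised as `ground_truth.json`.
#' @export
simulate_seed_snp_data <- function(config, output_dir) {
  if (!inherits(config, "simulation_config")) {
    stop("simulate_seed_snp_data: config must come from simulation_config()")
  }
  dir.create(output_dir, showWarnings = FALSE, recursive = TRUE)
  gt <- withr::with_seed(config$seed, sim_build(config))
  sim_write(gt, config, output_dir)
  gt$dir <- output_dir
  invisible(gt)
}

sim_build <- function(cfg) {
  ## --- genome layout -----------------------------------------------------
  n_clustered <- round(cfg$cluster_fraction * cfg$n_precursors)
  sizes <- integer(0)
  while (sum(sizes) < n_clustered - min(cfg$cluster_size_range) + 1L) {
    sizes <- c(sizes, resample(seq(cfg$cluster_size_range[1],
                                   cfg$cluster_size_range[2])))
  }
  if (sum(sizes) > n_clustered) {
    sizes[length(sizes)] <- sizes[length(sizes)] - (sum(sizes) - n_clustered)
    if (sizes[length(sizes)] < 2L) sizes <- sizes[-length(sizes)]
  }
  n_clustered <- sum(sizes)
  n_single <- cfg$n_precursors - n_clustered

  loci <- data.frame(size = c(sizes, rep(1L, n_single)))
  loci$cluster_id <- c(sprintf("sim_cluster_%02d", seq_along(sizes)),
                       rep(NA_character_, n_single))
  loci <- loci[sample.int(nrow(loci)), , drop = FALSE]
  loci$chrom <- paste0("chr", sample.int(cfg$n_chromosomes, nrow(loci),
                                         replace = TRUE))
  loci$strand <- resample(c("+", "-"), nrow(loci), replace = TRUE)

  pre <- vector("list", nrow(loci))
  cursor <- stats::setNames(rep(10000L, cfg$n_chromosomes),
                            paste0("chr", seq_len(cfg$n_chromosomes)))
  k <- 0L
  for (i in seq_len(nrow(loci))) {
    for (j in seq_len(loci$size[i])) {
      k <- k + 1L
      len <- resample(seq(cfg$precursor_length_range[1],
                          cfg$precursor_length_range[2]))
      s <- cursor[[loci$chrom[i]]]
      pre[[k]] <- data.frame(
        id = sprintf("PMIR%04d", k), name = sprintf("sim-mir-%d", k),
        chrom = loci$chrom[i], start = s, end = s + len - 1L,
        strand = loci$strand[i], cluster_id = loci$cluster_id[i],
        stringsAsFactors = FALSE)
      gap <- if (j < loci$size[i]) {
        resample(seq(cfg$intra_cluster_gap_range[1],
                     cfg$intra_cluster_gap_range[2]))
      } else {
        resample(seq(cfg$inter_locus_gap_range[1],
                     cfg$inter_locus_gap_range[2]))
      }
      cursor[[loci$chrom[i]]] <- s + len + gap
    }
  }
  pre <- do.call(rbind, pre)
  chrom_lengths <- as.list(cursor + 20000L)

  ## --- matures -----------------------------------------------------------
  ml <- cfg$mature_length
  arms <- if (cfg$matures_per_precursor == 2L) c("5p", "3p") else "5p"
  mat <- do.call(rbind, lapply(seq_len(nrow(pre)), function(i) {
    do.call(rbind, lapply(arms, function(arm) {
      if (arm == "5p") {
        s <- pre$start[i]; e <- pre$start[i] + ml - 1L
      } else {
        s <- pre$end[i] - ml + 1L; e <- pre$end[i]
      }
      data.frame(id = sprintf("MMAT%04d-%s", i, arm),
                 name = sprintf("%s-%s", pre$name[i], arm),
                 precursor_id = pre$id[i], chrom = pre$chrom[i],
                 start = s, end = e, strand = pre$strand[i],
                 sequence = random_rna(ml), stringsAsFactors = FALSE)
    }))
  }))
  mat_clustered <- !is.na(pre$cluster_id[match(mat$precursor_id, pre$id)])

  ## --- seed SNP placement (enrichment-weighted) --------------------------
  weights <- ifelse(mat_clustered, cfg$enrichment_odds_ratio, 1)
  free_offsets <- lapply(seq_len(nrow(mat)), function(i) 1:7)
  snp_mature <- integer(cfg$n_seed_snps)
  snp_offset <- integer(cfg$n_seed_snps)
  for (s in seq_len(cfg$n_seed_snps)) {
    repeat {
      i <- sample.int(nrow(mat), 1L, prob = weights)
      if (length(free_offsets[[i]])) break
    }
    o <- resample(free_offsets[[i]])
    free_offsets[[i]] <- setdiff(free_offsets[[i]], o)
    snp_mature[s] <- i
    snp_offset[s] <- o
  }

  seed_seq <- substr(mat$sequence[snp_mature], 2L, 8L)
  seed_base <- substr(seed_seq, snp_offset, snp_offset)
  minus <- mat$strand[snp_mature] == "-"
  pos <- ifelse(minus, mat$end[snp_mature] - snp_offset,
                mat$start[snp_mature] + snp_offset)
  ref_fwd <- ifelse(minus, complement_base(rna_to_dna(seed_base)),
                    rna_to_dna(seed_base))
  n_alts <- 1L + (stats::runif(cfg$n_seed_snps) < cfg$multiallelic_fraction)
  alts <- vapply(seq_len(cfg$n_seed_snps), function(s) {
    paste(resample(setdiff(DNA_BASES, ref_fwd[s]), n_alts[s]), collapse = ",")
  }, character(1))

  rs_pool <- sample(1000000:9999999, cfg$n_seed_snps + cfg$n_background_snps)
  seed_snps <- data.frame(
    rsid = sprintf("rs%07d", rs_pool[seq_len(cfg$n_seed_snps)]),
    chrom = mat$chrom[snp_mature], pos = pos, ref = ref_fwd, alts = alts,
    maf = sim_maf(cfg$n_seed_snps, cfg),
    is_seed = TRUE, mature_id = mat$id[snp_mature],
    seed_offset = snp_offset, stringsAsFactors = FALSE)
  seed_snps$rarity <- classify_rarity(seed_snps$maf)

  ## --- background SNPs (outside every seed interval) ---------------------
  seed_start <- ifelse(mat$strand == "+", mat$start + 1L, mat$end - 7L)
  seed_pos <- paste(rep(mat$chrom, each = 7L),
                    rep(seed_start, each = 7L) + 0:6)
  taken <- c(seed_pos, paste(seed_snps$chrom, seed_snps$pos))
  bg <- vector("list", cfg$n_background_snps)
  for (s in seq_len(cfg$n_background_snps)) {
    repeat {
      chrom <- paste0("chr", sample.int(cfg$n_chromosomes, 1L))
      p <- sample.int(chrom_lengths[[chrom]], 1L)
      if (!paste(chrom, p) %in% taken) break
    }
    taken <- c(taken, paste(chrom, p))
    ref <- resample(DNA_BASES)
    bg[[s]] <- data.frame(
      rsid = sprintf("rs%07d", rs_pool[cfg$n_seed_snps + s]),
      chrom = chrom, pos = p, ref = ref,
      alts = resample(setdiff(DNA_BASES, ref)),
      maf = sim_maf(1L, cfg), is_seed = FALSE,
      mature_id = NA_character_, seed_offset = NA_integer_,
      stringsAsFactors = FALSE)
  }
  bg <- do.call(rbind, bg)
  bg$rarity <- classify_rarity(bg$maf)
  snps <- rbind(seed_snps, bg)

  ## --- overlap cohort ----------------------------------------------------
  cohort <- sim_pick_cohort(cfg, seed_snps, mat_clustered,
                            match(seed_snps$mature_id, mat$id), mat)
  utr <- sim_build_utrs(cfg, cohort, mat)

  ## --- miRNA annotation sets ---------------------------------------------
  with_snp <- mat$name[mat$id %in% seed_snps$mature_id]
  clustered_with_snp <- intersect(with_snp, mat$name[mat_clustered])
  planted_members <- unique(c(
    resample(clustered_with_snp, min(25L, length(clustered_with_snp))),
    resample(mat$name, 5L)))
  sets <- c(list(planted_pathway = planted_members),
            stats::setNames(
              lapply(seq_len(cfg$n_mirna_sets - 1L), function(i)
                resample(mat$name, min(30L, nrow(mat)))),
              sprintf("decoy_pathway_%02d", seq_len(cfg$n_mirna_sets - 1L))))

  structure(list(
    config = unclass(cfg),
    chrom_lengths = chrom_lengths,
    precursors = pre[, c("id", "name", "chrom", "start", "end", "strand")],
    precursor_clusters = pre[, c("id", "cluster_id")],
    matures = mat,
    mature_status = data.frame(
      mature_id = mat$id,
      status = ifelse(mat_clustered, "clustered", "nonclustered"),
      stringsAsFactors = FALSE),
    snps = snps,
    cohort = cohort$table,
    gene_roles = utr$gene_roles,
    utr_sequences = utr$sequences,
    mirna_sets = sets,
    planted_set = "planted_pathway"
  ), class = "seed_sim_truth")
}

# choose the overlap cohort: biallelic seed SNPs per cluster-status group,
# skipping any SNP whose seed-match patterns collide with a previously
# selected cohort SNP (a random 7-mer collision would make the accidental-
# match screen unsatisfiable)
sim_pick_cohort <- function(cfg, seed_snps, mat_clustered, mat_idx, mat) {
  status <- ifelse(mat_clustered[mat_idx], "clustered", "nonclustered")
  biallelic <- !grepl(",", seed_snps$alts, fixed = TRUE)
  chosen <- list()
  used_patterns <- character(0)
  for (grp in c("clustered", "nonclustered")) {
    pool <- which(biallelic & status == grp)
    pool <- pool[sample.int(length(pool))]
    n_taken <- 0L
    for (i in pool) {
      if (n_taken >= cfg$n_overlap_snps_per_group) break
      seed <- substr(mat$sequence[mat_idx[i]], 2L, 8L)
      minus <- mat$strand[mat_idx[i]] == "-"
      alt_proj <- if (minus) {
        complement_base(seed_snps$alts[i], rna = TRUE)
      } else {
        dna_to_rna(seed_snps$alts[i])
      }
      der <- replace_base(seed, seed_snps$seed_offset[i], alt_proj)
      pats <- c(allele_patterns(seed), allele_patterns(der))
      if (any(pats %in% used_patterns)) next
      used_patterns <- c(used_patterns, pats)
      spec <- cfg$planted_overlap_spec[[grp]]
      n_ref_only <- resample(spec$n_ref_only)
      n_der_only <- resample(spec$n_der_only)
      n_common <- resample(spec$n_common)
      chosen[[length(chosen) + 1L]] <- data.frame(
        rsid = seed_snps$rsid[i], mature_id = seed_snps$mature_id[i],
        group = grp, ref_seed = seed, derived_seed = der,
        alt_fwd = seed_snps$alts[i],
        n_ref_only = n_ref_only, n_der_only = n_der_only,
        n_common = n_common,
        n_ref = n_ref_only + n_common, n_der = n_der_only + n_common,
        stringsAsFactors = FALSE)
      n_taken <- n_taken + 1L
    }
    if (n_taken < cfg$n_overlap_snps_per_group) {
      stop("simulate_seed_snp_data: not enough eligible ", grp,
           " biallelic seed SNPs for the overlap cohort (got ", n_taken,
           ", need ", cfg$n_overlap_snps_per_group,
           "); increase n_seed_snps or lower n_overlap_snps_per_group")
    }
  }
  tab <- do.call(rbind, chosen)
  tab$expected_overlap <- ifelse(
    tab$n_ref > 0 & tab$n_der > 0,
    tab$n_common / sqrt(tab$n_ref * tab$n_der), NA_real_)
  list(table = tab)
}

# build the UTR collection: planted sites for the cohort, screened so that
# each gene's UTR matches exactly its planted alleles and nothing else
sim_build_utrs <- function(cfg, cohort, mat) {
  tab <- cohort$table
  # pattern dictionary over all cohort alleles
  allele_keys <- character(0)
  pattern_rows <- list()
  for (i in seq_len(nrow(tab))) {
    for (allele in c("ref", "der")) {
      key <- paste0(tab$rsid[i], "|", allele)
      seed <- if (allele == "ref") tab$ref_seed[i] else tab$derived_seed[i]
      for (p in allele_patterns(seed)) {
        pattern_rows[[length(pattern_rows) + 1L]] <-
          data.frame(pattern = p, key = key, stringsAsFactors = FALSE)
      }
    }
  }
  pattern_df <- do.call(rbind, pattern_rows)
  patterns <- unique(pattern_df$pattern)
  key_of_pattern <- split(pattern_df$key, pattern_df$pattern)[patterns]
  pdict <- Biostrings::PDict(Biostrings::DNAStringSet(patterns))

  # gene role assignment
  roles <- list()
  g <- 0L
  for (i in seq_len(nrow(tab))) {
    counts <- c(ref_only = tab$n_ref_only[i], der_only = tab$n_der_only[i],
                common = tab$n_common[i])
    for (role in names(counts)) {
      for (j in seq_len(counts[[role]])) {
        g <- g + 1L
        roles[[g]] <- data.frame(gene_id = sprintf("GENE%04d", g),
                                 rsid = tab$rsid[i], role = role,
                                 stringsAsFactors = FALSE)
      }
    }
  }
  if (g > cfg$n_genes) {
    stop("simulate_seed_snp_data: planted sites (", g,
         " genes) exceed UTR capacity (n_genes = ", cfg$n_genes, ")")
  }
  while (g < cfg$n_genes) {
    g <- g + 1L
    roles[[g]] <- data.frame(gene_id = sprintf("GENE%04d", g),
                             rsid = NA_character_, role = "background",
                             stringsAsFactors = FALSE)
  }
  gene_roles <- do.call(rbind, roles)

  core_of <- function(rsid, allele) {
    i <- match(rsid, tab$rsid)
    seed <- if (allele == "ref") tab$ref_seed[i] else tab$derived_seed[i]
    # injected as a 7mer-m8 core followed by a deliberate non-A base, so no
    # unintended shared 7mer-A1 site arises for offset-7 SNPs
    paste0(reverse_complement_dna(rna_to_dna(seed)), resample(c("C", "G", "T")))
  }

  sequences <- character(nrow(gene_roles))
  for (i in seq_len(nrow(gene_roles))) {
    role <- gene_roles$role[i]
    inserts <- switch(role,
      background = character(0),
      ref_only = core_of(gene_roles$rsid[i], "ref"),
      der_only = core_of(gene_roles$rsid[i], "der"),
      common = c(core_of(gene_roles$rsid[i], "ref"),
                 core_of(gene_roles$rsid[i], "der")))
    allowed <- if (role == "background") {
      character(0)
    } else if (role == "common") {
      paste0(gene_roles$rsid[i], "|", c("ref", "der"))
    } else {
      paste0(gene_roles$rsid[i], "|", sub("_only", "", role))
    }
    len <- resample(seq(cfg$utr_length_range[1], cfg$utr_length_range[2]))
    ok <- FALSE
    for (attempt in seq_len(cfg$max_screen_attempts)) {
      n_seg <- length(inserts) + 1L
      bg_total <- len - sum(nchar(inserts))
      extra <- tabulate(sample.int(n_seg, bg_total - 5L * n_seg,
                                   replace = TRUE), nbins = n_seg)
      segs <- vapply(5L + extra, random_dna, character(1))
      pieces <- character(0)
      for (s in seq_len(n_seg)) {
        pieces <- c(pieces, segs[s],
                    if (s <= length(inserts)) inserts[s])
      }
      utr <- paste(pieces, collapse = "")
      hits <- Biostrings::countPDict(pdict, Biostrings::DNAString(utr)) > 0L
      matched_keys <- unique(unlist(key_of_pattern[hits], use.names = FALSE))
      if (setequal(matched_keys, allowed)) {
        ok <- TRUE
        break
      }
      inserts <- vapply(seq_along(inserts), function(s) {
        # re-roll the trailing base too, in case it caused a junction match
        switch(role,
               ref_only = core_of(gene_roles$rsid[i], "ref"),
               der_only = core_of(gene_roles$rsid[i], "der"),
               common = core_of(gene_roles$rsid[i],
                                c("ref", "der")[s]))
      }, character(1))
    }
    if (!ok) {
      stop("simulate_seed_snp_data: could not screen an accidental-match-",
           "free UTR for ", gene_roles$gene_id[i], " within ",
           cfg$max_screen_attempts, " attempts")
    }
    sequences[i] <- utr
  }
  names(sequences) <- gene_roles$gene_id
  list(gene_roles = gene_roles, sequences = sequences)
}

## ---- file emission -------------------------------------------------------

sim_write <- function(gt, cfg, dir) {
  pre <- gt$precursors
  mat <- gt$matures

  gff <- c("##gff-version 3",
           sprintf("%s\tsim\tmiRNA_primary_transcript\t%d\t%d\t.\t%s\t.\tID=%s;Name=%s",
                   pre$chrom, pre$start, pre$end, pre$strand, pre$id,
                   pre$name),
           sprintf("%s\tsim\tmiRNA\t%d\t%d\t.\t%s\t.\tID=%s;Name=%s;Derives_from=%s",
                   mat$chrom, mat$start, mat$end, mat$strand, mat$id,
                   mat$name, mat$precursor_id))
  writeLines(gff, file.path(dir, "mirna.gff3"))

  writeLines(paste0(">", mat$name, "\n", mat$sequence),
             file.path(dir, "mature.fa"))

  snps <- gt$snps
  chrom_order <- order(match(snps$chrom, names(gt$chrom_lengths)), snps$pos)
  snps <- snps[chrom_order, , drop = FALSE]
  info <- ifelse(is.na(snps$maf), ".",
                 ifelse(grepl(",", snps$alts, fixed = TRUE),
                        sprintf("AF=%.6f,%.6f", snps$maf, snps$maf / 2),
                        sprintf("AF=%.6f", snps$maf)))
  vcf <- c("##fileformat=VCFv4.2",
           sprintf("##contig=<ID=%s,length=%d>", names(gt$chrom_lengths),
                   unlist(gt$chrom_lengths)),
           "##INFO=<ID=AF,Number=A,Type=Float,Description=\"Alternate allele frequency\">",
           "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO",
           sprintf("%s\t%d\t%s\t%s\t%s\t.\t.\t%s", snps$chrom, snps$pos,
                   snps$rsid, snps$ref, snps$alts, info))
  writeLines(vcf, file.path(dir, "snps.vcf"))

  writeLines(paste0(">", names(gt$utr_sequences), "\n", gt$utr_sequences),
             file.path(dir, "utrs.fa"))

  gmt <- vapply(names(gt$mirna_sets), function(nm) {
    paste(c(nm, "synthetic miRNA set", gt$mirna_sets[[nm]]), collapse = "\t")
  }, character(1))
  writeLines(gmt, file.path(dir, "mirna_sets.gmt"))

  jsonlite::write_json(unclass(gt), file.path(dir, "ground_truth.json"),
                       auto_unbox = TRUE, digits = NA, null = "null",
                       na = "null")
  invisible(dir)
}
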