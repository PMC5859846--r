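#' Pipeline configuration
#'
#' Bundles the input paths and every tunable constant of the analysis:
#' the 10 kb clustering rule, the 5% rarity threshold, the enabled
#' seed-match site types, the continuity-correction switch and the
#' multiallelic aggregation mode. Every value is echoed into the run
#' report so no default stays hidden.
#'
#' @param gff Path to the miRNA GFF3 annotation.
#' @param mature_fasta Path to the mature miRNA FASTA.
#' @param vcf Path to the SNP VCF.
#' @param utr_fasta Optional path to the 3'UTR FASTA; without it the
#'   target/overlap stages are skipped.
#' @param mirna_sets Optional path to a GMT-like miRNA-set file for the
#'   over-representation stage.
#' @param out_dir Output directory for stage TSVs and the report JSON.
#' @param max_gap Clustering distance threshold in bp (inclusive).
#' @param maf_threshold Rarity threshold (strict `<`).
#' @param site_types Enabled seed-match site types.
#' @param continuity_correction Yates correction for the chi-square test.
#' @param multiallelic_mode Aggregation of per-allele overlaps to one value
#'   per SNP: "mean", "min" or "max".
#' @param maf_key INFO keys tried for allele frequencies, in order.
#' @param distance_mode Clustering distance definition ("edge" or "start").
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(gff, mature_fasta, vcf, utr_fasta = NULL,
                            mirna_sets = NULL, out_dir = tempfile("mirrun"),
                            max_gap = 10000L, maf_threshold = 0.05,
                            site_types = c("8mer", "7mer-m8", "7mer-A1"),
                            continuity_correction = FALSE,
                            multiallelic_mode = c("mean", "min", "max"),
                            maf_key = c("AF", "CAF"),
                            distance_mode = c("edge", "start")) {
  cfg <- list(gff = gff, mature_fasta = mature_fasta, vcf = vcf,
              utr_fasta = utr_fasta, mirna_sets = mirna_sets,
              out_dir = out_dir, max_gap = max_gap,
              maf_threshold = maf_threshold,
              site_types = match.arg(site_types, SITE_TYPES,
                                     several.ok = TRUE),
              continuity_correction = continuity_correction,
              multiallelic_mode = match.arg(multiallelic_mode),
              maf_key = maf_key,
              distance_mode = match.arg(distance_mode))
  for (f in c("gff", "mature_fasta", "vcf")) {
    if (!file.exists(cfg[[f]])) {
      stop("pipeline_config: missing input '", f, "': ", cfg[[f]])
    }
  }
  for (f in c("utr_fasta", "mirna_sets")) {
    if (!is.null(cfg[[f]]) && !file.exists(cfg[[f]])) {
      stop("pipeline_config: missing input '", f, "': ", cfg[[f]])
    }
  }
  structure(cfg, class = "pipeline_config")
}

stage_log <- function(stage, ...) {
  message(sprintf("[%s] %s", stage, paste0(...)))
}

#' Run the full seed-SNP analysis pipeline
#'
#' Executes seed mapping, clustering, allele-dependent target prediction,
#' percent-overlap computation and the inferential layer, writing every
#' stage table under `config$out_dir` together with a machine-readable run
#' report (`run_report.json`). Deterministic: identical inputs and
#' configuration give identical outputs.
#'
#' Stage outputs: `seed_snps.tsv`, `seed_intervals.bed`,
#' `snp_count_distribution.tsv`, `clusters.tsv`, `mature_status.tsv`,
#' `overlaps.tsv`, `overlap_by_snp.tsv`, `ora.tsv` (when inputs allow) and
#' `run_report.json`.
#'
#' @param config A [pipeline_config()].
#' @return The run report (a list, class `run_report`): per-stage record
#'   and reject counts, the cluster-enrichment summary with its chi-square
#'   test, overlap summaries by cluster status with the two-sample t-tests
#'   at per-SNP and per-miRNA granularity, the over-representation table,
#'   the configuration echo and the package version.
#' @export
run_pipeline <- function(config) {
  if (!inherits(config, "pipeline_config")) {
    stop("run_pipeline: config must come from pipeline_config()")
  }
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  report <- list(version = as.character(utils::packageVersion("mirseedclust")),
                 config = unclass(config))

  ## annotation
  ann <- read_mirna_gff(config$gff)
  matures <- attach_sequences(ann$matures, config$mature_fasta)
  snps <- read_vcf_snps(config$vcf, maf_key = config$maf_key)
  stage_log("annotation", nrow(ann$precursors), " precursors, ",
            nrow(matures), " matures, ", nrow(snps), " SNVs (",
            sum(ann$rejects), " rejects)")
  report$counts <- list(precursors = nrow(ann$precursors),
                        matures = nrow(matures), snvs = nrow(snps),
                        annotation_rejects = as.list(ann$rejects))

  ## seed mapping
  seeds <- compute_seed_intervals(matures)
  seed_snps <- map_snps_to_seeds(seeds, matures, snps,
                                 maf_threshold = config$maf_threshold)
  dist <- snp_count_distribution(seed_snps, matures)
  pairs <- unique(seed_snps[, c("mature_id", "rsid")])
  distinct_rsids <- unique(seed_snps$rsid)
  rarity_by_snp <- tapply(seed_snps$rarity, seed_snps$rsid, `[`, 1)
  stage_log("seed_mapping", length(distinct_rsids), " seed SNPs in ",
            length(unique(seed_snps$mature_id)), " matures (",
            attr(seed_snps, "n_ref_mismatch"), " reference mismatches)")
  write_seed_bed(seeds, file.path(config$out_dir, "seed_intervals.bed"))
  write_tsv(seed_snps, file.path(config$out_dir, "seed_snps.tsv"))
  write_tsv(data.frame(n_snps = names(dist), n_matures = as.integer(dist)),
            file.path(config$out_dir, "snp_count_distribution.tsv"))
  report$seed_mapping <- list(
    n_seed_snps = length(distinct_rsids),
    n_mature_snp_pairs = nrow(pairs),
    n_matures_with_snp = length(unique(seed_snps$mature_id)),
    n_reference_mismatch = attr(seed_snps, "n_ref_mismatch"),
    snp_count_distribution = as.list(dist),
    rarity = as.list(table(rarity_by_snp)))

  ## clustering + enrichment
  clusters <- cluster_precursors(ann$precursors, max_gap = config$max_gap,
                                 distance_mode = config$distance_mode)
  status <- mature_cluster_status(matures, clusters, ann$precursors)
  fig1 <- figure1_summary(status, seed_snps,
                          continuity_correction = config$continuity_correction)
  stage_log("clustering", nrow(clusters), " clusters; clustered ",
            fig1$pct_clustered_with_snp, "% (with SNP) vs ",
            fig1$pct_clustered_without_snp, "% (without); p = ",
            format(fig1$test$p_value, digits = 3))
  write_tsv(clusters, file.path(config$out_dir, "clusters.tsv"))
  write_tsv(status, file.path(config$out_dir, "mature_status.tsv"))
  report$clustering <- list(
    n_clusters = nrow(clusters),
    n_clustered_precursors = sum(clusters$n_members),
    n_clustered_matures = sum(status$status == "clustered"),
    enrichment = list(
      pct_clustered_with_snp = fig1$pct_clustered_with_snp,
      pct_clustered_without_snp = fig1$pct_clustered_without_snp,
      table = as.vector(t(fig1$table)),
      statistic = fig1$test$statistic, p_value = fig1$test$p_value,
      method = fig1$test$method))

  ## targets + overlap (optional)
  if (!is.null(config$utr_fasta)) {
    utrs <- read_utr_fasta(config$utr_fasta)
    overlaps <- compute_overlaps(seed_snps, utrs,
                                 site_types = config$site_types)
    by_snp <- overlap_by_snp(overlaps, mode = config$multiallelic_mode)
    by_snp$status <- status$status[match(by_snp$mature_id, status$mature_id)]
    write_tsv(overlaps, file.path(config$out_dir, "overlaps.tsv"))
    write_tsv(by_snp, file.path(config$out_dir, "overlap_by_snp.tsv"))

    overall <- summarize_overlaps(by_snp)
    grp <- split(by_snp$percent_overlap, by_snp$status)
    clus <- grp[["clustered"]] %||% numeric(0)
    nonc <- grp[["nonclustered"]] %||% numeric(0)
    clus <- clus[!is.na(clus)]
    nonc <- nonc[!is.na(nonc)]
    t_snp <- if (length(clus) >= 2 && length(nonc) >= 2) {
      students_t_test(clus, nonc)
    }
    # per-miRNA granularity: mean defined overlap per mature
    per_mir <- tapply(by_snp$percent_overlap, by_snp$mature_id,
                      function(v) mean(v, na.rm = TRUE))
    per_mir_status <- status$status[match(names(per_mir), status$mature_id)]
    mc <- per_mir[per_mir_status == "clustered"]
    mn <- per_mir[per_mir_status == "nonclustered"]
    mc <- mc[is.finite(mc)]; mn <- mn[is.finite(mn)]
    t_mir <- if (length(mc) >= 2 && length(mn) >= 2) {
      students_t_test(mc, mn)
    }
    stage_log("overlap", overall$n_defined, " defined / ",
              overall$n_undefined, " undefined; mean = ",
              format(overall$mean, digits = 3))
    tres <- function(t) if (is.null(t)) NULL else {
      list(statistic = t$statistic, df = t$df, p_value = t$p_value,
           method = t$method)
    }
    report$overlap <- list(
      summary = overall,
      mean_clustered = if (length(clus)) mean(clus) else NA_real_,
      mean_nonclustered = if (length(nonc)) mean(nonc) else NA_real_,
      n_defined_clustered = length(clus),
      n_defined_nonclustered = length(nonc),
      t_test_per_snp = tres(t_snp),
      t_test_per_mirna = tres(t_mir))
  }

  ## over-representation (optional)
  if (!is.null(config$mirna_sets)) {
    sets <- read_mirna_sets(config$mirna_sets)
    with_snp_clustered <- status$mature_id %in% seed_snps$mature_id &
      status$status == "clustered"
    query <- matures$name[match(status$mature_id[with_snp_clustered],
                                matures$id)]
    ora <- set_over_representation(query, sets, unique(matures$name))
    write_tsv(ora, file.path(config$out_dir, "ora.tsv"))
    stage_log("ora", nrow(ora), " sets tested; top: ", ora$set_name[1],
              " (p = ", format(ora$p_value[1], digits = 3), ")")
    report$ora <- ora
  }

  class(report) <- "run_report"
  jsonlite::write_json(unclass(report),
                       file.path(config$out_dir, "run_report.json"),
                       auto_unbox = TRUE, digits = NA, na = "null",
                       null = "null", force = TRUE)
  invisible(report)
}

#' @export
print.run_report <- function(x, ...) {
  cat("mirseedclust run report (v", x$version, ")\n", sep = "")
  cat("  precursors:", x$counts$precursors,
      " matures:", x$counts$matures, " SNVs:", x$counts$snvs, "\n")
  cat("  seed SNPs:", x$seed_mapping$n_seed_snps, "in",
      x$seed_mapping$n_matures_with_snp, "matures\n")
  e <- x$clustering$enrichment
  cat("  clustered: ", e$pct_clustered_with_snp, "% (with SNP) vs ",
      e$pct_clustered_without_snp, "% (without), chi-square p = ",
      format(e$p_value, digits = 3), "\n", sep = "")
  if (!is.null(x$overlap)) {
    cat("  mean percent overlap:",
        format(x$overlap$summary$mean, digits = 3), "(",
        x$overlap$summary$n_defined, "defined )\n")
  }
  invisible(x)
}
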