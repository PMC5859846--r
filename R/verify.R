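#' Re-check a synthetic dataset against its ground truth
#'
#' Re-reads the files emitted by [simulate_seed_snp_data()] through the
#' ordinary readers and confirms every ground-truth assertion: annotation
#' tables round-trip, the computed cluster partition equals the planted one,
#' every planted seed SNP maps back to its (mature, offset) with the planted
#' rarity, no background SNP maps into a seed, the overlap-cohort target
#' sets predicted from the UTRs equal the planted gene sets, and the planted
#' layout straddles the 10 kb rule (at least one same-strand neighbour pair
#' at gap <= 10 kb and one beyond it). Any discrepancy is a generator bug.
#'
#' @param output_dir Directory written by [simulate_seed_snp_data()].
#' @param stop_on_discrepancy Raise an error when discrepancies are found
#'   (default); set `FALSE` to inspect the report instead.
#' @return data.frame with columns `check` and `detail`, one row per
#'   discrepancy (zero rows when the dataset verifies clean).
#' @export
verify_ground_truth <- function(output_dir, stop_on_discrepancy = TRUE) {
  gt <- jsonlite::fromJSON(file.path(output_dir, "ground_truth.json"))
  bad <- list()
  note <- function(check, detail) {
    bad[[length(bad) + 1L]] <<- data.frame(check = check, detail = detail,
                                           stringsAsFactors = FALSE)
  }

  ann <- read_mirna_gff(file.path(output_dir, "mirna.gff3"))
  matures <- attach_sequences(ann$matures, file.path(output_dir, "mature.fa"))

  compare_table <- function(check, got, want, key, cols) {
    for (id in setdiff(want[[key]], got[[key]])) note(check, paste("missing", id))
    for (id in setdiff(got[[key]], want[[key]])) note(check, paste("extra", id))
    common <- intersect(want[[key]], got[[key]])
    gi <- match(common, got[[key]]); wi <- match(common, want[[key]])
    for (col in cols) {
      diff <- got[[col]][gi] != want[[col]][wi]
      for (id in common[diff]) note(check, paste(id, col, "differs"))
    }
  }
  compare_table("precursor_table", ann$precursors, gt$precursors, "id",
                c("name", "chrom", "start", "end", "strand"))
  compare_table("mature_table", matures, gt$matures, "id",
                c("name", "precursor_id", "chrom", "start", "end", "strand",
                  "sequence"))

  ## cluster partition
  clusters <- cluster_precursors(ann$precursors, max_gap = 10000L)
  got_sets <- lapply(clusters$members, function(m) sort(m))
  want_split <- split(gt$precursor_clusters$id, gt$precursor_clusters$cluster_id)
  want_sets <- lapply(want_split, sort)
  sig <- function(s) paste(s, collapse = ",")
  got_sig <- vapply(got_sets, sig, character(1))
  want_sig <- vapply(want_sets, sig, character(1))
  for (s in setdiff(want_sig, got_sig)) {
    note("cluster_partition", paste("planted cluster not recovered:", s))
  }
  for (s in setdiff(got_sig, want_sig)) {
    note("cluster_partition", paste("unplanted cluster found:", s))
  }

  status <- mature_cluster_status(matures, clusters, ann$precursors)
  si <- match(gt$mature_status$mature_id, status$mature_id)
  diff <- is.na(si) | status$status[si] != gt$mature_status$status
  for (id in gt$mature_status$mature_id[diff]) {
    note("mature_status", paste(id, "status differs"))
  }

  ## VCF round-trip and seed mapping
  snps <- read_vcf_snps(file.path(output_dir, "snps.vcf"))
  want <- gt$snps
  vi <- match(want$rsid, snps$rsid)
  for (j in which(is.na(vi))) note("vcf_records", paste("missing", want$rsid[j]))
  ok <- !is.na(vi)
  pos_diff <- ok & (snps$pos[vi] != want$pos | snps$chrom[vi] != want$chrom |
                      snps$ref[vi] != want$ref | snps$alts[vi] != want$alts)
  for (id in want$rsid[which(pos_diff)]) {
    note("vcf_records", paste(id, "position/allele differs"))
  }
  maf_diff <- ok & !(
    (is.na(snps$maf[vi]) & is.na(want$maf)) |
      (!is.na(snps$maf[vi]) & !is.na(want$maf) &
         abs(snps$maf[vi] - want$maf) < 1e-5))
  for (id in want$rsid[which(maf_diff)]) {
    note("vcf_records", paste(id, "MAF differs"))
  }

  seeds <- compute_seed_intervals(matures)
  mapped <- suppressWarnings(map_snps_to_seeds(seeds, matures, snps))
  mkey <- unique(paste(mapped$rsid, mapped$mature_id, mapped$seed_offset))
  want_seed <- want[want$is_seed, , drop = FALSE]
  wkey <- paste(want_seed$rsid, want_seed$mature_id, want_seed$seed_offset)
  for (k in setdiff(wkey, mkey)) {
    note("seed_snp_mapping", paste("planted seed SNP not recovered:", k))
  }
  for (k in setdiff(mkey, wkey)) {
    note("seed_snp_mapping", paste("unplanted seed mapping:", k))
  }
  rar <- mapped$rarity[match(want_seed$rsid, mapped$rsid)]
  diff <- !is.na(rar) & rar != want_seed$rarity
  for (id in want_seed$rsid[diff]) note("rarity", paste(id, "rarity differs"))

  ## overlap cohort target sets
  utrs <- read_utr_fasta(file.path(output_dir, "utrs.fa"))
  roles <- gt$gene_roles
  cohort <- gt$cohort
  for (i in seq_len(nrow(cohort))) {
    mine <- roles[!is.na(roles$rsid) & roles$rsid == cohort$rsid[i], ,
                  drop = FALSE]
    want_ref <- sort(mine$gene_id[mine$role %in% c("ref_only", "common")])
    want_der <- sort(mine$gene_id[mine$role %in% c("der_only", "common")])
    got_ref <- predict_targets(cohort$ref_seed[i], utrs)$genes
    got_der <- predict_targets(cohort$derived_seed[i], utrs)$genes
    if (!identical(sort(got_ref), want_ref)) {
      note("cohort_targets", paste(cohort$rsid[i], "reference target set differs"))
    }
    if (!identical(sort(got_der), want_der)) {
      note("cohort_targets", paste(cohort$rsid[i], "derived target set differs"))
    }
  }

  ## the layout must straddle the 10 kb rule
  gaps <- unlist(lapply(
    split(ann$precursors,
          paste(ann$precursors$chrom, ann$precursors$strand)),
    function(g) {
      g <- g[order(g$start), , drop = FALSE]
      if (nrow(g) < 2L) return(numeric(0))
      pmax(0, g$start[-1] - cummax(as.numeric(g$end))[-nrow(g)] - 1)
    }), use.names = FALSE)
  if (!any(gaps <= 10000)) {
    note("straddle", "no same-strand neighbour pair within 10 kb")
  }
  if (!any(gaps > 10000)) {
    note("straddle", "no same-strand neighbour pair beyond 10 kb")
  }

  report <- if (length(bad)) {
    do.call(rbind, bad)
  } else {
    data.frame(check = character(), detail = character(),
               stringsAsFactors = FALSE)
  }
  if (stop_on_discrepancy && nrow(report) > 0L) {
    stop("verify_ground_truth: ", nrow(report), " discrepancy(ies):\n",
         paste(utils::head(paste(report$check, report$detail, sep = ": "), 20),
               collapse = "\n"))
  }
  report
}
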