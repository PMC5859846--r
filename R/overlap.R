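#' Percent overlap (cosine similarity) between two target sets
#'
#' The functional effect of a seed SNP is quantified by how much of the
#' target spectrum survives the allele change: the number of genes targeted
#' by both alleles divided by the square root of the product of the two
#' target-set sizes. The square root damps seeds with abnormally many
#' targets and normalises the score to `[0, 1]` -- 1 iff the sets are equal,
#' 0 iff they are disjoint. When either set is empty the score carries no
#' information and `NA` is returned (the undefined sentinel), never 0.
#'
#' @param ref_targets Character vector of reference-allele target gene ids
#'   (or a `target_set`).
#' @param der_targets Character vector of derived-allele target gene ids (or
#'   a `target_set`).
#' @return A single numeric in `[0, 1]`, or `NA` when either set is empty.
#' @export
percent_overlap <- function(ref_targets, der_targets) {
  if (inherits(ref_targets, "target_set")) ref_targets <- ref_targets$genes
  if (inherits(der_targets, "target_set")) der_targets <- der_targets$genes
  r <- unique(ref_targets)
  d <- unique(der_targets)
  if (length(r) == 0L || length(d) == 0L) {
    return(NA_real_)
  }
  length(intersect(r, d)) / sqrt(length(r) * length(d))
}

#' Per-allele percent overlaps for all seed SNPs
#'
#' Predicts the reference and derived target sets for every (rsid, mature,
#' ALT) row of a seed-SNP table and computes the percent overlap. Identical
#' seeds are predicted once (cached), since many SNPs share a mature's
#' reference seed.
#'
#' @param seed_snps Seed SNP data.frame from [map_snps_to_seeds()].
#' @param utrs UTR collection as in [predict_targets()].
#' @param site_types Enabled site types.
#' @return data.frame with one row per (rsid, mature_id, alt): `rsid`,
#'   `mature_id`, `alt` (forward-strand ALT), `n_ref`, `n_der`, `n_common`,
#'   `percent_overlap` (`NA` when undefined).
#' @export
compute_overlaps <- function(seed_snps, utrs,
                             site_types = c("8mer", "7mer-m8", "7mer-A1")) {
  if (!is.character(utrs)) {
    utrs <- as.character(utrs)
  }
  cache <- new.env(parent = emptyenv())
  genes_of <- function(seed) {
    if (is.null(cache[[seed]])) {
      cache[[seed]] <- predict_targets(seed, utrs, site_types)$genes
    }
    cache[[seed]]
  }
  n <- nrow(seed_snps)
  n_ref <- integer(n); n_der <- integer(n); n_common <- integer(n)
  pov <- numeric(n)
  for (i in seq_len(n)) {
    r <- genes_of(seed_snps$ref_seed[i])
    d <- genes_of(seed_snps$derived_seed[i])
    n_ref[i] <- length(r)
    n_der[i] <- length(d)
    n_common[i] <- length(intersect(r, d))
    pov[i] <- percent_overlap(r, d)
  }
  data.frame(rsid = seed_snps$rsid, mature_id = seed_snps$mature_id,
             alt = seed_snps$alt_fwd, n_ref = n_ref, n_der = n_der,
             n_common = n_common, percent_overlap = pov,
             stringsAsFactors = FALSE)
}

#' Aggregate per-allele overlaps to one value per SNP
#'
#' A multiallelic SNP has one overlap per ALT allele; per-SNP summaries use
#' the mean across its alleles by default (configurable to min or max).
#' Undefined (`NA`) alleles are excluded; a SNP whose alleles are all
#' undefined stays undefined.
#'
#' @param overlaps data.frame from [compute_overlaps()].
#' @param mode Aggregation across a SNP's alleles: "mean", "min" or "max".
#' @return data.frame with one row per (rsid, mature_id):
#'   `percent_overlap`.
#' @export
overlap_by_snp <- function(overlaps, mode = c("mean", "min", "max")) {
  mode <- match.arg(mode)
  f <- switch(mode, mean = mean, min = min, max = max)
  agg <- function(v) {
    v <- v[!is.na(v)]
    if (!length(v)) NA_real_ else f(v)
  }
  out <- aggregate(percent_overlap ~ rsid + mature_id, data = overlaps,
                   FUN = agg, na.action = stats::na.pass)
  out[order(out$rsid, out$mature_id), , drop = FALSE]
}

#' Summarise a collection of percent overlaps
#'
#' Mean and median are taken over defined values only; the number of
#' undefined (empty-target-set) results is reported alongside rather than
#' coded as zero, which would bias the aggregate downward.
#'
#' @param overlaps Numeric vector of percent overlaps (NA = undefined), or a
#'   data.frame with a `percent_overlap` column.
#' @return List with `mean`, `median`, `n_defined`, `n_undefined` (`mean`
#'   and `median` are `NA` when nothing is defined).
#' @export
summarize_overlaps <- function(overlaps) {
  if (is.data.frame(overlaps)) overlaps <- overlaps$percent_overlap
  defined <- overlaps[!is.na(overlaps)]
  list(mean = if (length(defined)) mean(defined) else NA_real_,
       median = if (length(defined)) stats::median(defined) else NA_real_,
       n_defined = length(defined),
       n_undefined = sum(is.na(overlaps)))
}
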