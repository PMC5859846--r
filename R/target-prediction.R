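# Canonical seed-match target prediction. A gene is a predicted target of a
# seed when its 3'UTR contains at least one enabled site-type match; no
# context scoring, conservation filtering or free-energy term is applied.

SITE_TYPES <- c("8mer", "7mer-m8", "7mer-A1", "6mer")

#' Seed-match site patterns for a 7 nt seed
#'
#' Let `M` be the reverse complement of the seed written as DNA (7 nt; its
#' left end pairs with mature position 8, its right end with mature position
#' 2). The canonical site types searched on the forward (5'->3') UTR strand
#' are then:
#' \describe{
#'   \item{7mer-m8}{`M` -- perfect match to mature positions 2-8.}
#'   \item{8mer}{`M` followed by `A` -- 7mer-m8 plus an adenine opposite
#'     mature position 1.}
#'   \item{7mer-A1}{`M[2..7]` followed by `A` -- match to mature positions
#'     2-7 plus the A1 adenine.}
#'   \item{6mer}{`M[2..7]` -- match to mature positions 2-7 only.}
#' }
#' The A1 adenine is required to be a genomic `A` in the UTR, not a pairing.
#'
#' @param seed 7 nt RNA seed sequence (alphabet ACGU).
#' @return Named character vector of DNA patterns for all four site types.
#' @export
seed_match_patterns <- function(seed) {
  if (nchar(seed) != 7L || !is_valid_rna(seed)) {
    stop("seed_match_patterns: seed must be 7 nt over {A,C,G,U}, got ", seed)
  }
  m <- reverse_complement_dna(rna_to_dna(seed))
  c("8mer" = paste0(m, "A"),
    "7mer-m8" = m,
    "7mer-A1" = paste0(substr(m, 2L, 7L), "A"),
    "6mer" = substr(m, 2L, 7L))
}

#' Predict target genes of one seed allele
#'
#' Scans every UTR for the enabled site-type patterns. A gene is a target
#' iff at least one enabled match occurs anywhere in its UTR. Overlapping
#' matches of different types at the same locus collapse to the most
#' specific type (8mer > 7mer-m8 > 7mer-A1 > 6mer), so an 8mer site is
#' reported once, not additionally as the 7mers it contains.
#'
#' @param seed 7 nt RNA seed.
#' @param utrs A named [Biostrings::DNAStringSet] (or named character vector)
#'   of 3'UTR sequences, one per gene, forward mRNA sense. Multiple isoforms
#'   must be pre-collapsed to one sequence per gene id.
#' @param site_types Enabled site types, a non-empty subset of
#'   `c("8mer", "7mer-m8", "7mer-A1", "6mer")`.
#' @param allele_label Free-text label stored in the result (e.g.
#'   `"reference"` or `"derived:G"`).
#' @return An object of class `target_set`: list with `seed`,
#'   `allele_label`, `genes` (character vector) and `sites` (data.frame
#'   `gene_id`, `position` (1-based match start), `site_type`).
#' @export
predict_targets <- function(seed, utrs,
                            site_types = c("8mer", "7mer-m8", "7mer-A1"),
                            allele_label = "reference") {
  site_types <- match.arg(site_types, SITE_TYPES, several.ok = TRUE)
  if (!is.character(utrs)) {
    utrs <- as.character(utrs)
  }
  empty_sites <- data.frame(gene_id = character(), position = integer(),
                            site_type = character(), stringsAsFactors = FALSE)
  res <- structure(list(seed = seed, allele_label = allele_label,
                        genes = character(), sites = empty_sites),
                   class = "target_set")
  if (length(utrs) == 0L) {
    warning("predict_targets: empty UTR collection")
    return(res)
  }
  if (is.null(names(utrs)) || anyDuplicated(names(utrs))) {
    stop("predict_targets: UTRs must be uniquely named by gene id")
  }

  patterns <- seed_match_patterns(seed)[site_types]
  matches <- list()
  for (st in site_types) {
    hits <- stringi::stri_locate_all_fixed(utrs, patterns[[st]],
                                           overlap = TRUE)
    starts <- lapply(hits, function(h) h[!is.na(h[, 1L]), 1L])
    n <- lengths(starts)
    if (sum(n) == 0L) next
    matches[[st]] <- data.frame(
      gene_id = rep(names(utrs), n),
      position = unlist(starts, use.names = FALSE),
      site_type = st,
      width = nchar(patterns[[st]]),
      stringsAsFactors = FALSE
    )
  }
  if (!length(matches)) {
    return(res)
  }
  all_m <- do.call(rbind, matches)
  all_m$rank <- match(all_m$site_type, SITE_TYPES)

  # a match is suppressed when it overlaps a strictly more specific match in
  # the same gene (an 8mer site is not additionally reported as its 7mers);
  # overlapping matches of the same type are all kept
  keep_rows <- lapply(split(all_m, all_m$gene_id), function(g) {
    g <- g[order(g$rank, g$position), , drop = FALSE]
    e <- g$position + g$width - 1L
    kept <- vapply(seq_len(nrow(g)), function(i) {
      better <- g$rank < g$rank[i]
      !any(better & g$position <= e[i] & e >= g$position[i])
    }, logical(1))
    g[kept, , drop = FALSE]
  })
  sites <- do.call(rbind, keep_rows)
  sites <- sites[order(sites$gene_id, sites$position),
                 c("gene_id", "position", "site_type")]
  rownames(sites) <- NULL

  res$genes <- sort(unique(all_m$gene_id))
  res$sites <- sites
  res
}

#' @export
print.target_set <- function(x, ...) {
  cat("target_set: seed", x$seed, "(", x$allele_label, ")\n")
  cat("  ", length(x$genes), "target gene(s),", nrow(x$sites), "site(s)\n")
  invisible(x)
}

#' Allele-dependent target prediction for one seed SNP
#'
#' Runs [predict_targets()] once with the reference seed and once per
#' derived seed of a single seed SNP. Deterministic given its inputs; a SNP
#' with two ALT alleles yields exactly two derived target sets.
#'
#' @param seed_snp One seed SNP: the rows of a [map_snps_to_seeds()] result
#'   sharing one (`rsid`, `mature_id`) pair (one row per ALT allele).
#' @param utrs UTR collection as in [predict_targets()].
#' @param site_types Enabled site types.
#' @return List with elements `reference` (a `target_set`) and `derived` (a
#'   list of `target_set`s named by forward-strand ALT allele).
#' @export
allele_dependent_targets <- function(seed_snp, utrs,
                                     site_types = c("8mer", "7mer-m8",
                                                    "7mer-A1")) {
  if (length(unique(seed_snp$rsid)) != 1L ||
      length(unique(seed_snp$mature_id)) != 1L) {
    stop("allele_dependent_targets: expected rows of a single ",
         "(rsid, mature) seed SNP")
  }
  reference <- predict_targets(seed_snp$ref_seed[1], utrs, site_types,
                               allele_label = "reference")
  derived <- lapply(seq_len(nrow(seed_snp)), function(i) {
    predict_targets(seed_snp$derived_seed[i], utrs, site_types,
                    allele_label = paste0("derived:", seed_snp$alt_fwd[i]))
  })
  names(derived) <- seed_snp$alt_fwd
  list(reference = reference, derived = derived)
}
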