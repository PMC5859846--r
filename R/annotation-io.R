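#' Read miRNA annotations from a miRBase-style GFF3 file
#'
#' Parses a GFF3 file containing `miRNA_primary_transcript` (precursor) and
#' `miRNA` (mature) features, where every mature record points at its
#' precursor through a `Derives_from` attribute. Records that violate the
#' domain invariants are dropped with a warning rather than silently coerced:
#' precursors with undefined strand or duplicated IDs, matures with a
#' dangling `Derives_from`, matures shorter than 8 nt (no seed exists), and
#' matures whose chromosome or strand disagrees with their precursor.
#'
#' All coordinates are kept 1-based inclusive, as in GFF3.
#'
#' @param path Path to a GFF3 file.
#' @return A list with elements `precursors` (data.frame: `id`, `name`,
#'   `chrom`, `start`, `end`, `strand`), `matures` (data.frame: `id`, `name`,
#'   `precursor_id`, `chrom`, `start`, `end`, `strand`, `sequence` -- `NA`
#'   until [attach_sequences()] is called), and `rejects`, a named integer
#'   vector of per-reason drop counts.
#' @seealso [attach_sequences()], [compute_seed_intervals()]
#' @export
read_mirna_gff <- function(path) {
  if (!file.exists(path)) {
    stop("GFF3 file not found: ", path)
  }
  gr <- rtracklayer::import(path, format = "gff3")
  md <- S4Vectors::mcols(gr)

  get_attr <- function(name) {
    if (!name %in% names(md)) {
      return(rep(NA_character_, length(gr)))
    }
    col <- md[[name]]
    if (methods::is(col, "List") || is.list(col)) {
      vapply(col, function(x) if (length(x)) as.character(x[[1]]) else NA_character_,
             character(1))
    } else {
      as.character(col)
    }
  }

  type <- get_attr("type")
  all_df <- data.frame(
    type = type,
    id = get_attr("ID"),
    name = get_attr("Name"),
    derives_from = get_attr("Derives_from"),
    chrom = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr),
    end = GenomicRanges::end(gr),
    strand = as.character(GenomicRanges::strand(gr)),
    stringsAsFactors = FALSE
  )

  rejects <- c(precursor_bad_strand = 0L, precursor_duplicate_id = 0L,
               mature_bad_strand = 0L, mature_dangling_parent = 0L,
               mature_too_short = 0L, mature_parent_mismatch = 0L)

  pre <- all_df[all_df$type == "miRNA_primary_transcript", , drop = FALSE]
  bad <- !pre$strand %in% c("+", "-")
  rejects["precursor_bad_strand"] <- sum(bad)
  pre <- pre[!bad, , drop = FALSE]
  dup <- duplicated(pre$id)
  rejects["precursor_duplicate_id"] <- sum(dup)
  pre <- pre[!dup, , drop = FALSE]

  mat <- all_df[all_df$type == "miRNA", , drop = FALSE]
  bad <- !mat$strand %in% c("+", "-")
  rejects["mature_bad_strand"] <- sum(bad)
  mat <- mat[!bad, , drop = FALSE]

  dangling <- !mat$derives_from %in% pre$id
  rejects["mature_dangling_parent"] <- sum(dangling)
  mat <- mat[!dangling, , drop = FALSE]

  short <- (mat$end - mat$start + 1L) < 8L
  rejects["mature_too_short"] <- sum(short)
  mat <- mat[!short, , drop = FALSE]

  pidx <- match(mat$derives_from, pre$id)
  mism <- mat$chrom != pre$chrom[pidx] | mat$strand != pre$strand[pidx]
  rejects["mature_parent_mismatch"] <- sum(mism)
  mat <- mat[!mism, , drop = FALSE]

  if (sum(rejects) > 0L) {
    warning("read_mirna_gff dropped ", sum(rejects), " record(s): ",
            paste(names(rejects)[rejects > 0], rejects[rejects > 0],
                  sep = "=", collapse = ", "))
  }

  precursors <- data.frame(id = pre$id, name = pre$name, chrom = pre$chrom,
                           start = pre$start, end = pre$end,
                           strand = pre$strand, stringsAsFactors = FALSE)
  matures <- data.frame(id = mat$id, name = mat$name,
                        precursor_id = mat$derives_from, chrom = mat$chrom,
                        start = mat$start, end = mat$end, strand = mat$strand,
                        sequence = rep(NA_character_, nrow(mat)),
                        stringsAsFactors = FALSE)
  rownames(precursors) <- NULL
  rownames(matures) <- NULL
  list(precursors = precursors, matures = matures, rejects = rejects)
}

#' Attach mature miRNA sequences from a FASTA file
#'
#' Matches FASTA records to mature miRNAs by name (falling back to id), so
#' miRBase-style mature FASTA files work directly. DNA input is transcribed
#' (`T` becomes `U`); sequences are uppercased. A sequence whose length
#' disagrees with the annotated genomic interval is a fatal error because it
#' means the coordinates cannot be trusted; matures with no FASTA record or a
#' non-ACGU alphabet are dropped with a warning.
#'
#' @param matures Mature miRNA data.frame from [read_mirna_gff()].
#' @param fasta_path Path to a FASTA file of mature sequences (RNA or DNA).
#' @return The `matures` data.frame with the `sequence` column filled in;
#'   records that could not be sequenced are removed.
#' @export
attach_sequences <- function(matures, fasta_path) {
  ss <- Biostrings::readBStringSet(fasta_path)
  seqs <- toupper(dna_to_rna(as.character(ss)))
  names(seqs) <- sub("\\s.*$", "", names(ss))

  idx <- match(matures$name, names(seqs))
  idx[is.na(idx)] <- match(matures$id[is.na(idx)], names(seqs))

  missing <- is.na(idx)
  if (any(missing)) {
    warning("attach_sequences: no FASTA record for ", sum(missing),
            " mature(s); dropped: ",
            paste(utils::head(matures$name[missing], 5), collapse = ", "))
  }
  matures <- matures[!missing, , drop = FALSE]
  idx <- idx[!missing]
  matures$sequence <- unname(seqs[idx])

  len_ok <- nchar(matures$sequence) == matures$end - matures$start + 1L
  if (!all(len_ok)) {
    stop("attach_sequences: sequence length disagrees with genomic interval ",
         "for: ", paste(matures$name[!len_ok], collapse = ", "),
         " -- coordinates untrustworthy")
  }
  bad_alpha <- !is_valid_rna(matures$sequence)
  if (any(bad_alpha)) {
    warning("attach_sequences: non-ACGU sequence for ", sum(bad_alpha),
            " mature(s); dropped")
    matures <- matures[!bad_alpha, , drop = FALSE]
  }
  rownames(matures) <- NULL
  matures
}

#' Read single-nucleotide variants from a VCF file
#'
#' Reads a VCF v4.x text file and retains single-nucleotide substitutions
#' only: records whose REF is one base, with every single-base ALT kept
#' (multiallelic records survive with all SNV ALTs) and indel/symbolic ALTs
#' silently filtered with a logged count. Alleles are always interpreted on
#' the forward genomic strand (VCF convention); any strand reconciliation is
#' done downstream by [map_snps_to_seeds()].
#'
#' The minor allele frequency is taken from the first INFO key in `maf_key`
#' that is present for a record. For `AF`-style keys the values are ALT
#' frequencies (the REF frequency is inferred as their complement); for
#' `CAF`-style keys the comma list already includes the REF frequency first.
#' The MAF is the second-largest allele frequency. Records without parseable
#' frequencies get `maf = NA` and are later classified as `unknown` rarity.
#'
#' @param path Path to a VCF file (plain text).
#' @param maf_key Character vector of INFO keys to try, in order.
#' @return data.frame with columns `rsid`, `chrom`, `pos`, `ref`, `alts`
#'   (comma-separated single bases), `maf`, `multi_mapped` (TRUE when the
#'   same rsID appears at more than one locus; all placements are kept).
#' @export
read_vcf_snps <- function(path, maf_key = c("AF", "CAF")) {
  if (!file.exists(path)) {
    stop("VCF file not found: ", path)
  }
  vcf <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcf@fix
  if (is.null(fix) || nrow(fix) == 0L) {
    stop("read_vcf_snps: no parseable records in ", path)
  }

  ref <- toupper(fix[, "REF"])
  alt <- toupper(fix[, "ALT"])
  alt_list <- strsplit(ifelse(is.na(alt), "", alt), ",", fixed = TRUE)

  snv_ref <- !is.na(ref) & ref %in% DNA_BASES
  kept_alts <- lapply(alt_list, function(a) a[a %in% DNA_BASES])
  n_alt_dropped <- sum(lengths(alt_list)) - sum(lengths(kept_alts))
  keep <- snv_ref & lengths(kept_alts) > 0L
  # REF must not reappear among ALTs
  kept_alts <- Map(function(a, r) setdiff(a, r), kept_alts, ref)
  keep <- keep & lengths(kept_alts) > 0L

  if (n_alt_dropped > 0L || any(!keep)) {
    message("read_vcf_snps: filtered ", sum(!keep),
            " non-SNV record(s) and ", n_alt_dropped, " non-SNV ALT allele(s)")
  }
  if (!any(keep)) {
    stop("read_vcf_snps: no single-nucleotide substitutions in ", path)
  }

  maf <- rep(NA_real_, nrow(fix))
  for (key in maf_key) {
    vals <- tryCatch(vcfR::extract.info(vcf, element = key),
                     error = function(e) rep(NA_character_, nrow(fix)))
    todo <- is.na(maf) & !is.na(vals) & vals != "."
    if (!any(todo)) next
    maf[todo] <- vapply(vals[todo], function(s) {
      f <- suppressWarnings(as.numeric(strsplit(s, ",", fixed = TRUE)[[1]]))
      f <- f[!is.na(f)]
      if (!length(f)) return(NA_real_)
      freqs <- if (identical(key, "CAF")) f else c(max(0, 1 - sum(f)), f)
      if (length(freqs) < 2L) return(NA_real_)
      sort(freqs, decreasing = TRUE)[2]
    }, numeric(1), USE.NAMES = FALSE)
  }

  id <- fix[, "ID"]
  chrom <- fix[, "CHROM"]
  pos <- as.integer(fix[, "POS"])
  no_id <- is.na(id) | id == "."
  id[no_id] <- paste0(chrom[no_id], ":", pos[no_id])

  out <- data.frame(
    rsid = id[keep], chrom = chrom[keep], pos = pos[keep],
    ref = ref[keep],
    alts = vapply(kept_alts[keep], paste, character(1), collapse = ","),
    maf = maf[keep], stringsAsFactors = FALSE
  )
  out$multi_mapped <- out$rsid %in% out$rsid[duplicated(out$rsid)]
  rownames(out) <- NULL
  out
}

#' Read miRNA annotation sets from a GMT-like file
#'
#' Each line is `set_name <TAB> description <TAB> member <TAB> member ...`;
#' the description field is ignored. Sets with no members are dropped with a
#' warning.
#'
#' @param path Path to a tab-separated set file.
#' @return Named list of character vectors of member miRNA names.
#' @export
read_mirna_sets <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  fields <- strsplit(lines, "\t", fixed = TRUE)
  names_v <- vapply(fields, `[`, character(1), 1L)
  members <- lapply(fields, function(f) unique(f[-(1:2)][nzchar(f[-(1:2)])]))
  names(members) <- names_v
  empty <- lengths(members) == 0L
  if (any(empty)) {
    warning("read_mirna_sets: dropped ", sum(empty), " empty set(s)")
    members <- members[!empty]
  }
  members
}

#' Read a 3'UTR sequence collection from FASTA
#'
#' One record per gene, forward mRNA sense, DNA alphabet. Gene identifiers
#' must be unique; empty records and records containing characters outside
#' ACGT are dropped with a warning.
#'
#' @param path Path to a FASTA file.
#' @return A [Biostrings::DNAStringSet] named by gene id.
#' @export
read_utr_fasta <- function(path) {
  ss <- Biostrings::readBStringSet(path)
  names(ss) <- sub("\\s.*$", "", names(ss))
  seqs <- toupper(as.character(ss))
  ok <- nchar(seqs) > 0L & is_valid_dna(seqs)
  if (any(!ok)) {
    warning("read_utr_fasta: dropped ", sum(!ok),
            " empty or non-ACGT record(s)")
  }
  seqs <- seqs[ok]
  if (anyDuplicated(names(seqs))) {
    stop("read_utr_fasta: duplicated gene ids: ",
         paste(unique(names(seqs)[duplicated(names(seqs))]), collapse = ", "))
  }
  Biostrings::DNAStringSet(seqs)
}

#' Write seed intervals as a BED6 file
#'
#' Converts the 1-based inclusive seed intervals to BED's 0-based half-open
#' convention at write time; the name column carries the mature id and the
#' strand column is preserved.
#'
#' @param seeds Seed interval data.frame from [compute_seed_intervals()].
#' @param path Output path.
#' @return The path, invisibly.
#' @export
write_seed_bed <- function(seeds, path) {
  bed <- data.frame(seeds$chrom, seeds$start - 1L, seeds$end,
                    seeds$mature_id, 0L, seeds$strand)
  utils::write.table(bed, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}
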