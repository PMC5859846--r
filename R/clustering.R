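#' Group miRNA precursors into genomic clusters
#'
#' Two neighbouring precursors belong to the same cluster when they lie on
#' the same chromosome and strand within `max_gap` of each other (default
#' 10 kb, boundary inclusive). Chaining is single-linkage: if A-B and B-C
#' each satisfy the rule, A, B and C share a cluster even when A-C does not.
#' Chains of length >= 2 become clusters; singletons are non-clustered.
#'
#' The distance between two precursors is the edge-to-edge gap
#' `max(0, start2 - end1 - 1)` by default (overlapping precursors have gap
#' 0 and always co-cluster); `distance_mode = "start"` switches to
#' start-to-start distance.
#'
#' @param precursors Precursor data.frame from [read_mirna_gff()].
#' @param max_gap Maximum distance in bp (inclusive) for two neighbours to
#'   co-cluster.
#' @param distance_mode `"edge"` (inter-locus gap) or `"start"`.
#' @return data.frame with one row per cluster: `cluster_id`, `chrom`,
#'   `strand`, `span_start`, `span_end`, `n_members`, and `members` (a list
#'   column of precursor ids ordered by start).
#' @export
cluster_precursors <- function(precursors, max_gap = 10000L,
                               distance_mode = c("edge", "start")) {
  distance_mode <- match.arg(distance_mode)
  if (!all(precursors$strand %in% c("+", "-"))) {
    stop("cluster_precursors: precursor strand must be '+' or '-'")
  }
  groups <- split(precursors,
                  paste(precursors$chrom, precursors$strand, sep = "\r"))
  chains <- list()
  for (g in groups) {
    g <- g[order(g$start, g$end, g$id), , drop = FALSE]
    n <- nrow(g)
    if (distance_mode == "edge") {
      # running max end makes chaining correct for nested/overlapping loci
      prev_reach <- cummax(as.numeric(g$end))
      dist <- c(Inf, pmax(0, g$start[-1] - prev_reach[-n] - 1))
    } else {
      dist <- c(Inf, g$start[-1] - g$start[-n])
    }
    chain <- cumsum(dist > max_gap)
    for (members in split(g, chain)) {
      if (nrow(members) >= 2L) {
        chains[[length(chains) + 1L]] <- members
      }
    }
  }
  if (!length(chains)) {
    return(data.frame(cluster_id = character(), chrom = character(),
                      strand = character(), span_start = integer(),
                      span_end = integer(), n_members = integer(),
                      members = I(list()), stringsAsFactors = FALSE))
  }
  # deterministic ordering: by chrom, strand, span start
  ord <- order(vapply(chains, function(m) m$chrom[1], character(1)),
               vapply(chains, function(m) m$strand[1], character(1)),
               vapply(chains, function(m) min(m$start), numeric(1)))
  chains <- chains[ord]
  out <- data.frame(
    cluster_id = sprintf("cluster_%03d", seq_along(chains)),
    chrom = vapply(chains, function(m) m$chrom[1], character(1)),
    strand = vapply(chains, function(m) m$strand[1], character(1)),
    span_start = vapply(chains, function(m) min(m$start), numeric(1)),
    span_end = vapply(chains, function(m) max(m$end), numeric(1)),
    n_members = vapply(chains, nrow, integer(1)),
    stringsAsFactors = FALSE
  )
  out$members <- lapply(chains, function(m) m$id)
  out
}

#' Clustered / non-clustered status of mature miRNAs
#'
#' A mature miRNA is clustered iff its precursor belongs to any cluster.
#' When the full precursor table is supplied, a mature pointing at an
#' unknown precursor is a fatal error (upstream validation failed).
#'
#' @param matures Mature miRNA data.frame.
#' @param clusters Cluster data.frame from [cluster_precursors()].
#' @param precursors Optional precursor data.frame used to detect dangling
#'   `precursor_id`s.
#' @return data.frame with columns `mature_id`, `precursor_id`, `status`
#'   (`"clustered"` or `"nonclustered"`).
#' @export
mature_cluster_status <- function(matures, clusters, precursors = NULL) {
  if (!is.null(precursors)) {
    dangling <- !matures$precursor_id %in% precursors$id
    if (any(dangling)) {
      stop("mature_cluster_status: dangling precursor_id for matures: ",
           paste(utils::head(matures$id[dangling], 5), collapse = ", "))
    }
  }
  clustered_pre <- unlist(clusters$members, use.names = FALSE)
  data.frame(
    mature_id = matures$id,
    precursor_id = matures$precursor_id,
    status = ifelse(matures$precursor_id %in% clustered_pre,
                    "clustered", "nonclustered"),
    stringsAsFactors = FALSE
  )
}
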