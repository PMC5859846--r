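# Inferential layer: Pearson chi-square on a 2x2 table, two-sample t-test
# on overlap scores, and hypergeometric over-representation of miRNA sets.
# The test statistics are computed from their textbook formulas (contracts
# below); tests cross-check them against stats::chisq.test / stats::t.test.

new_test_result <- function(statistic, df, p_value, method, ...) {
  structure(list(statistic = statistic, df = df, p_value = p_value,
                 method = method, ...),
            class = "seed_test")
}

#' @export
print.seed_test <- function(x, ...) {
  cat(x$method, "\n  statistic =", format(x$statistic, digits = 6),
      if (!is.na(x$df)) paste(", df =", x$df) else "",
      ", p =", format(x$p_value, digits = 4), "\n")
  invisible(x)
}

#' Pearson chi-square test on a 2x2 contingency table
#'
#' Rows are with/without seed SNP, columns clustered/non-clustered (any 2x2
#' table works). The statistic is `sum((O - E)^2 / E)` on 1 degree of
#' freedom with expected counts from the margins; the p-value is the upper
#' tail of the chi-square distribution. The Yates continuity correction
#' (`sum((max(0, |O - E| - 1/2))^2 / E)`) is off by default and always
#' yields a statistic no larger than the uncorrected one. A zero marginal
#' makes the test undefined and raises an error suggesting Fisher's exact
#' test.
#'
#' @param table A 2x2 numeric matrix of non-negative counts, or the four
#'   counts `c(a, b, c, d)` filled row-wise.
#' @param continuity_correction Apply the Yates correction.
#' @return A `seed_test` with `statistic`, `df`, `p_value`, `method`,
#'   `observed` and `expected`.
#' @export
chi_square_2x2 <- function(table, continuity_correction = FALSE) {
  if (!is.matrix(table)) {
    if (length(table) != 4L) {
      stop("chi_square_2x2: supply a 2x2 matrix or 4 counts (row-wise)")
    }
    table <- matrix(table, nrow = 2, byrow = TRUE)
  }
  if (any(table < 0) || sum(table) <= 0) {
    stop("chi_square_2x2: counts must be non-negative with positive total")
  }
  expected <- outer(rowSums(table), colSums(table)) / sum(table)
  if (any(expected == 0)) {
    stop("chi_square_2x2: zero marginal (expected cell 0); ",
         "use Fisher's exact test instead")
  }
  dev <- abs(table - expected)
  if (continuity_correction) {
    dev <- pmax(0, dev - 0.5)
  }
  stat <- sum(dev^2 / expected)
  p <- stats::pchisq(stat, df = 1L, lower.tail = FALSE)
  new_test_result(stat, 1L, p,
                  method = paste0("Pearson chi-square (2x2",
                                  if (continuity_correction)
                                    ", Yates-corrected", ")"),
                  observed = table, expected = expected)
}

#' Two-sample t-test (Student's pooled-variance, two-sided)
#'
#' The pooled-variance Student statistic on `|x| + |y| - 2` degrees of
#' freedom, matching the classical test; `welch = TRUE` switches to the
#' Welch unequal-variance statistic with Satterthwaite degrees of freedom.
#' Both samples degenerate (zero variance everywhere) is an error.
#'
#' @param x,y Numeric vectors, each of length >= 2 (NAs removed).
#' @param welch Use the Welch statistic instead of the pooled one.
#' @return A `seed_test` with `statistic` (sign follows `mean(x) -
#'   mean(y)`), `df` and two-sided `p_value`.
#' @export
students_t_test <- function(x, y, welch = FALSE) {
  x <- x[!is.na(x)]
  y <- y[!is.na(y)]
  n1 <- length(x); n2 <- length(y)
  if (n1 < 2L || n2 < 2L) {
    stop("students_t_test: each sample needs at least 2 observations")
  }
  v1 <- stats::var(x); v2 <- stats::var(y)
  if (v1 == 0 && v2 == 0 && mean(x) == mean(y)) {
    # identical constants: no evidence of difference
    return(new_test_result(0, n1 + n2 - 2L, 1,
                           method = "Two-sample t-test (pooled, two-sided)"))
  }
  if (v1 == 0 && v2 == 0) {
    stop("students_t_test: both samples have zero variance")
  }
  if (welch) {
    se2 <- v1 / n1 + v2 / n2
    stat <- (mean(x) - mean(y)) / sqrt(se2)
    df <- se2^2 / ((v1 / n1)^2 / (n1 - 1) + (v2 / n2)^2 / (n2 - 1))
    method <- "Two-sample t-test (Welch, two-sided)"
  } else {
    sp2 <- ((n1 - 1) * v1 + (n2 - 1) * v2) / (n1 + n2 - 2)
    stat <- (mean(x) - mean(y)) / sqrt(sp2 * (1 / n1 + 1 / n2))
    df <- n1 + n2 - 2
    method <- "Two-sample t-test (pooled, two-sided)"
  }
  p <- 2 * stats::pt(-abs(stat), df = df)
  new_test_result(stat, df, p, method = method)
}

#' Hypergeometric over-representation of miRNA annotation sets
#'
#' For each annotation set, tests whether the query miRNAs overlap it more
#' than expected by chance given the universe: one-sided hypergeometric
#' (Fisher's exact) p-value, with Benjamini-Hochberg adjustment across all
#' sets. Annotation members outside the universe are ignored.
#'
#' @param query Character vector of query miRNA names (must lie within the
#'   universe).
#' @param annotation Named list of character vectors (annotation sets), as
#'   returned by [read_mirna_sets()].
#' @param universe Character vector: all miRNA names under consideration.
#' @return data.frame sorted by raw p-value: `set_name`, `set_size`
#'   (within universe), `overlap`, `p_value`, `p_adjusted`.
#' @export
set_over_representation <- function(query, annotation, universe) {
  query <- unique(query)
  universe <- unique(universe)
  if (!length(query) || !length(universe)) {
    stop("set_over_representation: empty query or universe")
  }
  if (!all(query %in% universe)) {
    stop("set_over_representation: query must be a subset of the universe")
  }
  n_univ <- length(universe)
  n_query <- length(query)
  rows <- lapply(names(annotation), function(nm) {
    members <- intersect(annotation[[nm]], universe)
    k <- length(intersect(query, members))
    big_k <- length(members)
    p <- stats::phyper(k - 1, big_k, n_univ - big_k, n_query,
                       lower.tail = FALSE)
    data.frame(set_name = nm, set_size = big_k, overlap = k, p_value = p,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$p_adjusted <- stats::p.adjust(out$p_value, method = "BH")
  out <- out[order(out$p_value, out$set_name), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Cluster-enrichment summary of seed-SNP-carrying miRNAs
#'
#' Cross-tabulates mature miRNAs by (carries a seed SNP) x (clustered) and
#' reports the percentage of clustered miRNAs in each group (one decimal
#' place, full precision in the attached table) together with the
#' chi-square test of independence.
#'
#' Either supply `status` (from [mature_cluster_status()]) and `seed_snps`
#' (from [map_snps_to_seeds()]), or the four `counts` directly as
#' `c(n_with_snp_clustered, n_with_snp_total, n_without_snp_clustered,
#' n_without_snp_total)`.
#'
#' @param status Mature cluster-status data.frame.
#' @param seed_snps Seed SNP data.frame.
#' @param counts Alternative direct input of the four group counts.
#' @param continuity_correction Passed to [chi_square_2x2()].
#' @return List with `pct_clustered_with_snp`, `pct_clustered_without_snp`
#'   (percent, 1 decimal), `table` (the 2x2 with/without x
#'   clustered/nonclustered matrix) and `test` (a `seed_test`).
#' @export
figure1_summary <- function(status = NULL, seed_snps = NULL, counts = NULL,
                            continuity_correction = FALSE) {
  if (is.null(counts)) {
    if (is.null(status) || is.null(seed_snps)) {
      stop("figure1_summary: supply status + seed_snps, or counts")
    }
    with_snp <- status$mature_id %in% seed_snps$mature_id
    clustered <- status$status == "clustered"
    counts <- c(sum(with_snp & clustered), sum(with_snp),
                sum(!with_snp & clustered), sum(!with_snp))
  }
  if (counts[2] == 0 || counts[4] == 0) {
    stop("figure1_summary: both groups (with and without seed SNP) must be ",
         "non-empty")
  }
  tab <- matrix(c(counts[1], counts[2] - counts[1],
                  counts[3], counts[4] - counts[3]),
                nrow = 2, byrow = TRUE,
                dimnames = list(c("with_snp", "without_snp"),
                                c("clustered", "nonclustered")))
  test <- if (any(colSums(tab) == 0)) {
    # every miRNA (or none) is clustered in both groups: the proportions are
    # identical by construction and there is no signal to test
    new_test_result(0, 1L, 1, method = "Pearson chi-square (2x2, degenerate)",
                    observed = tab, expected = tab)
  } else {
    chi_square_2x2(tab, continuity_correction = continuity_correction)
  }
  list(pct_clustered_with_snp = round(100 * counts[1] / counts[2], 1),
       pct_clustered_without_snp = round(100 * counts[3] / counts[4], 1),
       table = tab, test = test)
}
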