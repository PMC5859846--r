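# Internal sequence helpers. Single-base complements are done with chartr so
# that minus-strand allele projection never reverses anything by accident.

DNA_BASES <- c("A", "C", "G", "T")
RNA_BASES <- c("A", "C", "G", "U")

rna_to_dna <- function(x) chartr("Uu", "Tt", x)
dna_to_rna <- function(x) chartr("Tt", "Uu", x)

# complement of single forward-strand DNA bases; rna = TRUE additionally maps
# T -> U so the result reads in miRNA sense
complement_base <- function(x, rna = FALSE) {
  y <- chartr("ACGT", "TGCA", x)
  if (rna) dna_to_rna(y) else y
}

reverse_complement_dna <- function(x) {
  vapply(x, function(s) {
    as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))
  }, character(1), USE.NAMES = FALSE)
}

is_valid_rna <- function(x) grepl("^[ACGU]+$", x)
is_valid_dna <- function(x) grepl("^[ACGT]+$", x)

random_dna <- function(n) paste(sample(DNA_BASES, n, replace = TRUE), collapse = "")
random_rna <- function(n) paste(sample(RNA_BASES, n, replace = TRUE), collapse = "")

# replace a single character at position i
replace_base <- function(s, i, b) {
  substr(s, i, i) <- b
  s
}

write_tsv <- function(df, path) {
  df <- as.data.frame(df)
  # flatten list columns (e.g. cluster member lists) for the text report
  for (col in names(df)) {
    if (is.list(df[[col]])) {
      df[[col]] <- vapply(df[[col]], paste, character(1), collapse = ";")
    }
  }
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     fileEncoding = "UTF-8")
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
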