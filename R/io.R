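# File interfaces: TSV with header for tabular records, aligned FASTA +
# variant TSV for element alignments, JSON for simulation truth.  All
# genomic coordinates in files are 1-based inclusive.

#' Write / read a tab-separated table
#'
#' Thin wrappers fixing the conventions used by all the package's tabular
#' files: tab separator, header, no quoting, no row names.
#'
#' @param x Data frame or matrix.
#' @param path File path.
#' @return `read_tsv_file` returns a data frame.
#' @export
write_tsv_file <- function(x, path) {
  utils::write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_tsv_file
#' @export
read_tsv_file <- function(path) {
  utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
}

#' Write / read a capture table
#'
#' The locus-by-individual SSC matrix travels as TSV with a `locus` first
#' column and one column per individual.
#'
#' @param table Integer matrix loci x individuals.
#' @param path File path.
#' @return `read_capture_table` returns the matrix.
#' @export
write_capture_table <- function(table, path) {
  df <- data.frame(locus = rownames(table), table, check.names = FALSE,
                   stringsAsFactors = FALSE)
  write_tsv_file(df, path)
}

#' @rdname write_capture_table
#' @export
read_capture_table <- function(path) {
  df <- read_tsv_file(path)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df$locus
  m
}

#' Write an element alignment as FASTA plus a variant TSV
#'
#' The aligned sequences (consensus first) go to `fasta_path`; the variant
#' table (`variant_id`, `position` 1-based on the consensus, `ref`, `alt`)
#' to `variants_path`.
#'
#' @param alignment An `erv_alignment`.
#' @param fasta_path,variants_path Output paths.
#' @export
write_alignment <- function(alignment, fasta_path, variants_path) {
  seqs <- c(consensus = alignment$consensus, alignment$sequences)
  Biostrings::writeXStringSet(Biostrings::DNAStringSet(seqs), fasta_path)
  write_tsv_file(alignment$variants, variants_path)
  invisible(fasta_path)
}

#' Read an aligned FASTA into a named character vector
#'
#' @param path FASTA file.
#' @return Named character vector of sequences.
#' @export
read_alignment_fasta <- function(path) {
  x <- Biostrings::readDNAStringSet(path)
  stats::setNames(as.character(x), names(x))
}

#' Write simulation truth as JSON
#'
#' @param truth A list of ground-truth values.
#' @param path Output path.
#' @export
write_truth_json <- function(truth, path) {
  jsonlite::write_json(truth, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, force = TRUE)
  invisible(path)
}
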