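#' Write / read clone inserts or ORFs as FASTA
#'
#' Clone ids are the record identifiers.
#'
#' @param clones A [clone_table()] data.frame.
#' @param path FASTA path.
#' @param what `"insert"` or `"orf"`.
#' @return `path` invisibly; [read_inserts_fasta()] returns a named character
#'   vector of sequences.
#' @export
write_clones_fasta <- function(clones, path, what = c("insert", "orf")) {
  what <- match.arg(what)
  col <- c(insert = "insert_nt", orf = "orf_nt")[[what]]
  dna <- Biostrings::DNAStringSet(clones[[col]])
  names(dna) <- clones$clone_id
  Biostrings::writeXStringSet(dna, path)
  invisible(path)
}

#' @rdname write_clones_fasta
#' @export
read_inserts_fasta <- function(path) {
  dna <- Biostrings::readDNAStringSet(path)
  out <- as.character(dna)
  names(out) <- names(dna)
  out
}

#' Write / read the per-clone feature table as TSV
#'
#' Columns `clone_id`, `length_aa`, `gc_insert`, `gc_orf`, `peu`, `ids`;
#' missing feature values are written as empty fields.
#'
#' @param clones A [clone_table()] data.frame.
#' @param path TSV path.
#' @return `path` invisibly; [read_feature_table()] returns a data.frame.
#' @export
write_feature_table <- function(clones, path) {
  cols <- c("clone_id", "length_aa", "gc_insert", "gc_orf", "peu", "ids")
  df <- clones[, intersect(cols, names(clones)), drop = FALSE]
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     na = "")
  invisible(path)
}

#' @rdname write_feature_table
#' @export
read_feature_table <- function(path) {
  utils::read.delim(path, na.strings = "", stringsAsFactors = FALSE)
}
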