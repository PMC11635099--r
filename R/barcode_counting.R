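#' Pull the barcode (random insert) out of fixed-length amplicon reads
#'
#' Amplicons are fixed-length copies of the designed ORF, so the random
#' region sits at fixed coordinates; reads of any other length are returned
#' as `NA` (unmappable). Vectorized.
#'
#' @param reads Character vector of reads.
#' @param design A [library_design()].
#' @return Character vector of inserts (`NA` for off-length reads).
#' @export
read_inserts <- function(reads, design = library_design()) {
  out <- rep(NA_character_, length(reads))
  ok <- !is.na(reads) & nchar(reads) == design$orf_len_nt
  out[ok] <- substr(reads[ok], design$insert_start, design$insert_end)
  out
}

#' Build the clone reference from first-timepoint reads
#'
#' Tabulates candidate inserts across all first-timepoint samples, ranks them
#' by abundance (ties broken lexicographically), drops candidates below
#' `min_count`, and greedily absorbs any candidate lying within Hamming
#' distance `collapse_radius` of a more abundant retained center. Absorption
#' folds sequencing-error variants of a barcode back into it.
#'
#' @param t1_reads Character vector of reads, a list of such vectors (one per
#'   replicate sample), or a vector of FASTQ file paths.
#' @param design A [library_design()].
#' @param min_count Minimum founding abundance of a candidate (>= 1).
#' @param collapse_radius Hamming radius for error-variant absorption; 0
#'   disables collapsing.
#' @return An object of class `"reference_library"`: data.frame with columns
#'   `clone_id` (`ref_000001`, ... in abundance order), `insert_nt`, `count`
#'   (founding abundance, absorbed variants included). Attribute
#'   `collapse_radius` records the radius used.
#' @export
build_reference <- function(t1_reads, design = library_design(),
                            min_count = 2L, collapse_radius = 2L) {
  stopifnot(min_count >= 1L, collapse_radius >= 0L)
  tab <- tabulate_inserts(t1_reads, design)
  if (length(tab) == 0L)
    condition_error("pepgrow_empty_reference",
                    "empty reference: no parseable candidate insert")
  ## rank: abundance desc, then sequence lexicographic for determinism
  ord <- order(-tab, names(tab), method = "radix")
  counts <- as.numeric(tab[ord])
  seqs <- names(tab)[ord]
  assign <- greedy_collapse_cpp(seqs, as.integer(collapse_radius))
  total <- as.numeric(rowsum(counts, assign))
  centers <- sort(unique(assign))
  keep <- total >= min_count
  if (!any(keep))
    condition_error("pepgrow_empty_reference",
                    "empty reference: no candidate reaches min_count")
  ref <- data.frame(
    clone_id = sprintf("ref_%06d", seq_len(sum(keep))),
    insert_nt = seqs[centers[keep]],
    count = total[keep]
  )
  ## re-rank retained centers by founding (absorbed) abundance
  ord2 <- order(-ref$count, ref$insert_nt, method = "radix")
  ref <- ref[ord2, , drop = FALSE]
  ref$clone_id <- sprintf("ref_%06d", seq_len(nrow(ref)))
  rownames(ref) <- NULL
  structure(ref, class = c("reference_library", "data.frame"),
            collapse_radius = as.integer(collapse_radius))
}

## counts of unique inserts over one or more read sets / FASTQ files
tabulate_inserts <- function(reads, design) {
  if (is.character(reads) && length(reads) > 0 &&
      all(grepl("\\.(fastq|fq)(\\.gz)?$", reads)))
    reads <- lapply(reads, read_fastq)
  if (!is.list(reads)) reads <- list(reads)
  acc <- NULL
  for (rd in reads) {
    ins <- read_inserts(rd, design)
    ins <- ins[!is.na(ins) & !grepl("[^ACGT]", ins)]
    if (length(ins) == 0L) next
    t1 <- table(ins)
    v <- as.numeric(t1)
    names(v) <- names(t1)
    if (is.null(acc)) {
      acc <- v
    } else {
      new <- setdiff(names(v), names(acc))
      if (length(new)) acc[new] <- 0
      acc[names(v)] <- acc[names(v)] + v
    }
  }
  if (is.null(acc)) acc <- numeric(0)
  acc
}

#' Map amplicon reads to the clone reference
#'
#' A read is assigned to the unique reference clone whose insert lies within
#' `max_mismatch` Hamming distance of the read's insert; reads with no
#' in-range reference, with a distance tie between two references, or that
#' are unparseable count as unmapped. Internally unique inserts are mapped
#' once and weighted by their multiplicity.
#'
#' @param reads Character vector of reads or a FASTQ file path.
#' @param reference A [build_reference()] result.
#' @param design A [library_design()].
#' @param max_mismatch Maximum Hamming distance for assignment.
#' @return List with `counts` (named numeric, one entry per reference clone),
#'   `n_reads`, `n_mapped`, `mapping_rate`.
#' @export
map_reads <- function(reads, reference, design = library_design(),
                      max_mismatch = 2L) {
  if (!inherits(reference, "reference_library") || nrow(reference) == 0L)
    stop("`reference` must be a non-empty reference_library")
  if (is.character(reads) && length(reads) == 1L &&
      grepl("\\.(fastq|fq)(\\.gz)?$", reads))
    reads <- read_fastq(reads)
  n_reads <- length(reads)
  ins <- read_inserts(reads, design)
  ins[!is.na(ins) & grepl("[^ACGT]", ins)] <- NA_character_
  tab <- table(ins, useNA = "no")
  uniq <- names(tab)
  w <- as.numeric(tab)
  hit <- map_barcodes_cpp(uniq, reference$insert_nt, as.integer(max_mismatch))
  counts <- stats::setNames(rep(0, nrow(reference)), reference$clone_id)
  ok <- !is.na(hit)
  if (any(ok)) {
    agg <- rowsum(w[ok], hit[ok])
    counts[as.integer(rownames(agg))] <- as.numeric(agg)
  }
  n_mapped <- sum(w[ok])
  list(counts = counts, n_reads = n_reads, n_mapped = n_mapped,
       mapping_rate = if (n_reads > 0) n_mapped / n_reads else NA_real_)
}

#' Assemble per-sample counts into a clone x sample count matrix
#'
#' @param sample_counts Named list of [map_reads()] results (or bare named
#'   numeric count vectors); names are sample labels and must be unique.
#' @param metadata data.frame with columns `sample`, `replicate`,
#'   `timepoint`, one row per sample (row order defines column order).
#' @return An object of class `"count_matrix"`: list with `counts` (integer
#'   matrix, clones x samples; missing clone/sample combinations are 0),
#'   `samples` (the metadata, plus `n_reads`/`n_mapped` when available).
#' @export
assemble_count_matrix <- function(sample_counts, metadata) {
  stopifnot(is.list(sample_counts),
            all(c("sample", "replicate", "timepoint") %in% names(metadata)))
  if (anyDuplicated(metadata$sample) || anyDuplicated(names(sample_counts)))
    stop("duplicate sample labels")
  if (!setequal(names(sample_counts), metadata$sample))
    stop("sample_counts names and metadata$sample must agree")
  get_counts <- function(x) if (is.list(x) && !is.null(x$counts)) x$counts else x
  clone_ids <- unique(unlist(lapply(sample_counts, function(x) names(get_counts(x)))))
  m <- matrix(0L, nrow = length(clone_ids), ncol = nrow(metadata),
              dimnames = list(clone_ids, metadata$sample))
  meta <- metadata
  meta$n_reads <- NA_real_
  meta$n_mapped <- NA_real_
  for (s in metadata$sample) {
    x <- sample_counts[[s]]
    cv <- get_counts(x)
    m[names(cv), s] <- as.integer(round(cv))
    if (is.list(x) && !is.null(x$n_reads)) {
      meta$n_reads[meta$sample == s] <- x$n_reads
      meta$n_mapped[meta$sample == s] <- x$n_mapped
    }
  }
  structure(list(counts = m, samples = meta), class = "count_matrix")
}

#' @export
print.count_matrix <- function(x, ...) {
  cat(sprintf("count_matrix: %d clones x %d samples\n",
              nrow(x$counts), ncol(x$counts)))
  cat("  timepoints:", paste(unique(x$samples$timepoint), collapse = ", "), "\n")
  invisible(x)
}

#' Drop clones with insufficient total representation
#'
#' Retains clones whose total count across all samples is at least
#' `min_total`. Monotone: raising the threshold never adds clones.
#'
#' @param cm A `"count_matrix"`.
#' @param min_total Minimum total count (>= 0).
#' @return A filtered `"count_matrix"`.
#' @export
filter_low_representation <- function(cm, min_total = 50) {
  stopifnot(inherits(cm, "count_matrix"), min_total >= 0)
  keep <- rowSums(cm$counts) >= min_total
  cm$counts <- cm$counts[keep, , drop = FALSE]
  cm
}

#' Write / read a count matrix as TSV
#'
#' The matrix file has clones as rows and samples as columns (first column
#' `clone_id`); the sidecar file holds the sample metadata.
#'
#' @param cm A `"count_matrix"`.
#' @param path Matrix TSV path.
#' @param meta_path Metadata sidecar TSV path (default `path` +
#'   `".samples.tsv"`).
#' @return `path` invisibly ([write_count_matrix()]); a `"count_matrix"`
#'   ([read_count_matrix()]).
#' @export
write_count_matrix <- function(cm, path, meta_path = paste0(path, ".samples.tsv")) {
  stopifnot(inherits(cm, "count_matrix"))
  df <- data.frame(clone_id = rownames(cm$counts), cm$counts,
                   check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(cm$samples, meta_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname write_count_matrix
#' @export
read_count_matrix <- function(path, meta_path = paste0(path, ".samples.tsv")) {
  df <- utils::read.delim(path, check.names = FALSE)
  meta <- utils::read.delim(meta_path, check.names = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  mode(m) <- "integer"
  rownames(m) <- df$clone_id
  structure(list(counts = m, samples = meta), class = "count_matrix")
}

#' Write a reference library as FASTA
#'
#' @param reference A `"reference_library"`.
#' @param path FASTA path.
#' @return `path`, invisibly.
#' @export
write_reference_fasta <- function(reference, path) {
  dna <- Biostrings::DNAStringSet(reference$insert_nt)
  names(dna) <- reference$clone_id
  Biostrings::writeXStringSet(dna, path)
  invisible(path)
}

#' Read a reference library from FASTA
#'
#' @param path FASTA path with clone ids as record identifiers.
#' @return A `"reference_library"` (founding counts unknown, set to `NA`).
#' @export
read_reference_fasta <- function(path) {
  dna <- Biostrings::readDNAStringSet(path)
  structure(data.frame(clone_id = names(dna),
                       insert_nt = as.character(dna),
                       count = NA_real_),
            class = c("reference_library", "data.frame"),
            collapse_radius = NA_integer_)
}
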