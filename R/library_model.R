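#' Design of the random-insert expression library
#'
#' The library expresses a single open reading frame per clone: a start codon
#' and one constant codon, followed by a run of random codons, followed by a
#' six-histidine tag. With the defaults this is a 174-nt ORF (58 aa) holding a
#' 150-nt (50-codon) random region. The insert is flanked in the vector by a
#' HindIII site plus Kozak context upstream and a stop codon plus NotI site
#' downstream; the random insert itself doubles as the clone barcode.
#'
#' @param random_len_nt Length of the random region in nucleotides; must be a
#'   multiple of 3. Default 150.
#' @param constant5_codons Two constant codons opening the ORF. The first must
#'   be the start codon `ATG` (it terminates the Kozak context); the second is
#'   a design choice of the construct and is configurable.
#' @param histag_codons Six histidine codons closing the ORF. The default uses
#'   `CAC`, the most frequently used histidine codon in human genes.
#' @param stop_codon Stop codon placed after the His tag in the vector.
#' @param flank5,flank3 Constant vector context immediately outside the ORF:
#'   HindIII site + Kozak context upstream, stop codon + NotI site downstream.
#'   Used as anchors when parsing reads that include vector sequence.
#' @param p_stop Probability that a random codon is a stop codon; 3/64 under
#'   uniform nucleotide composition. Used by [peptide_length_null()].
#'
#' @return An object of class `"library_design"`: a list with the fields above
#'   plus derived fields `orf_len_nt`, `orf_len_aa`, `n_random_codons`,
#'   `insert_start`, `insert_end` (1-based ORF coordinates of the random
#'   region).
#' @examples
#' d <- library_design()
#' d$orf_len_nt   # 174
#' d$orf_len_aa   # 58
#' @export
library_design <- function(random_len_nt = 150L,
                           constant5_codons = c("ATG", "GCC"),
                           histag_codons = rep("CAC", 6L),
                           stop_codon = "TGA",
                           flank5 = "AAGCTTGCCACC",
                           flank3 = NULL,
                           p_stop = 3 / 64) {
  random_len_nt <- as.integer(random_len_nt)
  if (random_len_nt <= 0L || random_len_nt %% 3L != 0L)
    stop("`random_len_nt` must be a positive multiple of 3")
  if (length(constant5_codons) != 2L || any(nchar(constant5_codons) != 3L))
    stop("`constant5_codons` must be two nucleotide triplets")
  if (constant5_codons[1] != "ATG")
    stop("the first constant codon must be the start codon ATG")
  if (length(histag_codons) != 6L || any(nchar(histag_codons) != 3L))
    stop("`histag_codons` must be six nucleotide triplets")
  if (any(!histag_codons %in% c("CAC", "CAT")))
    stop("`histag_codons` must encode histidine (CAC/CAT)")
  if (!stop_codon %in% STOP_CODONS)
    stop("`stop_codon` must be one of TAA, TAG, TGA")
  if (!(p_stop > 0 && p_stop <= 1))
    stop("`p_stop` must be in (0, 1]")
  if (is.null(flank3)) flank3 <- paste0(stop_codon, "GCGGCCGC")

  n_random_codons <- random_len_nt %/% 3L
  orf_len_aa <- 2L + n_random_codons + 6L
  design <- structure(list(
    random_len_nt = random_len_nt,
    n_random_codons = n_random_codons,
    orf_len_nt = 3L * orf_len_aa,
    orf_len_aa = orf_len_aa,
    constant5_codons = constant5_codons,
    histag_codons = histag_codons,
    stop_codon = stop_codon,
    flank5 = flank5,
    flank3 = flank3,
    cloning_sites = c(HindIII = "AAGCTT", NotI = "GCGGCCGC"),
    insert_start = 7L,
    insert_end = 6L + random_len_nt,
    p_stop = p_stop
  ), class = "library_design")
  stopifnot(design$orf_len_aa * 3L == design$orf_len_nt)
  design
}

#' @export
print.library_design <- function(x, ...) {
  cat("Random-insert library design\n")
  cat(sprintf("  ORF: %d nt (%d aa) = ATG + %s + %d random nt + 6x%s\n",
              x$orf_len_nt, x$orf_len_aa, x$constant5_codons[2],
              x$random_len_nt, x$histag_codons[1]))
  cat(sprintf("  flanks: 5' %s | 3' %s\n", x$flank5, x$flank3))
  cat(sprintf("  stop probability per random codon: %.4f\n", x$p_stop))
  invisible(x)
}

STOP_CODONS <- c("TAA", "TAG", "TGA")

## standard genetic code as a named vector, stops as "*"
GENETIC_CODE_TABLE <- local({
  bases <- c("T", "C", "A", "G")
  aas <- strsplit(paste0(
    "FFLLSSSSYY**CC*W",   # TTT..TGG: third base fastest, order T,C,A,G
    "LLLLPPPPHHQQRRRR",
    "IIIMTTTTNNKKSSRR",
    "VVVVAAAADDEEGGGG"), "")[[1]]
  codons <- character(64)
  k <- 0L
  for (b1 in bases) for (b2 in bases) for (b3 in bases) {
    k <- k + 1L
    codons[k] <- paste0(b1, b2, b3)
  }
  names(aas) <- codons
  aas
})

condition_error <- function(class, msg, call = sys.call(-1)) {
  stop(structure(class = c(class, "error", "condition"),
                 list(message = msg, call = call)))
}

#' Extract the designed ORF from an amplicon read
#'
#' Locates the constant 5' context (HindIII + Kozak, ending immediately before
#' the start codon) and the constant 3' context (stop codon + NotI) in a read
#' and returns the ORF window between them: start codon through the last
#' His-tag codon.
#'
#' @param read_nt A single nucleotide sequence (character scalar) containing
#'   vector context around the ORF.
#' @param design A [library_design()].
#' @return The ORF sequence (`design$orf_len_nt` nt).
#' @section Errors: A read whose anchors are missing or ambiguous raises a
#'   condition of class `"pepgrow_unparseable_read"`; a read whose window is
#'   not the designed length (e.g. carries an indel) raises
#'   `"pepgrow_malformed_insert"`.
#' @export
extract_orf <- function(read_nt, design = library_design()) {
  stopifnot(is.character(read_nt), length(read_nt) == 1L)
  m5 <- gregexpr(design$flank5, read_nt, fixed = TRUE)[[1]]
  m3 <- gregexpr(design$flank3, read_nt, fixed = TRUE)[[1]]
  if (m5[1] == -1L || m3[1] == -1L)
    condition_error("pepgrow_unparseable_read",
                    "unparseable read: missing 5' or 3' anchor")
  if (length(m5) > 1L || length(m3) > 1L)
    condition_error("pepgrow_unparseable_read",
                    "unparseable read: ambiguous (repeated) flank anchor")
  from <- m5[1] + attr(m5, "match.length")[1]
  to <- m3[1] - 1L
  if (to - from + 1L != design$orf_len_nt)
    condition_error("pepgrow_malformed_insert",
                    sprintf("malformed insert: ORF window is %d nt, expected %d",
                            to - from + 1L, design$orf_len_nt))
  orf <- substr(read_nt, from, to)
  if (substr(orf, 1L, 3L) != "ATG")
    condition_error("pepgrow_unparseable_read",
                    "unparseable read: ORF window does not begin with ATG")
  orf
}

#' Translate designed ORFs to peptides
#'
#' Standard genetic code, reading frame fixed at the first position.
#' Translation stops at the first in-frame stop codon; an ORF without internal
#' stop yields the full-length peptide. Vectorized over sequences.
#'
#' @param orf_nt Character vector of ORF sequences, each of the designed
#'   length and starting with `ATG`.
#' @param design A [library_design()].
#' @return Character vector of peptides (no stop character included).
#' @section Errors: Any sequence containing a non-ACGT character raises a
#'   condition of class `"pepgrow_ambiguous_base"`; callers that tolerate
#'   ambiguous reads should exclude such clones and log them (see
#'   [clone_table()]).
#' @export
translate_orf <- function(orf_nt, design = library_design()) {
  stopifnot(is.character(orf_nt))
  if (length(orf_nt) == 0L) return(character(0))
  n <- unique(nchar(orf_nt))
  if (length(n) != 1L || n != design$orf_len_nt)
    stop(sprintf("all ORFs must be %d nt", design$orf_len_nt))
  if (any(grepl("[^ACGT]", orf_nt)))
    condition_error("pepgrow_ambiguous_base",
                    "ambiguous base: ORF contains a non-ACGT character")
  n_codons <- design$orf_len_aa
  starts <- 3L * (seq_len(n_codons) - 1L) + 1L
  ## codon matrix: n_codons x n_seq
  cod <- vapply(starts, function(s) substr(orf_nt, s, s + 2L),
                character(length(orf_nt)))
  if (length(orf_nt) == 1L) cod <- matrix(cod, nrow = 1L)
  aa <- matrix(GENETIC_CODE_TABLE[cod], nrow = length(orf_nt))
  vapply(seq_len(nrow(aa)), function(i) {
    r <- aa[i, ]
    stop_at <- which(r == "*")
    if (length(stop_at)) r <- r[seq_len(stop_at[1] - 1L)]
    paste(r, collapse = "")
  }, character(1))
}

#' Null distribution of peptide lengths in a random-codon library
#'
#' In an ORF whose random region spans `n_random_codons` codons, the peptide
#' is truncated at the first random codon that happens to be a stop. The
#' number of non-stop codons before the first stop is geometric: a peptide
#' truncated at random-codon trial `k` (probability `(1-p)^(k-1) p`) has
#' length `n_constant5 + k - 1` residues, and the full-length class (no
#' internal stop, probability `(1-p)^n_random_codons`) is reported as its own
#' atom.
#'
#' @param p_stop Per-codon stop probability in `(0, 1]` (3/64 for uniform
#'   nucleotides).
#' @param n_random_codons Number of random codons (50 with the default
#'   design).
#' @param library_size Number of clones; expected counts are `prob *
#'   library_size`.
#' @param n_constant5 Number of constant N-terminal residues preceding the
#'   random region (start codon counts as residue 1). Default 2.
#' @return A data.frame with columns `length_aa`, `prob`, `expected_count`,
#'   and logical `full_length`. Probabilities sum to 1.
#' @examples
#' null <- peptide_length_null()
#' null$prob[null$full_length]   # (61/64)^50, about 0.0907
#' @export
peptide_length_null <- function(p_stop = 3 / 64, n_random_codons = 50L,
                                library_size = 1L, n_constant5 = 2L) {
  if (!(is.numeric(p_stop) && length(p_stop) == 1L && p_stop > 0 && p_stop <= 1))
    stop("`p_stop` must be a probability in (0, 1]")
  n_random_codons <- as.integer(n_random_codons)
  stopifnot(n_random_codons >= 1L, library_size >= 0)
  k <- seq_len(n_random_codons)
  prob_trunc <- (1 - p_stop)^(k - 1) * p_stop
  full_len_aa <- n_constant5 + n_random_codons + 6L
  out <- data.frame(
    length_aa = c(n_constant5 + k - 1L, full_len_aa),
    prob = c(prob_trunc, (1 - p_stop)^n_random_codons),
    full_length = c(rep(FALSE, n_random_codons), TRUE)
  )
  out$expected_count <- out$prob * library_size
  stopifnot(abs(sum(out$prob) - 1) < 1e-12)
  out
}

#' Number of possible peptide sequences of a given length
#'
#' There are `20^k` ways to choose a `k`-residue sequence from the 20
#' proteinogenic amino acids. `20^58` (the full-length class) far exceeds
#' double precision, so the result is returned as an exact decimal digit
#' string computed by repeated schoolbook multiplication.
#'
#' @param k Non-negative integer peptide length (vectorized).
#' @return Character vector of exact integers, e.g. `"8000"` for `k = 3`.
#' @examples
#' unique_combinations(c(0, 1, 3))   # "1" "20" "8000"
#' @export
unique_combinations <- function(k) {
  k <- as.integer(k)
  if (any(is.na(k)) || any(k < 0L)) stop("`k` must be a non-negative integer")
  vapply(k, function(ki) {
    digits <- 1L            # little-endian base-10 digits
    if (ki > 0L) for (i in seq_len(ki)) {
      digits <- digits * 20L
      carry <- 0L
      for (j in seq_along(digits)) {
        v <- digits[j] + carry
        digits[j] <- v %% 10L
        carry <- v %/% 10L
      }
      while (carry > 0L) {
        digits <- c(digits, carry %% 10L)
        carry <- carry %/% 10L
      }
    }
    paste(rev(digits), collapse = "")
  }, character(1))
}

#' GC content of nucleotide sequences
#'
#' Fraction of G + C relative to sequence length. Vectorized.
#'
#' @param seq Character vector of non-empty ACGT sequences.
#' @return Numeric vector in `[0, 1]`.
#' @export
gc_content <- function(seq) {
  stopifnot(is.character(seq))
  if (any(is.na(seq)) || any(nchar(seq) == 0L))
    stop("sequences must be non-empty")
  if (any(grepl("[^ACGT]", seq)))
    condition_error("pepgrow_ambiguous_base",
                    "ambiguous base: sequence contains a non-ACGT character")
  gc <- nchar(gsub("[AT]", "", seq))
  gc / nchar(seq)
}

#' Per-position nucleotide frequencies of the random region
#'
#' @param inserts Character vector of equal-length ACGT sequences (the random
#'   inserts).
#' @return A 4 x L matrix with rows `A`, `C`, `G`, `T`; each column sums to 1.
#' @export
positional_nucleotide_freq <- function(inserts) {
  stopifnot(is.character(inserts), length(inserts) >= 1L)
  len <- nchar(inserts)
  if (length(unique(len)) != 1L) {
    bad <- which(len != len[1])[1]
    stop(sprintf("insert %d has length %d, expected %d", bad, len[bad], len[1]))
  }
  if (any(grepl("[^ACGT]", inserts)))
    condition_error("pepgrow_ambiguous_base",
                    "ambiguous base in insert")
  L <- len[1]
  m <- matrix(unlist(strsplit(inserts, "", fixed = TRUE), use.names = FALSE),
              nrow = L)          # positions x clones
  freq <- vapply(c("A", "C", "G", "T"),
                 function(b) rowMeans(m == b), numeric(L))
  t(freq)                       # 4 x L
}

AA_ALPHABET <- c("A","C","D","E","F","G","H","I","K","L",
                 "M","N","P","Q","R","S","T","V","W","Y")

#' Amino-acid composition of a set of peptides
#'
#' @param peptides Character vector; empty peptides contribute nothing.
#' @return Named numeric vector over the 20 amino acids, summing to 1.
#' @export
amino_acid_composition <- function(peptides) {
  stopifnot(is.character(peptides), length(peptides) >= 1L)
  all_aa <- unlist(strsplit(peptides, "", fixed = TRUE), use.names = FALSE)
  if (length(all_aa) == 0L) stop("all peptides are empty")
  bad <- setdiff(unique(all_aa), AA_ALPHABET)
  if (length(bad))
    stop("unexpected residue(s): ", paste(bad, collapse = ", "))
  counts <- table(factor(all_aa, levels = AA_ALPHABET))
  freq <- as.numeric(counts) / length(all_aa)
  names(freq) <- AA_ALPHABET
  freq
}

#' Expected amino-acid frequencies under a uniform codon model
#'
#' Codon usage uniform over the 61 sense codons (stop codons excluded, since
#' translation truncates at stops). Useful as the expectation for
#' [amino_acid_composition()] of the random region of a large unbiased
#' library.
#'
#' @return Named numeric vector over the 20 amino acids, summing to 1.
#' @export
uniform_codon_aa_expectation <- function() {
  sense <- GENETIC_CODE_TABLE[GENETIC_CODE_TABLE != "*"]
  counts <- table(factor(sense, levels = AA_ALPHABET))
  freq <- as.numeric(counts) / length(sense)
  names(freq) <- AA_ALPHABET
  freq
}

#' Per-clone feature table for a library
#'
#' Derives ORF, peptide and composition features for every insert. Clones
#' whose insert contains an ambiguous base (e.g. `N`) are excluded, not
#' imputed; exclusions are reported via an attribute and a message.
#'
#' @param inserts Named character vector of inserts (names = clone ids), or a
#'   data.frame with columns `clone_id`, `insert_nt`.
#' @param design A [library_design()].
#' @param peu,ids Optional numeric vectors of externally computed aggregation
#'   energies (pasta energy units) and intrinsic disorder scores, aligned with
#'   `inserts`. These are ingested, never computed here.
#' @return A data.frame (one row per retained clone) with columns `clone_id`,
#'   `insert_nt`, `orf_nt`, `peptide`, `length_aa`, `gc_insert`, `gc_orf`,
#'   `peu`, `ids`. Attribute `excluded` lists clone ids dropped for ambiguous
#'   bases.
#' @export
clone_table <- function(inserts, design = library_design(),
                        peu = NULL, ids = NULL) {
  if (is.data.frame(inserts)) {
    stopifnot(all(c("clone_id", "insert_nt") %in% names(inserts)))
    nm <- inserts$clone_id
    inserts <- inserts$insert_nt
    names(inserts) <- nm
  }
  if (is.null(names(inserts)))
    names(inserts) <- sprintf("clone_%05d", seq_along(inserts))
  ok <- !grepl("[^ACGT]", inserts)
  excluded <- names(inserts)[!ok]
  if (length(excluded))
    message(length(excluded), " clone(s) excluded for ambiguous bases")
  keep <- which(ok)
  insert_ok <- inserts[keep]
  orf <- paste0(paste(design$constant5_codons, collapse = ""), insert_ok,
                paste(design$histag_codons, collapse = ""))
  peptide <- translate_orf(orf, design)
  out <- data.frame(
    clone_id = names(insert_ok),
    insert_nt = unname(insert_ok),
    orf_nt = orf,
    peptide = peptide,
    length_aa = nchar(peptide),
    gc_insert = gc_content(insert_ok),
    gc_orf = gc_content(orf),
    peu = if (is.null(peu)) NA_real_ else peu[keep],
    ids = if (is.null(ids)) NA_real_ else ids[keep],
    row.names = NULL
  )
  attr(out, "excluded") <- excluded
  out
}
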