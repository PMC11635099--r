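#' Generate a synthetic random-insert library
#'
#' Draws `n_clones` random inserts of the designed length. Inserts are unique,
#' contain no internal HindIII/NotI recognition motif (offending draws are
#' resampled, so the cloning sites flanking the construct stay unambiguous),
#' and are reproducible for a given seed.
#'
#' @param n_clones Number of clones (>= 1).
#' @param design A [library_design()].
#' @param bias Nucleotide sampling probabilities, either a length-4 vector
#'   named `A`, `C`, `G`, `T` applied at every position, or a 4 x L matrix of
#'   per-position probabilities (columns sum to 1). Default uniform. The
#'   matrix form supports the positional bias seen in synthesized libraries
#'   (e.g. thymine over-represented, adenine under-represented at all
#'   positions).
#' @param seed Integer seed; the function uses R's RNG and restores no state.
#' @return A clone feature table as returned by [clone_table()].
#' @export
generate_library <- function(n_clones, design = library_design(),
                             bias = NULL, seed = NULL) {
  stopifnot(n_clones >= 1)
  n_clones <- as.integer(n_clones)
  L <- design$random_len_nt
  bases <- c("A", "C", "G", "T")
  if (is.null(bias)) bias <- stats::setNames(rep(0.25, 4), bases)
  if (is.matrix(bias)) {
    if (nrow(bias) != 4L || ncol(bias) != L)
      stop("`bias` matrix must be 4 x ", L)
    if (any(bias < 0) || any(abs(colSums(bias) - 1) > 1e-8))
      stop("`bias` columns must each be a probability distribution")
    pmat <- bias
  } else {
    if (length(bias) != 4L || any(bias < 0) || abs(sum(bias) - 1) > 1e-8)
      stop("`bias` must be 4 non-negative probabilities summing to 1")
    if (!is.null(names(bias))) bias <- bias[bases]
    pmat <- matrix(bias, nrow = 4L, ncol = L)
  }
  if (!is.null(seed)) set.seed(seed)

  forbidden <- unname(design$cloning_sites)
  draw <- function(n) {
    m <- vapply(seq_len(L),
                function(p) sample(bases, n, replace = TRUE, prob = pmat[, p]),
                character(n))
    if (n == 1L) m <- matrix(m, nrow = 1L)
    do.call(paste0, as.data.frame(m, stringsAsFactors = FALSE))
  }
  ## a fully degenerate bias admits a single sequence; uniqueness is then
  ## unattainable and not enforced
  degenerate <- all(apply(pmat, 2, max) == 1)
  inserts <- draw(n_clones)
  for (iter in seq_len(100L)) {
    bad <- grepl(forbidden[1], inserts, fixed = TRUE) |
      grepl(forbidden[2], inserts, fixed = TRUE)
    if (!degenerate) bad <- bad | duplicated(inserts)
    if (!any(bad)) break
    if (iter == 100L)
      stop("could not draw a motif-free unique library under this bias")
    inserts[bad] <- draw(sum(bad))
  }
  names(inserts) <- sprintf("clone_%05d", seq_len(n_clones))
  clone_table(inserts, design)
}

#' Configuration of the serial-passage growth simulation
#'
#' Defaults mirror the library time-course experiment the simulator emulates:
#' five replicate flasks sampled at ten timepoints, passaged every two days by
#' carrying one-fourth of the cells forward (two population doublings per
#' passage restore the flask), seeded with 3e6 cells.
#'
#' @param n_replicates Number of replicate flasks.
#' @param n_timepoints Number of sampling timepoints.
#' @param carryover_fraction Fraction of cells seeded into the next flask.
#' @param doublings_per_passage Population doublings between passages; fitness
#'   acts per doubling.
#' @param cells_per_passage Cells seeded per flask (bottleneck size for the
#'   multinomial carryover draw).
#' @param read_depth Amplicon reads per sequenced sample.
#' @param error_rate Per-base substitution probability of the sequencer.
#' @return An object of class `"growth_sim_config"`.
#' @export
growth_sim_config <- function(n_replicates = 5L, n_timepoints = 10L,
                              carryover_fraction = 1 / 4,
                              doublings_per_passage = 2,
                              cells_per_passage = 3e6,
                              read_depth = 1e6, error_rate = 0.001) {
  stopifnot(n_replicates >= 1, n_timepoints >= 1,
            carryover_fraction > 0, carryover_fraction < 1,
            doublings_per_passage > 0, cells_per_passage >= 1,
            read_depth >= 1)
  if (error_rate < 0 || error_rate >= 1)
    stop("`error_rate` must be in [0, 1)")
  structure(list(
    n_replicates = as.integer(n_replicates),
    n_timepoints = as.integer(n_timepoints),
    carryover_fraction = carryover_fraction,
    doublings_per_passage = doublings_per_passage,
    cells_per_passage = cells_per_passage,
    read_depth = read_depth,
    error_rate = error_rate
  ), class = "growth_sim_config")
}

#' One deterministic passage update
#'
#' Expected frequency update under multiplicative per-doubling fitness:
#' `f_i' = f_i (1+s_i)^d / sum_j f_j (1+s_j)^d`.
#'
#' @param freq Frequency vector summing to 1.
#' @param s Per-clone relative fitness (0 = neutral); requires `1 + s > 0`.
#' @param doublings Number of doublings in the passage.
#' @return Updated frequency vector.
#' @export
passage_update <- function(freq, s, doublings = 2) {
  stopifnot(length(freq) == length(s), all(1 + s > 0))
  w <- freq * (1 + s)^doublings
  w / sum(w)
}

#' Simulate competitive growth of a clone pool
#'
#' Each replicate flask starts at the founding frequencies. Per passage the
#' pool grows with per-clone multiplicative fitness, the current composition
#' is sampled (the sequenced aliquot), and a multinomial bottleneck of
#' `cells_per_passage` cells is carried into the next flask. Timepoint `t`
#' records the composition after the t-th growth step.
#'
#' @param fitness Numeric vector of per-clone fitness `s` (names = clone
#'   ids; 0 = neutral). `1 + s` must be positive.
#' @param config A [growth_sim_config()].
#' @param initial_freq Founding frequencies (default equal).
#' @param mode `"multinomial"` (stochastic bottleneck and sampling) or
#'   `"deterministic"` (expectation propagation, exact frequency
#'   conservation; used by closed-form tests).
#' @param seed Optional integer seed.
#' @return An object of class `"sim_truth"`: list with
#'   * `freq`: array `clones x timepoints x replicates` of true frequencies,
#'   * `cells`: array of sampled cell counts (multinomial mode),
#'   * `truth`: data.frame `clone_id`, `s`, `true_class` (`UP` if s > 0,
#'     `DOWN` if s < 0, else `NS`),
#'   * `config`.
#' @export
simulate_growth <- function(fitness, config = growth_sim_config(),
                            initial_freq = NULL,
                            mode = c("multinomial", "deterministic"),
                            seed = NULL) {
  mode <- match.arg(mode)
  n <- length(fitness)
  stopifnot(n >= 1, all(1 + fitness > 0))
  ids <- names(fitness)
  if (is.null(ids)) ids <- sprintf("clone_%05d", seq_len(n))
  if (is.null(initial_freq)) initial_freq <- rep(1 / n, n)
  stopifnot(length(initial_freq) == n, abs(sum(initial_freq) - 1) < 1e-8)
  if (config$cells_per_passage < n)
    warning("cells_per_passage < number of clones: severe bottleneck")
  if (!is.null(seed)) set.seed(seed)

  tps <- config$n_timepoints
  reps <- config$n_replicates
  freq <- array(NA_real_, dim = c(n, tps, reps),
                dimnames = list(ids, paste0("T", seq_len(tps)),
                                paste0("rep", seq_len(reps))))
  cells <- array(NA_real_, dim = dim(freq), dimnames = dimnames(freq))
  for (r in seq_len(reps)) {
    f <- initial_freq
    if (mode == "multinomial") {
      # independent founding bottleneck per flask
      seeded <- as.numeric(stats::rmultinom(1, config$cells_per_passage, f))
      f <- seeded / sum(seeded)
    }
    for (t in seq_len(tps)) {
      f <- passage_update(f, fitness, config$doublings_per_passage)
      if (mode == "multinomial") {
        samp <- as.numeric(stats::rmultinom(1, config$cells_per_passage, f))
        cells[, t, r] <- samp
        carried <- as.numeric(stats::rmultinom(1, config$cells_per_passage, f))
        f_rec <- f
        f <- carried / sum(carried)
      } else {
        cells[, t, r] <- f * config$cells_per_passage
        f_rec <- f
      }
      freq[, t, r] <- f_rec
    }
  }
  structure(list(
    freq = freq, cells = cells,
    truth = data.frame(
      clone_id = ids, s = unname(fitness),
      true_class = ifelse(fitness > 0, "UP", ifelse(fitness < 0, "DOWN", "NS"))
    ),
    config = config
  ), class = "sim_truth")
}

#' @export
print.sim_truth <- function(x, ...) {
  d <- dim(x$freq)
  cat(sprintf("Growth simulation: %d clones x %d timepoints x %d replicates\n",
              d[1], d[2], d[3]))
  cat("  true classes:", paste(names(table(x$truth$true_class)),
                               table(x$truth$true_class), collapse = ", "),
      "\n")
  invisible(x)
}

#' Simulate amplicon reads for one sample
#'
#' Draws `depth` reads multinomially from the clone frequencies and applies
#' independent per-base substitution errors. Reads are the clone ORFs (the
#' sequenced amplicon), shuffled into random order.
#'
#' @param frequencies Clone frequencies summing to 1.
#' @param orfs Clone ORF sequences aligned with `frequencies`.
#' @param depth Number of reads.
#' @param error_rate Per-base substitution probability in `[0, 1)`.
#' @param seed Optional integer seed.
#' @return Character vector of `depth` reads; attribute `source_clone` gives
#'   the (shuffled) index of each read's clone of origin.
#' @export
simulate_reads <- function(frequencies, orfs, depth = 1e6,
                           error_rate = 0.001, seed = NULL) {
  stopifnot(length(frequencies) == length(orfs),
            abs(sum(frequencies) - 1) < 1e-6, depth >= 1)
  if (error_rate < 0 || error_rate >= 1)
    stop("`error_rate` must be in [0, 1)")
  if (!is.null(seed)) set.seed(seed)
  counts <- as.numeric(stats::rmultinom(1, depth, frequencies))
  src <- rep.int(seq_along(orfs), counts)
  ord <- sample.int(length(src))
  src <- src[ord]
  reads <- add_substitution_errors_cpp(orfs[src], error_rate)
  attr(reads, "source_clone") <- src
  reads
}

#' Write amplicon reads to a FASTQ file
#'
#' Sanger encoding (Phred+33) with a constant per-base quality.
#'
#' @param reads Character vector of reads.
#' @param path Output file path; conventionally `rep{r}_T{t}.fastq`.
#' @param quality_char Single quality character applied to every base
#'   (default `"I"`, Phred 40).
#' @param ids Read identifiers (default `read_1..n`).
#' @return `path`, invisibly.
#' @export
write_fastq <- function(reads, path, quality_char = "I", ids = NULL) {
  stopifnot(is.character(reads), nchar(quality_char) == 1L)
  if (is.null(ids)) ids <- paste0("read_", seq_along(reads))
  dna <- Biostrings::DNAStringSet(reads)
  names(dna) <- ids
  qual <- Biostrings::PhredQuality(strrep(quality_char, nchar(reads)))
  qdna <- Biostrings::QualityScaledDNAStringSet(dna, qual)
  Biostrings::writeQualityScaledXStringSet(qdna, path)
  invisible(path)
}

#' Read amplicon reads from FASTQ
#'
#' @param path FASTQ file path.
#' @return Character vector of read sequences (names = read ids).
#' @export
read_fastq <- function(path) {
  dna <- Biostrings::readDNAStringSet(path, format = "fastq")
  out <- as.character(dna)
  names(out) <- names(dna)
  out
}

#' Write simulation ground truth as TSV
#'
#' Long format: `clone_id`, `replicate`, `timepoint`, `frequency`, `s`.
#'
#' @param sim A `"sim_truth"` object from [simulate_growth()].
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_sim_truth <- function(sim, path) {
  d <- dim(sim$freq)
  long <- data.frame(
    clone_id = rep(dimnames(sim$freq)[[1]], times = d[2] * d[3]),
    replicate = rep(rep(seq_len(d[3]), each = d[1] * d[2])),
    timepoint = rep(rep(seq_len(d[2]), each = d[1]), times = d[3]),
    frequency = as.vector(sim$freq),
    s = rep(sim$truth$s, times = d[2] * d[3])
  )
  utils::write.table(long, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Simulate the small pooled growth experiment
#'
#' Pool-scale wrapper around [simulate_growth()]: by default 14 clones in
#' three replicate flasks over five passage cycles, seeded with 7e5 cells,
#' emulating a joint growth experiment of individually constructed expression
#' clones.
#'
#' @param fitness Per-clone fitness vector (length defines the pool size;
#'   default 14 neutral clones named `Mdng*`).
#' @param n_replicates,n_cycles,cells_per_passage Pool-scale defaults.
#' @param mode,seed Passed to [simulate_growth()].
#' @return A `"sim_truth"` object with `n_cycles` timepoints.
#' @export
make_mdng_pool <- function(fitness = NULL, n_replicates = 3L, n_cycles = 5L,
                           cells_per_passage = 7e5,
                           mode = c("multinomial", "deterministic"),
                           seed = NULL) {
  if (is.null(fitness))
    fitness <- stats::setNames(rep(0, 14), paste0("Mdng", seq_len(14)))
  cfg <- growth_sim_config(n_replicates = n_replicates,
                           n_timepoints = n_cycles,
                           cells_per_passage = cells_per_passage)
  simulate_growth(fitness, cfg, mode = match.arg(mode), seed = seed)
}
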