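# Independent brute-force oracles used by the suite. These deliberately take
# the dumbest correct route so they share no code with the implementation.

# BH step-up, straight from the definition: find the largest k with
# p_(k) <= k/m * q by scanning all thresholds.
oracle_bh <- function(p) {
  m <- length(p)
  ord <- order(p)
  ranked <- p[ord]
  adj <- ranked * m / seq_len(m)
  # enforce monotonicity from the right
  for (i in rev(seq_len(m - 1))) adj[i] <- min(adj[i], adj[i + 1])
  adj <- pmin(adj, 1)
  out <- numeric(m)
  out[ord] <- adj
  out
}

# KS D statistic by exhaustive evaluation of both ECDFs over a fine grid of
# all jump points and their midpoints.
oracle_ks_D <- function(x, y) {
  pts <- sort(unique(c(x, y)))
  grid <- sort(unique(c(pts, pts - 1e-9, pts + 1e-9)))
  d <- vapply(grid, function(t) abs(mean(x <= t) - mean(y <= t)), numeric(1))
  max(d)
}

# Codon-by-codon translation using Biostrings' genetic code, truncating at
# the first stop.
oracle_translate <- function(orf) {
  aa <- as.character(Biostrings::translate(Biostrings::DNAString(orf),
                                           no.init.codon = TRUE))
  stop_at <- regexpr("*", aa, fixed = TRUE)
  if (stop_at > 0) aa <- substr(aa, 1, stop_at - 1)
  aa
}

# Spearman rho as Pearson on average ranks, written out longhand.
oracle_spearman_rho <- function(x, y) {
  rx <- rank(x); ry <- rank(y)
  mx <- mean(rx); my <- mean(ry)
  sum((rx - mx) * (ry - my)) /
    sqrt(sum((rx - mx)^2) * sum((ry - my)^2))
}

# Hamming distance by character comparison.
oracle_hamming <- function(a, b) {
  sum(strsplit(a, "")[[1]] != strsplit(b, "")[[1]])
}

random_insert <- function(n = 1, len = 150) {
  vapply(seq_len(n), function(i)
    paste(sample(c("A", "C", "G", "T"), len, replace = TRUE), collapse = ""),
    character(1))
}

# A valid synthetic amplicon read with vector flanks around a given insert.
flanked_read <- function(insert, design = library_design(),
                         pre = "TTGCAT", post = "GGTACC") {
  orf <- paste0(paste(design$constant5_codons, collapse = ""), insert,
                paste(design$histag_codons, collapse = ""))
  paste0(pre, design$flank5, orf, design$flank3, post)
}
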