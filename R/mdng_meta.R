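#' Tie-aware Spearman rank correlation
#'
#' Average ranks are assigned to ties; rho is the Pearson correlation of the
#' rank vectors. The two-tailed p-value uses the t approximation
#' `t = rho*sqrt((n-2)/(1-rho^2))` on `n-2` degrees of freedom, or an exact
#' permutation enumeration for small samples.
#'
#' @param x,y Paired numeric vectors; pairs with a missing value are dropped.
#' @param method `"t"` (default) or `"permutation"` (exact enumeration,
#'   `n <= 8`).
#' @return List with `rho`, `p_value`, `n`.
#' @export
spearman_with_ties <- function(x, y, method = c("t", "permutation")) {
  method <- match.arg(method)
  stopifnot(length(x) == length(y))
  ok <- !is.na(x) & !is.na(y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 3L) stop("need at least 3 complete pairs")
  rx <- rank(x); ry <- rank(y)
  if (stats::var(rx) == 0 || stats::var(ry) == 0)
    stop("rho undefined: zero rank variance")
  rho <- stats::cor(rx, ry)
  if (method == "t") {
    if (abs(rho) >= 1) {
      p <- 0
    } else {
      tstat <- rho * sqrt((n - 2) / (1 - rho^2))
      p <- 2 * stats::pt(-abs(tstat), df = n - 2)
    }
  } else {
    if (n > 8L) stop("exact permutation enumeration limited to n <= 8")
    perms <- permutations_of(n)
    obs <- abs(rho)
    rhos <- apply(perms, 1, function(pm) stats::cor(rx, ry[pm]))
    p <- mean(abs(rhos) >= obs - 1e-12)
  }
  list(rho = rho, p_value = p, n = n)
}

permutations_of <- function(n) {
  if (n == 1L) return(matrix(1L))
  sub <- permutations_of(n - 1L)
  do.call(rbind, lapply(seq_len(n), function(i) {
    rest <- seq_len(n)[-i]
    cbind(i, matrix(rest[sub], nrow = nrow(sub)))
  }))
}

#' Classify foldability from an intrinsic disorder score
#'
#' Average intrinsic disorder scores (IDS, in `[0, 1]`; higher = more
#' disordered) map to foldability labels with strict boundaries: `low`
#' foldability if IDS > 0.4, `high` if IDS < 0.1, `intermediate` otherwise
#' (boundary values inclusive in the intermediate class).
#'
#' @param ids Numeric vector of disorder scores in `[0, 1]`.
#' @return Character vector of labels in `{"low", "high", "intermediate"}`.
#' @export
classify_foldability <- function(ids) {
  stopifnot(is.numeric(ids))
  if (any(!is.na(ids) & (ids < 0 | ids > 1)))
    stop("`ids` must lie in [0, 1]")
  ifelse(is.na(ids), NA_character_,
         ifelse(ids > 0.4, "low", ifelse(ids < 0.1, "high", "intermediate")))
}

#' Filter differential-expression results to significant strong responders
#'
#' Retains genes with `padj < alpha` and at least `min_fold`-fold change in
#' either direction (`|log2fc| >= log2(min_fold)`).
#'
#' @param results data.frame with `log2fc` and `padj` columns.
#' @param alpha Adjusted-p threshold.
#' @param min_fold Minimal fold change (linear scale).
#' @return The qualifying rows; attribute `n_de` holds their count.
#' @export
de_filter <- function(results, alpha = 0.05, min_fold = 2) {
  stopifnot(all(c("log2fc", "padj") %in% names(results)), min_fold >= 1)
  keep <- !is.na(results$padj) & results$padj < alpha &
    !is.na(results$log2fc) & abs(results$log2fc) >= log2(min_fold)
  out <- results[keep, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "n_de") <- nrow(out)
  out
}

#' Expression relative to a co-expressed reference transcript
#'
#' Ratio of a transcript's (normalized) expression to a reference transcript
#' measured in the same sample; invariant to any common library-size scaling.
#'
#' @param gene_counts Numeric vector of transcript expression values.
#' @param reference_counts Matching reference-transcript values (> 0).
#' @return `gene_counts / reference_counts`.
#' @export
normalize_to_reference <- function(gene_counts, reference_counts) {
  stopifnot(length(reference_counts) %in% c(1L, length(gene_counts)))
  if (any(reference_counts <= 0)) stop("reference expression must be positive")
  gene_counts / reference_counts
}

#' Top up- and down-regulated genes of one experiment
#'
#' The `n` genes with the largest and the `n` with the smallest log2 fold
#' change, signed `+1`/`-1`. Ties at the cutoff are broken by gene id
#' (lexicographic, logged via a message); if fewer than `n` genes change in a
#' direction, all of them are taken and the shortfall is noted.
#'
#' @param results data.frame with `gene_id` and `log2fc` columns (typically
#'   pre-filtered with [de_filter()]).
#' @param n Number of genes per direction.
#' @return data.frame `gene_id`, `log2fc`, `sign`; attribute `shortfall`
#'   names directions with fewer than `n` genes.
#' @export
top_n_sets <- function(results, n = 10L) {
  stopifnot(all(c("gene_id", "log2fc") %in% names(results)))
  res <- results[!is.na(results$log2fc), , drop = FALSE]
  up <- res[res$log2fc > 0, , drop = FALSE]
  dn <- res[res$log2fc < 0, , drop = FALSE]
  shortfall <- character(0)
  pick <- function(df, decreasing) {
    ord <- order(if (decreasing) -df$log2fc else df$log2fc, df$gene_id,
                 method = "radix")
    k <- min(n, nrow(df))
    if (k < nrow(df)) {
      cut_val <- df$log2fc[ord[k]]
      if (any(df$log2fc[ord[-seq_len(k)]] == cut_val))
        message("tie at rank ", k, " broken by gene id")
    }
    df[ord[seq_len(k)], , drop = FALSE]
  }
  top_up <- pick(up, TRUE)
  top_dn <- pick(dn, FALSE)
  if (nrow(top_up) < n) shortfall <- c(shortfall, "up")
  if (nrow(top_dn) < n) shortfall <- c(shortfall, "down")
  out <- rbind(
    data.frame(gene_id = top_up$gene_id, log2fc = top_up$log2fc,
               sign = rep(1L, nrow(top_up))),
    data.frame(gene_id = top_dn$gene_id, log2fc = top_dn$log2fc,
               sign = rep(-1L, nrow(top_dn)))
  )
  rownames(out) <- NULL
  attr(out, "shortfall") <- shortfall
  out
}

#' Recurrence matrix of top-responding genes across experiments
#'
#' Builds the gene x experiment matrix of signed memberships (+1 up, -1
#' down, 0 absent) restricted to genes present in at least two experiments,
#' ordered by descending occurrence count `N`. A gene appearing with both
#' signs across experiments is flagged as a direction conflict.
#'
#' @param sets Named list (one element per experiment) of [top_n_sets()]
#'   results, or of data.frames with `gene_id` and `sign` columns.
#' @return List with `matrix` (integer, genes x experiments), `n_occurrences`
#'   (per retained gene), `conflict` (logical per gene), `per_set_recurrent`
#'   (number of retained genes per experiment).
#' @export
recurrence_matrix <- function(sets) {
  stopifnot(is.list(sets), length(sets) >= 2L)
  if (is.null(names(sets))) names(sets) <- paste0("set", seq_along(sets))
  genes <- sort(unique(unlist(lapply(sets, `[[`, "gene_id"))))
  m <- matrix(0L, nrow = length(genes), ncol = length(sets),
              dimnames = list(genes, names(sets)))
  for (s in names(sets)) {
    df <- sets[[s]]
    m[df$gene_id, s] <- as.integer(df$sign)
  }
  n_occ <- as.integer(rowSums(m != 0L))
  names(n_occ) <- rownames(m)
  keep <- n_occ >= 2L
  m <- m[keep, , drop = FALSE]
  n_occ <- n_occ[keep]
  if (nrow(m) > 0L) {
    ord <- order(-n_occ, rownames(m), method = "radix")
    m <- m[ord, , drop = FALSE]
    n_occ <- n_occ[ord]
  }
  conflict <- apply(m, 1, function(r) any(r > 0) && any(r < 0))
  per_set <- as.integer(colSums(m != 0L))
  names(per_set) <- colnames(m)
  list(matrix = m, n_occurrences = n_occ, conflict = conflict,
       per_set_recurrent = per_set)
}

#' Packaged per-gene summary tables for the expression experiments
#'
#' Two small TSV fixtures shipped with the package: per-gene relative
#' expression level (normalized to the hygromycin resistance transcript of
#' the same construct), counts of differentially responding host genes, the
#' top enriched GO term (pass-through annotation, not computed here), ORF
#' length, average intrinsic disorder score, foldability label, and rank in
#' the joint growth experiment (`NA` for members that failed to grow).
#'
#' @param which `"expression"` (expression level / DE counts / GO) or
#'   `"structure"` (length / IDS / foldability / growth rank).
#' @return data.frame.
#' @export
mdng_table <- function(which = c("expression", "structure")) {
  which <- match.arg(which)
  file <- c(expression = "mdng_expression_response.tsv",
            structure = "mdng_structure_growth.tsv")[[which]]
  path <- system.file("extdata", file, package = "pepgrow", mustWork = TRUE)
  utils::read.delim(path, comment.char = "#", stringsAsFactors = FALSE)
}
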