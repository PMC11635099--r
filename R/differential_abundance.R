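#' Median-of-ratios size factors
#'
#' For each clone with strictly positive counts in every sample, the ratio of
#' its count to its geometric mean across samples is formed; the size factor
#' of a sample is the median of these ratios. Absorbs sequencing-depth
#' differences without being dominated by the few strongly changing clones.
#'
#' @param counts Integer matrix, clones x samples, or a `"count_matrix"`.
#' @return Named numeric vector of positive per-sample factors.
#' @export
size_factors <- function(counts) {
  counts <- as_count_mat(counts)
  pos <- rowSums(counts > 0) == ncol(counts)
  if (!any(pos))
    condition_error("pepgrow_size_factors_undefined",
                    "size factors undefined: no clone with all-positive counts")
  lc <- log(counts[pos, , drop = FALSE])
  loggeo <- rowMeans(lc)
  sf <- apply(lc, 2, function(col) exp(stats::median(col - loggeo)))
  stopifnot(all(sf > 0))
  sf
}

as_count_mat <- function(x) {
  if (inherits(x, "count_matrix")) x$counts else as.matrix(x)
}

#' Per-clone negative-binomial dispersion estimates
#'
#' Method-of-moments estimate on size-factor-normalized counts, pooled within
#' condition: for each condition the sample mean and variance give a moment
#' estimate `alpha_c = (s^2 - mu)/mu^2`; these are pooled across conditions
#' weighted by degrees of freedom and floored at zero. The raw estimates are
#' then shrunk toward a mean-dispersion trend `alpha(mu) = a0 + a1/mu`
#' (fitted across clones) by `shrink_weight`.
#'
#' @param counts Count matrix or `"count_matrix"`.
#' @param sf Size factors from [size_factors()].
#' @param condition Factor/vector of two condition labels, one per sample;
#'   each condition needs >= 2 samples.
#' @param shrink_weight Weight in `[0, 1]` given to the fitted trend
#'   (0 = raw moments, 1 = trend only). Default 0.5.
#' @return data.frame `clone_id`, `mean_norm`, `alpha_mom`, `alpha_trend`,
#'   `alpha` (final), `untestable` (all-zero clones: `alpha` is `NA`).
#' @export
estimate_dispersion <- function(counts, sf, condition, shrink_weight = 0.5) {
  counts <- as_count_mat(counts)
  stopifnot(length(sf) == ncol(counts), length(condition) == ncol(counts),
            shrink_weight >= 0, shrink_weight <= 1)
  condition <- as.factor(condition)
  if (any(table(condition) < 2L)) stop("each condition needs >= 2 samples")
  k <- sweep(counts, 2, sf, "/")
  lev <- levels(condition)
  num <- 0; den <- 0
  for (l in lev) {
    kc <- k[, condition == l, drop = FALSE]
    n_c <- ncol(kc)
    mu_c <- rowMeans(kc)
    v_c <- apply(kc, 1, stats::var)
    a_c <- ifelse(mu_c > 0, (v_c - mu_c) / mu_c^2, NA_real_)
    w <- n_c - 1
    num <- num + ifelse(is.na(a_c), 0, w * a_c)
    den <- den + ifelse(is.na(a_c), 0, w)
  }
  alpha_mom <- pmax(0, ifelse(den > 0, num / den, NA_real_))
  mean_norm <- rowMeans(k)
  untestable <- rowSums(counts) == 0
  alpha_mom[untestable] <- NA_real_

  ## trend alpha(mu) = a0 + a1/mu fitted on testable clones
  ok <- !is.na(alpha_mom) & mean_norm > 0
  if (sum(ok) >= 10) {
    fit <- stats::lm(alpha_mom[ok] ~ I(1 / mean_norm[ok]))
    a0 <- max(0, unname(stats::coef(fit)[1]))
    a1 <- max(0, unname(stats::coef(fit)[2]))
  } else {
    a0 <- mean(alpha_mom[ok])
    a1 <- 0
  }
  alpha_trend <- ifelse(mean_norm > 0, a0 + a1 / mean_norm, NA_real_)
  alpha <- (1 - shrink_weight) * alpha_mom + shrink_weight * alpha_trend
  alpha <- pmax(0, alpha)
  data.frame(clone_id = rownames(counts) %||% seq_len(nrow(counts)),
             mean_norm = mean_norm, alpha_mom = alpha_mom,
             alpha_trend = alpha_trend, alpha = alpha,
             untestable = untestable, row.names = NULL)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Negative-binomial Wald test between two conditions
#'
#' Per clone, a negative-binomial GLM with log link and a two-level condition
#' indicator is fitted to the size-factor-normalized counts by iteratively
#' reweighted least squares at the clone's fixed dispersion (working weights
#' `mu/(1 + alpha*mu)`). Fitting on the normalized scale makes the result
#' exactly invariant to rescaling any sample's counts: the size factor
#' absorbs the scale. The Wald statistic is the condition coefficient over
#' its standard error (expected Fisher information), with a two-sided normal
#' p-value.
#'
#' @param counts Count matrix or `"count_matrix"`.
#' @param sf Size factors.
#' @param dispersions Result of [estimate_dispersion()] (or a bare numeric
#'   vector of per-clone `alpha`).
#' @param condition Two-level factor; the *second* level is the numerator of
#'   the fold change (use `relevel`/`factor(levels=)` to set T1 as
#'   reference and T10 as numerator).
#' @param max_iter,tol IRLS iteration cap and convergence tolerance on the
#'   coefficient step.
#' @return data.frame with `clone_id`, `base_mean` (mean normalized count),
#'   `log2fc`, `se` (of log2fc), `stat`, `wald_p`, `converged`. Clones that
#'   fail to converge or are untestable get `NA` p-values.
#' @export
wald_test <- function(counts, sf, dispersions, condition,
                      max_iter = 50L, tol = 1e-8) {
  counts <- as_count_mat(counts)
  condition <- as.factor(condition)
  if (nlevels(condition) != 2L) stop("`condition` must have exactly 2 levels")
  if (any(table(condition) < 2L)) stop("each condition needs >= 2 samples")
  alpha <- if (is.data.frame(dispersions)) dispersions$alpha else dispersions
  stopifnot(length(alpha) == nrow(counts), length(sf) == ncol(counts))

  x <- as.numeric(condition == levels(condition)[2])
  X <- cbind(1, x)
  n <- nrow(counts)
  log2fc <- se <- stat <- p <- rep(NA_real_, n)
  converged <- rep(FALSE, n)
  norm <- sweep(counts, 2, sf, "/")
  base_mean <- rowMeans(norm)

  for (i in seq_len(n)) {
    y <- norm[i, ]
    a <- alpha[i]
    if (is.na(a) || sum(y) == 0) next
    ## init from group means (pseudocount for zero groups)
    m0 <- mean(y[x == 0])
    m1 <- mean(y[x == 1])
    b <- c(log(max(m0, 0.1)), log(max(m1, 0.1)) - log(max(m0, 0.1)))
    ok <- FALSE
    for (it in seq_len(max_iter)) {
      eta <- as.numeric(X %*% b)
      mu <- pmax(exp(eta), 1e-10)
      w <- mu / (1 + a * mu)
      z <- eta + (y - mu) / mu
      xtw <- t(X * w)
      bnew <- tryCatch(solve(xtw %*% X, xtw %*% z),
                       error = function(e) NULL)
      if (is.null(bnew) || any(!is.finite(bnew))) break
      step <- max(abs(bnew - b))
      b <- as.numeric(bnew)
      if (step < tol) { ok <- TRUE; break }
    }
    if (!ok) next
    mu <- pmax(exp(as.numeric(X %*% b)), 1e-10)
    w <- mu / (1 + a * mu)
    info <- t(X * w) %*% X
    cov <- tryCatch(solve(info), error = function(e) NULL)
    if (is.null(cov) || cov[2, 2] <= 0) next
    converged[i] <- TRUE
    log2fc[i] <- b[2] / log(2)
    se[i] <- sqrt(cov[2, 2]) / log(2)
    stat[i] <- b[2] / sqrt(cov[2, 2])
    p[i] <- 2 * stats::pnorm(-abs(stat[i]))
  }
  data.frame(clone_id = rownames(counts) %||% seq_len(n),
             base_mean = base_mean, log2fc = log2fc, se = se,
             stat = stat, wald_p = p, converged = converged,
             row.names = NULL)
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up FDR adjustment over the non-missing p-values; missing entries are
#' excluded from the ranking and returned missing.
#'
#' @param p Numeric vector of p-values in `[0, 1]` (`NA` allowed).
#' @return Adjusted p-values, same length and order as `p`.
#' @export
adjust_bh <- function(p) {
  ok <- !is.na(p)
  if (any(p[ok] < 0 | p[ok] > 1)) stop("p-values must lie in [0, 1]")
  out <- rep(NA_real_, length(p))
  out[ok] <- stats::p.adjust(p[ok], method = "BH")
  out
}

#' Classify clones as UP / DOWN / NS
#'
#' `UP` if `padj < alpha` and `log2fc > 0`; `DOWN` if `padj < alpha` and
#' `log2fc < 0`; otherwise (including missing `padj`) `NS`. The three counts
#' partition the clone set.
#'
#' @param results data.frame with `log2fc` and `padj` columns (e.g.
#'   [wald_test()] output after [adjust_bh()]).
#' @param alpha Adjusted-significance threshold.
#' @return `results` with an added `class` column; attribute
#'   `class_counts` holds the UP/DOWN/NS tally.
#' @export
classify_clones <- function(results, alpha = 0.05) {
  stopifnot(all(c("log2fc", "padj") %in% names(results)))
  sig <- !is.na(results$padj) & results$padj < alpha & !is.na(results$log2fc)
  cls <- rep("NS", nrow(results))
  cls[sig & results$log2fc > 0] <- "UP"
  cls[sig & results$log2fc < 0] <- "DOWN"
  results$class <- factor(cls, levels = c("UP", "DOWN", "NS"))
  attr(results, "class_counts") <- table(results$class)
  results
}

#' Full differential-abundance pipeline for a T-first vs T-last contrast
#'
#' Convenience wrapper: size factors, dispersion estimation, Wald test, BH
#' adjustment and classification on the samples of two timepoints.
#'
#' @param cm A `"count_matrix"` whose `samples` metadata has a `timepoint`
#'   column.
#' @param t_ref,t_alt Reference and alternative timepoints (defaults: first
#'   and last present).
#' @param alpha Significance threshold for classification.
#' @param shrink_weight Dispersion shrinkage weight.
#' @return Classified results data.frame (one row per clone).
#' @export
diff_abundance <- function(cm, t_ref = NULL, t_alt = NULL, alpha = 0.05,
                           shrink_weight = 0.5) {
  stopifnot(inherits(cm, "count_matrix"))
  tps <- cm$samples$timepoint
  if (is.null(t_ref)) t_ref <- min(tps)
  if (is.null(t_alt)) t_alt <- max(tps)
  sel <- tps %in% c(t_ref, t_alt)
  counts <- cm$counts[, sel, drop = FALSE]
  cond <- factor(ifelse(tps[sel] == t_ref, "ref", "alt"),
                 levels = c("ref", "alt"))
  sf <- size_factors(counts)
  disp <- estimate_dispersion(counts, sf, cond, shrink_weight = shrink_weight)
  res <- wald_test(counts, sf, disp, cond)
  res$padj <- adjust_bh(res$wald_p)
  classify_clones(res, alpha = alpha)
}

#' Rank clones of a small pool by relative growth
#'
#' Per replicate, the relative change of a clone is its frequency at the
#' final cycle divided by its frequency at the start; clones are ranked by
#' the mean change over replicates (rank 1 = largest increase). Clones with
#' zero counts at the final cycle in every replicate are flagged
#' `failed_to_grow` and excluded from ranking (`NA` rank); clones with a zero
#' start frequency in any replicate are excluded with a warning. Mean-change
#' ties are broken by clone id.
#'
#' @param start_counts,end_counts Numeric matrices, clones x replicates, of
#'   counts (or frequencies) at the start and final cycle.
#' @return data.frame `clone_id`, per-replicate changes `change_rep*`,
#'   `mean_change`, `rank`, `failed_to_grow`.
#' @export
rank_pool_growth <- function(start_counts, end_counts) {
  start_counts <- as.matrix(start_counts)
  end_counts <- as.matrix(end_counts)
  stopifnot(identical(dim(start_counts), dim(end_counts)))
  ids <- rownames(start_counts) %||% sprintf("clone_%02d", seq_len(nrow(start_counts)))
  f_start <- sweep(start_counts, 2, colSums(start_counts), "/")
  f_end <- sweep(end_counts, 2, colSums(end_counts), "/")
  zero_start <- rowSums(f_start == 0) > 0
  if (any(zero_start))
    warning("excluding clone(s) with zero start frequency: ",
            paste(ids[zero_start], collapse = ", "))
  failed <- rowSums(end_counts) == 0 & !zero_start
  change <- f_end / f_start
  mean_change <- rowMeans(change)
  rankable <- !zero_start & !failed
  rk <- rep(NA_integer_, length(ids))
  ord <- order(-mean_change[rankable], ids[rankable], method = "radix")
  rk[which(rankable)[ord]] <- seq_len(sum(rankable))
  out <- data.frame(clone_id = ids, change, mean_change = mean_change,
                    rank = rk, failed_to_grow = failed, row.names = NULL)
  names(out)[seq_len(ncol(change)) + 1] <-
    paste0("change_rep", seq_len(ncol(change)))
  out
}

#' Tally UP/DOWN/NS classes from a deposited per-clone classification table
#'
#' Reads a TSV with at least `clone_id` and `class` columns (the format in
#' which per-clone differential-abundance classifications are deposited) and
#' returns the class counts and fractions.
#'
#' @param path TSV path, or a data.frame already in memory.
#' @return data.frame `class`, `n`, `fraction`.
#' @export
tally_classes <- function(path) {
  df <- if (is.data.frame(path)) path else utils::read.delim(path)
  stopifnot("class" %in% names(df))
  cls <- factor(df$class, levels = c("UP", "DOWN", "NS"))
  if (anyNA(cls)) stop("class column must contain only UP/DOWN/NS")
  tab <- table(cls)
  data.frame(class = names(tab), n = as.integer(tab),
             fraction = as.numeric(tab) / nrow(df), row.names = NULL)
}
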