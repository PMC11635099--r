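#' Two-sample Kolmogorov-Smirnov test
#'
#' The statistic is the supremum of the absolute difference between the two
#' empirical CDFs, evaluated over the pooled jump points. The p-value uses
#' the asymptotic Kolmogorov distribution at the effective sample size
#' `n = nx*ny/(nx+ny)`.
#'
#' @param x,y Non-empty numeric samples.
#' @return List with `D`, `p_value`, `n_x`, `n_y`.
#' @export
ks_two_sample <- function(x, y) {
  x <- x[!is.na(x)]; y <- y[!is.na(y)]
  if (length(x) == 0L || length(y) == 0L) stop("both samples must be non-empty")
  pts <- sort(unique(c(x, y)))
  Fx <- vapply(pts, function(t) mean(x <= t), numeric(1))
  Fy <- vapply(pts, function(t) mean(y <= t), numeric(1))
  D <- max(abs(Fx - Fy))
  n_eff <- length(x) * length(y) / (length(x) + length(y))
  lambda <- sqrt(n_eff) * D
  p <- kolmogorov_sf(lambda)
  list(D = D, p_value = p, n_x = length(x), n_y = length(y))
}

## survival function of the Kolmogorov distribution:
## P(K > lambda) = 2 * sum_{k>=1} (-1)^(k-1) exp(-2 k^2 lambda^2)
kolmogorov_sf <- function(lambda) {
  if (lambda <= 0) return(1)
  k <- seq_len(101)
  terms <- (-1)^(k - 1) * exp(-2 * k^2 * lambda^2)
  min(1, max(0, 2 * sum(terms)))
}

#' Compare a feature's distribution per class against the library background
#'
#' One KS test per class. The background is, by default, the full feature
#' table *including* the tested class (the convention of density panels that
#' overlay each class on the whole-library distribution); an exclusive
#' background (all other clones) is available as an option.
#'
#' @param features data.frame with a `class` column and the feature column.
#' @param feature_name Name of the numeric feature column to test.
#' @param background `"inclusive"` (default) or `"exclusive"`.
#' @param low_n Classes with fewer members than this are flagged (p still
#'   computed).
#' @return data.frame `class`, `n`, `D`, `p_value`, `low_n`.
#' @export
group_feature_tests <- function(features, feature_name,
                                background = c("inclusive", "exclusive"),
                                low_n = 5L) {
  background <- match.arg(background)
  stopifnot("class" %in% names(features), feature_name %in% names(features))
  v <- features[[feature_name]]
  classes <- sort(unique(as.character(features$class)))
  out <- lapply(classes, function(cl) {
    in_cl <- features$class == cl
    bg <- if (background == "inclusive") v else v[!in_cl]
    ks <- ks_two_sample(v[in_cl], bg)
    data.frame(class = cl, n = sum(in_cl), D = ks$D, p_value = ks$p_value,
               low_n = sum(in_cl) < low_n)
  })
  do.call(rbind, out)
}

#' Boxplot statistics of a feature within length classes
#'
#' Per bin: quartiles by linear interpolation between order statistics
#' (quantile type 7) and Tukey whiskers at the most extreme data points
#' within 1.5 x IQR of the hinges; points beyond the whiskers are listed as
#' outliers. Empty bins are omitted (with a note attribute).
#'
#' @param values Numeric feature values.
#' @param lengths Peptide lengths (same order as `values`).
#' @param bins Bin edges for `lengths`, passed to [cut()] with
#'   `right = FALSE`; default decade-wide classes covering the data.
#' @return data.frame per non-empty bin: `bin`, `n`, `q1`, `median`, `q3`,
#'   `whisker_low`, `whisker_high`; attribute `outliers` is a list of outlier
#'   values per bin, attribute `empty_bins` names omitted bins.
#' @export
length_class_boxstats <- function(values, lengths, bins = NULL) {
  stopifnot(length(values) == length(lengths))
  if (is.null(bins)) {
    lo <- 10 * floor(min(lengths) / 10)
    hi <- 10 * ceiling((max(lengths) + 1) / 10)
    bins <- seq(lo, hi, by = 10)
  }
  stopifnot(!is.unsorted(bins))
  grp <- cut(lengths, bins, right = FALSE)
  rows <- list(); outliers <- list(); empty <- character(0)
  for (lv in levels(grp)) {
    v <- values[grp == lv & !is.na(values)]
    if (length(v) == 0L) { empty <- c(empty, lv); next }
    q <- stats::quantile(v, c(0.25, 0.5, 0.75), names = FALSE, type = 7)
    iqr <- q[3] - q[1]
    lo_fence <- q[1] - 1.5 * iqr
    hi_fence <- q[3] + 1.5 * iqr
    inside <- v[v >= lo_fence & v <= hi_fence]
    rows[[lv]] <- data.frame(bin = lv, n = length(v), q1 = q[1],
                             median = q[2], q3 = q[3],
                             whisker_low = min(inside),
                             whisker_high = max(inside))
    outliers[[lv]] <- sort(v[v < lo_fence | v > hi_fence])
  }
  if (length(empty))
    message("empty bin(s) omitted: ", paste(empty, collapse = ", "))
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "outliers") <- outliers
  attr(out, "empty_bins") <- empty
  out
}

#' Flag aggregation-prone peptides from their best pairing energy
#'
#' Predicted cross-beta aggregation free energies (pasta energy units) of -5
#' or less indicate a high probability of amyloid formation / aggregation;
#' the boundary value -5 itself is flagged.
#'
#' @param peu Numeric vector of aggregation energies (`NA` allowed).
#' @return Logical vector (`NA` where `peu` is missing).
#' @export
flag_aggregation_prone <- function(peu) {
  stopifnot(is.numeric(peu))
  peu <= -5
}
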