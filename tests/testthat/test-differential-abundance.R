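## small NB count-matrix generator used across these tests
nb_matrix <- function(n_clones, mu, alpha, n_per_group, fc = 1, frac_de = 0,
                      seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  n <- 2 * n_per_group
  de <- seq_len(floor(frac_de * n_clones))
  mu_mat <- matrix(mu, n_clones, n)
  if (length(de)) mu_mat[de, (n_per_group + 1):n] <- mu * fc
  counts <- matrix(0L, n_clones, n)
  for (j in seq_len(n)) {
    counts[, j] <- if (alpha > 0)
      stats::rnbinom(n_clones, mu = mu_mat[, j], size = 1 / alpha)
    else stats::rpois(n_clones, mu_mat[, j])
  }
  dimnames(counts) <- list(sprintf("c%04d", seq_len(n_clones)),
                           sprintf("s%02d", seq_len(n)))
  counts
}

cond2 <- function(n_per_group)
  factor(rep(c("ref", "alt"), each = n_per_group), levels = c("ref", "alt"))

test_that("median-of-ratios size factors have the documented exact behavior", {
  # identical columns: all factors 1
  m <- matrix(rep(c(4L, 10L, 7L), 3), ncol = 3)
  expect_equal(unname(size_factors(m)), rep(1, 3), tolerance = 1e-12)

  # doubling one column doubles its factor exactly
  m2 <- m; m2[, 2] <- m2[, 2] * 2L
  sf <- size_factors(m2)
  expect_equal(sf[2] / sf[1], 2, tolerance = 1e-12)
  expect_equal(sf[2] / sf[3], 2, tolerance = 1e-12)

  # single clone (4, 9): factors proportional to (4/6, 9/6)
  sf1 <- size_factors(matrix(c(4L, 9L), nrow = 1))
  expect_equal(unname(sf1), c(4, 9) / 6, tolerance = 1e-12)

  expect_error(size_factors(matrix(c(0L, 5L, 3L, 0L), 2)),
               class = "pepgrow_size_factors_undefined")
})

test_that("dispersion estimates track the truth and degenerate cases", {
  # Poisson data: median estimate near zero
  cp <- nb_matrix(1000, mu = 100, alpha = 0, n_per_group = 5, seed = 1)
  dp <- estimate_dispersion(cp, rep(1, 10), cond2(5), shrink_weight = 0)
  expect_lt(stats::median(dp$alpha, na.rm = TRUE), 0.01)

  # NB alpha = 0.5 at 20 samples: mean estimate in [0.3, 0.7]
  cn <- nb_matrix(500, mu = 100, alpha = 0.5, n_per_group = 10, seed = 2)
  dn <- estimate_dispersion(cn, rep(1, 20), cond2(10), shrink_weight = 0)
  expect_gt(mean(dn$alpha, na.rm = TRUE), 0.3)
  expect_lt(mean(dn$alpha, na.rm = TRUE), 0.7)

  # constant counts: zero variance, zero dispersion
  cc <- matrix(7L, nrow = 3, ncol = 6)
  dc <- estimate_dispersion(cc, rep(1, 6), cond2(3), shrink_weight = 0)
  expect_equal(dc$alpha, rep(0, 3))

  # all-zero clone flagged untestable
  cz <- rbind(matrix(5L, 20, 4), 0L)
  dz <- estimate_dispersion(cz, rep(1, 4), cond2(2))
  expect_true(dz$untestable[21])
  expect_true(is.na(dz$alpha_mom[21]))
})

test_that("the Wald test is calibrated and recovers known fold changes", {
  # identical counts in both conditions: log2fc 0, p near 1
  ci <- matrix(rep(c(40L, 55L, 70L), 6), nrow = 3)
  sf <- rep(1, 6)
  ri <- wald_test(ci, sf, rep(0.01, 3), cond2(3))
  expect_equal(ri$log2fc, rep(0, 3), tolerance = 1e-6)
  expect_true(all(ri$wald_p > 0.99))

  # 4-fold shift at depth-scale means: log2fc near 2, tiny p. The DE
  # fraction is kept small so the median-of-ratios anchors on null clones
  # (a large one-sided DE fraction shifts the median ratio itself).
  set.seed(3)
  c4 <- nb_matrix(200, mu = 2500, alpha = 0.01, n_per_group = 5, fc = 4,
                  frac_de = 0.05)
  sf4 <- size_factors(c4)
  d4 <- estimate_dispersion(c4, sf4, cond2(5))
  r4 <- wald_test(c4, sf4, d4, cond2(5))
  de <- seq_len(10)
  expect_lt(abs(mean(r4$log2fc[de]) - 2), 0.2)
  expect_true(all(abs(r4$log2fc[de] - 2) < 4 * r4$se[de]))
  expect_true(all(r4$wald_p[de] < 1e-6))

  # null simulation: p-values approximately uniform
  cnull <- nb_matrix(10000, mu = 500, alpha = 0.02, n_per_group = 5, seed = 4)
  sfn <- size_factors(cnull)
  dn <- estimate_dispersion(cnull, sfn, cond2(5))
  rn <- wald_test(cnull, sfn, dn, cond2(5))
  ks <- stats::ks.test(rn$wald_p, "punif")
  expect_gt(ks$p.value, 0.001)
})

test_that("scale invariance: rescaling a sample leaves log2fc and p unchanged", {
  set.seed(5)
  cbase <- nb_matrix(100, mu = 300, alpha = 0.05, n_per_group = 3, fc = 2,
                     frac_de = 0.2)
  run <- function(m) {
    sf <- size_factors(m)
    d <- estimate_dispersion(m, sf, cond2(3))
    wald_test(m, sf, d, cond2(3))
  }
  r1 <- run(cbase)
  cscaled <- cbase; cscaled[, 2] <- cscaled[, 2] * 7L
  r2 <- run(cscaled)
  # the fold-change estimate is an exact function of normalized group means,
  # so the factor absorbs the scale completely
  expect_equal(r2$log2fc, r1$log2fc, tolerance = 1e-8)
  # p-values absorb the factor up to the global depth rebaseline: rescaling
  # one of m samples shifts every median-of-ratios factor by c^(1/m), a
  # uniform change in apparent depth that any depth-aware count model feels
  # slightly
  expect_equal(r2$wald_p, r1$wald_p, tolerance = 0.02)
  expect_gt(stats::cor(r2$stat, r1$stat), 0.9999)
})

test_that("BH adjustment matches the brute-force step-up oracle", {
  expect_equal(adjust_bh(rep(1, 5)), rep(1, 5))
  expect_equal(adjust_bh(0.03), 0.03)
  expect_equal(adjust_bh(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4),
               tolerance = 1e-12)
  expect_error(adjust_bh(c(0.5, 1.2)), "0, 1")

  set.seed(6)
  for (i in 1:20) {
    p <- runif(sample(3:50, 1))^sample(1:3, 1)
    expect_equal(adjust_bh(p), oracle_bh(p), tolerance = 1e-12)
  }

  # missing values are excluded and returned missing
  p <- c(0.01, NA, 0.04, NA, 0.20)
  adj <- adjust_bh(p)
  expect_true(all(is.na(adj[c(2, 4)])))
  expect_equal(adj[c(1, 3, 5)], oracle_bh(p[c(1, 3, 5)]), tolerance = 1e-12)
})

test_that("classification rule partitions clones and honours missingness", {
  res <- data.frame(
    log2fc = c(1.2, -0.5, 0.8, -2, NA),
    padj = c(0.01, 0.2, NA, 0.001, 0.01)
  )
  cls <- classify_clones(res, alpha = 0.05)
  expect_identical(as.character(cls$class), c("UP", "NS", "NS", "DOWN", "NS"))
  counts <- attr(cls, "class_counts")
  expect_identical(sum(counts), nrow(res))
})

test_that("FDR is controlled on a fully null experiment", {
  set.seed(7)
  rates <- replicate(5, {
    cnull <- nb_matrix(4000, mu = 400, alpha = 0.02, n_per_group = 5)
    res <- suppressWarnings({
      sf <- size_factors(cnull)
      d <- estimate_dispersion(cnull, sf, cond2(5))
      r <- wald_test(cnull, sf, d, cond2(5))
      r$padj <- adjust_bh(r$wald_p)
      classify_clones(r)
    })
    mean(res$class != "NS")
  })
  expect_lte(mean(rates), 0.07)
})

test_that("cross-check: size factors and fold changes agree with DESeq2", {
  skip_if_not_installed("DESeq2")
  set.seed(8)
  counts <- nb_matrix(300, mu = 800, alpha = 0.02, n_per_group = 5, fc = 3,
                      frac_de = 0.1)
  cond <- cond2(5)
  sf <- size_factors(counts)

  suppressMessages({
    dds <- DESeq2::DESeqDataSetFromMatrix(counts,
      S4Vectors::DataFrame(condition = cond), ~condition)
    dds <- DESeq2::estimateSizeFactors(dds)
    dsf <- DESeq2::sizeFactors(dds)
  })
  # DESeq2 divides by the geometric mean of factors; compare up to scale
  expect_equal(sf / exp(mean(log(sf))), dsf / exp(mean(log(dsf))),
               tolerance = 1e-10, ignore_attr = TRUE)

  suppressMessages({
    dds <- DESeq2::DESeq(dds, quiet = TRUE)
    dres <- DESeq2::results(dds, contrast = c("condition", "alt", "ref"))
  })
  disp <- estimate_dispersion(counts, sf, cond)
  mine <- wald_test(counts, sf, disp, cond)
  # strong effects: agree on log2fc within a few percent despite different
  # dispersion machinery
  de <- seq_len(30)
  expect_lt(stats::median(abs(mine$log2fc[de] - dres$log2FoldChange[de])), 0.05)
  expect_gt(stats::cor(mine$log2fc, dres$log2FoldChange), 0.99)
})

test_that("pool growth ranking reproduces closed-form changes and na rules", {
  # deterministic neutral pool: all changes 1
  start <- matrix(100, 4, 3, dimnames = list(letters[1:4], NULL))
  expect_warning(r0 <- rank_pool_growth(start, start), NA)
  expect_equal(r0$mean_change, rep(1, 4))
  expect_identical(r0$rank, 1:4)  # tie broken by clone id

  # known changes rank correctly
  end <- start * matrix(rep(c(4, 2, 1, 0.5), 3), 4)
  r1 <- rank_pool_growth(start, end)
  expect_identical(r1$rank, 1:4)
  expect_equal(r1$mean_change[1] / r1$mean_change[4], 8, tolerance = 1e-9)

  # clone absent at the final cycle in all replicates: failed, NA rank
  end2 <- end; end2["c", ] <- 0
  r2 <- rank_pool_growth(start, end2)
  expect_true(r2$failed_to_grow[r2$clone_id == "c"])
  expect_true(is.na(r2$rank[r2$clone_id == "c"]))
  expect_identical(sort(r2$rank[!is.na(r2$rank)]), 1:3)

  # zero start frequency: excluded with warning
  start3 <- start; start3["b", ] <- 0
  expect_warning(r3 <- rank_pool_growth(start3, end), "zero start")
  expect_true(is.na(r3$rank[r3$clone_id == "b"]))
})

test_that("simulated pools recover the fitness order of their clones", {
  s <- seq(0.12, -0.12, length.out = 14)
  names(s) <- sprintf("P%02d", 1:14)
  set.seed(9)
  concord <- replicate(60, {
    sim <- make_mdng_pool(fitness = s)
    r <- rank_pool_growth(sim$cells[, 1, ], sim$cells[, 5, ])
    # fraction of concordant pairs between fitness order and recovered rank
    stats::cor(r$rank, seq_len(14), method = "kendall")
  })
  expect_gte(mean((concord + 1) / 2), 0.90)
})

test_that("class tallies from a deposited-style table are exact", {
  tab <- data.frame(
    clone_id = sprintf("c%03d", 1:100),
    class = rep(c("DOWN", "NS", "UP"), c(53, 39, 8))
  )
  tl <- tally_classes(tab)
  expect_identical(tl$n[tl$class == "DOWN"], 53L)
  expect_identical(tl$n[tl$class == "UP"], 8L)
  expect_equal(sum(tl$fraction), 1)
  path <- withr::local_tempfile(fileext = ".tsv")
  write.table(tab, path, sep = "\t", row.names = FALSE, quote = FALSE)
  expect_identical(tally_classes(path), tl)
})
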