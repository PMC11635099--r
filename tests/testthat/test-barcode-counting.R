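test_that("hamming kernel matches the character-level oracle", {
  set.seed(21)
  a <- random_insert(50, len = 40)
  b <- random_insert(50, len = 40)
  expect_identical(as.integer(hamming_dist_cpp(a, b)),
                   vapply(seq_along(a), function(i) as.integer(
                     oracle_hamming(a[i], b[i])), integer(1)))
  expect_identical(hamming_dist_cpp("ACGT", "ACGT"), 0L)
})

test_that("reference building recovers the true clone set from clean reads", {
  lib <- generate_library(500, seed = 31)
  freq <- rep(1 / 500, 500)
  reads <- simulate_reads(freq, lib$orf_nt, depth = 50000, error_rate = 0,
                          seed = 32)
  ref <- build_reference(reads, min_count = 2)
  expect_s3_class(ref, "reference_library")
  expect_identical(nrow(ref), 500L)
  expect_setequal(ref$insert_nt, lib$insert_nt)
  expect_true(all(ref$count >= 2))
})

test_that("error variants are absorbed at positive radius and split at radius 0", {
  lib <- generate_library(500, seed = 41)
  freq <- rep(1 / 500, 500)
  reads <- simulate_reads(freq, lib$orf_nt, depth = 50000, error_rate = 0.002,
                          seed = 42)
  ref2 <- build_reference(reads, min_count = 2, collapse_radius = 2)
  expect_identical(nrow(ref2), 500L)
  expect_setequal(ref2$insert_nt, lib$insert_nt)

  ref0 <- build_reference(reads, min_count = 1, collapse_radius = 0)
  expect_gt(nrow(ref0), 500L)  # error variants remain separate entries

  # one clone plus its 1-mismatch variant collapse to a single entry
  center <- lib$insert_nt[1]
  variant <- paste0(ifelse(substr(center, 1, 1) == "A", "C", "A"),
                    substr(center, 2, 150))
  orfs <- paste0("ATGGCC", c(center, variant), strrep("CAC", 6))
  small <- build_reference(rep(orfs, c(10, 3)), min_count = 2,
                           collapse_radius = 2)
  expect_identical(nrow(small), 1L)
  expect_identical(small$insert_nt, center)
  expect_equal(small$count, 13)

  expect_error(build_reference(character(0)), class = "pepgrow_empty_reference")
})

test_that("read mapping assigns within radius, drops ties, and reports rates", {
  lib <- generate_library(200, seed = 51)
  ref <- build_reference(
    simulate_reads(rep(1 / 200, 200), lib$orf_nt, depth = 20000,
                   error_rate = 0, seed = 52), min_count = 2)

  # clean reads map perfectly
  clean <- simulate_reads(rep(1 / 200, 200), lib$orf_nt, depth = 5000,
                          error_rate = 0, seed = 53)
  m <- map_reads(clean, ref)
  expect_equal(m$mapping_rate, 1.0)
  expect_equal(sum(m$counts), 5000)

  # a read with one substitution maps to its source clone
  src <- lib$insert_nt[7]
  mut <- paste0(substr(src, 1, 74),
                chartr("ACGT", "CATG", substr(src, 75, 75)),
                substr(src, 76, 150))
  one <- map_reads(paste0("ATGGCC", mut, strrep("CAC", 6)), ref,
                   max_mismatch = 2)
  hit <- names(one$counts)[one$counts > 0]
  expect_identical(ref$insert_nt[ref$clone_id == hit], src)

  # a read equidistant from two references goes unmapped
  refA <- strrep("A", 150)
  refB <- paste0("CC", strrep("A", 148))
  tiny <- structure(data.frame(clone_id = c("r1", "r2"),
                               insert_nt = c(refA, refB), count = c(5, 5)),
                    class = c("reference_library", "data.frame"))
  midway <- paste0("C", strrep("A", 149))  # distance 1 from both
  tie <- map_reads(paste0("ATGGCC", midway, strrep("CAC", 6)), tiny,
                   max_mismatch = 2)
  expect_equal(sum(tie$counts), 0)
  expect_equal(tie$mapping_rate, 0)
})

test_that("counts equal the simulator's multinomial draws when error-free", {
  lib <- generate_library(100, seed = 61)
  freq <- as.numeric(stats::rmultinom(1, 1e5, rep(1, 100))) / 1e5
  reads <- simulate_reads(freq, lib$orf_nt, depth = 20000, error_rate = 0,
                          seed = 62)
  src <- attr(reads, "source_clone")
  truth <- tabulate(src, nbins = 100)
  ref <- structure(data.frame(clone_id = lib$clone_id,
                              insert_nt = lib$insert_nt,
                              count = NA_real_),
                   class = c("reference_library", "data.frame"))
  m <- map_reads(reads, ref)
  expect_identical(as.integer(m$counts[lib$clone_id]), truth)
})

test_that("mapping rate stays near 1 at nominal error rates", {
  lib <- generate_library(300, seed = 71)
  ref <- structure(data.frame(clone_id = lib$clone_id,
                              insert_nt = lib$insert_nt,
                              count = NA_real_),
                   class = c("reference_library", "data.frame"))
  reads <- simulate_reads(rep(1 / 300, 300), lib$orf_nt, depth = 1e5,
                          error_rate = 0.001, seed = 72)
  m <- map_reads(reads, ref, max_mismatch = 2)
  expect_gte(m$mapping_rate, 0.99)
})

test_that("count matrix assembly zero-fills, validates, and round-trips", {
  counts <- list(
    s1 = c(a = 5, b = 3),
    s2 = c(b = 2, c = 9)
  )
  meta <- data.frame(sample = c("s1", "s2"), replicate = c(1, 1),
                     timepoint = c(1, 10))
  cm <- assemble_count_matrix(counts, meta)
  expect_identical(dim(cm$counts), c(3L, 2L))
  expect_identical(cm$counts["a", "s2"], 0L)
  expect_identical(cm$counts["c", "s1"], 0L)
  expect_equal(colSums(cm$counts), c(s1 = 8, s2 = 11))

  expect_error(assemble_count_matrix(counts,
    data.frame(sample = c("s1", "s1"), replicate = 1:2, timepoint = c(1, 1))),
    "duplicate|agree")

  path <- withr::local_tempfile(fileext = ".tsv")
  write_count_matrix(cm, path)
  back <- read_count_matrix(path)
  expect_identical(back$counts, cm$counts)
  expect_identical(back$samples$sample, cm$samples$sample)
})

test_that("low-representation filtering is exact and monotone", {
  m <- matrix(c(2, 3, 4, 6, 8, 12), nrow = 3,
              dimnames = list(c("a", "b", "c"), c("s1", "s2")))
  cm <- structure(list(counts = m,
                       samples = data.frame(sample = c("s1", "s2"),
                                            replicate = 1, timepoint = c(1, 10))),
                  class = "count_matrix")
  expect_identical(rownames(filter_low_representation(cm, 0)$counts),
                   c("a", "b", "c"))
  expect_identical(rownames(filter_low_representation(cm, 10)$counts),
                   c("b", "c"))
  # monotone over a threshold sweep
  kept <- lapply(c(0, 5, 8, 10, 12, 20),
                 function(t) rownames(filter_low_representation(cm, t)$counts))
  for (i in seq_len(length(kept) - 1))
    expect_true(all(kept[[i + 1]] %in% kept[[i]]))
})

test_that("reference FASTA round-trip preserves ids and sequences", {
  lib <- generate_library(20, seed = 81)
  ref <- structure(data.frame(clone_id = lib$clone_id,
                              insert_nt = lib$insert_nt, count = 1),
                   class = c("reference_library", "data.frame"))
  path <- withr::local_tempfile(fileext = ".fasta")
  write_reference_fasta(ref, path)
  back <- read_reference_fasta(path)
  expect_identical(back$clone_id, ref$clone_id)
  expect_identical(back$insert_nt, ref$insert_nt)
})
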