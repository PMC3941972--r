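test_that("k-mer index covers both strands and finds planted k-mers", {
  lib <- tibble::tibble(family_id = "f1", consensus = "ACGTACGGTTCAACGGTCAA")
  idx <- kmer_index(lib, k = 20)
  expect_equal(nrow(idx$entries), 2)  # one window per strand

  lib2 <- fixture_library(seed = 5, len = 120)
  idx2 <- kmer_index(lib2, k = 15)
  expect_equal(nrow(kmer_hits(idx2, strrep("A", 15))), 0)
  # planted k-mer positions equal a brute-force substring scan
  kmer <- substr(lib2$consensus[2], 37, 51)
  hits <- kmer_hits(idx2, kmer)
  plus <- hits[hits$strand == "+", ]
  oracle <- unlist(gregexpr(kmer, lib2$consensus, fixed = TRUE))
  oracle_tbl <- tibble::tibble(
    family_id = rep(lib2$family_id, times = vapply(
      gregexpr(kmer, lib2$consensus, fixed = TRUE),
      function(m) sum(m > 0), integer(1))),
    pos = oracle[oracle > 0]
  )
  expect_equal(dplyr::arrange(plus[, c("family_id", "pos")], family_id, pos),
               dplyr::arrange(oracle_tbl, family_id, pos))
})

test_that("index validates k against the library", {
  lib <- tibble::tibble(family_id = "f1", consensus = strrep("ACGT", 5))
  expect_error(kmer_index(lib, k = 25), "shortest consensus")
  expect_error(kmer_index(lib, k = 5))
})

test_that("exact and reverse-complement reads are assigned with identity 1", {
  lib <- fixture_library(seed = 8, len = 400)
  idx <- kmer_index(lib, k = 15)
  read_fwd <- substr(lib$consensus[1], 101, 200)
  read_rc <- revcomp(substr(lib$consensus[2], 51, 150))
  asg <- assign_reads(make_reads(c(read_fwd, read_rc)), idx)
  expect_equal(asg$family_id, c("famA", "famB"))
  expect_equal(asg$identity, c(1, 1))
  expect_equal(asg$strand, c("+", "-"))
  expect_equal(asg$c_start, c(101L, 51L))
  # aligned_seq is reported in consensus-forward orientation
  expect_identical(asg$aligned_seq[2], substr(lib$consensus[2], 51, 150))
})

test_that("the closer family wins and identities reflect substitution counts", {
  withr::with_seed(77, {
    shared <- random_dna(200)
    lib <- tibble::tibble(
      family_id = c("famA", "famB"),
      consensus = c(shared, substitute_n(shared, 40, seed = 3))
    )
  })
  idx <- kmer_index(lib, k = 15)
  read <- substitute_n(substr(lib$consensus[1], 51, 150), 5, seed = 9)
  asg <- assign_reads(make_reads(read), idx)
  expect_equal(asg$family_id, "famA")
  expect_equal(asg$identity, 0.95)
})

test_that("assignment agrees with a Smith-Waterman oracle on small instances", {
  withr::with_seed(2024, {
    lib <- tibble::tibble(
      family_id = sprintf("fam%02d", 1:5),
      consensus = replicate(5, random_dna(200))
    )
    idx <- kmer_index(lib, k = 11)
    picks <- purrr::map_dfr(1:40, function(i) {
      fam <- sample(5, 1)
      start <- sample(100, 1)
      read <- substr(lib$consensus[fam], start, start + 99)
      read <- substitute_n(read, sample(0:8, 1), seed = i)
      if (i %% 2 == 0) read <- revcomp(read)
      asg <- assign_reads(make_reads(read), idx, min_identity = 0.8)
      oracle <- sw_best_family(read, lib)
      sc <- sort(oracle$scores, decreasing = TRUE)
      tibble::tibble(impl = asg$family_id, oracle = oracle$family,
                     margin = sc[1] - sc[2])
    })
  })
  # compare wherever best and second-best are separated by >= 1 substitution
  clear <- picks$margin >= 2
  expect_gt(sum(clear), 30)
  expect_true(all(picks$impl[clear] == picks$oracle[clear]))
})

test_that("reads below identity or aligned-fraction thresholds are unassigned", {
  lib <- fixture_library(seed = 12, len = 300)
  idx <- kmer_index(lib, k = 15)
  noisy <- substitute_n(substr(lib$consensus[1], 1, 100), 30, seed = 4)
  asg <- assign_reads(make_reads(noisy), idx, min_identity = 0.85)
  expect_true(is.na(asg$family_id))
  # read hanging off the consensus end: aligned fraction below threshold
  over <- paste0(fixture_dna(80, 55), substr(lib$consensus[1], 1, 20))
  asg2 <- assign_reads(make_reads(over), idx, min_aligned_fraction = 0.5)
  expect_true(is.na(asg2$family_id))
})

test_that("count table aggregation equals a brute-force recount", {
  withr::with_seed(31, {
    lib <- fixture_library(seed = 31, len = 400)
    idx <- kmer_index(lib, k = 15)
    reads <- purrr::map_dfr(c("s1", "s2"), function(s) {
      n <- if (s == "s1") 60 else 30
      sq <- vapply(seq_len(n), function(i) {
        fam <- sample(2, 1)
        st <- sample(300, 1)
        substr(lib$consensus[fam], st, st + 99)
      }, character(1))
      dplyr::mutate(make_reads(sq, ids = sprintf("%s_r%03d", s, seq_len(n))),
                    strain = s)
    })
  })
  asg <- dplyr::bind_rows(lapply(split(reads, reads$strain), function(d) {
    dplyr::mutate(assign_reads(d, idx), strain = d$strain[1])
  }))
  denoms <- tibble::tibble(strain = c("s1", "s2"), mapped_reads = c(60L, 30L))
  ct <- count_table(asg, denoms)
  for (i in seq_len(nrow(ct))) {
    recount <- sum(asg$strain == ct$strain[i] &
                     !is.na(asg$family_id) &
                     asg$family_id == ct$family_id[i])
    expect_equal(ct$n_reads[i], recount)
  }
  expect_error(count_table(asg, denoms[1, ]), "missing denominator")
})

test_that("an empty assignment set yields an all-zero table", {
  asg <- tibble::tibble(strain = "s1", family_id = NA_character_)
  denoms <- tibble::tibble(strain = "s1", mapped_reads = 10L)
  ct <- count_table(asg, denoms, families = c("famA", "famB"))
  expect_true(all(ct$n_reads == 0))
})

test_that("RPM normalization is exact and scale-invariant", {
  ct <- tibble::tibble(
    strain = c("a", "a", "b"), family_id = c("x", "y", "x"),
    n_reads = c(500L, 137L, 0L),
    mapped_reads = c(1000000L, 24300000L, 500000L)
  )
  norm <- rpm_normalize(ct)
  expect_equal(norm$rpm, c(500, 1e6 * 137 / 24300000, 0))
  doubled <- rpm_normalize(dplyr::mutate(ct, n_reads = n_reads * 2L,
                                         mapped_reads = mapped_reads * 2L))
  expect_equal(doubled$rpm, norm$rpm)
  expect_error(rpm_normalize(dplyr::mutate(ct, mapped_reads = 0L)))
})

test_that("fold enrichment matches hand arithmetic and is reciprocal", {
  ct <- tibble::tibble(
    strain = rep(c("s160", "s9"), each = 2),
    family_id = rep(c("pol", "other"), 2),
    n_reads = c(270L, 50L, 10L, 50L),
    mapped_reads = rep(1000000L, 4)
  )
  norm <- rpm_normalize(ct)
  fe <- fold_enrichment(norm, c("s160", "s9"))
  expect_equal(fe$fold[fe$family_id == "pol"], 27)
  expect_equal(fe$fold[fe$family_id == "other"], 1)
  swapped <- fold_enrichment(norm, c("s9", "s160"))
  expect_equal(swapped$fold[swapped$family_id == "pol"], 1 / 27)
  # both zero -> undefined
  z <- rpm_normalize(tibble::tibble(
    strain = c("a", "b"), family_id = "x", n_reads = 0L,
    mapped_reads = 1000L
  ))
  expect_true(is.na(fold_enrichment(z, c("a", "b"))$fold))
})

test_that("chi-squared enrichment equals the Pearson formula", {
  # hand Pearson oracle on the 2x2 table [[r1, M1-r1], [r2, M2-r2]]
  pearson <- function(r1, M1, r2, M2) {
    o <- matrix(c(r1, M1 - r1, r2, M2 - r2), 2, byrow = TRUE)
    e <- outer(rowSums(o), colSums(o)) / sum(o)
    sum((o - e)^2 / e)
  }
  res <- chisq_enrichment(10, 1000, 1, 1000)
  expect_equal(res$statistic, pearson(10, 1000, 1, 1000), tolerance = 1e-12)
  expect_equal(res$statistic, 7.40, tolerance = 0.01)
  expect_equal(res$p_value, pchisq(res$statistic, 1, lower.tail = FALSE))

  withr::with_seed(6, {
    for (i in 1:20) {
      M1 <- sample(500:5000, 1); M2 <- sample(500:5000, 1)
      r1 <- sample(1:400, 1); r2 <- sample(1:400, 1)
      expect_equal(chisq_enrichment(r1, M1, r2, M2)$statistic,
                   pearson(r1, M1, r2, M2), tolerance = 1e-9)
    }
  })
})

test_that("chi-squared is zero on equal proportions and symmetric in rows", {
  eq <- chisq_enrichment(50, 1000, 100, 2000)
  expect_equal(eq$statistic, 0, tolerance = 1e-12)
  expect_equal(eq$p_value, 1)
  a <- chisq_enrichment(30, 900, 7, 1100)
  b <- chisq_enrichment(7, 1100, 30, 900)
  expect_equal(a$statistic, b$statistic)
  # zero margin undefined
  expect_true(is.na(chisq_enrichment(0, 1000, 0, 1000)$statistic))
})

test_that("coverage arithmetic matches hand evaluation", {
  expect_equal(coverage_estimate(43.7e6, 100, 2, 364e6), 24.0, tolerance = 0.01)
  expect_equal(coverage_estimate(37.6e6, 100, 2, 364e6), 20.66, tolerance = 0.01)
  expect_equal(coverage_estimate(500, 100, 2, 100000), 1.0)
  expect_error(coverage_estimate(100, 100, 2, 0), "genome_size")
})

test_that("simulated copy-number ratios are recovered by fold enrichment", {
  # single-k spot check at desk scale (the full k sweep runs in acceptance)
  k <- 10
  spec_len <- 1200
  fam <- function(nA, nB, seed) {
    te_family_spec("fam1", consensus_length = spec_len, tir_length = 100,
                   n_active_copies = c(A = nA, B = nB),
                   active_divergence = 0.005, n_degraded_copies = 0,
                   seed = seed)
  }
  gs <- build_genomes(fam(2 * k, 2, seed = 41), background_length = 300000,
                      seed = 42)
  ra <- simulate_reads(gs, mean_coverage = 4, strain = "A", seed = 43)
  rb <- simulate_reads(gs, mean_coverage = 4, strain = "B", seed = 44)
  idx <- kmer_index(gs$library, k = 15)
  asg <- dplyr::bind_rows(
    dplyr::mutate(assign_reads(ra, idx), strain = "A"),
    dplyr::mutate(assign_reads(rb, idx), strain = "B")
  )
  denoms <- tibble::tibble(strain = c("A", "B"),
                           mapped_reads = c(nrow(ra), nrow(rb)))
  rep <- enrichment_report(count_table(asg, denoms), c("A", "B"))
  se3 <- 3 * rep$fold * sqrt(1 / rep$n_reads_a + 1 / rep$n_reads_b)
  expect_lt(abs(rep$fold - k), se3)
})
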