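test_that("planted full copies are collected as consensus-spanning fragments", {
  withr::with_seed(101, {
    cons <- random_dna(600)
    genome <- paste0(random_dna(2000), cons, random_dna(1500), cons,
                     random_dna(1500), revcomp(cons), random_dna(2000))
  })
  fs <- collect_fragments(genome, cons, min_identity = 0.9)
  expect_equal(nrow(fs$fragments), 3)
  expect_true(all(fs$fragments$q_start == 1))
  expect_true(all(fs$fragments$q_end == 600))
  # oriented fragment sequences equal the consensus exactly
  expect_true(all(fs$fragments$sequence == cons))
})

test_that("fragments shorter than the length floor are removed", {
  withr::with_seed(102, {
    cons <- random_dna(600)
    genome <- paste0(random_dna(1000), substr(cons, 100, 179),  # 80 bp
                     random_dna(1000), substr(cons, 1, 250),    # 250 bp
                     random_dna(1000))
  })
  fs <- collect_fragments(genome, cons, min_length = 100, min_identity = 0.9)
  expect_equal(nrow(fs$fragments), 1)
  # greedy extension can gain a base or two of coincidental flank matches
  expect_lt(abs(fs$fragments$length - 250L), 4)
})

test_that("planted copy counts are recovered exactly on error-free simulation", {
  spec <- te_family_spec(consensus_length = 800, tir_length = 60,
                         n_active_copies = c(A = 6), active_divergence = 0,
                         n_degraded_copies = 0, seed = 103)
  gs <- build_genomes(spec, background_length = 60000, seed = 104)
  fs <- collect_fragments(gs$genomes[["A"]], gs$library$consensus,
                          min_identity = 0.9)
  expect_equal(nrow(fs$fragments), 6)
})

test_that("TIR-only hits are excluded when flagged", {
  withr::with_seed(105, {
    arm <- random_dna(150)
    body <- random_dna(700)
    cons <- paste0(arm, body, revcomp(arm))
    # plant a full copy and one solo left-TIR fragment
    genome <- paste0(random_dna(2000), cons, random_dna(2000), arm,
                     random_dna(2000))
  })
  tir <- detect_tir(cons, min_len = 50)
  fs_all <- collect_fragments(genome, cons, min_identity = 0.9,
                              exclude_tir = FALSE)
  fs_excl <- collect_fragments(genome, cons, min_identity = 0.9,
                               exclude_tir = TRUE, tir = tir)
  # the solo arm (and palindromic TIR self-hits) are TIR-only; the full copy
  # survives the exclusion
  expect_gt(nrow(fs_all$fragments), nrow(fs_excl$fragments))
  expect_equal(nrow(fs_excl$fragments), 1)
  expect_equal(fs_excl$fragments$q_start, 1L)
  expect_equal(fs_excl$fragments$q_end, 1000L)
  # removed hits cover essentially no TIR-external consensus
  removed <- dplyr::anti_join(fs_all$fragments, fs_excl$fragments,
                              by = c("g_start", "g_end", "strand"))
  interior_cov <- pmax(0, pmin(removed$q_end, tir$right_start - 1) -
                         pmax(removed$q_start, tir$left_end + 1) + 1)
  expect_true(all(interior_cov < 20))
})

test_that("pairwise distances follow the closed-form Jukes-Cantor map", {
  withr::with_seed(106, {
    s <- random_dna(1000)
    s10 <- substitute_n(s, 100, seed = 1)  # exactly p = 0.10
  })
  frags <- tibble::tibble(
    fragment_id = c("a", "b", "c"),
    q_start = 1L, q_end = 1000L,
    sequence = c(s, s10, s)
  )
  dm <- pairwise_distance(frags, correction = "jc", consensus_length = 1000)
  expect_equal(dm$p["a", "b"], 0.10)
  expect_equal(dm$d["a", "b"], -0.75 * log(1 - 4 * 0.10 / 3), tolerance = 1e-12)
  expect_equal(dm$d["a", "b"], 0.1073, tolerance = 1e-3)
  expect_equal(dm$d["a", "c"], 0)
  # symmetric, zero diagonal, and JC >= p
  expect_true(isSymmetric(dm$d))
  expect_true(all(diag(dm$d) == 0))
  expect_true(all(dm$d >= dm$p - 1e-12))
})

test_that("JC distances agree with an independent phylogenetics implementation", {
  withr::with_seed(115, {
    base <- random_dna(600)
    seqs <- c(base,
              mutate_dna(base, 0.05),
              mutate_dna(base, 0.12),
              mutate_dna(base, 0.20))
  })
  frags <- tibble::tibble(
    fragment_id = paste0("f", 1:4),
    q_start = c(1L, 1L, 1L, 101L),
    q_end = c(600L, 600L, 600L, 600L),
    sequence = c(seqs[1:3], substr(seqs[4], 101, 600))
  )
  dm <- pairwise_distance(frags, correction = "jc", consensus_length = 600)
  # oracle: ape's JC69 distance with pairwise deletion on the same alignment
  chm <- matrix("-", nrow = 4, ncol = 600)
  for (i in 1:4) {
    chm[i, frags$q_start[i]:frags$q_end[i]] <-
      strsplit(frags$sequence[i], "")[[1]]
  }
  rownames(chm) <- frags$fragment_id
  oracle <- as.matrix(ape::dist.dna(ape::as.DNAbin(tolower(chm)),
                                    model = "JC69", pairwise.deletion = TRUE))
  expect_equal(dm$d[rownames(oracle), colnames(oracle)], oracle,
               tolerance = 1e-9)
})

test_that("distances use only shared anchored columns", {
  frags <- tibble::tibble(
    fragment_id = c("left", "right", "full"),
    q_start = c(1L, 201L, 1L), q_end = c(300L, 400L, 400L),
    sequence = c(strrep("A", 300), strrep("A", 200), strrep("A", 400))
  )
  dm <- pairwise_distance(frags, correction = "none", min_shared = 50,
                          consensus_length = 400)
  expect_equal(dm$shared["left", "right"], 100L)  # columns 201-300
  expect_equal(dm$d["left", "right"], 0)
})

test_that("saturated pairs are flagged undefined with a warning", {
  withr::with_seed(107, {
    a <- strrep("A", 200)
    b <- strrep("C", 200)  # p = 1
    frags <- tibble::tibble(fragment_id = c("a", "b"), q_start = 1L,
                            q_end = 200L, sequence = c(a, b))
  })
  expect_warning(
    dm <- pairwise_distance(frags, correction = "jc", consensus_length = 200),
    "saturated"
  )
  expect_true(is.na(dm$d["a", "b"]))
})

test_that("neighbor joining is exact on an additive 4-taxon matrix", {
  # tree ((A:1,B:2):1,(C:3,D:4)); internal edge 1
  d <- matrix(c(0, 3, 5, 6,
                3, 0, 6, 7,
                5, 6, 0, 7,
                6, 7, 7, 0), 4, 4,
              dimnames = list(c("A", "B", "C", "D"), c("A", "B", "C", "D")))
  tree <- nj_tree(d)
  tb <- terminal_branch_lengths(tree)
  expect_equal(tb$branch_length[match(c("A", "B", "C", "D"), tb$leaf)],
               c(1, 2, 3, 4))
  internal <- setdiff(seq_along(tree$edge.length),
                      match(1:4, tree$edge[, 2]))
  expect_equal(tree$edge.length[internal], 1)
  # taxon order permutation leaves lengths unchanged
  perm <- c("C", "A", "D", "B")
  tree2 <- nj_tree(d[perm, perm])
  tb2 <- terminal_branch_lengths(tree2)
  expect_equal(tb2$branch_length[match(c("A", "B", "C", "D"), tb2$leaf)],
               c(1, 2, 3, 4))
})

test_that("three taxa resolve to the closed-form star lengths", {
  d <- matrix(c(0, 3, 4,
                3, 0, 5,
                4, 5, 0), 3, 3,
              dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
  tree <- nj_tree(d)
  tb <- terminal_branch_lengths(tree)
  # a = (AB + AC - BC)/2, etc.
  expect_equal(tb$branch_length[match(c("A", "B", "C"), tb$leaf)],
               c(1, 2, 3))
})

test_that("nj_tree rejects incomplete matrices", {
  d <- matrix(0, 3, 3, dimnames = list(letters[1:3], letters[1:3]))
  d[1, 2] <- d[2, 1] <- NA
  expect_error(nj_tree(d), "undefined")
})

test_that("terminal branch lengths parse from newick and round-trip", {
  tb <- terminal_branch_lengths("(A:0.1,B:0.2,(C:0.3,D:0.4):0.05);")
  expect_equal(tb$branch_length[match(c("A", "B", "C", "D"), tb$leaf)],
               c(0.1, 0.2, 0.3, 0.4))
  # star tree with equal lengths
  star <- terminal_branch_lengths("(A:0.5,B:0.5,C:0.5);")
  expect_true(all(star$branch_length == 0.5))
  # write then re-read
  tree <- ape::read.tree(text = "(A:0.1,B:0.2,(C:0.3,D:0.4):0.05);")
  tf <- tempfile(fileext = ".nwk")
  ape::write.tree(tree, tf)
  expect_equal(terminal_branch_lengths(tf), tb)
})

test_that("the molecular clock converts branch lengths linearly", {
  expect_equal(branch_length_to_age(0.10), 0.10 / (1.45e-9 * 10))
  expect_equal(round(branch_length_to_age(0.10) / 1e6), 7)  # about 7 My
  expect_equal(branch_length_to_age(0), 0)
  expect_equal(branch_length_to_age(0.029), 2.0e6)
  # doubling mu*g halves the age
  expect_equal(branch_length_to_age(0.1, 2.9e-9, 10),
               branch_length_to_age(0.1) / 2)
  expect_error(branch_length_to_age(-0.1))
})

test_that("age histograms count every leaf and find the mode", {
  ad <- age_distribution(rep(2.5, 12), bins = 5)
  expect_equal(sum(ad$histogram$count), 12)
  expect_equal(sum(ad$histogram$count > 0), 1)
  x <- c(rep(0.005, 8), rep(0.15, 5))
  ad2 <- age_distribution(x, bins = 15)
  expect_equal(sum(ad2$histogram$count), 13)
  expect_lt(ad2$mode_mid, 0.05)
  expect_error(age_distribution(numeric(0)))
})

test_that("a two-epoch history yields a bimodal branch-length distribution", {
  spec <- te_family_spec(consensus_length = 1000, tir_length = 80,
                         n_active_copies = c(A = 8),
                         active_divergence = 0.005,
                         n_degraded_copies = 10,
                         degraded_divergence_range = c(0.10, 0.20),
                         truncation_fraction_range = c(0.4, 0.9),
                         seed = 108)
  gs <- build_genomes(spec, background_length = 150000, seed = 109)
  res <- fragment_ages(gs$genomes[["A"]], gs$library$consensus,
                       min_identity = 0.6, exclude_tir = FALSE)
  expect_gte(nrow(res$ages), 15)
  recent <- res$ages$branch_length < 0.05
  old <- res$ages$branch_length >= 0.05
  expect_gte(sum(recent), 6)
  expect_gte(sum(old), 6)
  # recent burst dates under 1 My; ancient cohort in the My range
  expect_true(all(res$ages$age_years[recent] < 1e6))
  expect_true(all(res$ages$age_years[old] > 2e6))
})
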