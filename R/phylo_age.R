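#' Collect element fragments from a genome, anchored to the consensus
#'
#' Local matches of the consensus in the genome above the identity threshold
#' are collected; fragments shorter than `min_length` are dropped, and (when
#' `exclude_tir` is set and TIR intervals are supplied) hits covering fewer
#' than `tir_interior_min` bp outside the terminal inverted repeats are
#' excluded, since TIR-only hits carry no element-internal signal. Each fragment's sequence is oriented to the
#' consensus forward strand and anchored at its consensus interval, so the
#' set of fragments forms a consensus-coordinate alignment (the
#' blast-output-as-alignment construction).
#'
#' @param genome Genome DNA string.
#' @param consensus Element consensus DNA string.
#' @param min_identity Identity threshold for a hit to be kept (stand-in for
#'   an E-value cutoff).
#' @param min_length Minimum fragment length in bp.
#' @param exclude_tir Drop hits that are (almost) contained in a TIR interval.
#' @param tir Optional one-row tibble from [detect_tir()] giving the TIR
#'   intervals on the consensus.
#' @param tir_interior_min Minimum bp of TIR-external consensus a kept
#'   fragment must cover when `exclude_tir` is set.
#' @param k Seed length for the local matcher.
#' @return A list of class `te_fragment_set`: `fragments` (tibble:
#'   `fragment_id`, `g_start`, `g_end`, `strand`, `q_start`, `q_end`,
#'   `length`, `identity`, `sequence` in consensus orientation) and
#'   `consensus_length`.
#' @export
collect_fragments <- function(genome, consensus, min_identity = 0.6,
                              min_length = 100L, exclude_tir = FALSE,
                              tir = NULL, k = 12L, tir_interior_min = 20L) {
  hits <- find_local_matches(genome, consensus, k = k,
                             min_length = min_length,
                             min_identity = min_identity)
  if (exclude_tir && !is.null(tir) && nrow(tir) == 1 && nrow(hits) > 0) {
    interior_lo <- tir$left_end + 1L
    interior_hi <- tir$right_start - 1L
    interior_cov <- pmax(0L, pmin(hits$q_end, interior_hi) -
                           pmax(hits$q_start, interior_lo) + 1L)
    hits <- hits[interior_cov >= tir_interior_min, , drop = FALSE]
  }
  seqs <- if (nrow(hits) == 0) character(0) else {
    substring(genome, hits$s_start, hits$s_end)
  }
  minus <- hits$strand == "-"
  if (any(minus)) seqs[minus] <- revcomp(seqs[minus])
  frags <- tibble::tibble(
    fragment_id = sprintf("frag_%03d", seq_len(nrow(hits))),
    g_start = hits$s_start, g_end = hits$s_end, strand = hits$strand,
    q_start = hits$q_start, q_end = hits$q_end,
    length = hits$length, identity = hits$identity, sequence = seqs
  )
  structure(
    list(fragments = frags, consensus_length = nchar(consensus)),
    class = "te_fragment_set"
  )
}

#' Pairwise distances between anchored fragments
#'
#' p-distance over consensus columns where both fragments have bases, with
#' optional Jukes-Cantor correction `d = -(3/4) log(1 - 4p/3)`. Pairs with
#' `p >= 0.75` are saturated (undefined under JC) and are set to `NA` with a
#' warning; pairs sharing fewer than `min_shared` columns likewise.
#'
#' @param fragments A `te_fragment_set` (or its `fragments` tibble plus
#'   `consensus_length`).
#' @param correction `"jc"` (default) or `"none"` (raw p-distance).
#' @param min_shared Minimum shared ungapped columns for a defined distance.
#' @param consensus_length Needed only when `fragments` is a bare tibble.
#' @return A list of class `te_distmat`: `d` (distance matrix), `p`
#'   (p-distance matrix), `shared` (shared-column counts), `correction`.
#' @export
pairwise_distance <- function(fragments, correction = c("jc", "none"),
                              min_shared = 30L, consensus_length = NULL) {
  correction <- match.arg(correction)
  if (inherits(fragments, "te_fragment_set")) {
    consensus_length <- fragments$consensus_length
    fragments <- fragments$fragments
  }
  stopifnot(!is.null(consensus_length), nrow(fragments) >= 2)
  n <- nrow(fragments)
  codes <- matrix(NA_integer_, nrow = n, ncol = consensus_length)
  for (i in seq_len(n)) {
    ch <- seq_chars(fragments$sequence[i])
    codes[i, fragments$q_start[i]:fragments$q_end[i]] <- match(ch, DNA_BASES)
  }
  p <- matrix(0, n, n, dimnames = list(fragments$fragment_id,
                                       fragments$fragment_id))
  shared <- matrix(0L, n, n, dimnames = dimnames(p))
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      both <- !is.na(codes[i, ]) & !is.na(codes[j, ])
      ns <- sum(both)
      shared[i, j] <- shared[j, i] <- ns
      pij <- if (ns > 0) mean(codes[i, both] != codes[j, both]) else NA_real_
      p[i, j] <- p[j, i] <- pij
    }
  }
  d <- p
  undefined <- shared < min_shared & !diag(TRUE, n)
  if (correction == "jc") {
    sat <- p >= 0.75 & !diag(TRUE, n)
    undefined <- undefined | sat
    d <- -0.75 * log(pmax(1 - 4 * p / 3, .Machine$double.eps))
  }
  if (any(undefined, na.rm = TRUE)) {
    warning(sum(undefined, na.rm = TRUE) / 2,
            " fragment pair(s) saturated or with too few shared sites; ",
            "distances set to NA")
    d[undefined] <- NA_real_
  }
  diag(d) <- 0
  structure(
    list(d = d, p = p, shared = shared, correction = correction),
    class = "te_distmat"
  )
}

#' Neighbor-joining tree from a distance matrix
#'
#' Standard neighbor-joining (via ape); negative branch lengths are clamped
#' to zero and the total clamped deficit reported as a message.
#'
#' @param d A `te_distmat`, `dist`, or complete symmetric matrix, n >= 3.
#' @return An `ape::phylo` tree with branch lengths in substitutions/bp.
#' @export
nj_tree <- function(d) {
  if (inherits(d, "te_distmat")) d <- d$d
  if (inherits(d, "dist")) d <- as.matrix(d)
  if (any(is.na(d))) {
    stop("distance matrix has undefined entries; ",
         "remove saturated fragments before tree building")
  }
  stopifnot(nrow(d) >= 3)
  tree <- ape::nj(as.dist(d))
  neg <- tree$edge.length < 0
  if (any(neg)) {
    message("clamped ", sum(neg), " negative branch length(s), total deficit ",
            signif(-sum(tree$edge.length[neg]), 3))
    tree$edge.length[neg] <- 0
  }
  tree
}

#' Terminal (pendant) branch lengths of a tree
#'
#' @param tree An `ape::phylo` tree with branch lengths, or a path to /
#'   string of newick (parsed with `ape::read.tree`).
#' @return A tibble with `leaf` and `branch_length` (substitutions/bp).
#' @export
terminal_branch_lengths <- function(tree) {
  if (is.character(tree)) {
    tree <- if (file.exists(tree)) ape::read.tree(tree) else ape::read.tree(text = tree)
  }
  stopifnot(inherits(tree, "phylo"))
  if (is.null(tree$edge.length)) stop("tree has no branch lengths")
  ntip <- length(tree$tip.label)
  edge_idx <- match(seq_len(ntip), tree$edge[, 2])
  tibble::tibble(
    leaf = tree$tip.label,
    branch_length = tree$edge.length[edge_idx]
  )
}

#' Convert branch lengths to ages via a molecular clock
#'
#' `age_years = L / (substitution_rate * generations_per_year)`, with L the
#' terminal branch length in substitutions per bp. Defaults are the
#' Drosophila clock used for dating TE fragments: 1.45e-9
#' substitutions/bp/generation and 10 generations per year, under which
#' L = 0.10 corresponds to about 7 million years.
#'
#' @param branch_length Branch length(s), substitutions/bp (>= 0).
#' @param substitution_rate Substitutions per bp per generation.
#' @param generations_per_year Generations per year.
#' @return Age(s) in years.
#' @export
branch_length_to_age <- function(branch_length,
                                 substitution_rate = 1.45e-9,
                                 generations_per_year = 10) {
  stopifnot(all(branch_length >= 0), substitution_rate > 0,
            generations_per_year > 0)
  branch_length / (substitution_rate * generations_per_year)
}

#' Histogram summary of fragment ages or branch lengths
#'
#' @param x Numeric vector of ages (or branch lengths), length >= 1.
#' @param bins Number of equal-width bins, or an explicit breaks vector.
#' @return A list of class `te_age_distribution`: `histogram` (tibble with
#'   `lower`, `upper`, `mid`, `count`), `mode_mid` (midpoint of the fullest
#'   bin), `quantiles` (0/25/50/75/100%), `n`.
#' @export
age_distribution <- function(x, bins = 20L) {
  stopifnot(length(x) >= 1, all(is.finite(x)))
  breaks <- if (length(bins) > 1) bins else {
    rng <- range(x)
    if (diff(rng) == 0) rng <- rng + c(-0.5, 0.5) * max(abs(rng[1]), 1) * 0.01
    seq(rng[1], rng[2], length.out = bins + 1L)
  }
  h <- graphics::hist(x, breaks = breaks, plot = FALSE,
                      include.lowest = TRUE, right = FALSE)
  hist_tbl <- tibble::tibble(
    lower = utils::head(h$breaks, -1),
    upper = utils::tail(h$breaks, -1),
    mid = h$mids,
    count = h$counts
  )
  structure(
    list(
      histogram = hist_tbl,
      mode_mid = h$mids[which.max(h$counts)],
      quantiles = stats::quantile(x, c(0, 0.25, 0.5, 0.75, 1)),
      n = length(x)
    ),
    class = "te_age_distribution"
  )
}

#' Date element fragments in a genome
#'
#' Composition of [collect_fragments()], [pairwise_distance()], [nj_tree()],
#' [terminal_branch_lengths()] and [branch_length_to_age()]: the
#' fragment-dating stage in one call.
#'
#' @param genome Genome DNA string.
#' @param consensus Element consensus.
#' @param min_identity,min_length,exclude_tir,tir,k Passed to
#'   [collect_fragments()].
#' @param correction Distance correction, `"jc"` or `"none"`.
#' @param substitution_rate,generations_per_year Clock parameters.
#' @return A list of class `te_age_result`: `fragments`, `tree`, `ages`
#'   (tibble: `leaf`, `branch_length`, `age_years`), `summary` (a
#'   `te_age_distribution` over branch lengths), or with `tree`/`ages` NULL
#'   and a warning when fewer than 3 fragments are found.
#' @export
fragment_ages <- function(genome, consensus, min_identity = 0.6,
                          min_length = 100L, exclude_tir = TRUE, tir = NULL,
                          k = 12L, correction = "jc",
                          substitution_rate = 1.45e-9,
                          generations_per_year = 10) {
  fs <- collect_fragments(genome, consensus, min_identity = min_identity,
                          min_length = min_length, exclude_tir = exclude_tir,
                          tir = tir, k = k)
  if (nrow(fs$fragments) < 3) {
    warning("fewer than 3 fragments found; no tree or ages computed")
    return(structure(
      list(fragments = fs, tree = NULL, ages = NULL, summary = NULL),
      class = "te_age_result"
    ))
  }
  dm <- suppressWarnings(pairwise_distance(fs, correction = correction))
  d <- dm$d
  # fragments anchored to disjoint consensus intervals (or saturated pairs)
  # have undefined distances; drop the worst offenders until the matrix is
  # complete, as a distance tree needs every pair defined
  while (any(is.na(d)) && nrow(d) > 3) {
    worst <- which.max(rowSums(is.na(d)))
    d <- d[-worst, -worst, drop = FALSE]
  }
  if (any(is.na(d))) {
    warning("could not obtain a complete distance matrix; no tree computed")
    return(structure(
      list(fragments = fs, tree = NULL, ages = NULL, summary = NULL),
      class = "te_age_result"
    ))
  }
  n_dropped <- nrow(dm$d) - nrow(d)
  if (n_dropped > 0) {
    message("dropped ", n_dropped,
            " fragment(s) with undefined pairwise distances before tree building")
  }
  tree <- nj_tree(d)
  tb <- terminal_branch_lengths(tree)
  tb$age_years <- branch_length_to_age(tb$branch_length,
                                       substitution_rate,
                                       generations_per_year)
  structure(
    list(
      fragments = fs, tree = tree, ages = tb,
      summary = age_distribution(tb$branch_length)
    ),
    class = "te_age_result"
  )
}
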