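test_that("pairwise alignment attains the exhaustive-search optimum", {
  # the documented example scoring
  a <- msa(c(x = "ACGT")); b <- msa(c(y = "AGT"))
  p <- align_params(match = 1, mismatch = -1, gap_open = -2, gap_extend = -1)
  merged <- profile_profile_align(a, b, p)
  expect_equal(attr(merged, "score"),
               oracle_pairwise_best("ACGT", "AGT", 1, -1, -2, -1))
  expect_equal(ncol(merged), 4)  # one gap in the shorter sequence
  expect_identical(ungap(merged)[["y"]], "AGT")

  set.seed(31)
  p2 <- align_params()  # package defaults
  for (rep in 1:25) {
    s1 <- random_seq(sample(2:7, 1)); s2 <- random_seq(sample(2:7, 1))
    m <- profile_profile_align(msa(c(x = s1)), msa(c(y = s2)), p2)
    expect_equal(attr(m, "score"),
                 oracle_pairwise_best(s1, s2, p2$match, p2$mismatch,
                                      p2$gap_open, p2$gap_extend),
                 tolerance = 1e-9)
  }
})

test_that("profile merging induces both inputs exactly and keeps their homologies", {
  set.seed(32)
  for (rep in 1:15) {
    sa <- random_seqset(sample(2:4, 1), c(8, 14))
    sb <- random_seqset(sample(2:4, 1), c(8, 14))
    names(sb) <- paste0("q", seq_along(sb))
    A <- random_alignment_of(sa)
    B <- random_alignment_of(sb)
    M <- profile_profile_align(A, B)
    indA <- induced_subalignment(M, rownames(A))
    indB <- induced_subalignment(M, rownames(B))
    expect_identical(as.character(indA)[rownames(A)], as.character(A))
    expect_identical(as.character(indB)[rownames(B)], as.character(B))
    expect_true(all(homology_pairs(A) %in% homology_pairs(M)))
  }
  expect_error(profile_profile_align(msa(c(a = "AC")), msa(c(a = "AC"))), "share")
})

test_that("identical profiles stack column-for-column with no added gaps", {
  A <- msa(c(a1 = "AC-GT", a2 = "ACTG-"))
  B <- msa(c(b1 = "AC-GT", b2 = "ACTG-"))
  M <- profile_profile_align(A, B)
  expect_equal(ncol(M), ncol(A))
})

test_that("profile DP matches exhaustive search over monotone column merges", {
  # oracle: enumerate every interleaving of A and B columns, score with the
  # same column-pair scores and occupancy-scaled affine gap costs
  score_ops <- function(ops, S, occA, occB, open, ext) {
    i <- 0; j <- 0; total <- 0; prev <- "s"
    for (op in ops) {
      if (op == 1) { i <- i + 1; j <- j + 1; total <- total + S[i, j]; prev <- "m" }
      else if (op == 2) {
        i <- i + 1
        total <- total + (if (prev == "x") ext else open) * occA[i]
        prev <- "x"
      } else {
        j <- j + 1
        total <- total + (if (prev == "y") ext else open) * occB[j]
        prev <- "y"
      }
    }
    total
  }
  enum_best <- function(S, occA, occB, open, ext) {
    la <- nrow(S); lb <- ncol(S)
    best <- -Inf
    rec <- function(i, j, ops) {
      if (i == la && j == lb) {
        best <<- max(best, score_ops(ops, S, occA, occB, open, ext))
        return(invisible(NULL))
      }
      if (i < la && j < lb) rec(i + 1, j + 1, c(ops, 1))
      if (i < la) rec(i + 1, j, c(ops, 2))
      if (j < lb) rec(i, j + 1, c(ops, 3))
    }
    rec(0, 0, integer(0))
    best
  }
  set.seed(33)
  for (rep in 1:8) {
    A <- random_alignment_of(random_seqset(2, c(4, 5)), L = 5)
    B <- random_alignment_of(setNames(random_seqset(2, c(4, 6)), c("y1", "y2")), L = 6)
    p <- align_params()
    pa <- dcmsa:::profile_of(A); pb <- dcmsa:::profile_of(B)
    S <- t(pa$freq) %*% dcmsa:::substitution_matrix(p) %*% pb$freq
    M <- profile_profile_align(A, B, p)
    expect_equal(attr(M, "score"),
                 enum_best(S, pa$occ, pb$occ, p$gap_open, p$gap_extend),
                 tolerance = 1e-9)
  }
})

test_that("the built-in aligner reproduces inputs and handles tiny cases", {
  one <- align_subset(new_seqs(c(a = "ACGT")))
  expect_identical(unname(as.character(one)), "ACGT")
  two <- align_subset(new_seqs(c(a = "ACGT", b = "ACGT")))
  expect_equal(ncol(two), 4)
  expect_false(any(unclass(two) == "-"))
  set.seed(34)
  seqs <- new_seqs(random_seqset(9, c(30, 50)))
  aln <- align_subset(seqs)
  expect_setequal(rownames(aln), names(seqs))
  expect_identical(sort(ungap(aln)), sort(unclass(seqs)))
})

test_that("transitivity merge induces every subset and every edge merge", {
  # three subsets in a chain, constructed by hand
  s1 <- msa(c(a = "AC-G", b = "ACTG"))
  s2 <- msa(c(c = "ACG", d = "A-G"))
  s3 <- msa(c(e = "AG", f = "AG"))
  g <- merge_graph(list(s1, s2, s3), rbind(c(1L, 2L), c(2L, 3L)))
  full <- transitivity_merge(g)
  expect_setequal(rownames(full), c("a", "b", "c", "d", "e", "f"))
  for (sub in list(s1, s2, s3)) {
    ind <- induced_subalignment(full, rownames(sub))
    expect_identical(as.character(ind)[rownames(sub)], as.character(sub))
  }
  for (e in g$edges) {
    ind <- induced_subalignment(full, rownames(e$aln))
    expect_identical(as.character(ind)[rownames(e$aln)], as.character(e$aln))
  }

  # single node: unchanged; two nodes: the edge merge itself
  g1 <- merge_graph(list(s1), matrix(integer(0), ncol = 2))
  expect_identical(as.character(transitivity_merge(g1)), as.character(s1))
  g2 <- merge_graph(list(s1, s2), rbind(c(1L, 2L)))
  expect_identical(as.character(transitivity_merge(g2))[rownames(g2$edges[[1]]$aln)],
                   as.character(g2$edges[[1]]$aln))
})

test_that("iterating on few sequences degenerates to a single subset alignment", {
  set.seed(36)
  seqs <- new_seqs(random_seqset(6, c(20, 30)))
  res <- pasta_iterate(seqs, pasta_config(iterations = 1, max_subset = 50))
  expect_identical(as.character(res$alignment)[names(seqs)],
                   as.character(align_subset(seqs))[names(seqs)])
})

test_that("a boost iteration with the same aligner still yields a valid alignment", {
  sim <- sim_fixture(n = 12, root_length = 60, seed = 41)
  cfg <- pasta_config(iterations = 1, max_subset = 6,
                      boost_aligner = subset_aligner(), boost_max_subset = 6)
  res <- pasta_iterate(sim$leaf_sequences, cfg)
  expect_equal(length(res$history), 3L)  # init + 1 iteration + boost
  expect_identical(sort(ungap(res$alignment)),
                   sort(unclass(sim$leaf_sequences)))
})

test_that("external subset aligners are validated and their failures surfaced", {
  seqs <- new_seqs(c(a = "ACGTACGT", b = "ACGTACGT", c = "ACGAACGT"))
  # a well-behaved external tool emulated with a shell copy (inputs equal length)
  spec <- subset_aligner("external", command = "cat {input} > {output}")
  aln <- align_subset(seqs, spec)
  expect_setequal(rownames(aln), names(seqs))
  # failing command propagates stderr
  bad <- subset_aligner("external", command = "echo boom >&2; false # {input} {output}")
  expect_error(align_subset(seqs, bad), "boom")
  # output that loses sequences is rejected
  lossy <- subset_aligner("external",
                          command = "head -n 2 {input} > {output}")
  expect_error(align_subset(seqs, lossy), "lost")
  expect_error(subset_aligner("external", command = "noplaceholders"),
               "placeholders")
})
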