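test_that("identical alignments score 100/100/100 and degenerate estimates 0", {
  set.seed(81)
  aln <- random_alignment_of(random_seqset(5, c(10, 15)))
  sc <- alignment_scores(aln, aln)
  expect_equal(c(sc$precision_pct, sc$recall_pct, sc$tc_pct), c(100, 100, 100))

  # every sequence in its own block: no shared columns at all
  seqs <- ungap(aln)
  L <- sum(nchar(seqs))
  m <- matrix("-", length(seqs), L, dimnames = list(names(seqs), NULL))
  at <- 0
  for (i in seq_along(seqs)) {
    ch <- strsplit(seqs[[i]], "")[[1]]
    m[i, at + seq_along(ch)] <- ch
    at <- at + length(ch)
  }
  block <- msa(m)
  sc0 <- alignment_scores(block, aln)
  expect_equal(sc0$recall_pct, 0)
  expect_equal(sc0$tc_pct, 0)
})

test_that("alignment scores agree with the brute-force enumerator, including lowercase handling", {
  set.seed(82)
  for (rep in 1:20) {
    seqs <- random_seqset(sample(3:6, 1), c(8, 20))
    est <- random_alignment_of(seqs, lowercase_frac = sample(c(0, 0.25), 1))
    ref <- random_alignment_of(seqs)
    o <- oracle_scores(est, ref)
    s <- alignment_scores(est, ref)
    expect_equal(s$precision_pct, o$precision_pct, tolerance = 1e-12)
    expect_equal(s$recall_pct, o$recall_pct, tolerance = 1e-12)
    expect_equal(s$tc_pct, o$tc_pct, tolerance = 1e-12)
  }
  expect_error(alignment_scores(random_alignment_of(random_seqset(3)),
                                random_alignment_of(random_seqset(4))),
               "different sequence sets")
})

test_that("precision equals recall when pair counts match, and TC degrades under column splitting", {
  ref <- msa(c(a = "AC-GT", b = "ACTGT"))
  est <- msa(c(a = "A-CGT", b = "ACTGT"))
  sc <- alignment_scores(est, ref)
  expect_equal(sc$est_pairs, sc$ref_pairs)
  expect_equal(sc$precision_pct, sc$recall_pct)
  expect_equal(sc$recall_pct, 75)  # 3 of the 4 reference pairs survive

  # splitting a column of the estimate cannot raise TC
  base <- msa(c(a = "ACGT", b = "ACGT", c = "ACGT"))
  split1 <- msa(c(a = "ACG-T", b = "ACG-T", c = "AC-GT"))
  expect_lt(alignment_scores(split1, base)$tc_pct,
            alignment_scores(base, base)$tc_pct)
})

test_that("RF error uses the missing-from-estimate normalization and matches phangorn", {
  t1 <- ape::read.tree(text = "((a,b),(c,d));")
  expect_equal(rf_error(t1, t1), 0)
  t2 <- ape::read.tree(text = "((a,c),(b,d));")
  expect_equal(rf_error(t2, t1), 100)
  expect_error(rf_error(t1, ape::read.tree(text = "((a,b),(c,e));")), "leaf sets")

  set.seed(83)
  for (rep in 1:25) {
    est <- ape::unroot(ape::rtree(8))
    ref <- ape::unroot(ape::rtree(8))
    # binary unrooted trees: missing count = symmetric distance / 2
    rf_sym <- phangorn::RF.dist(est, ref)
    expect_equal(rf_error(est, ref), 100 * (rf_sym / 2) / (8 - 3))
    expect_equal(rf_error(est, est), 0)
  }
})

test_that("delta-RF composes the two RF errors and can be negative", {
  set.seed(84)
  true_tree <- ape::unroot(ape::rtree(8))
  ta <- ape::unroot(ape::rtree(8))
  tb <- ape::unroot(ape::rtree(8))
  expect_equal(delta_rf(ta, ta, true_tree), 0)
  expect_equal(delta_rf(ta, true_tree, true_tree), rf_error(ta, true_tree))
  expect_equal(delta_rf(ta, tb, true_tree),
               rf_error(ta, true_tree) - rf_error(tb, true_tree))
  expect_lt(delta_rf(true_tree, ta, true_tree), 0)
})

test_that("dataset summaries match hand counts", {
  clean <- msa(c(a = "ACGT", b = "ACGT"))
  s <- dataset_summary(clean)
  expect_equal(s$p_distance_avg_pct, 0)
  expect_equal(s$gaps_per_seq, 0)
  expect_equal(s$pct_blank, 0)
  expect_equal(s$n_sites, 4)

  two <- msa(c(a = "AC-G", b = "A-TG"))
  s2 <- dataset_summary(two)
  expect_equal(s2$gaps_per_seq, 1)
  expect_equal(s2$gap_len_avg, 1)
  expect_equal(s2$pct_blank, 25)
  expect_equal(s2$p_distance_avg_pct, 0)  # comparable positions 0 and 3 agree

  perm <- msa(as.character(two)[c("b", "a")])
  expect_equal(dataset_summary(perm)$pct_blank, s2$pct_blank)
})

test_that("paired one-sided t-tests match closed-form arithmetic and BH dominates Bonferroni", {
  a <- c(5.1, 4.9, 5.3, 5.0, 5.2, 4.8, 5.4, 5.1, 5.0, 5.2)
  b <- c(4.8, 4.7, 5.0, 4.9, 5.0, 4.9, 5.1, 4.8, 4.9, 5.0)
  d <- a - b
  t_hand <- mean(d) / (sd(d) / sqrt(10))
  p_hand <- 1 - pt(t_hand, df = 9)
  res <- paired_comparison(a, b, "greater")
  expect_equal(res$t, t_hand, tolerance = 1e-9)
  expect_equal(res$p_value, p_hand, tolerance = 1e-9)

  expect_equal(suppressWarnings(paired_comparison(a, a, "greater"))$p_value, 0.5)
  expect_warning(res0 <- paired_comparison(b + 1, b, "greater"), "zero variance")
  expect_equal(res0$p_value, 0)
  expect_warning(res1 <- paired_comparison(b - 1, b, "greater"), "zero variance")
  expect_equal(res1$p_value, 1)

  set.seed(85)
  pv <- runif(20)^2
  bh <- bh_adjust(pv, 0.05)
  bonf <- pv <= 0.05 / length(pv)
  expect_true(all(bh[bonf]))  # BH rejections are a superset of Bonferroni's
})
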