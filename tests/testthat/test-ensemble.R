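test_that("profile HMM construction follows the 50% match rule with hand-checked counts", {
  one <- build_hmm(msa(c(x = "ACG")), pseudocount = 1e-12)
  expect_equal(one$match_cols, 1:3)
  expect_equal(round(one$emissions, 6),
               matrix(c(1, 0, 0, 0, 0, 1, 0, 0, 0, 0, 1, 0), 3, 4,
                      byrow = TRUE, dimnames = list(NULL, c("A", "C", "G", "T"))))

  two <- build_hmm(msa(c(x = "ACG", y = "ACG")), pseudocount = 0.1)
  expect_equal(two$match_cols, 1:3)
  # insert states unused: M->I stays at the smoothing floor (< pseudocount)
  expect_lt(max(two$tM[, 2]), 0.1)
  expect_equal(two$tM[1, 2], 0.1 / 1.3, tolerance = 1e-9)  # alpha / (1 + 3 alpha)

  # 3 x 6 hand alignment; column 4 is 2/3 gapped and must not be a match state
  aln <- msa(c(x = "ACT-GG", y = "AC--GG", z = "GCTA-G"))
  h <- build_hmm(aln, pseudocount = 1e-12)
  expect_equal(h$match_cols, c(1L, 2L, 3L, 5L, 6L))
  expect_false(4L %in% h$match_cols)
  # hand counts: match column 1 holds A,A,G
  expect_equal(unname(h$emissions[1, ]), c(2/3, 0, 1/3, 0), tolerance = 1e-9)
  expect_equal(unname(h$emissions[2, ]), c(0, 1, 0, 0), tolerance = 1e-9)

  expect_error(build_hmm(msa(c(x = "A---", y = "-A--", z = "--A-", w = "---A"))),
               "50")
})

test_that("forward bitscores match full path enumeration on toy models", {
  set.seed(61)
  for (rep in 1:10) {
    rows <- random_seqset(sample(1:3, 1), c(2, 4))
    names(rows) <- paste0("r", seq_along(rows))
    aln <- align_subset(new_seqs(rows))
    h <- build_hmm(aln, pseudocount = 0.1)
    if (nrow(h$emissions) > 4) next
    q <- random_seq(sample(1:5, 1))
    fwd <- score_query(h, q)
    null <- sum(log2(h$background[match(strsplit(q, "")[[1]], c("A", "C", "G", "T"))]))
    expect_equal(fwd, unname(log2(oracle_forward_prob(h, q)) - null), tolerance = 1e-6)
  }
})

test_that("hand-computable one-hot model scores behave as expected", {
  h <- build_hmm(msa(c(x = "ACG")), pseudocount = 1e-12)
  # perfect match: emission terms alone give sum(log2(1/0.25)) = 6 bits
  expect_equal(score_query(h, "ACG"), 6, tolerance = 1e-3)
  # symbols the model never saw score far below the null
  h2 <- build_hmm(msa(c(x = "AAAA", y = "AAAA")), pseudocount = 1e-6)
  expect_lt(score_query(h2, "TTTT"), 0)
  # duplicating backbone rows leaves the bitscore unchanged
  h4 <- build_hmm(msa(c(x = "AAAA", y = "AAAA", x2 = "AAAA", y2 = "AAAA")),
                  pseudocount = 1e-6)
  expect_equal(score_query(h2, "AATA"), score_query(h4, "AATA"), tolerance = 1e-9)
})

test_that("forward dominates Viterbi for every model/query pair", {
  set.seed(62)
  for (rep in 1:10) {
    sim <- sim_fixture(n = 6, root_length = 40, seed = 60 + rep)
    h <- build_hmm(sim$true_alignment)
    q <- random_seq(sample(10:40, 1))
    lt <- dcmsa:::hmm_log_tables(h)
    code <- dcmsa:::encode_query(q)
    fwd <- dcmsa:::hmm_forward_log2(code, lt$em, lt$tM, lt$tI, lt$tD, lt$ins, lt$amb)
    vit <- viterbi_query(h, q)$log2prob
    expect_gte(fwd, vit - 1e-9)
  }
})

test_that("backbone selection is a seed-deterministic partition", {
  set.seed(63)
  seqs <- new_seqs(random_seqset(100, c(20, 30)))
  sp <- select_backbone(seqs, 10, seed = 5)
  expect_equal(length(sp$backbone), 10)
  expect_equal(length(sp$queries), 90)
  expect_length(intersect(sp$backbone, sp$queries), 0)
  expect_setequal(c(sp$backbone, sp$queries), names(seqs))
  expect_identical(sp, select_backbone(seqs, 10, seed = 5))
  all_bb <- select_backbone(seqs, 200, seed = 5)
  expect_equal(length(all_bb$queries), 0)
})

test_that("the ensemble hierarchy retains every nested centroid subset", {
  sim <- sim_fixture(n = 8, root_length = 60, seed = 70, ins = 0, del = 0)
  aln <- sim$true_alignment
  tr <- make_model_tree(8, "balanced", 1, seed = 1)
  tr$tip.label <- rownames(aln)  # balanced topology over the same ids
  ens <- build_ensemble(aln, ape::unroot(tr), min_subset = 2)
  expect_equal(length(ens), 7)  # 1 + 2 + 4
  expect_setequal(ens[[1]]$ids, rownames(aln))
  expect_true(all(vapply(ens, function(e) length(e$ids), 1L) >= 2))
  expect_error(build_ensemble(aln, ape::unroot(tr), min_subset = 1), "min_subset")
})

test_that("a backbone sequence re-placed through the ensemble lands insert-free in its own columns", {
  # gap-free backbone: every column is a match state of every HMM, so a
  # re-queried backbone sequence must occupy exactly its original columns
  sim <- sim_fixture(n = 12, root_length = 80, seed = 71, ins = 0, del = 0)
  res <- pasta_iterate(sim$leaf_sequences, pasta_config(iterations = 1, max_subset = 6))
  ens <- build_ensemble(res$alignment, res$tree, min_subset = 4)
  for (id in c("t0001", "t0007")) {
    q <- setNames(ungap(res$alignment)[[id]], "requery")
    backbone_wo <- induced_subalignment(res$alignment, setdiff(rownames(res$alignment), id))
    p <- place_query(q, ens, backbone_wo)
    expect_length(p$inserts, 0)
    own_cols <- which(unclass(res$alignment)[id, ] != "-")
    expect_equal(p$cols$col, own_cols)
  }
})

test_that("a fragment of a backbone sequence maps to a contiguous run of its columns", {
  # one-hot backbone: the fragment must Viterbi-align to its source window
  # with flanking delete states and no inserts
  bb <- msa(c(r1 = "ACGTTGCA", r2 = "ACGTTGCA", r3 = "ACGTTGCA"))
  tr <- ape::read.tree(text = "(r1:1,(r2:1,r3:1):1);")
  ens <- build_ensemble(bb, tr, min_subset = 3, pseudocount = 0.01)
  p <- place_query(c(frag = "TTGC"), ens, bb)
  expect_length(p$inserts, 0)
  expect_equal(p$cols$col, 4:7)
})

test_that("query placement is independent of placement order and keeps the backbone immutable", {
  sim <- sim_fixture(n = 30, root_length = 80, seed = 72)
  seqs <- sim$leaf_sequences
  u <- upp_align(seqs, backbone_size = 10,
                 config = pasta_config(iterations = 1, max_subset = 6),
                 min_subset = 4, seed = 3)
  bb <- rownames(u$backbone_alignment)
  # backbone rows restricted to homologous columns are bit-identical
  ind <- induced_subalignment(u$alignment, bb)
  expect_identical(sort(as.character(ind)), sort(as.character(u$backbone_alignment)))
  # placements are per-query deterministic: rebuild in reverse order
  ens <- build_ensemble(u$backbone_alignment, u$backbone_tree, min_subset = 4)
  qids <- setdiff(names(seqs), bb)
  p_fwd <- lapply(qids, function(q) place_query(setNames(unclass(seqs)[q], q), ens, u$backbone_alignment))
  p_rev <- rev(lapply(rev(qids), function(q) place_query(setNames(unclass(seqs)[q], q), ens, u$backbone_alignment)))
  expect_equal(p_fwd, p_rev)
  a1 <- dcmsa:::assemble_extended(u$backbone_alignment, p_fwd)
  a2 <- dcmsa:::assemble_extended(u$backbone_alignment, p_rev)
  expect_identical(as.character(a1), as.character(a2))
})

test_that("full-set backbones return the backbone alignment unchanged", {
  sim <- sim_fixture(n = 8, root_length = 50, seed = 73)
  u <- upp_align(sim$leaf_sequences, backbone_size = 8,
                 config = pasta_config(iterations = 1, max_subset = 6), seed = 2)
  expect_identical(as.character(u$alignment), as.character(u$backbone_alignment))
  expect_length(u$placements, 0)
})
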