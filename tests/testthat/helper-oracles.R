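# Fixture generators and independent brute-force oracles used across the
# suite. Oracles deliberately avoid the package's own column machinery.

random_seq <- function(len) paste(sample(c("A", "C", "G", "T"), len, replace = TRUE),
                                  collapse = "")

random_seqset <- function(n, len_range = c(10, 20)) {
  lens <- sample(len_range[1]:len_range[2], n, replace = TRUE)
  setNames(vapply(lens, random_seq, character(1)), paste0("s", seq_len(n)))
}

# a random alignment of the given ungapped sequences: each row's residues are
# scattered over L columns at sorted random positions; optionally some cells
# are flagged non-homologous (lowercase)
random_alignment_of <- function(seqs, L = NULL, lowercase_frac = 0) {
  lens <- nchar(seqs)
  if (is.null(L)) L <- max(lens) + sample(0:8, 1)
  m <- matrix("-", length(seqs), L, dimnames = list(names(seqs), NULL))
  for (i in seq_along(seqs)) {
    pos <- sort(sample(L, lens[i]))
    ch <- strsplit(seqs[[i]], "")[[1]]
    if (lowercase_frac > 0) {
      flip <- runif(lens[i]) < lowercase_frac
      ch[flip] <- tolower(ch[flip])
    }
    m[i, pos] <- ch
  }
  keep <- colSums(m != "-") > 0
  msa(m[, keep, drop = FALSE])
}

# O(n^2 L^2)-style oracle: all homologous pairs by direct cell enumeration
oracle_pair_set <- function(aln) {
  m <- unclass(aln)
  ids <- rownames(m)
  pairs <- character(0)
  for (i in seq_len(nrow(m) - 1)) {
    si <- -1L
    for (col in seq_len(ncol(m))) {
      ci <- m[i, col]
      if (ci != "-") si <- si + 1L
      if (ci == "-" || ci != toupper(ci)) next
      for (j in (i + 1):nrow(m)) {
        cj_all <- m[j, seq_len(col)]
        sj <- sum(cj_all != "-") - 1L
        cj <- m[j, col]
        if (cj == "-" || cj != toupper(cj)) next
        a <- paste0(ids[i], ":", si); b <- paste0(ids[j], ":", sj)
        pairs <- c(pairs, if (ids[i] < ids[j]) paste0(a, "|", b) else paste0(b, "|", a))
      }
    }
  }
  pairs
}

# oracle precision/recall/TC by set operations on enumerated pairs/columns
oracle_scores <- function(est, ref) {
  pe <- oracle_pair_set(est)
  pr <- oracle_pair_set(ref)
  shared <- length(intersect(pe, pr))
  col_keys <- function(aln) {
    m <- unclass(aln)
    keys <- character(0)
    site <- rep(-1L, nrow(m))
    for (col in seq_len(ncol(m))) {
      lab <- character(0)
      for (i in seq_len(nrow(m))) {
        if (m[i, col] != "-") {
          site[i] <- site[i] + 1L
          if (m[i, col] == toupper(m[i, col])) {
            lab <- c(lab, paste0(rownames(m)[i], ":", site[i]))
          }
        }
      }
      if (length(lab)) keys <- c(keys, paste(sort(lab), collapse = "|"))
    }
    keys
  }
  rk <- col_keys(ref)
  list(precision_pct = 100 * shared / length(pe),
       recall_pct = 100 * shared / length(pr),
       tc_pct = 100 * sum(rk %in% col_keys(est)) / length(rk))
}

# exhaustive global affine pairwise alignment by recursion over all monotone
# alignments; gap run of length k costs open + (k-1) * ext
oracle_pairwise_best <- function(s1, s2, match, mismatch, open, ext) {
  a <- strsplit(s1, "")[[1]]; b <- strsplit(s2, "")[[1]]
  best <- -Inf
  rec <- function(i, j, prev, score) {
    if (i > length(a) && j > length(b)) {
      best <<- max(best, score)
      return(invisible(NULL))
    }
    if (i <= length(a) && j <= length(b)) {
      s <- if (a[i] == b[j]) match else mismatch
      rec(i + 1, j + 1, "m", score + s)
    }
    if (i <= length(a)) {
      g <- if (prev == "x") ext else open
      rec(i + 1, j, "x", score + g)
    }
    if (j <= length(b)) {
      g <- if (prev == "y") ext else open
      rec(i, j + 1, "y", score + g)
    }
  }
  rec(1, 1, "start", 0)
  best
}

# component sizes after deleting one edge of a phylo, by BFS on the raw
# edge list (independent of the package's postorder bookkeeping)
oracle_edge_split <- function(tree, edge_idx) {
  edges <- tree$edge[-edge_idx, , drop = FALSE]
  nodes <- sort(unique(as.vector(tree$edge)))
  adj <- lapply(setNames(vector("list", max(nodes)), seq_len(max(nodes))), identity)
  for (k in seq_len(nrow(edges))) {
    u <- edges[k, 1]; v <- edges[k, 2]
    adj[[u]] <- c(adj[[u]], v); adj[[v]] <- c(adj[[v]], u)
  }
  start <- tree$edge[edge_idx, 2]
  seen <- rep(FALSE, max(nodes)); seen[start] <- TRUE
  queue <- start
  while (length(queue)) {
    u <- queue[1]; queue <- queue[-1]
    for (v in adj[[u]]) if (!seen[v]) { seen[v] <- TRUE; queue <- c(queue, v) }
  }
  ntip <- length(tree$tip.label)
  side <- sort(tree$tip.label[which(seen[seq_len(ntip)])])
  list(side = side, other = sort(setdiff(tree$tip.label, side)))
}

oracle_best_max_component <- function(tree) {
  ntip <- length(tree$tip.label)
  sizes <- vapply(seq_len(nrow(tree$edge)), function(k) {
    sp <- oracle_edge_split(tree, k)
    if (length(sp$side) == 0 || length(sp$other) == 0) return(NA_integer_)
    max(length(sp$side), length(sp$other))
  }, 1L)
  min(sizes, na.rm = TRUE)
}

# forward probability of a query under a profile HMM by explicit enumeration
# of all state paths (Begin -> ... -> End); probabilities in plain space
oracle_forward_prob <- function(hmm, q) {
  code <- match(strsplit(toupper(q), "")[[1]], c("A", "C", "G", "T"))
  L <- nrow(hmm$emissions)
  n <- length(code)
  total <- 0
  trans <- function(type, k, dest) {
    tm <- switch(type, M = hmm$tM, I = hmm$tI, D = hmm$tD)
    tm[k + 1, dest]
  }
  # state: type in M/I/D, slot k; Begin = (M, 0); End = arriving at M slot L+1
  rec <- function(type, k, i, prob) {
    if (prob == 0) return(invisible(NULL))
    # end transition
    if (i == n) total <<- total + prob * trans(type, k, 1) * (if (k == L) 1 else 0)
    # to M_{k+1}
    if (k < L && i < n) {
      p <- trans(type, k, 1) * hmm$emissions[k + 1, code[i + 1]]
      rec("M", k + 1, i + 1, prob * p)
    }
    # to I_k
    if (i < n) {
      p <- trans(type, k, 2) * hmm$background[code[i + 1]]
      rec("I", k, i + 1, prob * p)
    }
    # to D_{k+1}
    if (k < L) rec("D", k + 1, i, prob * trans(type, k, 3))
    invisible(NULL)
  }
  rec("M", 0, 0, 1)
  total
}

# independent compatibility check: disjoint cells plus an acyclic pairwise
# precedence relation (DFS cycle detection)
oracle_columns_compatible <- function(columns) {
  cells <- unlist(lapply(columns, function(s) paste0(names(s), ":", s)))
  if (anyDuplicated(cells)) return(FALSE)
  n <- length(columns)
  prec <- matrix(FALSE, n, n)
  for (u in seq_len(n)) {
    for (v in seq_len(n)) {
      if (u == v) next
      shared <- intersect(names(columns[[u]]), names(columns[[v]]))
      for (id in shared) {
        if (columns[[u]][[id]] < columns[[v]][[id]]) prec[u, v] <- TRUE
        if (columns[[u]][[id]] > columns[[v]][[id]]) prec[v, u] <- TRUE
      }
    }
  }
  color <- rep(0L, n)  # 0 white, 1 gray, 2 black
  ok <- TRUE
  visit <- function(u) {
    color[u] <<- 1L
    for (v in which(prec[u, ])) {
      if (color[v] == 1L) { ok <<- FALSE; return(invisible(NULL)) }
      if (color[v] == 0L) visit(v)
      if (!ok) return(invisible(NULL))
    }
    color[u] <<- 2L
  }
  for (u in seq_len(n)) if (color[u] == 0L && ok) visit(u)
  ok
}

# maximum-weight compatible column subset by exhaustive search
oracle_pd_best_weight <- function(columns, weights) {
  n <- length(columns)
  best <- 0
  for (mask in 0:(2^n - 1)) {
    pick <- which(bitwAnd(mask, 2^(seq_len(n) - 1)) > 0)
    if (!length(pick)) next
    if (!oracle_columns_compatible(columns[pick])) next
    best <- max(best, sum(weights[pick]))
  }
  best
}

# simple simulation fixture used by several files
sim_fixture <- function(n = 20, root_length = 100, scale = 0.4, seed = 11,
                        ins = 0.02, del = 0.02) {
  tree <- make_model_tree(n, "birth-death", scale, seed = seed)
  model <- evolution_model(insertion_rate = ins, deletion_rate = del,
                           indel_mean_len = 2, root_length = root_length)
  simulate_msa(tree, model, seed = seed + 1000L)
}
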